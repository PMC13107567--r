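#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across reference genes of
#' the ratio of that sample's count to the gene's geometric mean across all
#' samples; reference genes are those with a strictly positive count in
#' every sample. Factors are rescaled to geometric mean 1.
#'
#' @param counts gene x sample matrix of non-negative counts, or an
#'   [sb_counts()] object.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "sb_counts")) counts <- counts$counts
  counts <- as.matrix(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    stop("no gene has positive counts in every sample; ",
         "size factors need a pseudo-reference fallback")
  }
  lg <- log(counts[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  s <- apply(exp(lg - geo), 2, stats::median)
  s <- s / exp(mean(log(s)))
  stats::setNames(s, colnames(counts))
}

# Method-of-moments NB dispersion per gene on size-factor-normalised counts.
# The male/female mean difference is removed before pooling: each value is
# shifted to the grand mean of its gene, then
#   alpha = max((s2 - mbar) / mbar^2, floor)
# with s2 the pooled variance on n - 2 df (two group means estimated).
mom_dispersion <- function(norm, is_male, floor = 1e-8) {
  n <- ncol(norm)
  mF <- rowMeans(norm[, !is_male, drop = FALSE])
  mM <- rowMeans(norm[, is_male, drop = FALSE])
  grand <- rowMeans(norm)
  adj <- norm
  adj[, !is_male] <- adj[, !is_male, drop = FALSE] - mF + grand
  adj[, is_male] <- adj[, is_male, drop = FALSE] - mM + grand
  s2 <- rowSums((adj - grand)^2) / (n - 2)
  alpha <- (s2 - grand) / grand^2
  alpha[!is.finite(alpha)] <- floor
  pmax(alpha, floor)
}

# Vectorised per-group NB maximum likelihood with known dispersion alpha and
# size-factor offsets: solves, per gene, sum_j (y_j - s_j m)/(1 + a s_j m) = 0
# for the group mean m by damped Newton. Returns the MLE and the Fisher
# information of log(m), I = sum_j mu_j / (1 + a mu_j).
nb_group_mle <- function(y, s, alpha, iter = 50, tol = 1e-10) {
  # y: genes x samples (one sex group); s: size factors; alpha: per gene
  m <- rowSums(y) / sum(s)                 # moment start (alpha = 0 MLE)
  zero <- m == 0
  m[zero] <- 1e-8
  for (it in seq_len(iter)) {
    mu <- outer(m, s)                      # genes x samples
    den <- 1 + alpha * mu
    g <- rowSums((y - mu) / den)
    gp <- -rowSums(sweep(1 / den^2, 2, s, "*") * (1 + alpha * y))
    step <- g / gp
    m_new <- m - step
    m_new <- pmax(m_new, m / 10)           # keep positive, damp overshoot
    if (max(abs(m_new - m) / pmax(m, 1e-8)) < tol) {
      m <- m_new
      break
    }
    m <- m_new
  }
  m[zero] <- 1e-8
  mu <- outer(m, s)
  info <- rowSums(mu / (1 + alpha * mu))
  list(m = m, info = info)
}

#' Call sex-biased genes within one species and body part
#'
#' Fits, per analysed gene, a negative-binomial log-link model of counts on
#' sex with median-of-ratios size factors as offsets and a per-gene
#' method-of-moments dispersion (floored at 1e-8), and tests the sex
#' coefficient with a two-sided Wald test. q-values are Benjamini-Hochberg
#' within the analysed gene set and categories follow the sign convention
#' log2fc = male relative to female (positive = male-biased).
#'
#' @param cm an [sb_counts()] object (any species/body parts; the subset is
#'   taken here).
#' @param species,body_part the stratum to analyse.
#' @param analyzed optional logical vector or character vector of gene ids
#'   defining the analysed set (e.g. a column of [filter_expressed()]);
#'   default: all genes.
#' @param fdr false discovery rate for the MB/FB calls (default 0.05).
#' @param p_reference reference distribution for the Wald statistic:
#'   `"t"` (default; df = n samples - 2, matching the plug-in variance at
#'   the study's small sample sizes) or `"normal"`.
#' @return data.frame with one row per gene: `gene_id`, `species`,
#'   `body_part`, `log2fc`, `se`, `p`, `q`, `category` (MB/FB/UB/NA).
#' @export
call_sex_bias <- function(cm, species, body_part, analyzed = NULL,
                          fdr = 0.05, p_reference = c("t", "normal")) {
  stopifnot(inherits(cm, "sb_counts"))
  p_reference <- match.arg(p_reference)
  sel <- cm$samples$species == species & cm$samples$body_part == body_part
  if (!any(sel)) stop("no samples for ", species, " ", body_part)
  meta <- cm$samples[sel, , drop = FALSE]
  y <- cm$counts[, sel, drop = FALSE]
  is_male <- meta$sex == "male"
  if (sum(is_male) < 2 || sum(!is_male) < 2) {
    stop("need at least 2 strains per sex in ", species, " ", body_part)
  }
  genes <- rownames(y)
  n_genes <- length(genes)
  if (is.null(analyzed)) {
    analyzed <- rep(TRUE, n_genes)
  } else if (is.character(analyzed)) {
    analyzed <- genes %in% analyzed
  }
  stopifnot(length(analyzed) == n_genes)

  s <- size_factors(y)
  norm <- sweep(y, 2, s, "/")
  allzero <- rowSums(y) == 0

  alpha <- mom_dispersion(norm, is_male)
  fitF <- nb_group_mle(y[, !is_male, drop = FALSE], s[!is_male], alpha)
  fitM <- nb_group_mle(y[, is_male, drop = FALSE], s[is_male], alpha)
  mF <- pmax(fitF$m, 1e-8)
  mM <- pmax(fitM$m, 1e-8)
  log2fc <- log2(mM / mF)
  se_ln <- sqrt(1 / fitF$info + 1 / fitM$info)
  se <- se_ln / log(2)
  z <- log(mM / mF) / se_ln
  p <- if (p_reference == "t") {
    2 * stats::pt(-abs(z), df = ncol(y) - 2)
  } else {
    2 * stats::pnorm(-abs(z))
  }

  callable <- analyzed & !allzero & is.finite(p)
  q <- rep(NA_real_, n_genes)
  q[callable] <- stats::p.adjust(p[callable], method = "BH")
  category <- rep(NA_character_, n_genes)
  category[callable] <- "UB"
  category[callable & q < fdr & log2fc > 0] <- "MB"
  category[callable & q < fdr & log2fc < 0] <- "FB"

  log2fc[!callable] <- NA_real_
  se[!callable] <- NA_real_
  p[!callable] <- NA_real_

  data.frame(gene_id = genes, species = species, body_part = body_part,
             log2fc = log2fc, se = se, p = p, q = q, category = category,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call sex bias for every species x body part in a study
#'
#' @param cm an [sb_counts()] object.
#' @param analyzed optional logical matrix from [filter_expressed()]
#'   (columns `species|body_part`).
#' @param fdr false discovery rate.
#' @param ... passed to [call_sex_bias()].
#' @return row-bound data.frame of calls for all strata.
#' @export
call_sex_bias_all <- function(cm, analyzed = NULL, fdr = 0.05, ...) {
  strata <- unique(cm$samples[, c("species", "body_part")])
  out <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    mask <- NULL
    if (!is.null(analyzed)) {
      key <- paste(strata$species[i], strata$body_part[i], sep = "|")
      if (!key %in% colnames(analyzed)) stop("no analyzed mask for ", key)
      mask <- analyzed[, key]
    }
    out[[i]] <- call_sex_bias(cm, strata$species[i], strata$body_part[i],
                              analyzed = mask, fdr = fdr, ...)
  }
  do.call(rbind, out)
}

#' Cross-species sharing spectrum of sex bias
#'
#' Restricted to genes with a non-NA category in every species of the given
#' body part, genes are classified as switchers (called MB in at least one
#' species and FB in at least one), as same-direction sex-biased in k
#' species (k = number of species where the gene is SB), or as unbiased in
#' all species.
#'
#' @param calls data.frame of sex-bias calls (as from [call_sex_bias_all()]).
#' @param body_part `"head"` or `"body"`.
#' @return list with `n_species`, `eligible` (gene count), `sb_in_k`
#'   (named integer vector, k = 1..n_species), `switchers`, `ub_all`.
#' @export
sharing_spectrum <- function(calls, body_part) {
  calls <- calls[calls$body_part == body_part, , drop = FALSE]
  species <- unique(calls$species)
  catm <- category_matrix(calls)
  keep <- rowSums(is.na(catm) | catm == "NA") == 0
  catm <- catm[keep, , drop = FALSE]
  n_mb <- rowSums(catm == "MB")
  n_fb <- rowSums(catm == "FB")
  switcher <- n_mb > 0 & n_fb > 0
  k_sb <- n_mb + n_fb
  sb_in_k <- vapply(seq_along(species), function(k) {
    sum(!switcher & k_sb == k)
  }, integer(1))
  names(sb_in_k) <- as.character(seq_along(species))
  res <- list(n_species = length(species), eligible = nrow(catm),
              sb_in_k = sb_in_k, switchers = sum(switcher),
              ub_all = sum(k_sb == 0))
  stopifnot(sum(sb_in_k) + res$switchers + res$ub_all == res$eligible)
  res
}

#' Gene x species category matrix from a calls table
#'
#' @param calls calls data.frame restricted to one body part.
#' @return character matrix (MB/FB/UB/NA), genes x species.
#' @export
category_matrix <- function(calls) {
  species <- unique(calls$species)
  genes <- unique(calls$gene_id)
  m <- matrix(NA_character_, length(genes), length(species),
              dimnames = list(genes, species))
  m[cbind(match(calls$gene_id, genes), match(calls$species, species))] <-
    calls$category
  m
}

#' Pairwise sex-bias switch table between two species
#'
#' Over genes with non-NA categories in both species, counts genes with the
#' same sex bias (both MB or both FB), unbiased in both, sex-biased in one
#' species only, or switched (MB in one, FB in the other).
#'
#' @param calls calls data.frame.
#' @param species_a,species_b the two species.
#' @param body_part body part to compare.
#' @return named integer vector `same_bias`, `UB_both`, `SB_one_only`,
#'   `switched`, plus `n` (the shared gene total).
#' @export
pairwise_switches <- function(calls, species_a, species_b, body_part) {
  sub <- calls[calls$body_part == body_part &
                 calls$species %in% c(species_a, species_b), , drop = FALSE]
  catm <- category_matrix(sub)[, c(species_a, species_b), drop = FALSE]
  keep <- rowSums(is.na(catm)) == 0
  a <- catm[keep, 1]
  b <- catm[keep, 2]
  out <- c(
    same_bias = sum((a == "MB" & b == "MB") | (a == "FB" & b == "FB")),
    UB_both = sum(a == "UB" & b == "UB"),
    SB_one_only = sum((a == "UB") != (b == "UB")),
    switched = sum((a == "MB" & b == "FB") | (a == "FB" & b == "MB")),
    n = sum(keep)
  )
  stopifnot(sum(out[1:4]) == out[["n"]])
  out
}
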