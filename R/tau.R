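#' Tissue-specificity index tau
#'
#' On (optionally log2(x+1)-transformed) tissue expression values x with
#' xhat = x / max(x), tau = sum(1 - xhat) / (n - 1): 0 for a uniform
#' positive profile, 1 for expression confined to a single tissue.
#'
#' @param profile non-negative numeric vector, one value per tissue
#'   (named or not); length >= 2.
#' @param transform `"log2p1"` (default) or `"none"`.
#' @return list: `tau` (NA for an all-zero profile), `n_tissues`,
#'   `top_tissue` (label or index of the maximum; ties broken by the
#'   alphabetically first label).
#' @export
tau <- function(profile, transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  if (length(profile) < 2) stop("tau needs at least 2 tissues")
  if (any(profile < 0) || anyNA(profile)) stop("profile must be non-negative")
  labels <- names(profile)
  if (is.null(labels)) labels <- as.character(seq_along(profile))
  if (all(profile == 0)) {
    return(list(tau = NA_real_, n_tissues = length(profile),
                top_tissue = NA_character_))
  }
  x <- if (transform == "log2p1") log2(profile + 1) else profile
  xhat <- x / max(x)
  t_val <- sum(1 - xhat) / (length(x) - 1)
  top <- labels[x == max(x)]
  list(tau = t_val, n_tissues = length(profile),
       top_tissue = sort(top)[1])
}

#' Tau for every gene of a tissue expression matrix
#'
#' @param tissue_matrix gene x tissue matrix of non-negative expression
#'   values (rownames = gene ids, colnames = tissue labels).
#' @param transform passed to [tau()].
#' @return data.frame: `gene_id`, `tau`, `n_tissues`, `top_tissue`.
#' @export
tau_table <- function(tissue_matrix, transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  tissue_matrix <- as.matrix(tissue_matrix)
  res <- apply(tissue_matrix, 1, tau, transform = transform)
  data.frame(gene_id = rownames(tissue_matrix),
             tau = vapply(res, `[[`, numeric(1), "tau"),
             n_tissues = ncol(tissue_matrix),
             top_tissue = vapply(res, `[[`, character(1), "top_tissue"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Association between tissue specificity and sex-bias magnitude
#'
#' Per species x body part x category (with at least `min_n` genes),
#' Spearman's rho between tau and `|log2fc|`; category contrasts compare
#' the per-species rho collections with a rank-sum test.
#'
#' @param taus data.frame from [tau_table()].
#' @param calls sex-bias calls data.frame.
#' @param min_n minimum genes per cell (default 3).
#' @return list with `cells` (per-stratum rho and p) and `contrasts`
#'   (pairwise category comparisons per body part).
#' @export
tau_bias_association <- function(taus, calls, min_n = 3) {
  calls <- calls[!is.na(calls$category) & calls$category != "NA", , drop = FALSE]
  calls$tau <- taus$tau[match(calls$gene_id, taus$gene_id)]
  calls <- calls[!is.na(calls$tau) & is.finite(calls$log2fc), , drop = FALSE]
  cells <- unique(calls[, c("species", "body_part", "category")])
  cells$n <- 0L; cells$rho <- NA_real_; cells$p <- NA_real_
  for (i in seq_len(nrow(cells))) {
    sel <- calls$species == cells$species[i] &
      calls$body_part == cells$body_part[i] &
      calls$category == cells$category[i]
    cells$n[i] <- sum(sel)
    if (sum(sel) >= min_n && stats::sd(calls$tau[sel]) > 0 &&
        stats::sd(abs(calls$log2fc[sel])) > 0) {
      ct <- suppressWarnings(
        stats::cor.test(calls$tau[sel], abs(calls$log2fc[sel]),
                        method = "spearman"))
      cells$rho[i] <- unname(ct$estimate)
      cells$p[i] <- ct$p.value
    }
  }
  contrasts <- list()
  for (bp in unique(cells$body_part)) {
    cats <- unique(cells$category[cells$body_part == bp])
    if (length(cats) < 2) next
    cmb <- utils::combn(sort(cats), 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cells$rho[cells$body_part == bp & cells$category == cmb[1, j]]
      b <- cells$rho[cells$body_part == bp & cells$category == cmb[2, j]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) >= 1 && length(b) >= 1) {
        wt <- suppressWarnings(stats::wilcox.test(a, b))
        contrasts[[length(contrasts) + 1]] <- data.frame(
          body_part = bp, category_a = cmb[1, j], category_b = cmb[2, j],
          mean_rho_a = mean(a), mean_rho_b = mean(b), p = wt$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(cells = cells,
       contrasts = if (length(contrasts)) do.call(rbind, contrasts) else NULL)
}

#' X-versus-autosome distribution of sex-biased genes
#'
#' Per species and body part, dot-chromosome and unknown genes are
#' excluded; for the X and the autosomes separately, the expected count in
#' each category is the class total times the overall category proportion,
#' and a chi-squared goodness-of-fit statistic is computed over
#' {MB, FB, UB}.
#'
#' @param calls sex-bias calls data.frame.
#' @param ann annotation data.frame with a `chromosome` column.
#' @return data.frame with one row per species x body_part x class x
#'   category: `n_class`, `observed`, `expected`, `obs_exp`, and the class
#'   chi-squared `statistic`, `df`, `p` (NA for an empty class).
#' @export
xa_enrichment <- function(calls, ann) {
  ann <- validate_annotation(ann)
  calls <- calls[!is.na(calls$category) & calls$category != "NA", , drop = FALSE]
  calls$chrom <- ann$chromosome[match(calls$gene_id, ann$gene_id)]
  calls <- calls[calls$chrom %in% c("X", "autosome"), , drop = FALSE]
  strata <- unique(calls[, c("species", "body_part")])
  cats <- c("MB", "FB", "UB")
  out <- list()
  for (i in seq_len(nrow(strata))) {
    d <- calls[calls$species == strata$species[i] &
                 calls$body_part == strata$body_part[i], , drop = FALSE]
    prop <- table(factor(d$category, levels = cats)) / nrow(d)
    for (cls in c("X", "autosome")) {
      dc <- d[d$chrom == cls, , drop = FALSE]
      n_cls <- nrow(dc)
      obs <- table(factor(dc$category, levels = cats))
      expd <- n_cls * prop
      if (n_cls == 0) {
        stat <- NA_real_; df <- NA_integer_; p <- NA_real_
      } else {
        use <- expd > 0
        stat <- sum((obs[use] - expd[use])^2 / expd[use])
        df <- sum(use) - 1L
        p <- stats::pchisq(stat, df, lower.tail = FALSE)
      }
      out[[length(out) + 1]] <- data.frame(
        species = strata$species[i], body_part = strata$body_part[i],
        chromosome_class = cls, category = cats, n_class = n_cls,
        observed = as.integer(obs), expected = as.numeric(expd),
        obs_exp = as.numeric(obs) / as.numeric(expd),
        statistic = stat, df = df, p = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
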