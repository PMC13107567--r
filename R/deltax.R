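#' Divergence-to-polymorphism expression selection statistic
#'
#' For one gene, sex and body part, with per-strain log2 expression in the
#' focal species (`x_focal`, m strains) and in the reference/outgroup
#' species (`x_ref`):
#' \deqn{d = (mean(x_F) - mean(x_R)) / mean(x_F)}
#' \deqn{r = (max(x_F) - min(x_F)) / mean(x_F)}
#' \deqn{f = (mN - 1) / (mN - m)}
#' \deqn{\Delta x = d f / r}
#' where `N` is the reference strain count (the study's most common strain
#' number). `|delta_x| > 1` flags putative directional selection, with the
#' sign giving the direction of regulation in the focal species. `delta_x`
#' is NA when the focal strains are all equal (zero observed polymorphism)
#' or when `mean(x_focal) <= 0`, with a reason code.
#'
#' @param x_focal numeric vector of per-strain log2 expression, length >= 2.
#' @param x_ref numeric vector for the reference species, length >= 1.
#' @param N reference strain count (>= 2).
#' @return list: `d`, `r`, `f`, `m`, `N`, `delta_x`, `selected`,
#'   `direction` (up/down/none/NA), `reason` (`ok`, `zero_range`,
#'   `nonpositive_mean`).
#' @export
delta_x <- function(x_focal, x_ref, N) {
  if (length(x_focal) < 2) stop("x_focal needs at least 2 strains")
  if (length(x_ref) < 1) stop("x_ref must be non-empty")
  stopifnot(N >= 2)
  m <- length(x_focal)
  mf <- mean(x_focal)
  f <- (m * N - 1) / (m * N - m)
  if (mf == 0) {
    return(list(d = NA_real_, r = NA_real_, f = f, m = m, N = N,
                delta_x = NA_real_, selected = NA, direction = NA_character_,
                reason = "nonpositive_mean"))
  }
  d <- (mf - mean(x_ref)) / mf
  r <- (max(x_focal) - min(x_focal)) / mf
  if (mf < 0) {
    return(list(d = d, r = r, f = f, m = m, N = N, delta_x = NA_real_,
                selected = NA, direction = NA_character_,
                reason = "nonpositive_mean"))
  }
  if (r == 0) {
    return(list(d = d, r = 0, f = f, m = m, N = N, delta_x = NA_real_,
                selected = NA, direction = NA_character_,
                reason = "zero_range"))
  }
  dx <- d * f / r
  direction <- if (dx > 1) "up" else if (dx < -1) "down" else "none"
  list(d = d, r = r, f = f, m = m, N = N, delta_x = dx,
       selected = abs(dx) > 1, direction = direction, reason = "ok")
}

#' Delta-x table for every focal species, sex and body part
#'
#' Computes [delta_x()] per gene from per-strain `log2(TPM + pseudocount)`
#' values, for each non-outgroup species against the designated outgroup.
#' A gene is eligible in a stratum when it is in the analysed set of the
#' focal species (if a mask is supplied) and at least one outgroup strain
#' expresses it (TPM > 0); otherwise the row carries NA with a reason.
#'
#' @param tpm an `sb_tpm` object.
#' @param outgroup reference species name.
#' @param N reference strain count used in the correction factor f
#'   (default 5).
#' @param pseudocount added to TPM before log2 (default 1).
#' @param analyzed optional logical matrix from [filter_expressed()].
#' @return data.frame: gene_id, species, sex, body_part, m, d, r, f,
#'   delta_x, selected, direction, reason.
#' @export
delta_x_table <- function(tpm, outgroup, N = 5, pseudocount = 1,
                          analyzed = NULL) {
  stopifnot(inherits(tpm, "sb_tpm"))
  meta <- tpm$samples
  if (!outgroup %in% meta$species) stop("outgroup not present: ", outgroup)
  species <- setdiff(unique(meta$species), outgroup)
  out <- list()
  genes <- rownames(tpm$tpm)
  for (bp in unique(meta$body_part)) {
    for (sx in unique(meta$sex)) {
      ref_sel <- meta$species == outgroup & meta$sex == sx & meta$body_part == bp
      if (!any(ref_sel)) next
      ref_tpm <- tpm$tpm[, ref_sel, drop = FALSE]
      ref_expressed <- rowSums(ref_tpm > 0) > 0
      xr <- log2(ref_tpm + pseudocount)
      mean_ref <- rowMeans(xr)
      for (sp in species) {
        sel <- meta$species == sp & meta$sex == sx & meta$body_part == bp
        if (!any(sel)) next
        xf <- log2(tpm$tpm[, sel, drop = FALSE] + pseudocount)
        m <- ncol(xf)
        mf <- rowMeans(xf)
        rng <- apply(xf, 1, max) - apply(xf, 1, min)
        f <- (m * N - 1) / (m * N - m)
        eligible <- ref_expressed
        if (!is.null(analyzed)) {
          key <- paste(sp, bp, sep = "|")
          if (!key %in% colnames(analyzed)) stop("no analyzed mask for ", key)
          eligible <- eligible & analyzed[, key]
        }
        d <- (mf - mean_ref) / mf
        r <- rng / mf
        dx <- d * f / r
        reason <- rep("ok", length(genes))
        reason[!eligible] <- "not_eligible"
        reason[eligible & mf <= 0] <- "nonpositive_mean"
        reason[eligible & mf > 0 & rng == 0] <- "zero_range"
        ok <- reason == "ok"
        dx[!ok] <- NA_real_
        selected <- ifelse(ok, abs(dx) > 1, NA)
        direction <- rep(NA_character_, length(genes))
        direction[ok] <- ifelse(dx[ok] > 1, "up",
                                ifelse(dx[ok] < -1, "down", "none"))
        out[[length(out) + 1]] <- data.frame(
          gene_id = genes, species = sp, sex = sx, body_part = bp, m = m,
          d = ifelse(mf != 0, d, NA_real_), r = ifelse(mf != 0, r, NA_real_),
          f = f, delta_x = dx, selected = selected, direction = direction,
          reason = reason, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Enrichment of putatively selected genes across sex-bias categories
#'
#' Within each species, body part and sex, the expected number of selected
#' genes in category c is `total_selected * n_c / n_total` (and likewise
#' for non-selected genes); a chi-squared goodness-of-fit statistic is
#' summed over categories, excluding (with a note) categories whose
#' expected selected or non-selected count is below 5.
#'
#' @param dx data.frame from [delta_x_table()].
#' @param calls sex-bias calls data.frame.
#' @param chromosome_class optional: restrict to genes on this chromosome
#'   class (`"X"` or `"autosome"`), requires `ann`.
#' @param ann annotation data.frame (needed with `chromosome_class`).
#' @return data.frame with one row per species x body_part x sex x
#'   category: observed/expected selected counts, obs/exp ratio, and the
#'   stratum chi-squared statistic, df and p (repeated per row);
#'   `excluded` marks low-expectation categories.
#' @export
selection_enrichment <- function(dx, calls, chromosome_class = NULL,
                                 ann = NULL) {
  if (!is.null(chromosome_class)) {
    if (is.null(ann)) stop("ann is required with chromosome_class")
    keep_genes <- ann$gene_id[ann$chromosome == chromosome_class]
    dx <- dx[dx$gene_id %in% keep_genes, , drop = FALSE]
  }
  key_dx <- paste(dx$gene_id, dx$species, dx$body_part, sep = "|")
  key_ca <- paste(calls$gene_id, calls$species, calls$body_part, sep = "|")
  dx$category <- calls$category[match(key_dx, key_ca)]
  dx <- dx[!is.na(dx$selected) & !is.na(dx$category) & dx$category != "NA", ,
           drop = FALSE]
  strata <- unique(dx[, c("species", "body_part", "sex")])
  out <- list()
  for (i in seq_len(nrow(strata))) {
    sel <- dx$species == strata$species[i] &
      dx$body_part == strata$body_part[i] & dx$sex == strata$sex[i]
    d <- dx[sel, , drop = FALSE]
    cats <- sort(unique(d$category))
    n_tot <- nrow(d)
    n_sel <- sum(d$selected)
    rows <- data.frame(strata[i, , drop = FALSE], category = cats,
                       row.names = NULL)
    rows$n <- as.integer(table(factor(d$category, levels = cats)))
    rows$observed <- as.integer(tapply(d$selected, factor(d$category, cats), sum))
    rows$expected <- n_sel * rows$n / n_tot
    rows$expected_nonsel <- (n_tot - n_sel) * rows$n / n_tot
    rows$obs_exp <- rows$observed / rows$expected
    rows$excluded <- rows$expected < 5 | rows$expected_nonsel < 5
    inc <- !rows$excluded
    if (sum(inc) >= 2) {
      obs_ns <- rows$n - rows$observed
      stat <- sum((rows$observed[inc] - rows$expected[inc])^2 / rows$expected[inc] +
                    (obs_ns[inc] - rows$expected_nonsel[inc])^2 /
                      rows$expected_nonsel[inc])
      df <- sum(inc) - 1
      rows$chisq <- stat
      rows$df <- df
      rows$p <- stats::pchisq(stat, df, lower.tail = FALSE)
    } else {
      rows$chisq <- NA_real_; rows$df <- NA_integer_; rows$p <- NA_real_
      if (any(rows$excluded)) {
        message("selection_enrichment: all usable cells excluded for ",
                paste(strata[i, ], collapse = " "))
      }
    }
    if (any(rows$excluded)) {
      message("selection_enrichment: expected count < 5, excluding ",
              paste(rows$category[rows$excluded], collapse = ","), " in ",
              paste(strata[i, ], collapse = " "))
    }
    out[[length(out) + 1]] <- rows
  }
  do.call(rbind, out)
}

#' Compare delta-x between the sexes
#'
#' Welch t-test on `|delta_x|` male vs female and Spearman correlation of
#' the signed values over genes with a complete male/female pair (NA pairs
#' dropped listwise).
#'
#' @param dx_f,dx_m data.frames from [delta_x_table()] for one stratum
#'   (same species/body part), female and male.
#' @return list: `n`, `mean_abs_female`, `mean_abs_male`, `t_statistic`,
#'   `t_p`, `rho`, `rho_p`; all NA with fewer than 3 complete pairs.
#' @export
dx_sex_comparison <- function(dx_f, dx_m) {
  v_m <- dx_m$delta_x[match(dx_f$gene_id, dx_m$gene_id)]
  ok <- !is.na(dx_f$delta_x) & !is.na(v_m)
  f <- dx_f$delta_x[ok]; m <- v_m[ok]
  if (length(f) < 3) {
    return(list(n = length(f), mean_abs_female = NA_real_,
                mean_abs_male = NA_real_, t_statistic = NA_real_,
                t_p = NA_real_, rho = NA_real_, rho_p = NA_real_))
  }
  if (stats::sd(abs(f)) == 0 && stats::sd(abs(m)) == 0) {
    tt <- list(statistic = 0, p.value = 1)
  } else {
    tt <- stats::t.test(abs(m), abs(f))
  }
  ct <- suppressWarnings(stats::cor.test(m, f, method = "spearman"))
  list(n = length(f), mean_abs_female = mean(abs(f)),
       mean_abs_male = mean(abs(m)), t_statistic = unname(tt$statistic),
       t_p = tt$p.value, rho = unname(ct$estimate), rho_p = ct$p.value)
}
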