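#' Classify a male/female expression-change pair
#'
#' Axis convention (printed in all output headers): x = female change,
#' y = male change; quadrant ii = both positive, iii = both negative
#' (the concordant pair), i = female up / male down, iv = female down /
#' male up. Exact zeros and NAs give quadrant NA. The size class is large
#' when the larger absolute change of the two sexes reaches the body-part
#' threshold (head 1, body 2 by default).
#'
#' @param delta_f,delta_m numeric vectors of female and male changes
#'   (log2 focal/ancestor).
#' @param body_part `"head"` or `"body"` (vector or scalar).
#' @param large_change named thresholds per body part.
#' @return data.frame `delta_f`, `delta_m`, `quadrant` (i/ii/iii/iv/NA),
#'   `concordant` (logical or NA), `size_class` (large/small/NA).
#' @export
classify_change <- function(delta_f, delta_m, body_part,
                            large_change = c(head = 1, body = 2)) {
  n <- max(length(delta_f), length(delta_m))
  delta_f <- rep_len(delta_f, n)
  delta_m <- rep_len(delta_m, n)
  body_part <- rep_len(body_part, n)
  ok <- is.finite(delta_f) & is.finite(delta_m) & delta_f != 0 & delta_m != 0
  quadrant <- rep(NA_character_, n)
  quadrant[ok & delta_f > 0 & delta_m > 0] <- "ii"
  quadrant[ok & delta_f < 0 & delta_m < 0] <- "iii"
  quadrant[ok & delta_f > 0 & delta_m < 0] <- "i"
  quadrant[ok & delta_f < 0 & delta_m > 0] <- "iv"
  concordant <- ifelse(ok, quadrant %in% c("ii", "iii"), NA)
  thr <- large_change[body_part]
  size_class <- ifelse(ok, ifelse(pmax(abs(delta_f), abs(delta_m)) >= thr,
                                  "large", "small"), NA_character_)
  data.frame(delta_f = delta_f, delta_m = delta_m, quadrant = quadrant,
             concordant = concordant, size_class = size_class,
             stringsAsFactors = FALSE)
}

#' Build classified change pairs for terminal gain/loss events
#'
#' Joins per-sex ancestral expression changes (from [ancestral_changes()])
#' to terminal-branch gain/loss turnover events and classifies each pair.
#'
#' @param changes data.frame from [ancestral_changes()].
#' @param events data.frame from [polarize_turnover()]; only single-tip
#'   branches with `gain_*`/`loss_*` events are used.
#' @param large_change thresholds per body part.
#' @return data.frame with gene/species/body_part, the event, and the
#'   classified pair columns.
#' @export
change_pairs <- function(changes, events,
                         large_change = c(head = 1, body = 2)) {
  ev <- events[grepl("^(gain|loss)_", events$event) &
                 !grepl(",", events$branch), , drop = FALSE]
  if (nrow(ev) == 0) {
    return(data.frame(gene_id = character(0), species = character(0),
                      body_part = character(0), event = character(0),
                      delta_f = numeric(0), delta_m = numeric(0),
                      quadrant = character(0), concordant = logical(0),
                      size_class = character(0), stringsAsFactors = FALSE))
  }
  key <- function(g, s, bp) paste(g, s, bp, sep = "|")
  chf <- changes[changes$sex == "female", , drop = FALSE]
  chm <- changes[changes$sex == "male", , drop = FALSE]
  kf <- key(chf$gene_id, chf$species, chf$body_part)
  km <- key(chm$gene_id, chm$species, chm$body_part)
  ke <- key(ev$gene_id, ev$branch, ev$body_part)
  df <- chf$delta[match(ke, kf)]
  dm <- chm$delta[match(ke, km)]
  cls <- classify_change(df, dm, ev$body_part, large_change)
  cbind(data.frame(gene_id = ev$gene_id, species = ev$branch,
                   body_part = ev$body_part, event = ev$event,
                   stringsAsFactors = FALSE),
        cls)
}

#' Summarise concordance of sex-specific expression changes
#'
#' Quadrant occupancy, concordant fractions (overall, among gains, among
#' losses, and within the large/small size classes), per-species Spearman
#' correlations of male vs female changes for gains and losses, a
#' head-vs-body chi-squared test on the 2 x 4 quadrant table, a rank test
#' comparing gain vs loss correlations, and a paired rank test comparing
#' head vs body correlations (paired by species).
#'
#' @param pairs data.frame from [change_pairs()].
#' @return nested list; see the elements `by_body_part`, `rho`,
#'   `head_vs_body_chisq`, `gain_vs_loss`, `head_vs_body_rho`.
#' @export
concordance_summary <- function(pairs) {
  pairs <- pairs[!is.na(pairs$quadrant), , drop = FALSE]
  pairs$etype <- sub("_(MB|FB)$", "", pairs$event)
  quad_levels <- c("i", "ii", "iii", "iv")

  per_bp <- list()
  for (bp in unique(pairs$body_part)) {
    p <- pairs[pairs$body_part == bp, , drop = FALSE]
    qc <- table(factor(p$quadrant, levels = quad_levels))
    frac <- function(sel) {
      if (!any(sel)) NA_real_ else mean(p$concordant[sel])
    }
    per_bp[[bp]] <- list(
      quadrant_counts = qc,
      n = nrow(p),
      frac_concordant = frac(rep(TRUE, nrow(p))),
      frac_concordant_gains = frac(p$etype == "gain"),
      frac_concordant_losses = frac(p$etype == "loss"),
      frac_concordant_large = frac(p$size_class == "large"),
      frac_concordant_small = frac(p$size_class == "small"))
  }

  cells <- unique(pairs[, c("species", "body_part", "etype")])
  cells$rho <- NA_real_
  cells$n <- 0L
  for (i in seq_len(nrow(cells))) {
    sel <- pairs$species == cells$species[i] &
      pairs$body_part == cells$body_part[i] & pairs$etype == cells$etype[i]
    cells$n[i] <- sum(sel)
    if (sum(sel) >= 3 && stats::sd(pairs$delta_f[sel]) > 0 &&
        stats::sd(pairs$delta_m[sel]) > 0) {
      cells$rho[i] <- stats::cor(pairs$delta_m[sel], pairs$delta_f[sel],
                                 method = "spearman")
    }
  }

  hb <- NULL
  if (all(c("head", "body") %in% pairs$body_part)) {
    tab <- rbind(head = table(factor(pairs$quadrant[pairs$body_part == "head"],
                                     levels = quad_levels)),
                 body = table(factor(pairs$quadrant[pairs$body_part == "body"],
                                     levels = quad_levels)))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) >= 2 && all(rowSums(tab) > 0)) {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      hb <- list(table = tab, statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value)
    }
  }

  gl <- NULL
  g <- cells$rho[cells$etype == "gain" & !is.na(cells$rho)]
  l <- cells$rho[cells$etype == "loss" & !is.na(cells$rho)]
  if (length(g) >= 1 && length(l) >= 1) {
    wt <- suppressWarnings(stats::wilcox.test(g, l))
    gl <- list(mean_rho_gain = mean(g), mean_rho_loss = mean(l),
               p = wt$p.value)
  }

  hbr <- NULL
  wide <- cells[cells$etype == "gain", , drop = FALSE]
  if (all(c("head", "body") %in% wide$body_part)) {
    sp <- intersect(wide$species[wide$body_part == "head"],
                    wide$species[wide$body_part == "body"])
    h <- wide$rho[match(paste(sp, "head"), paste(wide$species, wide$body_part))]
    b <- wide$rho[match(paste(sp, "body"), paste(wide$species, wide$body_part))]
    ok <- !is.na(h) & !is.na(b)
    if (sum(ok) >= 2) {
      wt <- suppressWarnings(stats::wilcox.test(h[ok], b[ok], paired = TRUE))
      hbr <- list(species = sp[ok], rho_head = h[ok], rho_body = b[ok],
                  p = wt$p.value)
    }
  }

  list(by_body_part = per_bp, rho = cells[, c("species", "body_part",
                                              "etype", "n", "rho")],
       head_vs_body_chisq = hb, gain_vs_loss = gl, head_vs_body_rho = hbr)
}
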