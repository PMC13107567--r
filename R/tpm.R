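#' Transcripts per million from counts and CDS lengths
#'
#' Per sample, each gene's count is divided by its CDS length (bp) to give a
#' length-normalised rate, and rates are rescaled so the sample sums to one
#' million. A sample with no counts at all yields an all-zero column with a
#' warning.
#'
#' @param cm an [sb_counts()] object.
#' @param ann annotation data.frame covering every gene in `cm`
#'   (see [read_annotation()]); all lengths must be known and positive.
#' @return An object of class `sb_tpm`: same structure as `sb_counts` but
#'   with real-valued TPM in `$tpm`.
#' @export
compute_tpm <- function(cm, ann) {
  stopifnot(inherits(cm, "sb_counts"))
  ann <- validate_annotation(ann)
  genes <- rownames(cm$counts)
  missing <- setdiff(genes, ann$gene_id)
  if (length(missing) > 0) {
    stop("annotation missing for gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  len <- ann$cds_length_bp[match(genes, ann$gene_id)]
  if (any(len <= 0)) stop("cds_length_bp must be positive")
  rate <- cm$counts / len
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("all-zero sample column(s): ",
            paste(colnames(cm$counts)[zero], collapse = ", "))
    tot[zero] <- 1  # leaves the column at zero
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  structure(list(tpm = tpm, samples = cm$samples), class = "sb_tpm")
}

#' @export
print.sb_tpm <- function(x, ...) {
  cat("sb_tpm:", nrow(x$tpm), "genes x", ncol(x$tpm), "samples\n")
  invisible(x)
}

#' Mean TPM per species / sex / body part
#'
#' Arithmetic mean over strains (one replicate each) for every combination
#' of the grouping columns present in the sample metadata.
#'
#' @param tpm an `sb_tpm` object.
#' @param by character vector of metadata columns to group by.
#' @return list with `values` (gene x group matrix, columns named by the
#'   `|`-joined group key) and `groups` (data.frame of group levels).
#' @export
group_mean_tpm <- function(tpm, by = c("species", "sex", "body_part")) {
  stopifnot(inherits(tpm, "sb_tpm"))
  meta <- tpm$samples
  key <- do.call(paste, c(meta[by], sep = "|"))
  levels_key <- unique(key)
  vals <- vapply(levels_key, function(k) {
    rowMeans(tpm$tpm[, key == k, drop = FALSE])
  }, numeric(nrow(tpm$tpm)))
  colnames(vals) <- levels_key
  groups <- unique(meta[by])
  rownames(groups) <- NULL
  list(values = vals, groups = groups)
}

#' Expressed-gene filter per species and body part
#'
#' A gene is analysed in a species x body-part group when its mean TPM over
#' strains reaches `threshold` in at least one sex of that group.
#'
#' @param tpm an `sb_tpm` object.
#' @param threshold minimum mean TPM (default 0.5).
#' @return logical matrix, genes x groups, with columns named
#'   `species|body_part`.
#' @export
filter_expressed <- function(tpm, threshold = 0.5) {
  stopifnot(inherits(tpm, "sb_tpm"), threshold >= 0)
  meta <- tpm$samples
  groups <- unique(meta[, c("species", "body_part")])
  out <- matrix(FALSE, nrow(tpm$tpm), nrow(groups),
                dimnames = list(rownames(tpm$tpm),
                                paste(groups$species, groups$body_part, sep = "|")))
  for (i in seq_len(nrow(groups))) {
    sel <- meta$species == groups$species[i] & meta$body_part == groups$body_part[i]
    if (!any(sel)) stop("empty species x body_part group")
    best <- rep(-Inf, nrow(tpm$tpm))
    for (sx in unique(meta$sex[sel])) {
      cols <- sel & meta$sex == sx
      best <- pmax(best, rowMeans(tpm$tpm[, cols, drop = FALSE]))
    }
    out[, i] <- best >= threshold
  }
  out
}

#' Expression divergence between two sample groups
#'
#' Divergence is 1 minus Spearman's rho between the per-gene mean TPM of the
#' two groups, over the supplied gene set.
#'
#' @param tpm an `sb_tpm` object.
#' @param group_a,group_b named lists of metadata filters, e.g.
#'   `list(species = "mel", sex = "female", body_part = "head")`.
#' @param genes optional character vector of gene ids (default: all).
#' @return list with `rho`, `divergence` (`1 - rho`), `n_genes`, and the two
#'   group descriptors. `rho` is `NA` when either mean-TPM vector is constant.
#' @export
expression_divergence <- function(tpm, group_a, group_b, genes = NULL) {
  stopifnot(inherits(tpm, "sb_tpm"))
  pick <- function(g) {
    sel <- rep(TRUE, nrow(tpm$samples))
    for (nm in names(g)) sel <- sel & tpm$samples[[nm]] %in% g[[nm]]
    if (!any(sel)) stop("no samples match group filter")
    rowMeans(tpm$tpm[, sel, drop = FALSE])
  }
  a <- pick(group_a)
  b <- pick(group_b)
  if (!is.null(genes)) {
    idx <- match(genes, rownames(tpm$tpm))
    if (anyNA(idx)) stop("unknown gene id in gene set")
    a <- a[idx]; b <- b[idx]
  }
  if (length(a) < 3) stop("need at least 3 genes")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    rho <- NA_real_
  } else {
    rho <- stats::cor(a, b, method = "spearman")
  }
  list(group_a = group_a, group_b = group_b, rho = rho,
       divergence = 1 - rho, n_genes = length(a))
}
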