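#' Brownian-motion maximum-likelihood ancestral states
#'
#' Joint ML reconstruction of a continuous trait under Brownian motion on a
#' rooted tree with branch lengths: every internal node takes the
#' precision-weighted (1 / branch length) average of its neighbours, which
#' is solved as one sparse linear system; this equals the generalised
#' least-squares solution under the BM covariance. Tip values are fixed at
#' the observations.
#'
#' @param tree a rooted binary `phylo` tree with positive internal branch
#'   lengths.
#' @param tip_values named numeric vector (names = tip labels), or a matrix
#'   with one row per gene and columns named by tip label.
#' @return For a vector input, a named numeric vector of internal-node
#'   values (names `node<N>` in `ape` numbering); for a matrix, a genes x
#'   internal-nodes matrix.
#' @export
asr_bm <- function(tree, tip_values) {
  validate_species_tree(tree)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  len <- tree$edge.length
  internal_edge <- edge[, 2] > ntip
  if (any(len[internal_edge] <= 0)) {
    stop("zero-length internal branch; collapse it before reconstruction")
  }
  if (any(len <= 0)) stop("zero-length branch; reconstruction needs positive lengths")

  one_row <- is.null(dim(tip_values))
  vals <- if (one_row) matrix(tip_values, nrow = 1,
                              dimnames = list(NULL, names(tip_values)))
          else as.matrix(tip_values)
  if (!setequal(colnames(vals), tree$tip.label)) {
    stop("tip_values names must match tree tip labels")
  }
  vals <- vals[, tree$tip.label, drop = FALSE]
  if (anyNA(vals) || any(!is.finite(vals))) stop("tip values must be finite")

  # A x = B' for internal nodes: A[i,i] = sum of neighbour weights,
  # A[i,k] = -w for internal neighbours, tips contribute w * value to B.
  A <- matrix(0, nnode, nnode)
  B <- matrix(0, nrow(vals), nnode)
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1] - ntip
    child <- edge[e, 2]
    w <- 1 / len[e]
    A[par, par] <- A[par, par] + w
    if (child > ntip) {
      ci <- child - ntip
      A[ci, ci] <- A[ci, ci] + w
      A[par, ci] <- A[par, ci] - w
      A[ci, par] <- A[ci, par] - w
    } else {
      B[, par] <- B[, par] + w * vals[, child]
    }
  }
  anc <- t(solve(A, t(B)))
  dimnames(anc) <- list(rownames(vals),
                        paste0("node", seq_len(nnode) + ntip))
  if (one_row) anc[1, ] else anc
}

#' Expression change relative to the reconstructed ancestor
#'
#' `log2(tpm_focal / tpm_anc)`; invalid (NA) whenever either value is
#' non-positive, which can happen for ancestors reconstructed on the raw
#' TPM scale.
#'
#' @param tpm_focal,tpm_anc numeric vectors (recycled).
#' @return list with `delta` (numeric, NA where invalid) and `valid`
#'   (logical).
#' @export
expression_change <- function(tpm_focal, tpm_anc) {
  valid <- is.finite(tpm_focal) & is.finite(tpm_anc) &
    tpm_focal > 0 & tpm_anc > 0
  delta <- rep(NA_real_, length(valid))
  delta[valid] <- log2(tpm_focal[valid] / tpm_anc[valid])
  list(delta = delta, valid = valid)
}

#' Terminal-branch expression changes for all genes
#'
#' For each species, sex and body part, reconstructs ancestral mean TPM at
#' every internal node with [asr_bm()] and returns the focal-vs-parent-node
#' change `log2(TPM_focal / TPM_anc)` for each terminal branch.
#'
#' @param tpm an `sb_tpm` object.
#' @param tree species tree whose tips match the species in `tpm`.
#' @param asr_scale `"tpm"` (raw mean TPM, default) or `"log2"`
#'   (reconstruct on `log2(TPM + 1)`); on the log scale ancestors are mapped
#'   back with `2^x - 1` before the ratio.
#' @return data.frame: `gene_id`, `species`, `sex`, `body_part`, `delta`,
#'   `valid`.
#' @export
ancestral_changes <- function(tpm, tree, asr_scale = c("tpm", "log2")) {
  stopifnot(inherits(tpm, "sb_tpm"))
  asr_scale <- match.arg(asr_scale)
  validate_species_tree(tree, unique(tpm$samples$species))
  ntip <- length(tree$tip.label)
  parent_of_tip <- tree$edge[match(seq_len(ntip), tree$edge[, 2]), 1]
  gm <- group_mean_tpm(tpm)
  genes <- rownames(tpm$tpm)
  out <- list()
  for (bp in unique(tpm$samples$body_part)) {
    for (sx in unique(tpm$samples$sex)) {
      keys <- paste(tree$tip.label, sx, bp, sep = "|")
      if (!all(keys %in% colnames(gm$values))) next
      tips <- gm$values[, keys, drop = FALSE]
      colnames(tips) <- tree$tip.label
      anc <- if (asr_scale == "log2") {
        2^asr_bm(tree, log2(tips + 1)) - 1
      } else {
        asr_bm(tree, tips)
      }
      for (i in seq_len(ntip)) {
        ch <- expression_change(tips[, i], anc[, parent_of_tip[i] - ntip])
        out[[length(out) + 1]] <- data.frame(
          gene_id = genes, species = tree$tip.label[i], sex = sx,
          body_part = bp, delta = ch$delta, valid = ch$valid,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# Clade table for polarization: one row per distinct bipartition of the
# rooted tree. Non-root edges keep their own bipartition; the two
# root-incident edges collapse to a single root split attributed to the
# smaller root-adjacent clade (ties: first in newick tip order).
polar_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1
  tipsets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tipsets[[i]] <- i
  # postorder accumulation of descendant tips
  po <- stats::reorder(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]
    child <- po$edge[e, 2]
    tipsets[[par]] <- c(tipsets[[par]], tipsets[[child]])
  }
  out <- list()
  root_children <- tree$edge[tree$edge[, 1] == root, 2]
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    below <- sort(tipsets[[child]])
    if (tree$edge[e, 1] == root) next  # handled once below
    out[[length(out) + 1]] <- list(below = below, root_split = FALSE)
  }
  # single root split: smaller side, ties by first tip in newick order
  sides <- lapply(root_children, function(ch) sort(tipsets[[ch]]))
  sizes <- lengths(sides)
  pick <- if (sizes[1] != sizes[2]) which.min(sizes)
          else which.min(vapply(sides, min, integer(1)))
  out[[length(out) + 1]] <- list(below = sides[[pick]], root_split = TRUE)
  out
}

polar_branch_label <- function(tree, tips) {
  paste(tree$tip.label[sort(tips)], collapse = ",")
}

#' Polarize lineage-specific sex-bias turnover on the tree
#'
#' For each gene and each branch of the rooted tree, a turnover event is
#' emitted when all species below the branch share one category, all other
#' species share another, and the two differ: a gain when the outside is
#' UB, a loss when the focal lineage is UB, a switch when both are
#' sex-biased. The two root-incident branches form a single bipartition
#' that cannot be polarized without an external outgroup; it is reported
#' once as `unpolarized_root_change` attributed to the smaller
#' root-adjacent clade (ties broken by newick tip order). Genes with any NA
#' category are skipped.
#'
#' @param categories character matrix (genes x species; values MB/FB/UB/NA)
#'   as from [category_matrix()], or a calls data.frame for one body part.
#' @param tree rooted binary `phylo`; tips must match the matrix columns.
#' @param body_part label copied into the output (default `NA`).
#' @return data.frame `gene_id`, `body_part`, `branch` (comma-joined tip
#'   labels in tree order), `event`.
#' @export
polarize_turnover <- function(categories, tree, body_part = NA_character_) {
  if (is.data.frame(categories)) categories <- category_matrix(categories)
  validate_species_tree(tree, colnames(categories))
  categories <- categories[, tree$tip.label, drop = FALSE]
  ntip <- length(tree$tip.label)
  bips <- polar_bipartitions(tree)
  keep <- rowSums(is.na(categories) | categories == "NA") == 0
  cat_ok <- categories[keep, , drop = FALSE]
  genes <- rownames(cat_ok)

  res_gene <- character(0); res_branch <- character(0); res_event <- character(0)
  all_tips <- seq_len(ntip)
  for (b in bips) {
    below <- b$below
    outside <- setdiff(all_tips, below)
    cb <- cat_ok[, below, drop = FALSE]
    co <- cat_ok[, outside, drop = FALSE]
    ub <- cb[, 1]
    uniform_b <- rowSums(cb != ub) == 0
    uo <- co[, 1]
    uniform_o <- rowSums(co != uo) == 0
    hit <- uniform_b & uniform_o & ub != uo
    if (!any(hit)) next
    c1 <- ub[hit]   # focal lineage category
    c2 <- uo[hit]   # outgroup category
    ev <- if (b$root_split) {
      rep("unpolarized_root_change", length(c1))
    } else {
      ifelse(c2 == "UB", paste0("gain_", c1),
        ifelse(c1 == "UB", paste0("loss_", c2),
          paste0("switch_", c2, "_to_", c1)))
    }
    res_gene <- c(res_gene, genes[hit])
    res_branch <- c(res_branch, rep(polar_branch_label(tree, below), length(c1)))
    res_event <- c(res_event, ev)
  }
  out <- data.frame(gene_id = res_gene,
                    body_part = rep(body_part, length(res_gene)),
                    branch = res_branch, event = res_event,
                    stringsAsFactors = FALSE)
  out[order(match(out$gene_id, genes), out$branch), , drop = FALSE]
}
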