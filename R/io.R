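#' Sample metadata validation
#'
#' Checks a sample-metadata data frame for the columns and invariants the
#' study design requires: one library per strain, sex and body part, with
#' `sex` in \{female, male\} and `body_part` in \{head, body\}.
#'
#' @param meta data.frame with columns `sample_id`, `species`, `strain`,
#'   `sex`, `body_part`.
#' @return The validated data.frame (character columns, row order preserved).
#' @export
validate_sample_meta <- function(meta) {
  req <- c("sample_id", "species", "strain", "sex", "body_part")
  missing <- setdiff(req, names(meta))
  if (length(missing) > 0) {
    stop("sample metadata lacks column(s): ", paste(missing, collapse = ", "))
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  for (col in req) meta[[col]] <- as.character(meta[[col]])
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  if (!all(meta$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'")
  }
  if (!all(meta$body_part %in% c("head", "body"))) {
    stop("body_part must be 'head' or 'body'")
  }
  key <- paste(meta$species, meta$strain, meta$sex, meta$body_part, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- meta[duplicated(key), , drop = FALSE]
    stop("duplicate (species, strain, sex, body_part) combination: ",
         paste(bad$species[1], bad$strain[1], bad$sex[1], bad$body_part[1]))
  }
  meta
}

#' Construct a count matrix object
#'
#' Bundles a gene x sample matrix of non-negative integer counts with its
#' sample metadata. Columns of `counts` are reordered to follow `samples`.
#'
#' @param counts numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); non-negative integers.
#' @param samples sample metadata, see [validate_sample_meta()].
#' @return An object of class `sb_counts` with elements `counts` and
#'   `samples`.
#' @export
sb_counts <- function(counts, samples) {
  samples <- validate_sample_meta(samples)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in counts")
  missing <- setdiff(samples$sample_id, colnames(counts))
  if (length(missing) > 0) {
    stop("samples in metadata missing from counts: ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(colnames(counts), samples$sample_id)
  if (length(extra) > 0) {
    stop("samples in counts missing from metadata: ",
         paste(extra, collapse = ", "))
  }
  counts <- counts[, samples$sample_id, drop = FALSE]
  if (anyNA(counts)) stop("counts contain missing cells")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != floor(counts))) {
    bad <- which(counts != floor(counts), arr.ind = TRUE)[1, ]
    stop("non-integer count for gene ", rownames(counts)[bad[1]],
         ", sample ", colnames(counts)[bad[2]])
  }
  structure(list(counts = counts, samples = samples), class = "sb_counts")
}

#' @export
print.sb_counts <- function(x, ...) {
  cat("sb_counts:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("species:", paste(unique(x$samples$species), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.sb_counts <- function(x) dim(x$counts)

#' Read a gene x sample count table with its metadata
#'
#' The count table is tab-separated, UTF-8, `#` comment lines ignored,
#' first column gene ids, remaining columns one per sample. The metadata
#' table is tab-separated with columns `sample_id`, `species`, `strain`,
#' `sex`, `body_part`. Samples are returned in metadata order.
#'
#' @param path path to the count table.
#' @param meta_path path to the sample metadata table.
#' @return An [sb_counts()] object.
#' @export
read_counts <- function(path, meta_path) {
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                            comment.char = "#", colClasses = "character")
  meta <- validate_sample_meta(meta)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE)
  if (ncol(tab) < 2) stop("count table needs a gene-id column plus samples")
  genes <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop("non-numeric or missing count for gene ", genes[bad[1]],
         ", sample ", colnames(mat)[bad[2]])
  }
  sb_counts(mat, meta)
}

#' Write a count table and metadata table
#'
#' @param cm an [sb_counts()] object.
#' @param path,meta_path output paths (tab-separated, with header).
#' @return Invisibly, `cm`.
#' @export
write_counts <- function(cm, path, meta_path) {
  stopifnot(inherits(cm, "sb_counts"))
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cm$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(cm)
}

#' Read a gene annotation table
#'
#' Tab-separated with columns `gene_id`, `cds_length_bp`, `chromosome`
#' (one of `X`, `autosome`, `dot`, `unknown`).
#'
#' @param path input path.
#' @return data.frame with validated columns.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_annotation(ann)
}

#' @rdname read_annotation
#' @param ann annotation data.frame to validate.
#' @export
validate_annotation <- function(ann) {
  req <- c("gene_id", "cds_length_bp", "chromosome")
  missing <- setdiff(req, names(ann))
  if (length(missing) > 0) {
    stop("annotation lacks column(s): ", paste(missing, collapse = ", "))
  }
  ann$gene_id <- as.character(ann$gene_id)
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene_id in annotation")
  ann$cds_length_bp <- as.numeric(ann$cds_length_bp)
  if (anyNA(ann$cds_length_bp) || any(ann$cds_length_bp < 1)) {
    stop("cds_length_bp must be >= 1 for every gene")
  }
  if (!all(ann$chromosome %in% c("X", "autosome", "dot", "unknown"))) {
    stop("chromosome must be one of X, autosome, dot, unknown")
  }
  ann
}

#' Write an annotation table
#' @param ann annotation data.frame.
#' @param path output path.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(validate_annotation(ann), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(ann)
}

#' Read a rooted species tree from newick
#'
#' Requires a single rooted, binary tree with a finite branch length on
#' every edge. If `species` is given the tip set must match it exactly.
#'
#' @param path path to a newick file.
#' @param species optional character vector of expected tip labels.
#' @return An `ape::phylo` tree.
#' @export
read_species_tree <- function(path, species = NULL) {
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) stop("expected a single tree")
  if (is.null(tree)) stop("could not parse newick file: ", path)
  validate_species_tree(tree, species)
}

#' @rdname read_species_tree
#' @param tree a `phylo` object to validate.
#' @export
validate_species_tree <- function(tree, species = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length) ||
      any(!is.finite(tree$edge.length))) {
    stop("every edge must have a finite branch length")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) stop("tree must be binary (fully resolved)")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  if (!is.null(species) && !setequal(tree$tip.label, species)) {
    stop("tree tips do not match the declared species set")
  }
  tree
}

#' Write a species tree to newick
#' @param tree a `phylo` object.
#' @param path output path.
#' @export
write_species_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(tree)
}
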