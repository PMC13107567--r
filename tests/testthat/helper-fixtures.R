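# Small in-code fixtures shared across test files.

six_species_tree <- function() default_species_tree()

# A tiny hand-built count study: 2 species x 2 strains x 2 sexes x 1 body
# part, 3 genes.
tiny_counts <- function() {
  meta <- expand.grid(strain = c("s1", "s2"), sex = c("female", "male"),
                      species = c("spA", "spB"), body_part = "head",
                      stringsAsFactors = FALSE)
  meta$sample_id <- with(meta, paste(species, strain, sex, body_part, sep = "_"))
  meta <- meta[, c("sample_id", "species", "strain", "sex", "body_part")]
  counts <- matrix(rpois(3 * nrow(meta), 50), 3,
                   dimnames = list(paste0("g", 1:3), meta$sample_id))
  sb_counts(counts, meta)
}

# Write a counts/meta pair to temp files, returning the two paths.
write_tmp_counts <- function(cm) {
  p <- tempfile(fileext = ".tsv"); m <- tempfile(fileext = ".tsv")
  write_counts(cm, p, m)
  c(counts = p, meta = m)
}

# Dense independent reconstruction oracle: build the full graph Laplacian
# weighted by 1/branch length over all nodes, partition into tips (T) and
# internal nodes (I), and solve x_I = -L_II^{-1} L_IT x_T.
asr_laplacian_oracle <- function(tree, tip_values) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  W <- matrix(0, nn, nn)
  for (e in seq_len(nrow(tree$edge))) {
    i <- tree$edge[e, 1]; j <- tree$edge[e, 2]
    W[i, j] <- W[i, j] + 1 / tree$edge.length[e]
    W[j, i] <- W[i, j]
  }
  L <- diag(rowSums(W)) - W
  tips <- seq_len(ntip); internal <- (ntip + 1):nn
  xT <- tip_values[tree$tip.label]
  drop(-solve(L[internal, internal], L[internal, tips] %*% xT))
}

# Numeric-optimisation oracle for the same quantity: minimise the
# Brownian sum of squared contrasts over edges.
asr_optim_oracle <- function(tree, tip_values) {
  ntip <- length(tree$tip.label)
  f <- function(z) {
    all <- c(tip_values[tree$tip.label], z)
    sum((all[tree$edge[, 1]] - all[tree$edge[, 2]])^2 / tree$edge.length)
  }
  stats::optim(rep(mean(tip_values), tree$Nnode), f, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 2000))$par
}

# Brute-force polarization oracle: plain-loop restatement of the rule,
# deriving clades with ape::prop.part rather than the package's traversal.
polarize_oracle <- function(cats, tree) {
  ntip <- length(tree$tip.label)
  if (any(is.na(cats))) return(NULL)
  parts <- ape::prop.part(tree)            # tip sets of internal nodes
  root_children <- tree$edge[tree$edge[, 1] == ntip + 1, 2]
  belows <- list()
  for (i in seq_len(ntip)) {               # terminal edges
    if (!(i %in% root_children)) belows[[length(belows) + 1]] <- i
  }
  for (k in seq_along(parts)) {            # internal edges
    node <- ntip + k
    if (node == ntip + 1) next             # root itself
    if (node %in% root_children) next      # root-incident, handled below
    belows[[length(belows) + 1]] <- parts[[k]]
  }
  # root split once, smaller side (tie: earlier first tip)
  sides <- lapply(root_children, function(ch) {
    if (ch <= ntip) ch else parts[[ch - ntip]]
  })
  pick <- if (length(sides[[1]]) != length(sides[[2]])) {
    which.min(lengths(sides))
  } else which.min(vapply(sides, min, numeric(1)))
  root_below <- sort(sides[[pick]])

  events <- list()
  emit <- function(below, root_split) {
    outside <- setdiff(seq_len(ntip), below)
    cb <- unique(cats[below]); co <- unique(cats[outside])
    if (length(cb) != 1 || length(co) != 1 || cb == co) return()
    type <- if (root_split) {
      "unpolarized_root_change"
    } else if (co == "UB") {
      paste0("gain_", cb)
    } else if (cb == "UB") {
      paste0("loss_", co)
    } else {
      paste0("switch_", co, "_to_", cb)
    }
    events[[length(events) + 1]] <<- list(
      branch = paste(tree$tip.label[sort(below)], collapse = ","),
      event = type)
  }
  for (b in belows) emit(sort(b), FALSE)
  emit(root_below, TRUE)
  events
}
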