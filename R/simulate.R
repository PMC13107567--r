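#' Default six-species study tree
#'
#' Rooted, ultrametric topology `(((((mel,sim),suz),ana),sub),imm)` with
#' branch lengths in millions of years (2/10/15/30/50 to the root), the
#' shape of the study design the simulator emulates.
#'
#' @return a `phylo` tree.
#' @export
default_species_tree <- function() {
  ape::read.tree(
    text = "(((((mel:2,sim:2):8,suz:10):5,ana:15):15,sub:30):20,imm:50);")
}

#' Default planted selection shift
#'
#' Three times the expected within-species range of log2 expression over
#' five strains under the negative-binomial noise model: the per-strain
#' log2 sd is approximately `sqrt(dispersion)/ln 2` for well-expressed
#' genes and the expected range of five normal draws is 2.326 sd.
#'
#' @param nb_dispersion NB dispersion (variance = mean + dispersion *
#'   mean^2).
#' @return shift in log2 units.
#' @export
default_selection_shift <- function(nb_dispersion = 0.05) {
  3 * 2.326 * sqrt(nb_dispersion) / log(2)
}

#' Specify a planted turnover event
#'
#' @param branch tip label or comma-joined tip labels of the clade gaining
#'   the change.
#' @param event one of `gain_MB`, `gain_FB`, `loss_MB`, `loss_FB`,
#'   `switch_MB_to_FB`, `switch_FB_to_MB`.
#' @param n_genes number of genes carrying this event.
#' @param mag_f,mag_m log2 expression change applied to the female / male
#'   mean on that branch; `mag_m - mag_f` must move the sex difference
#'   consistently with `event`.
#' @param body_part body part the event lives in.
#' @return a `turnover_spec` list.
#' @export
turnover_spec <- function(branch, event, n_genes, mag_f, mag_m,
                          body_part = "head") {
  ev_ok <- c("gain_MB", "gain_FB", "loss_MB", "loss_FB",
             "switch_MB_to_FB", "switch_FB_to_MB")
  stopifnot(event %in% ev_ok, n_genes >= 1, body_part %in% c("head", "body"))
  structure(list(branch = branch, event = event, n_genes = as.integer(n_genes),
                 mag_f = mag_f, mag_m = mag_m, body_part = body_part),
            class = "turnover_spec")
}

#' Specify a planted selective expression shift
#'
#' @param species focal species receiving the shift.
#' @param sex `"female"` or `"male"`.
#' @param n_genes number of shifted genes.
#' @param shift log2 shift (sign = direction); default
#'   [default_selection_shift()].
#' @param body_part body part.
#' @return a `selection_spec` list.
#' @export
selection_spec <- function(species, sex, n_genes,
                           shift = default_selection_shift(),
                           body_part = "body") {
  stopifnot(sex %in% c("female", "male"), n_genes >= 1,
            body_part %in% c("head", "body"))
  structure(list(species = species, sex = sex, n_genes = as.integer(n_genes),
                 shift = shift, body_part = body_part),
            class = "selection_spec")
}

#' Spread terminal-branch turnover events over the polarizable tips
#'
#' Convenience generator of a `turnover_events` list: `n_events` gain/loss
#' events are cycled over the tips whose parent is not the root (events on
#' a root-adjacent tip cannot be polarized) and over the requested event
#' types, with a deterministic fraction made concordant. Concordant events
#' add a shared shift of `-(effect/2 + 1)` to both sexes (both go down);
#' opposing events split `effect` symmetrically across the sexes.
#'
#' @param tree species tree.
#' @param n_events total events to plant (one gene each).
#' @param body_part body part.
#' @param events event types to cycle over.
#' @param frac_concordant fraction of events with same-sign changes.
#' @param effect log2 sex-difference change per event.
#' @return list of [turnover_spec()] objects.
#' @export
plant_terminal_events <- function(tree, n_events, body_part = "head",
                                  events = c("gain_MB", "gain_FB"),
                                  frac_concordant = 1, effect = 2) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1
  parent <- tree$edge[match(seq_len(ntip), tree$edge[, 2]), 1]
  tips <- tree$tip.label[parent != root]
  n_con <- round(n_events * frac_concordant)
  out <- vector("list", n_events)
  for (i in seq_len(n_events)) {
    ev <- events[(i - 1) %% length(events) + 1]
    tip <- tips[(i - 1) %% length(tips) + 1]
    diff <- switch(ev,
                   gain_MB = effect, gain_FB = -effect,
                   loss_MB = -effect, loss_FB = effect,
                   switch_MB_to_FB = -2 * effect,
                   switch_FB_to_MB = 2 * effect)
    shared <- if (i <= n_con) -(abs(diff) / 2 + 1) else 0
    out[[i]] <- turnover_spec(tip, ev, 1L,
                              mag_f = shared - diff / 2,
                              mag_m = shared + diff / 2,
                              body_part = body_part)
  }
  out
}

#' Simulation configuration
#'
#' Defaults emulate the study design the package targets: six species with
#' 2-50 My divergence, 5-8 strains per species (reference strain count 5),
#' two sexes x two body parts with one replicate per strain, NB counts
#' with dispersion 0.05 over ~2,000 genes, Brownian-motion drift of log2
#' baseline expression along the tree, and a planted sex effect of 2 log2
#' units for MB/FB genes.
#'
#' @param tree species tree (default [default_species_tree()]).
#' @param n_genes number of genes.
#' @param strains_per_species named integer vector per species (default
#'   8/6/6/5/5/5 on the default tree, otherwise 5 each).
#' @param nb_dispersion NB dispersion (variance = mean + dispersion *
#'   mean^2).
#' @param bm_sigma2 per-unit-branch-length variance of the log2 baseline.
#' @param sex_effect_log2fc planted male-minus-female log2 fold change for
#'   MB/FB genes.
#' @param frac_MB,frac_FB fractions of genes with ancestral male / female
#'   bias (per body part).
#' @param turnover_events list of [turnover_spec()].
#' @param selection_shifts list of [selection_spec()].
#' @param n_tissues,tissue_concentration,tau_bias_coupling tissue-profile
#'   Dirichlet parameters; larger planted |log2fc| lowers the
#'   concentration (more tissue-specific) when `tau_bias_coupling > 0`.
#' @param frac_x_linked,frac_dot,x_fb_factor chromosome assignment
#'   probabilities; `x_fb_factor` multiplies the X odds of genes with
#'   ancestral female bias in the body.
#' @param library_size,lib_size_range mean library size and the log-uniform
#'   multiplier range.
#' @param cds_length_range CDS length range (bp).
#' @param seed RNG seed; identical seeds give bit-identical studies.
#' @return a `sim_config` list.
#' @export
sim_config <- function(tree = default_species_tree(),
                       n_genes = 2000,
                       strains_per_species = NULL,
                       nb_dispersion = 0.05,
                       bm_sigma2 = 8e-4,
                       sex_effect_log2fc = 2,
                       frac_MB = 0.1, frac_FB = 0.1,
                       turnover_events = list(),
                       selection_shifts = list(),
                       n_tissues = 10,
                       tissue_concentration = 5,
                       tau_bias_coupling = 1,
                       frac_x_linked = 0.2,
                       frac_dot = 0.02,
                       x_fb_factor = 1,
                       library_size = 1e6,
                       lib_size_range = c(0.5, 2),
                       cds_length_range = c(300, 3000),
                       seed = 1) {
  validate_species_tree(tree)
  if (is.null(strains_per_species)) {
    default6 <- c(mel = 8L, sim = 6L, suz = 6L, ana = 5L, sub = 5L, imm = 5L)
    strains_per_species <- if (setequal(tree$tip.label, names(default6))) {
      default6[tree$tip.label]
    } else {
      stats::setNames(rep(5L, length(tree$tip.label)), tree$tip.label)
    }
  }
  if (!setequal(names(strains_per_species), tree$tip.label)) {
    stop("strains_per_species must name every tree tip")
  }
  stopifnot(frac_MB >= 0, frac_FB >= 0, frac_MB + frac_FB <= 1,
            frac_x_linked >= 0, frac_dot >= 0, frac_x_linked + frac_dot <= 1,
            nb_dispersion > 0, bm_sigma2 > 0, n_genes >= 1)
  labels <- vapply(polar_bipartitions(tree), function(b)
    polar_branch_label(tree, b$below), character(1))
  labels <- c(labels, tree$tip.label)  # root-adjacent tips are valid branches
  for (ev in turnover_events) {
    stopifnot(inherits(ev, "turnover_spec"))
    if (!normalize_branch(ev$branch, tree) %in% labels) {
      stop("turnover event branch not in tree: ", ev$branch)
    }
  }
  for (ss in selection_shifts) {
    stopifnot(inherits(ss, "selection_spec"))
    if (!ss$species %in% tree$tip.label) {
      stop("selection shift species not in tree: ", ss$species)
    }
  }
  structure(list(tree = tree, n_genes = as.integer(n_genes),
                 strains_per_species = strains_per_species[tree$tip.label],
                 nb_dispersion = nb_dispersion, bm_sigma2 = bm_sigma2,
                 sex_effect_log2fc = sex_effect_log2fc,
                 frac_MB = frac_MB, frac_FB = frac_FB,
                 turnover_events = turnover_events,
                 selection_shifts = selection_shifts,
                 n_tissues = n_tissues,
                 tissue_concentration = tissue_concentration,
                 tau_bias_coupling = tau_bias_coupling,
                 frac_x_linked = frac_x_linked, frac_dot = frac_dot,
                 x_fb_factor = x_fb_factor,
                 library_size = library_size, lib_size_range = lib_size_range,
                 cds_length_range = cds_length_range, seed = as.integer(seed)),
            class = "sim_config")
}

normalize_branch <- function(branch, tree) {
  tips <- strsplit(branch, ",")[[1]]
  if (!all(tips %in% tree$tip.label)) {
    stop("unknown tip in branch label: ", branch)
  }
  paste(tree$tip.label[sort(match(tips, tree$tip.label))], collapse = ",")
}

# Tip values of a Brownian walk along the tree, one column per tip,
# n independent genes in rows.
bm_tips <- function(tree, n, root_values, sigma2) {
  ntip <- length(tree$tip.label)
  vals <- matrix(NA_real_, n, ntip + tree$Nnode)
  vals[, ntip + 1] <- root_values
  pre <- stats::reorder(tree, "cladewise")  # parents precede children
  for (e in seq_len(nrow(pre$edge))) {
    par <- pre$edge[e, 1]; child <- pre$edge[e, 2]
    vals[, child] <- vals[, par] +
      stats::rnorm(n, 0, sqrt(sigma2 * pre$edge.length[e]))
  }
  tipv <- vals[, seq_len(ntip), drop = FALSE]
  colnames(tipv) <- tree$tip.label
  tipv
}

#' Simulate a study-shaped count dataset with planted truth
#'
#' Per gene and body part, a log2 baseline evolves by Brownian motion along
#' the tree; species x sex means add half the planted sex effect per
#' ancestral category, plus the per-sex magnitudes of any planted turnover
#' event below its branch and any planted selective shift. Strain counts
#' are drawn NB(mean = library size x relative expression x CDS length,
#' dispersion) with log-uniform library sizes. True categories are derived
#' from the realized mean sex difference (threshold: half the sex effect),
#' and the planted event list is checked against them.
#'
#' @param cfg a [sim_config()].
#' @return list: `counts` ([sb_counts()]), `annotation`, `tree`, `tissues`
#'   (gene x tissue matrix), `truth` (list: `categories` data.frame,
#'   `events`, `selected`, `sex_diff` array, `tau_concentration`).
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tree <- cfg$tree
  ntip <- length(tree$tip.label)
  n <- cfg$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  body_parts <- c("head", "body")
  sexes <- c("female", "male")
  e <- cfg$sex_effect_log2fc

  cds_len <- sample(seq(cfg$cds_length_range[1], cfg$cds_length_range[2]),
                    n, replace = TRUE)

  # ancestral categories per body part
  anc_cat <- sapply(body_parts, function(bp) {
    sample(c("MB", "FB", "UB"), n, replace = TRUE,
           prob = c(cfg$frac_MB, cfg$frac_FB, 1 - cfg$frac_MB - cfg$frac_FB))
  })
  rownames(anc_cat) <- genes

  # chromosome assignment; body-FB genes get x_fb_factor-times X odds
  p_x <- rep(cfg$frac_x_linked, n)
  fb_body <- anc_cat[, "body"] == "FB"
  odds <- p_x / (1 - p_x)
  odds[fb_body] <- odds[fb_body] * cfg$x_fb_factor
  p_x <- pmin(odds / (1 + odds), 1 - cfg$frac_dot)
  u <- stats::runif(n)
  chrom <- ifelse(u < p_x, "X",
                  ifelse(u < p_x + cfg$frac_dot, "dot", "autosome"))

  # log2 baselines by Brownian motion, one walk per body part
  base <- array(NA_real_, c(n, ntip, 2),
                dimnames = list(genes, tree$tip.label, body_parts))
  root_expr <- stats::rnorm(n, mean = 3, sd = 2)
  for (bp in body_parts) {
    base[, , bp] <- bm_tips(tree, n, root_expr, cfg$bm_sigma2)
  }

  # per-sex offsets: ancestral category half-effects
  offset <- array(0, c(n, ntip, 2, 2),
                  dimnames = list(genes, tree$tip.label, sexes, body_parts))
  for (bp in body_parts) {
    mb <- anc_cat[, bp] == "MB"; fb <- anc_cat[, bp] == "FB"
    offset[mb, , "male", bp] <- offset[mb, , "male", bp] + e / 2
    offset[mb, , "female", bp] <- offset[mb, , "female", bp] - e / 2
    offset[fb, , "female", bp] <- offset[fb, , "female", bp] + e / 2
    offset[fb, , "male", bp] <- offset[fb, , "male", bp] - e / 2
  }

  # planted turnover events: one gene per spec slot, one event per
  # gene/body part (nested or duplicate events on a gene are thereby
  # impossible by construction)
  used <- matrix(FALSE, n, 2, dimnames = list(genes, body_parts))
  ev_rows <- list()
  tipset_of <- function(branch) {
    match(strsplit(normalize_branch(branch, tree), ",")[[1]], tree$tip.label)
  }
  needs_cat <- c(gain_MB = "UB", gain_FB = "UB", loss_MB = "MB",
                 loss_FB = "FB", switch_MB_to_FB = "MB",
                 switch_FB_to_MB = "FB")
  below_cat <- c(gain_MB = "MB", gain_FB = "FB", loss_MB = "UB",
                 loss_FB = "UB", switch_MB_to_FB = "FB",
                 switch_FB_to_MB = "MB")
  for (ev in cfg$turnover_events) {
    bp <- ev$body_part
    pool <- which(anc_cat[, bp] == needs_cat[[ev$event]] & !used[, bp])
    if (length(pool) < ev$n_genes) {
      stop("not enough unused ", needs_cat[[ev$event]],
           " genes to plant event ", ev$event, " on ", ev$branch)
    }
    pick <- if (length(pool) == 1) pool else sample(pool, ev$n_genes)
    used[pick, bp] <- TRUE
    tipsel <- tipset_of(ev$branch)
    offset[pick, tipsel, "female", bp] <-
      offset[pick, tipsel, "female", bp] + ev$mag_f
    offset[pick, tipsel, "male", bp] <-
      offset[pick, tipsel, "male", bp] + ev$mag_m
    # consistency: the implied below-branch category must match the event
    anc_diff <- switch(needs_cat[[ev$event]], MB = e, FB = -e, UB = 0)
    new_diff <- anc_diff + ev$mag_m - ev$mag_f
    implied <- if (new_diff >= e / 2) "MB" else if (new_diff <= -e / 2) "FB" else "UB"
    if (implied != below_cat[[ev$event]]) {
      stop("magnitudes (", ev$mag_f, ", ", ev$mag_m,
           ") inconsistent with event ", ev$event)
    }
    ev_rows[[length(ev_rows) + 1]] <- data.frame(
      gene_id = genes[pick], body_part = bp,
      branch = normalize_branch(ev$branch, tree), event = ev$event,
      mag_f = ev$mag_f, mag_m = ev$mag_m, stringsAsFactors = FALSE)
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(gene_id = character(0), body_part = character(0),
               branch = character(0), event = character(0),
               mag_f = numeric(0), mag_m = numeric(0))

  # planted selective shifts (kept off event genes so each truth signal
  # stays attributable)
  sel_rows <- list()
  for (ss in cfg$selection_shifts) {
    bp <- ss$body_part
    pool <- which(!used[, bp])
    if (length(pool) < ss$n_genes) stop("not enough unused genes for shifts")
    pick <- if (length(pool) == 1) pool else sample(pool, ss$n_genes)
    used[pick, bp] <- TRUE
    offset[pick, ss$species, ss$sex, bp] <-
      offset[pick, ss$species, ss$sex, bp] + ss$shift
    sel_rows[[length(sel_rows) + 1]] <- data.frame(
      gene_id = genes[pick], species = ss$species, sex = ss$sex,
      body_part = bp, shift = ss$shift, stringsAsFactors = FALSE)
  }
  selected <- if (length(sel_rows)) do.call(rbind, sel_rows) else
    data.frame(gene_id = character(0), species = character(0),
               sex = character(0), body_part = character(0),
               shift = numeric(0))

  # realized sex differences and derived true categories
  sex_diff <- offset[, , "male", ] - offset[, , "female", ]
  cat_list <- list()
  for (bp in body_parts) {
    dmat <- sex_diff[, , bp]
    cm <- ifelse(dmat >= e / 2, "MB", ifelse(dmat <= -e / 2, "FB", "UB"))
    cat_list[[bp]] <- data.frame(
      gene_id = rep(genes, ntip),
      species = rep(tree$tip.label, each = n),
      body_part = bp, true_category = as.vector(cm),
      stringsAsFactors = FALSE)
  }
  categories <- do.call(rbind, cat_list)

  # strain-level NB counts
  meta_rows <- list(); cols <- list()
  for (si in seq_len(ntip)) {
    sp <- tree$tip.label[si]
    for (k in seq_len(cfg$strains_per_species[[sp]])) {
      strain <- sprintf("s%02d", k)
      for (sx in sexes) {
        for (bp in body_parts) {
          lib <- cfg$library_size *
            exp(stats::runif(1, log(cfg$lib_size_range[1]),
                             log(cfg$lib_size_range[2])))
          L <- base[, si, bp] + offset[, si, sx, bp]
          E <- 2^L * cds_len
          mu <- lib * E / sum(E)
          y <- stats::rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
          id <- paste(sp, strain, sx, bp, sep = "_")
          cols[[id]] <- y
          meta_rows[[id]] <- data.frame(
            sample_id = id, species = sp, strain = strain, sex = sx,
            body_part = bp, stringsAsFactors = FALSE)
        }
      }
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- genes
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL
  cm <- sb_counts(counts, meta)

  # tissue profiles; higher planted bias -> more concentrated (specific)
  bias_mag <- apply(abs(sex_diff), 1, max)
  conc <- cfg$tissue_concentration / (1 + cfg$tau_bias_coupling * bias_mag)
  tissues <- matrix(0, n, cfg$n_tissues,
                    dimnames = list(genes, sprintf("t%02d", seq_len(cfg$n_tissues))))
  total <- 2^root_expr
  for (g in seq_len(n)) {
    w <- stats::rgamma(cfg$n_tissues, shape = conc[g])
    if (sum(w) == 0) w <- rep(1, cfg$n_tissues)
    tissues[g, ] <- total[g] * w / sum(w)
  }

  ann <- data.frame(gene_id = genes, cds_length_bp = cds_len,
                    chromosome = chrom, stringsAsFactors = FALSE)

  list(counts = cm, annotation = ann, tree = tree, tissues = tissues,
       truth = list(categories = categories, events = events,
                    selected = selected, sex_diff = sex_diff,
                    anc_category = anc_cat, tau_concentration = conc,
                    chromosome = stats::setNames(chrom, genes)))
}

#' Write a simulated study to a fixture directory
#'
#' Writes the external-interface files (counts, metadata, annotation,
#' newick tree, tissue matrix) plus tab-separated truth tables; reading
#' them back with [read_counts()] / [read_species_tree()] reproduces the
#' objects.
#'
#' @param sim output of [simulate_study()].
#' @param dir target directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return invisibly, the vector of files written.
#' @export
write_fixture <- function(sim, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    stop("directory exists and is not empty: ", dir,
         " (use overwrite = TRUE)")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c(counts = "counts.tsv", meta = "samples.tsv",
                            ann = "annotation.tsv", tree = "tree.nwk",
                            tissues = "tissues.tsv",
                            cat = "truth_categories.tsv",
                            ev = "truth_events.tsv",
                            sel = "truth_selected.tsv"))
  names(paths) <- c("counts", "meta", "ann", "tree", "tissues", "cat",
                    "ev", "sel")
  write_counts(sim$counts, paths["counts"], paths["meta"])
  write_annotation(sim$annotation, paths["ann"])
  write_species_tree(sim$tree, paths["tree"])
  utils::write.table(data.frame(gene_id = rownames(sim$tissues),
                                sim$tissues, check.names = FALSE),
                     paths["tissues"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth$categories, paths["cat"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$events, paths["ev"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$selected, paths["sel"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
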