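#' Pipeline run configuration
#'
#' Collects input paths and analysis thresholds for [run_pipeline()].
#' Thresholds default to the study values: 5% FDR, TPM >= 0.5 expression
#' filter, large-change thresholds of 1 (head) and 2 (body) log2 units,
#' |delta_x| > 1 selection flag, pseudocount 1 on the delta-x log scale,
#' and reference strain count 5.
#'
#' @param counts,meta,annotation,tree paths to the count table, sample
#'   metadata, annotation and newick tree.
#' @param tissues optional path to a gene x tissue matrix (enables the tau
#'   stage).
#' @param out_dir output directory for the stage files and report.
#' @param outgroup reference species for polarization context and delta-x.
#' @param fdr,tpm_min,large_change,dx_threshold,pseudocount,ref_n
#'   thresholds, see above.
#' @param seed RNG seed echoed in the report (the pipeline itself is
#'   deterministic).
#' @return a `run_config` list.
#' @export
run_config <- function(counts, meta, annotation, tree, tissues = NULL,
                       out_dir, outgroup, fdr = 0.05, tpm_min = 0.5,
                       large_change = c(head = 1, body = 2),
                       dx_threshold = 1, pseudocount = 1, ref_n = 5,
                       seed = 1) {
  if (missing(tree)) stop("run_config: 'tree' path is required")
  if (missing(counts)) stop("run_config: 'counts' path is required")
  if (missing(meta)) stop("run_config: 'meta' path is required")
  if (missing(annotation)) stop("run_config: 'annotation' path is required")
  if (missing(out_dir)) stop("run_config: 'out_dir' is required")
  if (missing(outgroup)) stop("run_config: 'outgroup' is required")
  stopifnot(fdr > 0, tpm_min >= 0, all(large_change > 0), dx_threshold > 0,
            pseudocount >= 0, ref_n >= 2)
  structure(list(counts = counts, meta = meta, annotation = annotation,
                 tree = tree, tissues = tissues, out_dir = out_dir,
                 outgroup = outgroup, fdr = fdr, tpm_min = tpm_min,
                 large_change = large_change, dx_threshold = dx_threshold,
                 pseudocount = pseudocount, ref_n = ref_n,
                 seed = as.integer(seed)),
            class = "run_config")
}

num_fmt <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

write_stage <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- num_fmt(df[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full comparative sex-bias pipeline
#'
#' Stages, in dependency order: TPM -> expression filter -> sex-bias calls
#' per species and body part -> sharing spectrum and turnover polarization
#' -> ancestral changes and concordance -> delta-x and selection
#' enrichment -> tau and X/autosome enrichment -> report. All stage tables
#' are written tab-separated into `cfg$out_dir`; identical config gives
#' byte-identical outputs.
#'
#' @param cfg a [run_config()].
#' @return a `run_report` list: config echo, per-stage row counts,
#'   category tallies, event tallies, concordance and enrichment
#'   summaries, and per-stage wall-clock seconds (the timings are not
#'   written by [write_report()], keeping outputs deterministic).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    message(sprintf("[%s] stage %s done", format(Sys.time(), "%H:%M:%S"),
                    stage))
    val
  }

  cm <- tick("read", read_counts(cfg$counts, cfg$meta))
  ann <- read_annotation(cfg$annotation)
  tree <- read_species_tree(cfg$tree, unique(cm$samples$species))
  if (!cfg$outgroup %in% tree$tip.label) {
    stop("outgroup not in tree: ", cfg$outgroup)
  }

  tpm <- tick("tpm", compute_tpm(cm, ann))
  analyzed <- tick("filter", filter_expressed(tpm, cfg$tpm_min))
  calls <- tick("callbias", call_sex_bias_all(cm, analyzed, fdr = cfg$fdr))
  write_stage(calls, file.path(cfg$out_dir, "calls.tsv"))

  body_parts <- unique(cm$samples$body_part)
  spectra <- lapply(stats::setNames(body_parts, body_parts),
                    function(bp) sharing_spectrum(calls, bp))
  events <- tick("turnover", {
    ev <- lapply(body_parts, function(bp) {
      polarize_turnover(calls[calls$body_part == bp, ], tree, body_part = bp)
    })
    do.call(rbind, ev)
  })
  write_stage(events, file.path(cfg$out_dir, "events.tsv"))

  changes <- tick("changes", ancestral_changes(tpm, tree))
  pairs <- change_pairs(changes, events, cfg$large_change)
  write_stage(pairs, file.path(cfg$out_dir, "change_pairs.tsv"))
  conc <- tick("concordance",
               if (nrow(pairs) > 0) concordance_summary(pairs) else NULL)

  dx <- tick("selection",
             delta_x_table(tpm, cfg$outgroup, N = cfg$ref_n,
                           pseudocount = cfg$pseudocount,
                           analyzed = analyzed))
  write_stage(dx, file.path(cfg$out_dir, "delta_x.tsv"))
  sel_enr <- suppressMessages(selection_enrichment(dx, calls))
  write_stage(sel_enr, file.path(cfg$out_dir, "selection_enrichment.tsv"))

  taus <- NULL; tb <- NULL
  if (!is.null(cfg$tissues)) {
    tt <- utils::read.delim(cfg$tissues, check.names = FALSE)
    tm <- as.matrix(tt[, -1, drop = FALSE])
    rownames(tm) <- tt[[1]]
    taus <- tick("tau", tau_table(tm))
    write_stage(taus, file.path(cfg$out_dir, "tau.tsv"))
    tb <- tau_bias_association(taus, calls)
  }
  xa <- tick("enrich", xa_enrichment(calls, ann))
  write_stage(xa, file.path(cfg$out_dir, "xa_enrichment.tsv"))

  tallies <- as.data.frame(table(calls$species, calls$body_part,
                                 addNA(calls$category)))
  names(tallies) <- c("species", "body_part", "category", "n")
  ev_tally <- if (nrow(events)) {
    as.data.frame(table(events$body_part, events$branch, events$event))
  } else NULL
  if (!is.null(ev_tally)) {
    names(ev_tally) <- c("body_part", "branch", "event", "n")
    ev_tally <- ev_tally[ev_tally$n > 0, , drop = FALSE]
  }

  report <- structure(list(
    version = as.character(utils::packageVersion("sexbiasevo")),
    config = unclass(cfg),
    axis_convention = paste("quadrants: x = female change, y = male change;",
                            "ii = both up, iii = both down (concordant)"),
    n_genes = nrow(cm$counts), n_samples = ncol(cm$counts),
    n_analyzed = colSums(analyzed),
    category_tallies = tallies[tallies$n > 0, , drop = FALSE],
    sharing = spectra, event_tallies = ev_tally,
    n_events = nrow(events), n_change_pairs = nrow(pairs),
    concordance = conc, selection_enrichment = sel_enr,
    xa_enrichment = xa, tau_association = tb,
    timings = timings), class = "run_report")
  write_report(report, file.path(cfg$out_dir, "report.txt"))
  report
}

#' Write a run report as structured text
#'
#' Key-value lines plus embedded tab-separated tables, in stable field
#' order. Per-stage wall-clock timings are deliberately omitted so that
#' repeated runs with the same config produce byte-identical files.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# sexbiasevo run report")
  w("version\t", report$version)
  w("axis_convention\t", report$axis_convention)
  for (nm in names(report$config)) {
    v <- report$config[[nm]]
    if (is.null(v)) v <- "NULL"
    w("config.", nm, "\t", paste(num_fmt_chr(v), collapse = ","))
  }
  w("n_genes\t", report$n_genes)
  w("n_samples\t", report$n_samples)
  for (nm in names(report$n_analyzed)) {
    w("n_analyzed.", nm, "\t", report$n_analyzed[[nm]])
  }
  w("n_events\t", report$n_events)
  w("n_change_pairs\t", report$n_change_pairs)
  for (bp in names(report$sharing)) {
    s <- report$sharing[[bp]]
    w("sharing.", bp, ".eligible\t", s$eligible)
    w("sharing.", bp, ".switchers\t", s$switchers)
    w("sharing.", bp, ".ub_all\t", s$ub_all)
    w("sharing.", bp, ".sb_in_k\t", paste(s$sb_in_k, collapse = ","))
  }
  if (!is.null(report$concordance)) {
    for (bp in names(report$concordance$by_body_part)) {
      b <- report$concordance$by_body_part[[bp]]
      w("concordance.", bp, ".n\t", b$n)
      w("concordance.", bp, ".frac_concordant\t", num_fmt(b$frac_concordant))
      w("concordance.", bp, ".quadrants\t",
        paste(b$quadrant_counts, collapse = ","))
    }
  }
  tbl <- function(name, df) {
    if (is.null(df) || nrow(df) == 0) return(invisible())
    w("")
    w("## ", name)
    num <- vapply(df, is.numeric, logical(1))
    for (j in which(num)) df[[j]] <- num_fmt(df[[j]])
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tbl("category_tallies", report$category_tallies)
  tbl("event_tallies", report$event_tallies)
  tbl("selection_enrichment", report$selection_enrichment)
  tbl("xa_enrichment", report$xa_enrichment)
  if (!is.null(report$tau_association)) {
    tbl("tau_association", report$tau_association$cells)
  }
  invisible(path)
}

num_fmt_chr <- function(v) {
  if (is.numeric(v)) num_fmt(v) else as.character(v)
}

#' @export
print.run_report <- function(x, ...) {
  cat("sexbiasevo run report:", x$n_genes, "genes,", x$n_samples,
      "samples,", x$n_events, "turnover events\n")
  invisible(x)
}
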