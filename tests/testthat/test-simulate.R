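test_that("the simulator is deterministic and honours a null configuration", {
  cfg <- sim_config(n_genes = 150, frac_MB = 0, frac_FB = 0, seed = 3)
  sim1 <- simulate_study(cfg)
  sim2 <- simulate_study(cfg)
  expect_identical(sim1$counts$counts, sim2$counts$counts)
  expect_identical(sim1$tissues, sim2$tissues)
  expect_true(all(sim1$truth$categories$true_category == "UB"))
  expect_equal(nrow(sim1$truth$events), 0)
  # different seed changes the draw
  sim3 <- simulate_study(sim_config(n_genes = 150, frac_MB = 0, frac_FB = 0,
                                    seed = 4))
  expect_false(identical(sim1$counts$counts, sim3$counts$counts))
})

test_that("planted fold changes are realized in mean log2 expression", {
  cfg <- sim_config(n_genes = 800, frac_MB = 0.25, frac_FB = 0.25,
                    strains_per_species = c(mel = 8, sim = 8, suz = 8,
                                            ana = 8, sub = 8, imm = 8),
                    seed = 12)
  sim <- simulate_study(cfg)
  tpm <- compute_tpm(sim$counts, sim$annotation)
  gm <- group_mean_tpm(tpm)
  truth_cat <- sim$truth$anc_category[, "body"]
  lfc <- log2(gm$values[, "mel|male|body"] + 0.5) -
    log2(gm$values[, "mel|female|body"] + 0.5)
  expect_equal(mean(lfc[truth_cat == "MB"]), 2, tolerance = 0.1)
  expect_equal(mean(lfc[truth_cat == "FB"]), -2, tolerance = 0.1)
  expect_equal(mean(lfc[truth_cat == "UB"]), 0, tolerance = 0.1)
})

test_that("planted turnover events respect the polarization rule on truth categories", {
  tr <- six_species_tree()
  evs <- c(plant_terminal_events(tr, 40, body_part = "head",
                                 events = c("gain_MB", "gain_FB",
                                            "loss_MB", "loss_FB"),
                                 frac_concordant = 0.5),
           list(turnover_spec("mel,sim", "gain_MB", 5, mag_f = -3, mag_m = -1,
                              body_part = "head"),
                turnover_spec("suz", "switch_MB_to_FB", 5, mag_f = 2,
                              mag_m = -2, body_part = "head")))
  cfg <- sim_config(n_genes = 600, turnover_events = evs, seed = 44)
  sim <- simulate_study(cfg)
  truth <- sim$truth
  expect_equal(nrow(truth$events), 50)
  cm <- category_matrix(data.frame(
    gene_id = truth$categories$gene_id,
    species = truth$categories$species,
    category = truth$categories$true_category)[
      truth$categories$body_part == "head", ])
  replay <- polarize_turnover(cm, tr, body_part = "head")
  key <- function(d) paste(d$gene_id, d$branch, d$event)
  expect_true(all(key(truth$events) %in% key(replay)))
  expect_true(all(key(replay) %in% key(truth$events)))

  # magnitudes inconsistent with the event type are rejected
  bad <- list(turnover_spec("mel", "gain_MB", 3, mag_f = 1, mag_m = -1,
                            body_part = "head"))
  expect_error(simulate_study(sim_config(n_genes = 100,
                                         turnover_events = bad, seed = 1)),
               "inconsistent")
})

test_that("fixtures round-trip through the on-disk formats", {
  cfg <- sim_config(n_genes = 60, seed = 9)
  sim <- simulate_study(cfg)
  d <- file.path(tempfile(), "fix")
  write_fixture(sim, d)
  cm <- read_counts(file.path(d, "counts.tsv"), file.path(d, "samples.tsv"))
  expect_equal(cm$counts, sim$counts$counts)
  expect_equal(cm$samples, sim$counts$samples)
  tr <- read_species_tree(file.path(d, "tree.nwk"),
                          species = sim$tree$tip.label)
  expect_equal(sort(tr$edge.length), sort(sim$tree$edge.length))
  ann <- read_annotation(file.path(d, "annotation.tsv"))
  expect_equal(ann$cds_length_bp, sim$annotation$cds_length_bp)
  truth_cat <- utils::read.delim(file.path(d, "truth_categories.tsv"))
  expect_equal(nrow(truth_cat), 60 * 6 * 2)  # genes x species x body parts

  # refuse to clobber a non-empty directory without the flag
  expect_error(write_fixture(sim, d), "overwrite")
  expect_silent(write_fixture(sim, d, overwrite = TRUE))
})

test_that("null-generator p-values are approximately uniform", {
  cfg <- sim_config(n_genes = 2000, frac_MB = 0, frac_FB = 0,
                    strains_per_species = c(mel = 5, sim = 5, suz = 5,
                                            ana = 5, sub = 5, imm = 5),
                    seed = 42)
  sim <- simulate_study(cfg)
  calls <- call_sex_bias(sim$counts, "mel", "head")
  p <- calls$p[!is.na(calls$p)]
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})
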