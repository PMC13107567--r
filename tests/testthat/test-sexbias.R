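test_that("size factors match the median-of-ratios hand example and scale", {
  m <- matrix(c(10, 20, 20, 40), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  s <- size_factors(m)
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(exp(mean(log(s))), 1, tolerance = 1e-12)

  # identical samples -> all 1; doubling a sample doubles its factor
  m2 <- matrix(rpois(40, 30) + 1, 10, 4,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  m2[, 2] <- m2[, 1]
  s2 <- size_factors(m2[, 1:2])
  expect_equal(unname(s2), c(1, 1))
  m3 <- cbind(m2[, 1, drop = FALSE], s2x = 2 * m2[, 1])
  s3 <- size_factors(m3)
  expect_equal(unname(s3[2] / s3[1]), 2, tolerance = 1e-12)

  expect_error(size_factors(matrix(c(1, 0, 0, 1), 2,
                                   dimnames = list(c("a", "b"), c("x", "y")))),
               "pseudo-reference")
})

test_that("the NB Wald stage agrees with a per-gene glm fit at fixed dispersion", {
  skip_if_not_installed("MASS")
  set.seed(21)
  cfg <- sim_config(n_genes = 60, frac_MB = 0.2, frac_FB = 0.2,
                    strains_per_species = c(mel = 5, sim = 5, suz = 5,
                                            ana = 5, sub = 5, imm = 5),
                    seed = 21)
  sim <- simulate_study(cfg)
  calls <- call_sex_bias(sim$counts, "mel", "head", p_reference = "normal")

  sel <- sim$counts$samples$species == "mel" &
    sim$counts$samples$body_part == "head"
  y <- sim$counts$counts[, sel]
  meta <- sim$counts$samples[sel, ]
  s <- size_factors(y)
  norm <- sweep(y, 2, s, "/")
  alpha <- sexbiasevo:::mom_dispersion(norm, meta$sex == "male")

  for (g in c(1, 7, 25, 42)) {
    if (sum(y[g, ]) == 0) next
    fit <- suppressWarnings(stats::glm(
      y[g, ] ~ factor(meta$sex, levels = c("female", "male")) + offset(log(s)),
      family = MASS::negative.binomial(theta = 1 / alpha[g])))
    co <- summary(fit, dispersion = 1)$coefficients
    expect_equal(calls$log2fc[g], unname(co[2, 1]) / log(2), tolerance = 1e-4)
    expect_equal(calls$se[g], unname(co[2, 2]) / log(2), tolerance = 1e-3)
  }
})

test_that("sex-label swap negates fold changes and exchanges MB/FB", {
  cfg <- sim_config(n_genes = 300, frac_MB = 0.15, frac_FB = 0.15, seed = 33)
  sim <- simulate_study(cfg)
  calls <- call_sex_bias(sim$counts, "sim", "body")

  swapped <- sim$counts
  swapped$samples$sex <- ifelse(swapped$samples$sex == "male", "female", "male")
  calls_sw <- call_sex_bias(swapped, "sim", "body")

  ok <- !is.na(calls$log2fc)
  expect_equal(calls_sw$log2fc[ok], -calls$log2fc[ok], tolerance = 1e-9)
  map <- c(MB = "FB", FB = "MB", UB = "UB")
  expect_identical(unname(map[calls$category[ok]]), calls_sw$category[ok])

  # q is a monotone BH transform of p, and q >= p
  expect_true(all(calls$q[ok] >= calls$p[ok] - 1e-12))
  o <- order(calls$p[ok])
  expect_true(all(diff(calls$q[ok][o]) >= -1e-12))
})

test_that("category assignment respects the q/fold-change invariant and NA path", {
  cfg <- sim_config(n_genes = 400, frac_MB = 0.2, frac_FB = 0.1, seed = 55)
  sim <- simulate_study(cfg)
  # force one gene to all-zero in one stratum
  sel <- sim$counts$samples$species == "ana" & sim$counts$samples$body_part == "head"
  sim$counts$counts[5, sel] <- 0
  calls <- call_sex_bias(sim$counts, "ana", "head")
  expect_identical(calls$category[5], NA_character_)
  ok <- !is.na(calls$category)
  expect_true(all((calls$category[ok] == "MB") ==
                    (calls$q[ok] < 0.05 & calls$log2fc[ok] > 0)))
  expect_true(all((calls$category[ok] == "FB") ==
                    (calls$q[ok] < 0.05 & calls$log2fc[ok] < 0)))
  expect_equal(sum(table(calls$category, useNA = "always")), nrow(calls))

  # analyzed mask forces NA outside the mask
  mask <- rep(c(TRUE, FALSE), length.out = 400)
  calls2 <- call_sex_bias(sim$counts, "ana", "head", analyzed = mask)
  expect_true(all(is.na(calls2$category[!mask])))
})

test_that("sharing spectrum partitions eligible genes and excludes NA genes", {
  genes <- paste0("g", 1:6)
  species <- c("a", "b", "c", "d", "e", "f")
  grid <- expand.grid(gene_id = genes, species = species,
                      stringsAsFactors = FALSE)
  grid$body_part <- "head"
  cat_of <- rbind(
    g1 = c("MB", "MB", "MB", "UB", "UB", "UB"),  # SB in 3, same direction
    g2 = c("MB", "FB", "UB", "UB", "UB", "UB"),  # switcher
    g3 = rep("UB", 6),                           # UB everywhere
    g4 = c("FB", "UB", "UB", "UB", "UB", "UB"),  # SB in 1
    g5 = c(NA, "MB", "MB", "MB", "MB", "MB"),    # NA -> excluded
    g6 = c("FB", "FB", "FB", "FB", "FB", "FB"))  # SB in 6
  grid$category <- cat_of[cbind(match(grid$gene_id, rownames(cat_of)),
                                match(grid$species, species))]
  sp <- sharing_spectrum(grid, "head")
  expect_equal(sp$eligible, 5)
  expect_equal(sp$switchers, 1)
  expect_equal(sp$ub_all, 1)
  expect_equal(unname(sp$sb_in_k), c(1, 0, 1, 0, 0, 1))
})

test_that("pairwise switch counts partition the shared gene set", {
  calls <- data.frame(
    gene_id = rep(paste0("g", 1:10), 2),
    species = rep(c("a", "b"), each = 10), body_part = "body",
    category = c("MB", "FB", "UB", "MB", "FB", "UB", "MB", "FB", "UB", "MB",
                 "FB", "MB", "UB", "MB", "FB", "MB", "UB", "UB", "FB", NA))
  out <- pairwise_switches(calls, "a", "b", "body")
  expect_equal(out[["switched"]], 2)   # g1 MB->FB, g2 FB->MB
  expect_equal(out[["n"]], 9)
  expect_equal(sum(out[c("same_bias", "UB_both", "SB_one_only", "switched")]),
               out[["n"]])
  # identical call sets: no switches
  same <- calls; same$category[11:20] <- same$category[1:10]
  expect_equal(pairwise_switches(same, "a", "b", "body")[["switched"]], 0)
})
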