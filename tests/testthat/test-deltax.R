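test_that("delta-x reproduces the hand-computed example and degenerate paths", {
  r <- delta_x(c(1, 2, 3), rep(4, 5), N = 5)
  expect_equal(r$d, -1)
  expect_equal(r$r, 1)
  expect_equal(r$f, 14 / 12, tolerance = 1e-12)
  expect_equal(r$delta_x, -7 / 6, tolerance = 1e-12)
  expect_true(r$selected)
  expect_equal(r$direction, "down")

  # equal means: no divergence
  r0 <- delta_x(c(3, 4, 5), c(4, 4), N = 5)
  expect_equal(r0$delta_x, 0)
  expect_false(r0$selected)
  expect_equal(r0$direction, "none")

  # zero polymorphism: NA with reason
  rz <- delta_x(c(2, 2, 2), c(4, 4), N = 5)
  expect_true(is.na(rz$delta_x))
  expect_equal(rz$reason, "zero_range")

  # correction factor arithmetic
  expect_equal(delta_x(c(1, 2, 3, 4, 5), 1, N = 5)$f, 1.2, tolerance = 1e-12)
  expect_equal(delta_x(1:8, 1, N = 5)$f, 39 / 32, tolerance = 1e-12)

  expect_error(delta_x(numeric(0), 1, 5), "strain")
  expect_error(delta_x(c(1, 2), numeric(0), 5), "non-empty")
})

test_that("delta-x is invariant to strain order and global scaling; f -> 1 for large N", {
  set.seed(14)
  for (i in 1:50) {
    m <- sample(2:8, 1)
    xf <- runif(m, 1, 10)
    xr <- runif(sample(1:8, 1), 1, 10)
    base <- delta_x(xf, xr, N = 5)$delta_x
    if (is.na(base)) next
    expect_equal(delta_x(sample(xf), xr, N = 5)$delta_x, base, tolerance = 1e-12)
    c_scale <- runif(1, 0.1, 10)
    expect_equal(delta_x(c_scale * xf, c_scale * xr, N = 5)$delta_x, base,
                 tolerance = 1e-10)
    # sign of delta-x equals sign of d
    expect_equal(sign(delta_x(xf, xr, N = 5)$delta_x),
                 sign(delta_x(xf, xr, N = 5)$d))
  }
  expect_equal(delta_x(c(1, 2, 3), 1, N = 1e9)$f, 1, tolerance = 1e-6)
})

test_that("selection enrichment matches the hand-computed observed/expected toy", {
  # 1000 genes, 100 MB; 200 selected overall, 40 of them MB
  n <- 1000
  genes <- sprintf("g%04d", 1:n)
  cat <- c(rep("MB", 100), rep("UB", 900))
  selected <- c(rep(TRUE, 40), rep(FALSE, 60),        # MB genes
                rep(TRUE, 160), rep(FALSE, 740))      # UB genes
  dx <- data.frame(gene_id = genes, species = "sp", sex = "male",
                   body_part = "head", delta_x = ifelse(selected, 2, 0.1),
                   selected = selected)
  calls <- data.frame(gene_id = genes, species = "sp", body_part = "head",
                      category = cat)
  enr <- suppressMessages(selection_enrichment(dx, calls))
  mb <- enr[enr$category == "MB", ]
  expect_equal(mb$expected, 20)
  expect_equal(mb$obs_exp, 2.0)
  # chi-square over both categories, selected and non-selected cells
  stat_hand <- (40 - 20)^2 / 20 + (60 - 80)^2 / 80 +
    (160 - 180)^2 / 180 + (740 - 720)^2 / 720
  expect_equal(unique(enr$chisq), stat_hand, tolerance = 1e-12)

  # low-expectation categories are excluded with a note
  cat2 <- c(rep("FB", 10), cat[11:n])
  calls2 <- transform(calls, category = cat2)
  expect_message(enr2 <- selection_enrichment(dx, calls2), "excluding")
  expect_true(enr2$excluded[enr2$category == "FB"][1])
})

test_that("identical or scaled male/female delta-x give the expected comparisons", {
  dxf <- data.frame(gene_id = sprintf("g%02d", 1:20),
                    delta_x = seq(-1, 1, length.out = 20))
  dxm <- dxf
  sc <- dx_sex_comparison(dxf, dxm)
  expect_equal(sc$t_statistic, 0)
  expect_equal(sc$t_p, 1, tolerance = 1e-9)
  expect_equal(sc$rho, 1)

  dxm2 <- transform(dxf, delta_x = 2 * delta_x)
  sc2 <- dx_sex_comparison(dxf, dxm2)
  expect_equal(sc2$rho, 1)
  expect_gt(sc2$mean_abs_male, sc2$mean_abs_female)

  expect_equal(dx_sex_comparison(dxf[1:2, ], dxm[1:2, ])$rho, NA_real_)
})

test_that("planted selective shifts are recovered with high sensitivity and low FPR", {
  shifts <- list(selection_spec("mel", "male", 120, body_part = "body"),
                 selection_spec("suz", "female", 120,
                                shift = -default_selection_shift(),
                                body_part = "body"))
  cfg <- sim_config(n_genes = 1200, frac_MB = 0, frac_FB = 0,
                    selection_shifts = shifts, seed = 91)
  sim <- simulate_study(cfg)
  tpm <- compute_tpm(sim$counts, sim$annotation)
  dx <- delta_x_table(tpm, "imm", N = 5, analyzed = filter_expressed(tpm, 0.5))
  truth <- sim$truth$selected
  planted <- paste(dx$gene_id, dx$species, dx$sex, dx$body_part) %in%
    paste(truth$gene_id, truth$species, truth$sex, truth$body_part)
  ok <- !is.na(dx$selected)
  expect_gte(mean(dx$selected[ok & planted]), 0.9)
  expect_lte(mean(dx$selected[ok & !planted]), 0.1)
  # direction matches the planted shift sign
  up <- dx$direction[ok & planted & dx$species == "mel"]
  expect_gte(mean(up == "up"), 0.85)
  dn <- dx$direction[ok & planted & dx$species == "suz"]
  expect_gte(mean(dn == "down"), 0.85)
})
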