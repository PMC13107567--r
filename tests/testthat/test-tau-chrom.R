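test_that("tau reproduces the index arithmetic and boundary profiles", {
  expect_equal(tau(c(5, 5, 5, 5), transform = "none")$tau, 0)
  expect_equal(tau(c(10, 0, 0, 0))$tau, 1)
  expect_equal(tau(c(10, 0, 0, 0), transform = "none")$tau, 1)
  expect_equal(tau(c(1, 0.5), transform = "none")$tau, 0.5)
  expect_true(is.na(tau(c(0, 0, 0))$tau))
  expect_error(tau(5), "2 tissues")
  expect_error(tau(c(-1, 2)), "non-negative")

  # top tissue with alphabetical tie-break
  expect_equal(tau(c(b = 3, a = 3, c = 1))$top_tissue, "a")

  # scale invariance (transform none) and monotone zeroing
  set.seed(6)
  for (i in 1:50) {
    p <- runif(sample(3:12, 1), 0, 10)
    t0 <- tau(p, transform = "none")$tau
    expect_equal(tau(runif(1, 0.5, 5) * p, transform = "none")$tau, t0,
                 tolerance = 1e-12)
    j <- which(p < max(p))[1]
    if (!is.na(j)) {
      p2 <- p; p2[j] <- 0
      expect_gte(tau(p2, transform = "none")$tau, t0 - 1e-12)
    }
  }
})

test_that("tau-bias association recovers the planted tau/|log2fc| coupling", {
  cfg <- sim_config(n_genes = 1000, frac_MB = 0.2, frac_FB = 0.1,
                    tau_bias_coupling = 3, seed = 17)
  sim <- simulate_study(cfg)
  taus <- tau_table(sim$tissues)
  tpm <- compute_tpm(sim$counts, sim$annotation)
  calls <- call_sex_bias_all(sim$counts, filter_expressed(tpm, 0.5))
  tb <- tau_bias_association(taus, calls)
  body_cells <- tb$cells[tb$cells$body_part == "body", ]
  rho_mb <- mean(body_cells$rho[body_cells$category == "MB"], na.rm = TRUE)
  rho_ub <- mean(body_cells$rho[body_cells$category == "UB"], na.rm = TRUE)
  expect_gt(rho_mb, rho_ub)

  # independent tau and magnitude stay near zero
  set.seed(18)
  taus0 <- data.frame(gene_id = sprintf("g%04d", 1:1000), tau = runif(1000))
  calls0 <- data.frame(gene_id = sprintf("g%04d", 1:1000), species = "sp",
                       body_part = "head", category = "UB",
                       log2fc = rnorm(1000))
  tb0 <- tau_bias_association(taus0, calls0)
  expect_lt(abs(tb0$cells$rho[1]), 0.08)

  # identical ranks give rho = 1
  calls1 <- transform(calls0, log2fc = taus0$tau)
  expect_equal(tau_bias_association(taus0, calls1)$cells$rho[1], 1)
})

test_that("X/autosome enrichment matches hand-computed expectations and excludes dot", {
  n <- 1000
  genes <- sprintf("g%04d", 1:n)
  # 200 X + 800 autosomal; overall 10% MB; 10 MB observed on X
  chrom <- c(rep("X", 200), rep("autosome", 800))
  cat <- c(rep("MB", 10), rep("UB", 190),          # X genes
           rep("MB", 90), rep("UB", 710))          # autosomes
  calls <- data.frame(gene_id = genes, species = "sp", body_part = "head",
                      category = cat)
  ann <- data.frame(gene_id = genes, cds_length_bp = 100, chromosome = chrom)
  enr <- xa_enrichment(calls, ann)
  xmb <- enr[enr$chromosome_class == "X" & enr$category == "MB", ]
  expect_equal(xmb$expected, 20)
  expect_equal(xmb$obs_exp, 0.5)
  # expected counts conserve the class totals
  for (cls in c("X", "autosome")) {
    sub <- enr[enr$chromosome_class == cls, ]
    expect_equal(sum(sub$expected), sub$n_class[1])
    expect_equal(sum(sub$observed), sub$n_class[1])
  }

  # homogeneous proportions: all ratios 1 and statistic 0
  cat2 <- rep(c(rep("MB", 1), rep("UB", 9)), 100)
  enr2 <- xa_enrichment(transform(calls, category = cat2), ann)
  expect_equal(enr2$obs_exp[!is.nan(enr2$obs_exp) & enr2$expected > 0],
               rep(1, sum(!is.nan(enr2$obs_exp) & enr2$expected > 0)))
  expect_equal(unique(enr2$statistic), 0)

  # dot genes drop out of both classes
  ann3 <- ann; ann3$chromosome[1:50] <- "dot"
  enr3 <- xa_enrichment(calls, ann3)
  expect_equal(enr3$n_class[enr3$chromosome_class == "X"][1], 150)

  # planted X enrichment of body-FB genes is detected on generator truth
  cfg <- sim_config(n_genes = 1500, frac_MB = 0.1, frac_FB = 0.15,
                    x_fb_factor = 3, seed = 29)
  sim <- simulate_study(cfg)
  truth <- sim$truth$categories
  tb <- truth[truth$body_part == "body" & truth$species == "mel", ]
  calls_t <- data.frame(gene_id = tb$gene_id, species = "mel",
                        body_part = "body", category = tb$true_category)
  enr4 <- xa_enrichment(calls_t, sim$annotation)
  fbx <- enr4[enr4$chromosome_class == "X" & enr4$category == "FB", ]
  expect_gt(fbx$obs_exp, 1)
  expect_lt(fbx$p, 0.05)
})
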