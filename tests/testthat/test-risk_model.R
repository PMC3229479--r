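test_that("Hardy-Weinberg genotype frequencies", {
  expect_equal(hwe_genotype_freqs(0.5), c(0.25, 0.5, 0.25))
  expect_equal(hwe_genotype_freqs(0), c(1, 0, 0))
  expect_equal(hwe_genotype_freqs(0.13), c(0.7569, 0.2262, 0.0169))
  expect_error(hwe_genotype_freqs(-0.1), "raf")
  expect_error(hwe_genotype_freqs(1.1), "raf")
})

test_that("case allele frequency follows odds scaling by the per-allele OR", {
  expect_equal(case_allele_freq(0.30, 1.0), 0.30)
  expect_equal(case_allele_freq(0.5, 4.0), 0.8)
  # HLA tag SNP: odds 3.08 * 0.13/0.87 = 0.4601, freq 0.4601/1.4601
  expect_equal(case_allele_freq(0.13, 3.08), 0.3152, tolerance = 1e-3)
  expect_error(case_allele_freq(0, 2), "raf_controls")
  expect_error(case_allele_freq(1, 2), "raf_controls")
  expect_error(case_allele_freq(0.3, 0), "per_allele_or")
})

test_that("per-variant likelihood ratios: null variant, HLA, bounded weak effect", {
  null_lr <- build_variant_lr("rsX", 0.37, 1.0)
  expect_equal(null_lr$lr_by_count, c(1, 1, 1))

  hla <- build_variant_lr("rs3135388", 0.13, 3.08)
  expect_equal(hla$lr_by_count, c(0.6195, 1.9080, 5.8767), tolerance = 5e-4)

  weak <- build_variant_lr("rsY", 0.30, 1.1)
  expect_true(all(weak$lr_by_count >= 0.9 & weak$lr_by_count <= 1.25))
})

test_that("calibration identities hold exactly for every packaged variant", {
  m <- build_risk_model(builtin_panel("panel_53"), 0.001)
  expect_equal(unname(rowSums(m$freq_cases)), rep(1, 53), tolerance = 1e-12)
  expect_equal(unname(rowSums(m$freq_controls)), rep(1, 53), tolerance = 1e-12)
  expect_equal(m$lr * m$freq_controls, m$freq_cases, tolerance = 1e-15)
  # expectation of the LR under the control genotype distribution is 1
  expect_equal(unname(rowSums(m$freq_controls * m$lr)), rep(1, 53),
               tolerance = 1e-12)
  # monotone LRs whenever OR >= 1
  ors <- builtin_panel("panel_53")$variants$or
  mono <- m$lr[, 2] >= m$lr[, 1] & m$lr[, 3] >= m$lr[, 2]
  expect_true(all(mono[ors >= 1]))
})

test_that("penetrance-based construction agrees with the allele-odds route", {
  v <- builtin_panel("panel_6")$variants
  for (j in seq_len(nrow(v))) {
    a <- build_variant_lr(v$rsid[j], v$raf[j], v$or[j])
    b <- build_variant_lr_penetrance(v$rsid[j], v$raf[j], v$or[j], 0.001)
    expect_equal(b$lr_by_count, a$lr_by_count, tolerance = 5e-3)
  }
  # and the resulting model AUCs agree to three decimals at p = 0.001
  m <- build_risk_model(builtin_panel("panel_6"), 0.001)
  m_pen <- m
  for (j in seq_len(6)) {
    b <- build_variant_lr_penetrance(v$rsid[j], v$raf[j], v$or[j], 0.001)
    m_pen$freq_controls[j, ] <- b$freq_controls
    m_pen$freq_cases[j, ] <- b$freq_cases
    m_pen$lr[j, ] <- b$lr_by_count
    m_pen$log_lr[j, ] <- log(b$lr_by_count)
  }
  expect_equal(analytic_auc(m_pen), analytic_auc(m), tolerance = 5e-4)
})

test_that("posterior risk applies Bayes updating in log space", {
  p6 <- builtin_panel("panel_6")
  null_panel <- new_panel(transform(p6$variants, or = 1), name = "null6")
  m_null <- build_risk_model(null_panel, 0.001)
  g <- matrix(sample(0:2, 60, replace = TRUE), ncol = 6)
  expect_equal(posterior_risk(m_null, g), rep(0.001, 10))

  hla_only <- new_panel(p6$variants[p6$variants$rsid == "rs3135388", ])
  m_hla <- build_risk_model(hla_only, 0.001)
  expect_equal(posterior_risk(m_hla, 2L), 0.005851, tolerance = 5e-4)

  m_flat <- build_risk_model(new_panel(p6$variants[1, , drop = FALSE]), 0.5)
  flat <- build_risk_model(new_panel(transform(p6$variants[1, , drop = FALSE],
                                               or = 1)), 0.5)
  expect_equal(posterior_risk(flat, 1L), 0.5)

  expect_error(posterior_risk(m_hla, 3L), "genotype values")
  expect_error(posterior_risk(build_risk_model(p6, 0.001), c(0L, 1L)),
               "does not match panel size")
})

test_that("posterior risk is nondecreasing in each genotype when ORs >= 1", {
  m <- build_risk_model(builtin_panel("panel_6"), 0.001)
  set.seed(11)
  for (i in 1:25) {
    g <- sample(0:2, 6, replace = TRUE)
    j <- sample(6, 1)
    if (g[j] == 2) next
    g_up <- g; g_up[j] <- g[j] + 1L
    expect_gte(posterior_risk(m, g_up), posterior_risk(m, g))
  }
})

test_that("enumeration AUC: null model, single-variant closed form, capacity", {
  p6 <- builtin_panel("panel_6")
  null1 <- new_panel(transform(p6$variants[1, , drop = FALSE], or = 1))
  expect_equal(analytic_auc(build_risk_model(null1, 0.001)), 0.5)

  hla_only <- new_panel(p6$variants[p6$variants$rsid == "rs3135388", ])
  expect_equal(analytic_auc(build_risk_model(hla_only, 0.001)),
               pair_auc_one_variant(0.13, 3.08), tolerance = 1e-12)

  expect_error(analytic_auc(build_risk_model(builtin_panel("panel_53"), 0.001)),
               "capacity error")
})

test_that("AUC is invariant to strictly increasing score transforms", {
  m <- build_risk_model(builtin_panel("panel_6"), 0.001)
  set.seed(12)
  g <- simulate_genotypes(m, 5000, seed = 3)
  risk <- posterior_risk(m, g)
  log_odds <- log(risk / (1 - risk))
  status <- assign_disease(pmin(risk * 50, 1), seed = 4)  # enrich cases
  expect_identical(empirical_auc(risk, status), empirical_auc(log_odds, status))
})
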