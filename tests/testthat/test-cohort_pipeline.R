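test_that("a-priori risk is the case fraction among complete subjects", {
  co <- toy_cohort(status = rep(c(1, 0), c(564, 581)),
                   genotypes = rep(0L, 1145))
  expect_equal(round(100 * a_priori_risk(co)), 49)
  expect_equal(a_priori_risk(toy_cohort(c(1, 0), c(0, 0))), 0.5)
  expect_equal(a_priori_risk(toy_cohort(c(1, 1), c(0, 0))), 1.0)
  # incomplete subjects are excluded from the denominator
  co2 <- toy_cohort(c(1, 1, 0), c(0, NA, 0))
  expect_equal(a_priori_risk(co2), 0.5)
})

test_that("weighted scores multiply allele counts by ln(OR) for complete subjects", {
  pe <- builtin_panel("panel_empirical_6")
  co <- generate_cohort(cohort_spec(n_cases = 40, n_controls = 40, seed = 12,
                                    missing_rate = 0))
  sc <- weighted_scores(co, pe)
  expect_equal(nrow(sc), 80L)

  g <- as.matrix(co[, pe$variants$rsid])
  expect_equal(sc$weighted_score, as.numeric(g %*% log(pe$variants$or)))
  expect_equal(sc$risk_allele_count, as.integer(rowSums(g)))

  # hand-built subject: homozygous HLA risk, zero elsewhere
  hand <- co[1, ]
  hand[, pe$variants$rsid] <- 0L
  hand$rs3135388 <- 2L
  sc1 <- weighted_scores(hand, pe)
  expect_equal(sc1$weighted_score, 2 * log(2.53), tolerance = 1e-12)
  hand$rs3135388 <- 0L
  expect_equal(weighted_scores(hand, pe)$weighted_score, 0)

  # raw-OR weighting behind the flag
  sc_or <- weighted_scores(co, pe, weights = "or")
  expect_equal(sc_or$weighted_score, as.numeric(g %*% pe$variants$or))

  co$rs3135388[1] <- NA_integer_
  expect_equal(nrow(weighted_scores(co, pe)), 79L)
})

test_that("per-SNP logistic regression recovers generative ORs on large cohorts", {
  spec <- cohort_spec(n_cases = 3000, n_controls = 3000, seed = 14,
                      missing_rate = 0)
  co <- generate_cohort(spec)
  assoc <- per_snp_association(co, adjust = "age_sex")
  true_or <- builtin_panel("panel_empirical_6")$variants$or
  covered <- assoc$ci_low <= true_or & true_or <= assoc$ci_high
  expect_gte(sum(covered), 5L)
  expect_equal(attr(assoc, "bonferroni_alpha"), 0.05 / 6)
  # HLA is overwhelmingly significant at this size
  expect_true(assoc$significant[assoc$rsid == "rs3135388"])
})

test_that("association flags degenerate variants instead of fitting them", {
  co <- toy_cohort(status = rep(c(1, 0), 10), genotypes = rep(0L, 20))
  assoc <- per_snp_association(co, adjust = "none")
  expect_true(assoc$separation[1])
  expect_true(is.na(assoc$p_value[1]))
})

test_that("deviation coding makes bin effects average to zero over bin sizes", {
  co <- generate_cohort(cohort_spec(seed = 15))
  sc <- weighted_scores(co, builtin_panel("panel_empirical_6"))
  b <- binned_or_vs_prior(sc, n_variants = 6, adjust = "none")
  expect_equal(sum(b$n * log(b$or_vs_prior)), 0, tolerance = 1e-8)
  # saturated unadjusted model: bin effect = bin log-odds minus their
  # size-weighted mean (the overall reference)
  lo <- log(b$n_cases / b$n_controls)
  expect_equal(log(b$or_vs_prior), lo - sum(b$n * lo) / sum(b$n),
               tolerance = 1e-8)
  expect_true(all(b$ci_low < b$or_vs_prior & b$or_vs_prior < b$ci_high))
})

test_that("risk gradient: top bin exceeds the prior, bottom bin falls below", {
  co <- generate_cohort(cohort_spec(seed = 16))
  sc <- weighted_scores(co, builtin_panel("panel_empirical_6"))
  b <- binned_or_vs_prior(sc, n_variants = 6)
  expect_gt(b$or_vs_prior[nrow(b)], 1)
  expect_lt(b$or_vs_prior[1], 1)
})

test_that("excluding the HLA variant flattens the risk gradient", {
  pe <- builtin_panel("panel_empirical_6")
  p5 <- new_panel(pe$variants[pe$variants$rsid != "rs3135388", ], "no_hla")
  top6 <- numeric(10); top5 <- numeric(10)
  for (s in 1:10) {
    co <- generate_cohort(cohort_spec(seed = 500 + s))
    sc6 <- weighted_scores(co, pe)
    sc5 <- weighted_scores(co, p5)
    b6 <- binned_or_vs_prior(sc6, n_variants = 6)
    b5 <- binned_or_vs_prior(sc5, n_variants = 5)
    top6[s] <- b6$or_vs_prior[nrow(b6)]
    top5[s] <- b5$or_vs_prior[nrow(b5)]
  }
  expect_lt(mean(top5), mean(top6))
  expect_gt(mean(top5), 1)  # residual gradient without HLA
})

test_that("cohort AUC behaves at the extremes and matches the rank route", {
  expect_equal(cohort_auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1.0)
  pe <- builtin_panel("panel_empirical_6")
  null_panel <- new_panel(transform(pe$variants, or = 1), "null6")
  co <- generate_cohort(cohort_spec(panel = null_panel, seed = 18))
  sc <- weighted_scores(co, pe)  # weights from real panel, null generator
  expect_lt(abs(cohort_auc(sc) - 0.5), 0.06)
})

test_that("bin OR figure builds without evaluation errors", {
  co <- generate_cohort(cohort_spec(seed = 19))
  sc <- weighted_scores(co, builtin_panel("panel_empirical_6"))
  b <- binned_or_vs_prior(sc, n_variants = 6)
  p <- plot_bin_or(b)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gte(length(built$data), 2L)
})
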