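# Independent oracles used across tests.

# brute-force AUC: count case-control pairs, ties worth 1/2
brute_auc <- function(scores, status) {
  cases <- scores[status == 1]
  ctrls <- scores[status == 0]
  tot <- 0
  for (a in cases) for (b in ctrls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(ctrls))
}

# closed-form AUC for a single three-genotype variant: sum over the 9
# ordered (case genotype, control genotype) pairs; LR (hence score) is
# increasing in allele count when OR > 1
pair_auc_one_variant <- function(raf, or) {
  q_case <- (or * raf / (1 - raf)) / (1 + or * raf / (1 - raf))
  f0 <- c((1 - raf)^2, 2 * raf * (1 - raf), raf^2)
  f1 <- c((1 - q_case)^2, 2 * q_case * (1 - q_case), q_case^2)
  auc <- 0
  for (gc in 0:2) for (g0 in 0:2) {
    w <- f1[gc + 1] * f0[g0 + 1]
    auc <- auc + w * ((gc > g0) + 0.5 * (gc == g0))
  }
  auc
}

# toy cohort table built by hand (one variant), for pipeline edge cases
toy_cohort <- function(status, genotypes, age = NULL, sex = NULL) {
  n <- length(status)
  structure(data.frame(subject_id = sprintf("T%03d", seq_len(n)),
                       status = as.integer(status),
                       age = if (is.null(age)) rep(50, n) else age,
                       sex = if (is.null(sex)) rep("female", n) else sex,
                       rs0001 = as.integer(genotypes),
                       stringsAsFactors = FALSE),
            class = c("cohort_table", "data.frame"),
            panel_rsids = "rs0001")
}
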