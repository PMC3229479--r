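# Replicate seeds are derived from one master seed by a fixed counter scheme
# so that replicates are independent, reproducible and re-drawable. Streams:
# 0 = genotypes, 1 = disease status; retries bump the rep counter by 10000.
derive_seed <- function(master_seed, rep, stream = 0L) {
  as.integer((as.double(master_seed) * 48271 + rep * 1009 + stream * 523) %%
               2147483587)
}

#' Simulate genotype risk-allele counts for a population
#'
#' Each variant is drawn independently from its control genotype distribution
#' (at a 0.1% lifetime risk the population is control-dominated, so control
#' frequencies stand in for population frequencies). Columns follow panel
#' order.
#'
#' @param model a `risk_model`.
#' @param n number of individuals.
#' @param seed integer seed; the same seed reproduces the same matrix.
#' @return n x K integer matrix with values in \{0,1,2\}.
#' @export
simulate_genotypes <- function(model, n, seed) {
  stopifnot(n >= 1)
  k <- panel_size(model$panel)
  set.seed(seed)
  g <- matrix(0L, nrow = n, ncol = k,
              dimnames = list(NULL, model$panel$variants$rsid))
  for (j in seq_len(k)) {
    f <- model$freq_controls[j, ]
    u <- stats::runif(n)
    g[, j] <- (u > f[1]) + (u > f[1] + f[2])
  }
  g
}

#' Assign disease status from posterior risks
#'
#' Independent Bernoulli draw per individual with success probability equal
#' to the individual's posterior risk, so the joint genotype-status law
#' implied by the likelihood ratios is preserved and the realized prevalence
#' matches the prior in expectation.
#'
#' @param posterior vector of risks in (0,1) (0 and 1 allowed as degenerate
#'   probabilities).
#' @param seed integer seed.
#' @return integer vector of 0/1 disease indicators.
#' @export
assign_disease <- function(posterior, seed) {
  if (any(!is.finite(posterior)) || any(posterior < 0) || any(posterior > 1)) {
    stop("validation error: posterior risks must lie in [0,1]")
  }
  set.seed(seed)
  as.integer(stats::runif(length(posterior)) < posterior)
}

#' Empirical AUC (Mann-Whitney with midrank ties)
#'
#' Probability that a randomly chosen case scores higher than a randomly
#' chosen control, ties counted half; computed from the rank-sum statistic
#' and identical to brute-force pair counting.
#'
#' @param scores numeric risk scores.
#' @param status 0/1 disease indicators, same length.
#' @return AUC in \[0,1\].
#' @examples
#' empirical_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
empirical_auc <- function(scores, status) {
  stopifnot(length(scores) == length(status))
  status <- as.integer(status)
  n1 <- sum(status == 1L)
  n0 <- sum(status == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("undefined AUC: need at least one case and one control")
  }
  r <- rank(scores)
  (sum(r[status == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Monte-Carlo AUC of a risk panel over repeated population simulations
#'
#' For each replicate: draw genotypes for `n_individuals`, compute posterior
#' risks under the Bayes likelihood-ratio model, assign disease status by
#' Bernoulli draws from those risks, and score the Mann-Whitney AUC of the
#' posterior risk against status. Replicates that happen to contain zero
#' cases (possible at low prevalence) are re-drawn with a fresh derived seed,
#' at most 5 times. Returns all replicate AUCs and their mean.
#'
#' @param panel a `risk_panel` (or anything [resolve_panel()] accepts).
#' @param config a [study_config()].
#' @param verbose if TRUE, prints one line per replicate.
#' @return An object of class `auc_distribution`: list with `per_rep_auc`,
#'   `mean_auc`, `sd_auc`, `n_reps`, `panel_name`, `config`.
#' @examples
#' run_scenario(builtin_panel("panel_6"),
#'              study_config(n_individuals = 2000, n_reps = 2, master_seed = 1))
#' @export
run_scenario <- function(panel, config = study_config(), verbose = FALSE) {
  panel <- resolve_panel(panel)
  model <- build_risk_model(panel, config$population_risk)
  aucs <- numeric(config$n_reps)
  for (r in seq_len(config$n_reps)) {
    aucs[r] <- simulate_one_rep(model, config, r, verbose = verbose)
  }
  structure(list(per_rep_auc = aucs, mean_auc = mean(aucs),
                 sd_auc = stats::sd(aucs), n_reps = config$n_reps,
                 panel_name = panel$name, config = config),
            class = "auc_distribution")
}

simulate_one_rep <- function(model, config, r, verbose = FALSE) {
  for (attempt in 0:5) {
    rep_id <- r + attempt * 10000L
    g <- simulate_genotypes(model, config$n_individuals,
                            derive_seed(config$master_seed, rep_id, 0L))
    s <- score_log_lr(model, g)
    prior_lo <- log(config$population_risk / (1 - config$population_risk))
    risk <- 1 / (1 + exp(-(prior_lo + s)))
    status <- assign_disease(risk, derive_seed(config$master_seed, rep_id, 1L))
    n_cases <- sum(status)
    if (n_cases > 0L && n_cases < length(status)) {
      auc <- empirical_auc(s, status)
      if (verbose) {
        message(sprintf("rep %d: seed %d, %d cases, AUC %.4f", r,
                        derive_seed(config$master_seed, rep_id, 0L),
                        n_cases, auc))
      }
      return(auc)
    }
    message("replicate ", r, " drew a single-class population; re-drawing")
  }
  stop("replicate ", r, " failed to produce both classes after 5 retries")
}

#' @export
print.auc_distribution <- function(x, ...) {
  cat(sprintf("<auc_distribution> %s: mean AUC %.4f (SD %.4f) over %d replicate(s)\n",
              x$panel_name, x$mean_auc, x$sd_auc, x$n_reps))
  invisible(x)
}

#' Write per-replicate AUCs to a TSV file
#'
#' @param auc an `auc_distribution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_auc_tsv <- function(auc, path) {
  tab <- data.frame(rep = seq_len(auc$n_reps), auc = auc$per_rep_auc)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' ROC curve points for a scored population
#'
#' False- and true-positive rates over the observed score thresholds,
#' suitable for plotting a ROC curve.
#'
#' @param scores numeric risk scores.
#' @param status 0/1 disease indicators.
#' @param n_grid optional number of evenly spaced FPR grid points; by default
#'   all distinct thresholds are returned.
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, status, n_grid = NULL) {
  status <- as.integer(status)
  o <- order(scores, decreasing = TRUE)
  st <- status[o]
  tpr <- cumsum(st) / sum(st)
  fpr <- cumsum(1L - st) / sum(1L - st)
  keep <- !duplicated(scores[o], fromLast = TRUE)
  out <- rbind(data.frame(fpr = 0, tpr = 0),
               data.frame(fpr = fpr[keep], tpr = tpr[keep]))
  if (!is.null(n_grid)) {
    grid <- seq(0, 1, length.out = n_grid)
    out <- data.frame(fpr = grid,
                      tpr = stats::approx(out$fpr, out$tpr, xout = grid,
                                          ties = "ordered", rule = 2)$y)
  }
  out
}
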