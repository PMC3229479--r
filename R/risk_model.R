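#' Hardy-Weinberg genotype distribution
#'
#' Genotype probabilities for carrying 0, 1 or 2 copies of an allele with
#' frequency `raf` under Hardy-Weinberg equilibrium:
#' \eqn{((1-q)^2, 2q(1-q), q^2)}.
#'
#' @param raf allele frequency in \[0,1\].
#' @return numeric vector of length 3 summing to 1.
#' @examples
#' hwe_genotype_freqs(0.13)
#' @export
hwe_genotype_freqs <- function(raf) {
  if (!is.finite(raf) || raf < 0 || raf > 1) {
    stop("validation error: raf must lie in [0,1], got ", raf)
  }
  c((1 - raf)^2, 2 * raf * (1 - raf), raf^2)
}

#' Case risk-allele frequency implied by a per-allele odds ratio
#'
#' Scales the control allele odds by the per-allele OR:
#' \eqn{q_{case}/(1-q_{case}) = OR \cdot q/(1-q)}.
#'
#' @param raf_controls risk-allele frequency in controls, strictly in (0,1).
#' @param per_allele_or per-allele odds ratio, > 0.
#' @return case allele frequency in (0,1).
#' @examples
#' case_allele_freq(0.13, 3.08)  # 0.3152
#' @export
case_allele_freq <- function(raf_controls, per_allele_or) {
  if (!is.finite(raf_controls) || raf_controls <= 0 || raf_controls >= 1) {
    stop("validation error: raf_controls must lie strictly in (0,1)")
  }
  if (!is.finite(per_allele_or) || per_allele_or <= 0) {
    stop("validation error: per_allele_or must be > 0")
  }
  odds <- per_allele_or * raf_controls / (1 - raf_controls)
  odds / (1 + odds)
}

#' Per-genotype likelihood ratios for one variant
#'
#' Builds the genotype-by-disease-status structure for a single variant from
#' its control risk-allele frequency and per-allele odds ratio. Controls
#' follow HWE at `raf`; cases follow HWE at the OR-scaled case allele
#' frequency (equivalently, case genotype frequencies are proportional to
#' control frequencies times \eqn{OR^g}). The likelihood ratio of genotype g
#' is \eqn{P(g|case)/P(g|control)}.
#'
#' @param rsid variant identifier.
#' @param raf control risk-allele frequency, strictly in (0,1).
#' @param or per-allele odds ratio.
#' @return list with `rsid`, `freq_controls`, `freq_cases`, `lr_by_count`
#'   (all length-3, indexed by risk-allele count 0/1/2).
#' @examples
#' build_variant_lr("rs3135388", 0.13, 3.08)$lr_by_count
#' @export
build_variant_lr <- function(rsid, raf, or) {
  f_ctrl <- hwe_genotype_freqs(raf)
  if (any(f_ctrl == 0)) {
    stop("validation error: control genotype frequency 0 for ", rsid)
  }
  q_case <- case_allele_freq(raf, or)
  f_case <- hwe_genotype_freqs(q_case)
  list(rsid = rsid, freq_controls = f_ctrl, freq_cases = f_case,
       lr_by_count = f_case / f_ctrl)
}

#' Cross-check constructor: likelihood ratios via genotype penetrances
#'
#' Alternative route to the same calibration: treat the per-allele OR as the
#' heterozygote odds ratio (homozygote OR = square), keep HWE genotype
#' frequencies in the population, and solve the baseline genotype risk so
#' that the marginal disease risk equals `population_risk` (root bracketing
#' to |delta| < 1e-12). Case/control genotype frequencies then follow from
#' the penetrances. At low population risk this agrees with
#' [build_variant_lr()] to high accuracy; it is retained as an independent
#' verification route.
#'
#' @inheritParams build_variant_lr
#' @param population_risk marginal disease risk constraint.
#' @return list with the same shape as [build_variant_lr()].
#' @export
build_variant_lr_penetrance <- function(rsid, raf, or, population_risk = 0.001) {
  f_pop <- hwe_genotype_freqs(raf)
  or_g <- c(1, or, or^2)
  marginal <- function(odds0) {
    risk_g <- (odds0 * or_g) / (1 + odds0 * or_g)
    sum(f_pop * risk_g) - population_risk
  }
  root <- stats::uniroot(marginal, lower = 1e-300, upper = 1e6,
                         tol = .Machine$double.eps)$root
  risk_g <- (root * or_g) / (1 + root * or_g)
  f_case <- f_pop * risk_g / sum(f_pop * risk_g)
  f_ctrl <- f_pop * (1 - risk_g) / sum(f_pop * (1 - risk_g))
  list(rsid = rsid, freq_controls = f_ctrl, freq_cases = f_case,
       lr_by_count = f_case / f_ctrl)
}

#' Calibrate a Bayes multi-variant risk model
#'
#' One likelihood-ratio triple per panel variant plus the population prior.
#' Posterior disease odds for an individual are prior odds times the product
#' of the genotype likelihood ratios across variants (independent effects;
#' no interaction terms, no linkage disequilibrium).
#'
#' @param panel a `risk_panel`.
#' @param population_risk Bayes prior disease risk p; prior odds = p/(1-p).
#' @return An object of class `risk_model`: list with `panel`,
#'   `population_risk`, and K x 3 matrices `freq_controls`, `freq_cases`,
#'   `lr` and `log_lr` (rows follow panel order).
#' @examples
#' m <- build_risk_model(builtin_panel("panel_6"), 0.001)
#' @export
build_risk_model <- function(panel, population_risk = 0.001) {
  validate_panel(panel)
  stopifnot(population_risk > 0, population_risk < 1)
  v <- panel$variants
  k <- nrow(v)
  fc <- fd <- lr <- matrix(NA_real_, nrow = k, ncol = 3L,
                           dimnames = list(v$rsid, c("g0", "g1", "g2")))
  for (j in seq_len(k)) {
    vl <- build_variant_lr(v$rsid[j], v$raf[j], v$or[j])
    fc[j, ] <- vl$freq_controls
    fd[j, ] <- vl$freq_cases
    lr[j, ] <- vl$lr_by_count
  }
  structure(list(panel = panel, population_risk = population_risk,
                 freq_controls = fc, freq_cases = fd,
                 lr = lr, log_lr = log(lr)),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %s: %d variant(s), prior risk %g\n",
              x$panel$name, panel_size(x$panel), x$population_risk))
  invisible(x)
}

# Sum of per-variant log LRs for a genotype matrix (internal hot path).
# genotypes: n x K integer matrix of risk-allele counts.
score_log_lr <- function(model, genotypes) {
  k <- panel_size(model$panel)
  if (is.null(dim(genotypes))) {
    if (length(genotypes) != k) {
      stop("validation error: genotype vector length ", length(genotypes),
           " does not match panel size ", k)
    }
    genotypes <- matrix(genotypes, ncol = max(k, 1L))
  }
  if (ncol(genotypes) != k) {
    stop("validation error: genotype matrix has ", ncol(genotypes),
         " columns; panel size is ", k)
  }
  bad <- !(genotypes %in% c(0L, 1L, 2L))
  if (any(bad)) stop("validation error: genotype values must be 0, 1 or 2")
  s <- numeric(nrow(genotypes))
  for (j in seq_len(k)) {
    s <- s + unname(model$log_lr[j, genotypes[, j] + 1L])
  }
  s
}

#' Posterior disease risk for genotype profiles
#'
#' Applies Bayes' theorem in log space: posterior log odds = log prior odds
#' plus the sum of per-variant genotype log likelihood ratios; the posterior
#' risk is odds/(1+odds).
#'
#' @param model a `risk_model`.
#' @param genotypes vector of risk-allele counts (one individual) or an
#'   n x K matrix (one row per individual), values in \{0,1,2\}.
#' @return numeric vector of posterior risks in (0,1).
#' @examples
#' m <- build_risk_model(builtin_panel("panel_6"), 0.001)
#' posterior_risk(m, rep(0L, 6))
#' @export
posterior_risk <- function(model, genotypes) {
  log_odds <- log(model$population_risk / (1 - model$population_risk)) +
    score_log_lr(model, genotypes)
  1 / (1 + exp(-log_odds))
}

#' Exact AUC of a risk model by genotype enumeration
#'
#' Enumerates all 3^K genotype combinations, scores each with the model's
#' posterior log odds, and computes the probability that a random case
#' outscores a random control (ties counted half), where case combinations
#' are distributed as the product of per-variant case genotype frequencies
#' and controls as the product of control frequencies. Serves as the exact
#' oracle for the Monte-Carlo AUC at low population risk.
#'
#' @param model a `risk_model`.
#' @param max_variants enumeration cap; panels above it raise a capacity
#'   error directing the caller to the Monte-Carlo route (default 12).
#' @return AUC in \[0.5, 1).
#' @examples
#' analytic_auc(build_risk_model(builtin_panel("panel_6"), 0.001))
#' @export
analytic_auc <- function(model, max_variants = 12L) {
  k <- panel_size(model$panel)
  if (k > max_variants) {
    stop("capacity error: panel has ", k, " variants; enumeration capped at ",
         max_variants, " (3^K combinations). Use run_scenario() for Monte Carlo.")
  }
  if (k == 0L) return(0.5)
  combos <- as.matrix(expand.grid(rep(list(0L:2L), k), KEEP.OUT.ATTRS = FALSE))
  idx <- cbind(rep(seq_len(k), each = nrow(combos)), as.vector(combos) + 1L)
  p_ctrl <- matrix(model$freq_controls[idx], nrow = nrow(combos))
  p_case <- matrix(model$freq_cases[idx], nrow = nrow(combos))
  s <- rowSums(matrix(model$log_lr[idx], nrow = nrow(combos)))
  p0 <- apply(p_ctrl, 1, prod)
  p1 <- apply(p_case, 1, prod)
  o <- order(s)
  s <- s[o]; p0 <- p0[o]; p1 <- p1[o]
  # group scores equal to within 1e-12 on the log-odds axis as ties
  grp <- cumsum(c(1, diff(s) > 1e-12))
  P0 <- as.numeric(tapply(p0, grp, sum))
  P1 <- as.numeric(tapply(p1, grp, sum))
  below <- c(0, cumsum(P0)[-length(P0)])
  sum(P1 * (below + P0 / 2))
}
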