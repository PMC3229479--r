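#' Add hypothetical variants to a panel
#'
#' Appends `k` exchangeable hypothetical variants, all sharing one control
#' risk-allele frequency and one per-allele odds ratio, with rsids
#' `synth_1..synth_k`.
#'
#' @param base a `risk_panel`.
#' @param k number of variants to add (k = 0 returns the base unchanged).
#' @param raf control risk-allele frequency of the added variants.
#' @param or_value per-allele odds ratio of the added variants.
#' @return A `risk_panel` of `panel_size(base) + k` variants.
#' @examples
#' augment_panel(builtin_panel("panel_53"), 20, 0.30, 1.1)
#' @export
augment_panel <- function(base, k, raf, or_value) {
  stopifnot(k >= 0)
  if (k == 0L) return(base)
  extra <- data.frame(gene = paste0("SYNTH", seq_len(k)),
                      rsid = paste0("synth_", seq_len(k)),
                      chrom = "NA", risk_allele = "A",
                      raf = raf, or = or_value)
  new_panel(rbind(base$variants, extra),
            name = sprintf("%s+%dx(raf=%g,or=%g)", base$name, k, raf, or_value))
}

#' Specification of an inverse odds-ratio search
#'
#' @param base_panel base `risk_panel` the hypothetical variants are added to.
#' @param n_extra number of added variants.
#' @param raf_extra their shared control risk-allele frequency.
#' @param target_auc mean AUC to reach.
#' @param reps_per_eval simulation replicates per objective evaluation
#'   (default 20, the grid's own convention).
#' @return list of class `search_spec`.
#' @export
search_spec <- function(base_panel, n_extra, raf_extra, target_auc,
                        reps_per_eval = 20L) {
  stopifnot(n_extra >= 1, raf_extra > 0, raf_extra < 1,
            target_auc > 0.5, target_auc < 1, reps_per_eval >= 1)
  structure(list(base_panel = base_panel, n_extra = as.integer(n_extra),
                 raf_extra = raf_extra, target_auc = target_auc,
                 reps_per_eval = as.integer(reps_per_eval)),
            class = "search_spec")
}

#' Mean AUC of the augmented panel at a candidate odds ratio
#'
#' Runs the population simulation on `base_panel` plus `n_extra` hypothetical
#' variants at the candidate OR, with `reps_per_eval` replicates. Replicate
#' seeds derive from `config$master_seed` only, so successive calls with
#' different candidate ORs share common random numbers: the objective is
#' then monotone in the OR up to coupling noise, which keeps the bisection
#' well behaved.
#'
#' @param spec a [search_spec()].
#' @param or_value candidate per-allele OR (>= 1).
#' @param config a [study_config()]; its `n_reps` is overridden by
#'   `spec$reps_per_eval`.
#' @return mean AUC.
#' @export
mean_auc_at <- function(spec, or_value, config = study_config()) {
  stopifnot(or_value >= 1)
  aug <- augment_panel(spec$base_panel, spec$n_extra, spec$raf_extra, or_value)
  cfg <- study_config(population_risk = config$population_risk,
                      n_individuals = config$n_individuals,
                      n_reps = spec$reps_per_eval,
                      master_seed = config$master_seed)
  run_scenario(aug, cfg)$mean_auc
}

#' Required per-allele odds ratio to reach a target mean AUC
#'
#' Bisection on the OR axis with common random numbers. If the mean AUC of
#' the base panel alone (OR = 1) already meets the target the search returns
#' 1.0. Otherwise the upper bracket grows geometrically from 2 until the
#' target is met, capped at `or_max` (probing only as far up the OR axis as
#' needed keeps every evaluation in the regime where a finite population
#' still realizes the nominal prevalence); if the AUC at `or_max` is still
#' below the target a bracket error is raised reporting that AUC. Bisection
#' then stops when the bracket is narrower than `tol` on the OR axis; the
#' midpoint is reported rounded to one decimal, the resolution the study
#' grid uses.
#'
#' @param spec a [search_spec()].
#' @param config a [study_config()].
#' @param or_max upper end of the search bracket (default 20).
#' @param tol bracket-width convergence criterion (default 0.05).
#' @return list of class `search_result` with `required_or` (one decimal),
#'   `or_exact` (unrounded midpoint), `evaluations` (data.frame of or,
#'   mean_auc), `converged`, and the spec.
#' @export
required_or <- function(spec, config = study_config(), or_max = 20,
                        tol = 0.05) {
  evals <- list()
  eval_or <- function(o) {
    a <- mean_auc_at(spec, o, config)
    evals[[length(evals) + 1L]] <<- data.frame(or = o, mean_auc = a)
    a
  }
  auc_lo <- eval_or(1)
  if (auc_lo >= spec$target_auc) {
    return(structure(list(required_or = 1.0, or_exact = 1.0,
                          evaluations = do.call(rbind, evals),
                          converged = TRUE, spec = spec),
                     class = "search_result"))
  }
  lo <- 1
  hi <- min(2, or_max)
  auc_hi <- eval_or(hi)
  while (auc_hi < spec$target_auc && hi < or_max) {
    lo <- hi
    hi <- min(hi * 2, or_max)
    auc_hi <- eval_or(hi)
  }
  if (auc_hi < spec$target_auc) {
    stop(sprintf(
      "bracket error: mean AUC at or_max = %g is %.4f, below target %.2f",
      or_max, auc_hi, spec$target_auc))
  }
  while (hi - lo >= tol) {
    mid <- (lo + hi) / 2
    if (eval_or(mid) >= spec$target_auc) hi <- mid else lo <- mid
  }
  mid <- (lo + hi) / 2
  structure(list(required_or = round(mid, 1), or_exact = mid,
                 evaluations = do.call(rbind, evals),
                 converged = TRUE, spec = spec),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf(
    "<search_result> %d extra @ raf %.2f -> AUC %.2f: required OR %.1f (%d evaluation(s))\n",
    x$spec$n_extra, x$spec$raf_extra, x$spec$target_auc, x$required_or,
    nrow(x$evaluations)))
  invisible(x)
}

#' Full inverse-search grid
#'
#' Runs [required_or()] for every combination of added-variant frequency,
#' added-variant count and target AUC, mirroring the layout of the study's
#' requirement table. Cells whose target is unreachable within the bracket
#' are recorded with `NA` and the grid continues.
#'
#' @param config a [study_config()].
#' @param base_panel base panel (default the 53-variant panel).
#' @param rafs added-variant frequencies (default 0.05, 0.30, 0.50).
#' @param counts added-variant counts (default 1, 5, 20, 50, 100).
#' @param targets target AUCs (default 0.70, 0.75, 0.80, 0.85).
#' @param reps_per_eval replicates per objective evaluation (default 20).
#' @return data.frame with columns raf, n_extra, target_auc, required_or,
#'   mean_auc_achieved, n_evals.
#' @export
table4_grid <- function(config = study_config(),
                        base_panel = builtin_panel("panel_53"),
                        rafs = c(0.05, 0.30, 0.50),
                        counts = c(1L, 5L, 20L, 50L, 100L),
                        targets = c(0.70, 0.75, 0.80, 0.85),
                        reps_per_eval = 20L) {
  grid <- expand.grid(raf = rafs, n_extra = counts, target_auc = targets,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$raf, grid$n_extra, grid$target_auc), ]
  rownames(grid) <- NULL
  grid$required_or <- NA_real_
  grid$mean_auc_achieved <- NA_real_
  grid$n_evals <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    sp <- search_spec(base_panel, grid$n_extra[i], grid$raf[i],
                      grid$target_auc[i], reps_per_eval)
    res <- tryCatch(required_or(sp, config), error = function(e) {
      message("grid cell ", i, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      grid$required_or[i] <- res$required_or
      last <- res$evaluations[nrow(res$evaluations), ]
      grid$mean_auc_achieved[i] <- last$mean_auc
      grid$n_evals[i] <- nrow(res$evaluations)
    }
  }
  grid
}
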