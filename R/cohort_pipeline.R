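#' Per-SNP association by logistic regression
#'
#' For each panel variant, fits `status ~ allele count` (optionally plus age
#' and sex) by binomial regression on the subjects with a non-missing
#' genotype for that variant, and reports the per-allele odds ratio with its
#' Wald 95% confidence interval and p-value. Variants are flagged as
#' significant at the Bonferroni threshold 0.05 / number of variants
#' (0.008 for a six-variant panel). Fits showing separation (absent allele or
#' exploding standard error) are flagged and their CI reported as
#' unavailable.
#'
#' @param cohort a `cohort_table`.
#' @param adjust `"age_sex"` (default, the study's convention) or `"none"`.
#' @return data.frame with columns rsid, n, or, ci_low, ci_high, p_value,
#'   significant, separation.
#' @export
per_snp_association <- function(cohort, adjust = c("age_sex", "none")) {
  adjust <- match.arg(adjust)
  rsids <- cohort_rsids(cohort)
  alpha_bonf <- 0.05 / length(rsids)
  out <- data.frame(rsid = rsids, n = NA_integer_, or = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
                    significant = NA, separation = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(rsids)) {
    g <- cohort[[rsids[i]]]
    keep <- !is.na(g)
    dat <- data.frame(status = cohort$status[keep], count = g[keep],
                      age = cohort$age[keep], sex = cohort$sex[keep])
    out$n[i] <- nrow(dat)
    if (length(unique(dat$count)) < 2L) {
      out$separation[i] <- TRUE
      next
    }
    fml <- if (adjust == "age_sex") status ~ count + age + sex else status ~ count
    fit <- suppressWarnings(stats::glm(fml, data = dat, family = stats::binomial()))
    beta <- stats::coef(fit)["count"]
    se <- sqrt(stats::vcov(fit)["count", "count"])
    if (!is.finite(se) || se > 10) {
      out$separation[i] <- TRUE
      out$or[i] <- exp(beta)
      next
    }
    out$or[i] <- exp(beta)
    out$ci_low[i] <- exp(beta - 1.96 * se)
    out$ci_high[i] <- exp(beta + 1.96 * se)
    out$p_value[i] <- 2 * stats::pnorm(-abs(beta / se))
    out$significant[i] <- out$p_value[i] < alpha_bonf
  }
  attr(out, "bonferroni_alpha") <- alpha_bonf
  out
}

#' A-priori disease risk of the analysed cohort
#'
#' The fraction of complete-genotype subjects who are cases; the reference
#' probability against which risk-allele-count bins are compared.
#'
#' @param cohort a `cohort_table`.
#' @return fraction in \[0,1\].
#' @examples
#' # 564 complete cases and 581 complete controls give 0.4926 (49%)
#' @export
a_priori_risk <- function(cohort) {
  keep <- complete_genotypes(cohort)
  if (!any(keep)) stop("no subjects with complete genotype information")
  mean(cohort$status[keep] == 1L)
}

#' Weighted risk-allele scores
#'
#' For every subject with complete genotype information, the number of risk
#' alleles at each variant is multiplied by that variant's effect size and
#' summed. The effect size is ln(per-allele OR) by default, which makes the
#' score proportional to the Bayes model's log posterior odds; raw-OR
#' weighting is available for sensitivity analysis.
#'
#' @param cohort a `cohort_table`.
#' @param panel a `risk_panel` supplying the weights; its rsids must all be
#'   present in the cohort. Defaults to the panel the cohort was generated
#'   from, identified by column names.
#' @param weights `"log_or"` (default) or `"or"`.
#' @return data.frame with columns subject_id, status, age, sex,
#'   risk_allele_count, weighted_score (one row per complete subject).
#' @export
weighted_scores <- function(cohort, panel = NULL, weights = c("log_or", "or")) {
  weights <- match.arg(weights)
  if (is.null(panel)) stop("a panel supplying effect sizes is required")
  rsids <- panel$variants$rsid
  missing_rs <- setdiff(rsids, names(cohort))
  if (length(missing_rs) > 0L) {
    stop("cohort lacks genotype column(s): ", paste(missing_rs, collapse = ", "))
  }
  g <- as.matrix(cohort[, rsids, drop = FALSE])
  keep <- rowSums(is.na(g)) == 0L
  g <- g[keep, , drop = FALSE]
  w <- if (weights == "log_or") log(panel$variants$or) else panel$variants$or
  data.frame(subject_id = cohort$subject_id[keep],
             status = cohort$status[keep],
             age = cohort$age[keep], sex = cohort$sex[keep],
             risk_allele_count = as.integer(rowSums(g)),
             weighted_score = as.numeric(g %*% w),
             stringsAsFactors = FALSE)
}

#' Default risk-allele-count bins
#'
#' The six-variant analysis uses \{0-5, 6, 7, 8, 9, 10-12\} and the
#' five-variant (HLA-excluded) analysis \{0-5, 6, 7, 8-10\}; other panel
#' sizes fall back to five equal-frequency bins of the observed counts.
#'
#' @param n_variants panel size.
#' @param counts observed risk-allele counts (used by the fallback).
#' @return list of `c(lo, hi)` integer ranges.
#' @export
default_bins <- function(n_variants, counts = NULL) {
  if (n_variants == 6L) {
    list(c(0L, 5L), c(6L, 6L), c(7L, 7L), c(8L, 8L), c(9L, 9L), c(10L, 12L))
  } else if (n_variants == 5L) {
    list(c(0L, 5L), c(6L, 6L), c(7L, 7L), c(8L, 10L))
  } else {
    stopifnot(!is.null(counts))
    br <- unique(stats::quantile(counts, probs = seq(0, 1, 0.2), type = 1))
    lo <- c(min(counts), utils::head(br, -1) + 1L)
    lapply(seq_along(br), function(i) c(as.integer(lo[i]), as.integer(br[i])))
  }
}

bin_labels <- function(bins) {
  vapply(bins, function(b) if (b[1] == b[2]) as.character(b[1])
         else paste0(b[1], "-", b[2]), character(1))
}

# weighted sum-to-zero (deviation) contrast: effects average to zero with
# bin-size weights, so the intercept is the size-weighted mean of bin
# log-odds -- the "overall" reference the bin ORs are compared against
weighted_effect_contrasts <- function(sizes) {
  B <- length(sizes)
  C <- matrix(0, nrow = B, ncol = B - 1L)
  for (b in seq_len(B - 1L)) {
    C[b, b] <- 1
    C[B, b] <- -sizes[b] / sizes[B]
  }
  C
}

#' Odds ratios of risk-allele-count bins against the cohort-average risk
#'
#' Groups complete-genotype subjects into risk-allele-count bins and
#' estimates each bin's odds of disease relative to the overall (a-priori)
#' odds of the analysed sample, via a logistic regression with weighted
#' sum-to-zero coding of the bin factor (optionally adjusted for age and
#' sex). With this coding the intercept is the bin-size-weighted mean of the
#' bin log-odds, so each bin coefficient is directly the log OR versus the
#' cohort average. Empty bins are dropped with a warning.
#'
#' @param scores output of [weighted_scores()].
#' @param bins list of `c(lo, hi)` count ranges covering the observed counts;
#'   default from [default_bins()].
#' @param adjust `"age_sex"` (default) or `"none"`.
#' @param n_variants panel size used to pick default bins; inferred from the
#'   maximum observed count when omitted.
#' @return data.frame with columns bin_label, lo, hi, n, n_cases, n_controls,
#'   or_vs_prior, ci_low, ci_high.
#' @export
binned_or_vs_prior <- function(scores, bins = NULL,
                               adjust = c("age_sex", "none"),
                               n_variants = NULL) {
  adjust <- match.arg(adjust)
  counts <- scores$risk_allele_count
  if (is.null(bins)) {
    if (is.null(n_variants)) n_variants <- ceiling(max(counts) / 2)
    bins <- default_bins(n_variants, counts)
  }
  lo <- vapply(bins, `[`, integer(1), 1L)
  hi <- vapply(bins, `[`, integer(1), 2L)
  if (any(counts < min(lo)) || any(counts > max(hi))) {
    stop("bins do not cover the observed risk-allele counts (",
         min(counts), "-", max(counts), ")")
  }
  idx <- vapply(counts, function(cc) which(cc >= lo & cc <= hi)[1], integer(1))
  if (any(is.na(idx))) stop("bins leave gaps in the observed count range")
  labels <- bin_labels(bins)
  present <- sort(unique(idx))
  if (length(present) < length(bins)) {
    warning("dropping empty bin(s): ",
            paste(labels[setdiff(seq_along(bins), present)], collapse = ", "))
    bins <- bins[present]; labels <- labels[present]
    idx <- match(idx, present)
  }
  B <- length(bins)
  if (B < 2L) stop("need at least two non-empty bins")
  sizes <- tabulate(idx, nbins = B)
  f <- factor(idx, levels = seq_len(B))
  attr(f, "contrasts") <- weighted_effect_contrasts(sizes)
  dat <- data.frame(status = scores$status, bin = f, age = scores$age,
                    sex = scores$sex)
  fml <- if (adjust == "age_sex") status ~ bin + age + sex else status ~ bin
  fit <- suppressWarnings(stats::glm(fml, data = dat, family = stats::binomial()))
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  bin_cols <- paste0("bin", seq_len(B - 1L))
  # effect of each bin as a linear combination of the B-1 contrast coefs
  L <- rbind(diag(B - 1L), -sizes[-B] / sizes[B])
  eff <- as.numeric(L %*% cf[bin_cols])
  se <- sqrt(diag(L %*% V[bin_cols, bin_cols] %*% t(L)))
  data.frame(bin_label = labels,
             lo = vapply(bins, `[`, integer(1), 1L),
             hi = vapply(bins, `[`, integer(1), 2L),
             n = sizes,
             n_cases = as.integer(tapply(scores$status, f, sum)),
             n_controls = as.integer(tapply(1L - scores$status, f, sum)),
             or_vs_prior = exp(eff),
             ci_low = exp(eff - 1.96 * se),
             ci_high = exp(eff + 1.96 * se),
             stringsAsFactors = FALSE)
}

#' Cohort AUC of the weighted risk-allele score
#'
#' Mann-Whitney AUC of the weighted score against case-control status among
#' complete-genotype subjects.
#'
#' @param scores output of [weighted_scores()] (or a numeric vector).
#' @param status disease indicators; taken from `scores` when omitted.
#' @return AUC in \[0,1\].
#' @export
cohort_auc <- function(scores, status = NULL) {
  if (is.data.frame(scores)) {
    if (is.null(status)) status <- scores$status
    scores <- scores$weighted_score
  }
  empirical_auc(scores, status)
}

#' Plot bin odds ratios against the a-priori reference
#'
#' Point estimates with 95% CI whiskers per risk-allele-count bin, with the
#' reference line at OR 1 (the cohort-average risk).
#'
#' @param bin_or output of [binned_or_vs_prior()].
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_bin_or <- function(bin_or, title = "Risk by number of risk alleles") {
  bin_or$bin_label <- factor(bin_or$bin_label, levels = bin_or$bin_label)
  ggplot2::ggplot(bin_or, ggplot2::aes(x = bin_label, y = or_vs_prior)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = ci_low, ymax = ci_high)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Number of risk alleles", y = "OR vs a-priori risk",
                  title = title) +
    ggplot2::theme_minimal()
}
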