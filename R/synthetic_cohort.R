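#' Specification of a synthetic case-control cohort
#'
#' Defaults emulate the empirical MS case-control study this package models:
#' 591 cases and 600 controls; case age 45 (SD 12) and control age 49
#' (SD 17) years; 71% female cases and 55% female controls; independent
#' per-genotype missingness at a rate calibrated so roughly 564 cases and
#' 581 controls have complete genotype data on a six-variant panel. Panel
#' odds ratios are interpreted as generative crude allelic ORs: control
#' genotypes follow HWE at the panel's control allele frequencies, case
#' genotypes follow HWE at the OR-scaled case allele frequencies.
#'
#' @param panel a `risk_panel` (default the cohort-observed six-variant
#'   panel).
#' @param n_cases,n_controls cohort arm sizes.
#' @param age_case_mean,age_case_sd,age_control_mean,age_control_sd age
#'   moments in years (ages truncated to 18-90).
#' @param frac_female_cases,frac_female_controls female fractions.
#' @param missing_rate independent per-genotype missingness probability.
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(panel = builtin_panel("panel_empirical_6"),
                        n_cases = 591L, n_controls = 600L,
                        age_case_mean = 45, age_case_sd = 12,
                        age_control_mean = 49, age_control_sd = 17,
                        frac_female_cases = 0.71, frac_female_controls = 0.55,
                        missing_rate = 0.0065, seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, age_case_sd > 0, age_control_sd > 0,
            frac_female_cases >= 0, frac_female_cases <= 1,
            frac_female_controls >= 0, frac_female_controls <= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(panel = panel, n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 age_case_mean = age_case_mean, age_case_sd = age_case_sd,
                 age_control_mean = age_control_mean,
                 age_control_sd = age_control_sd,
                 frac_female_cases = frac_female_cases,
                 frac_female_controls = frac_female_controls,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

# truncated-normal draw by inverse-CDF on the truncated quantile range
rtnorm <- function(n, mean, sd, lower = 18, upper = 90) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic case-control cohort
#'
#' Draws genotypes stratum-wise under HWE (controls at the panel control
#' allele frequency, cases at the OR-implied case frequency), demographics
#' from the specified moments, and injects independent per-genotype
#' missingness. Age and sex are generated independently of genotype, so
#' crude and demographics-adjusted odds ratios coincide in expectation.
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame of class `cohort_table` with columns `subject_id`,
#'   `status` (1 = case), `age`, `sex` ("female"/"male"), then one 0/1/2/NA
#'   column per panel rsid.
#' @examples
#' generate_cohort(cohort_spec(n_cases = 20, n_controls = 20, seed = 7))
#' @export
generate_cohort <- function(spec) {
  set.seed(spec$seed)
  v <- spec$panel$variants
  n <- spec$n_cases + spec$n_controls
  status <- rep(c(1L, 0L), c(spec$n_cases, spec$n_controls))
  age <- numeric(n)
  age[status == 1L] <- rtnorm(spec$n_cases, spec$age_case_mean, spec$age_case_sd)
  age[status == 0L] <- rtnorm(spec$n_controls, spec$age_control_mean,
                              spec$age_control_sd)
  sex <- character(n)
  sex[status == 1L] <- ifelse(
    stats::runif(spec$n_cases) < spec$frac_female_cases, "female", "male")
  sex[status == 0L] <- ifelse(
    stats::runif(spec$n_controls) < spec$frac_female_controls, "female", "male")
  out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    status = status, age = round(age, 1), sex = sex,
                    stringsAsFactors = FALSE)
  for (j in seq_len(nrow(v))) {
    q_case <- case_allele_freq(v$raf[j], v$or[j])
    g <- integer(n)
    g[status == 0L] <- stats::rbinom(spec$n_controls, 2L, v$raf[j])
    g[status == 1L] <- stats::rbinom(spec$n_cases, 2L, q_case)
    if (spec$missing_rate > 0) {
      g[stats::runif(n) < spec$missing_rate] <- NA_integer_
    }
    out[[v$rsid[j]]] <- g
  }
  structure(out, class = c("cohort_table", "data.frame"),
            panel_rsids = v$rsid)
}

#' Variant columns of a cohort table
#' @param cohort a `cohort_table`.
#' @return character vector of rsid column names.
#' @export
cohort_rsids <- function(cohort) {
  rs <- attr(cohort, "panel_rsids")
  if (is.null(rs)) rs <- setdiff(names(cohort), c("subject_id", "status", "age", "sex"))
  rs
}

#' Subjects with complete genotype information
#' @param cohort a `cohort_table`.
#' @return logical vector, TRUE where no genotype is missing.
#' @export
complete_genotypes <- function(cohort) {
  g <- as.matrix(cohort[, cohort_rsids(cohort), drop = FALSE])
  rowSums(is.na(g)) == 0L
}

#' Write / read a cohort table as TSV
#'
#' Lossless round trip; missing genotypes are encoded as `NA`.
#'
#' @param cohort a `cohort_table`.
#' @param path file path.
#' @return `path` invisibly (write) or a `cohort_table` (read).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", na.strings = "NA",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("subject_id", "status", "age", "sex")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("cohort format error: missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  rsids <- setdiff(names(tab), required)
  for (rs in rsids) {
    g <- tab[[rs]]
    bad <- which(!is.na(g) & !(g %in% 0:2))
    if (length(bad) > 0L) {
      stop("cohort parse error: genotype outside {0,1,2,NA} for ", rs,
           " at line ", bad[1] + 1L)
    }
    tab[[rs]] <- as.integer(g)
  }
  structure(tab, class = c("cohort_table", "data.frame"), panel_rsids = rsids)
}

#' Chi-square Hardy-Weinberg equilibrium check within a stratum
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against HWE expectations at the observed allele frequency.
#'
#' @param genotype_counts vector of risk-allele counts (NA allowed, dropped).
#' @return list with `chisq`, `p_value`, `n`.
#' @export
hwe_test <- function(genotype_counts) {
  g <- genotype_counts[!is.na(genotype_counts)]
  n <- length(g)
  obs <- tabulate(g + 1L, nbins = 3L)
  q <- (obs[2] + 2 * obs[3]) / (2 * n)
  expd <- n * hwe_genotype_freqs(q)
  keep <- expd > 0
  chisq <- sum((obs[keep] - expd[keep])^2 / expd[keep])
  list(chisq = chisq, p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       n = n)
}
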