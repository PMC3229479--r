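#' Create a risk panel
#'
#' A panel is an ordered collection of biallelic risk variants, each described
#' by its risk-allele frequency in the control/reference population and its
#' per-allele odds ratio. Column order of all genotype matrices downstream
#' follows panel order.
#'
#' @param variants data.frame with columns `gene`, `rsid`, `chrom`,
#'   `risk_allele`, `raf` (risk-allele frequency in controls, in (0,1)) and
#'   `or` (per-allele odds ratio, > 0).
#' @param name character scalar naming the panel.
#' @return An object of class `risk_panel`: a list with elements `name` and
#'   `variants`.
#' @examples
#' new_panel(data.frame(gene = "HLA-DRB", rsid = "rs3135388", chrom = "6",
#'                      risk_allele = "A", raf = 0.13, or = 3.08), "hla_only")
#' @export
new_panel <- function(variants, name = "panel") {
  required <- c("gene", "rsid", "chrom", "risk_allele", "raf", "or")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0L) {
    stop("panel format error: missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  variants <- as.data.frame(variants)[, required]
  variants$gene <- as.character(variants$gene)
  variants$rsid <- as.character(variants$rsid)
  variants$chrom <- as.character(variants$chrom)
  variants$risk_allele <- as.character(variants$risk_allele)
  variants$raf <- as.numeric(variants$raf)
  variants$or <- as.numeric(variants$or)
  rownames(variants) <- NULL
  panel <- structure(list(name = name, variants = variants), class = "risk_panel")
  validate_panel(panel)
  panel
}

#' Validate a risk panel
#'
#' Checks the panel invariants: unique rsids, risk-allele frequencies strictly
#' inside (0,1) and positive odds ratios.
#'
#' @param panel a `risk_panel`.
#' @return The panel, invisibly. Errors name the offending rsid.
#' @export
validate_panel <- function(panel) {
  v <- panel$variants
  if (nrow(v) > 0L) {
    dup <- v$rsid[duplicated(v$rsid)]
    if (length(dup) > 0L) {
      stop("panel validation error: duplicate rsid(s) ", paste(unique(dup), collapse = ", "))
    }
    bad_raf <- v$rsid[!is.finite(v$raf) | v$raf <= 0 | v$raf >= 1]
    if (length(bad_raf) > 0L) {
      stop("panel validation error: raf outside (0,1) for ", paste(bad_raf, collapse = ", "))
    }
    bad_or <- v$rsid[!is.finite(v$or) | v$or <= 0]
    if (length(bad_or) > 0L) {
      stop("panel validation error: or <= 0 for ", paste(bad_or, collapse = ", "))
    }
  }
  invisible(panel)
}

#' @export
print.risk_panel <- function(x, ...) {
  cat(sprintf("<risk_panel> %s: %d variant(s)\n", x$name, nrow(x$variants)))
  if (nrow(x$variants) > 0L) {
    print(utils::head(x$variants, 10L))
    if (nrow(x$variants) > 10L) cat("  ...\n")
  }
  invisible(x)
}

#' Number of variants in a panel
#' @param panel a `risk_panel`.
#' @return integer count.
#' @export
panel_size <- function(panel) nrow(panel$variants)

#' Read a risk panel from a tab-separated file
#'
#' The file must carry a header line with the six columns
#' `gene  rsid  chrom  risk_allele  raf  or` (any order); one variant per row.
#'
#' @param path path to a TSV file.
#' @param name panel name; defaults to the file name without extension.
#' @return A `risk_panel`.
#' @export
read_panel <- function(path, name = NULL) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  new_panel(tab, name = name)
}

#' Write a risk panel to a tab-separated file
#'
#' Round-trips losslessly: `read_panel(write_panel(p))` equals `p`
#' field-for-field. An empty panel writes a header-only file.
#'
#' @param panel a `risk_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  utils::write.table(panel$variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Packaged risk panels
#'
#' Returns one of the panels shipped with the package:
#' \describe{
#'   \item{panel_6}{the six replicated variants (HLA-DRB, EVI5, CD58, IL7R,
#'     IL2RA, CLEC16A) with GWAS-replication parameters.}
#'   \item{panel_24}{the 24 well-replicated MS risk loci (23 non-MHC loci plus
#'     the HLA-DRB1*15:01 tag SNP rs3135388).}
#'   \item{panel_53}{panel_24 plus the 29 novel susceptibility loci.}
#'   \item{panel_empirical_6}{the six variants with the cohort-observed
#'     control allele frequencies and crude odds ratios, used as generative
#'     parameters for the synthetic case-control cohort.}
#' }
#'
#' @param name one of `"panel_6"`, `"panel_24"`, `"panel_53"`,
#'   `"panel_empirical_6"`.
#' @return A `risk_panel`.
#' @examples
#' builtin_panel("panel_53")
#' @export
builtin_panel <- function(name) {
  valid <- c("panel_6", "panel_24", "panel_53", "panel_empirical_6")
  if (length(name) != 1L || !name %in% valid) {
    stop("unknown builtin panel '", paste(name, collapse = ","),
         "'; valid names: ", paste(valid, collapse = ", "))
  }
  path <- system.file("extdata", paste0(name, ".tsv"), package = "msrisksim",
                      mustWork = TRUE)
  read_panel(path, name = name)
}

#' Resolve a panel argument
#'
#' Accepts a `risk_panel`, a `builtin:<name>` string, or a file path.
#' Used by the command-line entry points.
#'
#' @param x panel object, `builtin:` string, or path.
#' @return A `risk_panel`.
#' @export
resolve_panel <- function(x) {
  if (inherits(x, "risk_panel")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (startsWith(x, "builtin:")) return(builtin_panel(sub("^builtin:", "", x)))
    return(read_panel(x))
  }
  stop("cannot interpret panel argument")
}

#' Study-level simulation parameters
#'
#' @param population_risk lifetime disease risk used as the Bayes prior
#'   (default 0.001, i.e. a 0.1% lifetime MS risk).
#' @param n_individuals simulated population size per replicate
#'   (default 100000).
#' @param n_reps number of simulation replicates averaged for each AUC
#'   estimate (default 100).
#' @param master_seed integer seed from which all replicate seeds are derived.
#' @return A list of class `study_config`.
#' @export
study_config <- function(population_risk = 0.001, n_individuals = 100000L,
                         n_reps = 100L, master_seed = 1L) {
  stopifnot(population_risk > 0, population_risk < 1,
            n_individuals >= 1, n_reps >= 1)
  structure(list(population_risk = population_risk,
                 n_individuals = as.integer(n_individuals),
                 n_reps = as.integer(n_reps),
                 master_seed = as.integer(master_seed)),
            class = "study_config")
}

#' Read study parameters from a configuration file
#'
#' Accepts either JSON (`{"population_risk": 0.001, ...}`) or `key=value`
#' lines (`#` comments allowed). Recognized keys are the [study_config()]
#' arguments; unrecognized keys raise an error, and omitted keys keep their
#' defaults.
#'
#' @param path configuration file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  first <- trimws(paste(txt, collapse = ""))
  vals <- if (startsWith(first, "{")) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    lines <- trimws(txt)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    bad <- lengths(kv) != 2L
    if (any(bad)) stop("config parse error: expected key=value, got '",
                       lines[bad][1], "'")
    stats::setNames(lapply(kv, function(x) as.numeric(trimws(x[2]))),
                    vapply(kv, function(x) trimws(x[1]), character(1)))
  }
  known <- c("population_risk", "n_individuals", "n_reps", "master_seed")
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("config error: unrecognized key(s) ", paste(unknown, collapse = ", "))
  }
  do.call(study_config, vals)
}
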