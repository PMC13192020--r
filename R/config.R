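#' Pipeline configuration
#'
#' Builds the resolved configuration object used across all pipeline stages.
#' Every threshold printed in a report traces back to one of these fields.
#'
#' @param max_divergence Maximum alignment divergence from the consensus at
#'   which a genomic segment is still annotated as a monomer copy. Fraction in
#'   \[0,1\], default 0.45.
#' @param bin_width Width of a divergence-landscape bin, as a fraction.
#'   Default 0.01 (1\% bins).
#' @param peak_factor A landscape bin run qualifies as a peak when every bin in
#'   the run is at least \code{peak_factor} times both flanking bins.
#'   Default 1.5 (the "50\% higher" rule).
#' @param flank_length Length in bp of the upstream/downstream flanks extracted
#'   around each array. Default 1000.
#' @param mismatch_limit Maximum mismatches allowed when counting a read
#'   against a satellite dimer reference. Default 1.
#' @param subsample_n Number of monomers subsampled per family for phylogeny.
#'   Default 100.
#' @param coverage_threshold Query-coverage fraction a taxon's best hit must
#'   strictly exceed to count as presence. Default 0.5.
#' @param gap_tolerance Maximum gap in bp between consecutive monomer hits
#'   merged into one array, or \code{NULL} for one monomer length (the
#'   default, resolved per family).
#' @param rng_seed Integer seed recorded with the run; \code{NULL} for none.
#' @return A list of class \code{"sat_config"}.
#' @examples
#' cfg <- sat_config()
#' cfg$max_divergence
#' @export
sat_config <- function(max_divergence = 0.45,
                       bin_width = 0.01,
                       peak_factor = 1.5,
                       flank_length = 1000L,
                       mismatch_limit = 1L,
                       subsample_n = 100L,
                       coverage_threshold = 0.5,
                       gap_tolerance = NULL,
                       rng_seed = NULL) {
  cfg <- list(
    max_divergence = as.numeric(max_divergence),
    bin_width = as.numeric(bin_width),
    peak_factor = as.numeric(peak_factor),
    flank_length = as.integer(flank_length),
    mismatch_limit = as.integer(mismatch_limit),
    subsample_n = as.integer(subsample_n),
    coverage_threshold = as.numeric(coverage_threshold),
    gap_tolerance = if (is.null(gap_tolerance)) NULL else as.integer(gap_tolerance),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  )
  stopifnot(
    cfg$max_divergence >= 0, cfg$max_divergence <= 1,
    cfg$bin_width > 0, cfg$bin_width <= 1,
    cfg$peak_factor >= 1,
    cfg$flank_length > 0,
    cfg$mismatch_limit >= 0,
    cfg$subsample_n > 0,
    cfg$coverage_threshold >= 0, cfg$coverage_threshold <= 1
  )
  class(cfg) <- "sat_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys absent from the file keep their \code{\link{sat_config}} defaults;
#' unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @param ... Overrides applied on top of the file (e.g. from CLI flags).
#' @return A \code{"sat_config"} object.
#' @export
read_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(sat_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(sat_config, vals)
}

#' @export
print.sat_config <- function(x, ...) {
  cat("satkit pipeline configuration\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-20s %s\n", k, if (is.null(v)) "<default>" else format(v)))
  }
  invisible(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
# All package-level stochastic operations funnel through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Lightweight logging: messages prefixed with the stage name, suppressible
# via options(satkit.quiet = TRUE).
sat_log <- function(...) {
  if (!isTRUE(getOption("satkit.quiet", FALSE))) {
    message("[satkit] ", sprintf(...))
  }
  invisible(NULL)
}

DNA_BASES_ <- c("A", "C", "G", "T")

# Random uniform i.i.d. DNA string(s) of the given length(s).
random_dna <- function(n) {
  vapply(n, function(len) {
    paste(sample(DNA_BASES_, len, replace = TRUE), collapse = "")
  }, character(1))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Validate and normalise a DNA string: uppercase; only A,C,G,T,N allowed.
# Other IUPAC ambiguity codes are rejected unless coerce_n = TRUE.
check_dna <- function(x, what = "sequence", coerce_n = FALSE) {
  x <- toupper(x)
  if (coerce_n) {
    x <- gsub("[^ACGT]", "N", x)
  }
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(what, " contains characters outside {A,C,G,T,N}; ",
         "use coerce_n = TRUE to mask ambiguity codes")
  }
  x
}
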