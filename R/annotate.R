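# Consensus-based monomer annotation. The search is an exhaustive ungapped
# wraparound scan: for every rotation-phase diagonal of the (conceptually
# doubled) consensus, a monomer-length window slides along the chromosome and
# every window within the divergence ceiling is a candidate. Candidates on
# one diagonal are clustered into array regions, region boundaries are
# refined by a change-point criterion on the per-base mismatch profile, and
# monomers are tiled from the refined start at consensus-length periodicity.

#' Find all monomer copies of a family on a genome
#'
#' Reports every genomic segment matching some rotation of the consensus on
#' either strand with ungapped alignment divergence (mismatches / monomer
#' length) at most \code{max_divergence}. Hits of one family never overlap:
#' conflicts are resolved greedily by ascending divergence, ties by leftmost
#' start, then by + strand.
#'
#' @param genome Named character vector of chromosome sequences (uppercase
#'   A/C/G/T/N), e.g. from \code{\link{read_fasta}}.
#' @param family A \code{\link{sat_family}}; consensus must be at least 20 bp.
#' @param max_divergence Divergence ceiling; default 0.45.
#' @return Hit data.frame: \code{seq_id}, \code{start}, \code{end} (0-based
#'   half-open, forward strand), \code{strand}, \code{family_id},
#'   \code{divergence}, \code{rotation} (offset into the consensus at which
#'   the hit begins, read along its own strand), \code{aligned_length}.
#' @export
find_monomers <- function(genome, family, max_divergence = 0.45) {
  stopifnot(inherits(family, "sat_family"))
  if (family$monomer_length < 20L) {
    stop("consensus of ", family$family_id, " is shorter than 20 bp")
  }
  if (length(genome) == 0L || all(nchar(genome) == 0L)) {
    warning("empty genome: no monomers to find")
    return(empty_hits())
  }
  L <- family$monomer_length
  max_mm <- as.integer(floor(max_divergence * L))
  hits <- list()
  for (chrom in names(genome)) {
    gseq <- genome[[chrom]]
    G <- nchar(gseq)
    if (G < L) next
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") gseq else revcomp(gseq)
      cand <- .scan_diagonals_cpp(sseq, family$consensus, max_mm)
      if (!length(cand$start)) next
      h <- scan_to_hits(cand, sseq, family, max_mm)
      if (!nrow(h)) next
      if (strand == "-") {
        s <- h$start
        h$start <- G - h$end
        h$end <- G - s
        h <- h[order(h$start), , drop = FALSE]
      }
      h$seq_id <- chrom
      h$strand <- strand
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (!length(hits)) return(empty_hits())
  hits <- do.call(rbind, hits)
  hits$family_id <- family$family_id
  hits$aligned_length <- L
  hits <- resolve_overlaps(hits)
  rownames(hits) <- NULL
  hits[, c("seq_id", "start", "end", "strand", "family_id",
           "divergence", "rotation", "aligned_length")]
}

empty_hits <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), family_id = character(0),
             divergence = numeric(0), rotation = integer(0),
             aligned_length = integer(0), stringsAsFactors = FALSE)
}

# Turn qualifying windows on one strand of one chromosome into tiled monomer
# hits (strand-local coordinates).
scan_to_hits <- function(cand, sseq, family, max_mm) {
  L <- family$monomer_length
  G <- nchar(sseq)
  out <- list()
  ord <- order(cand$diag, cand$start)
  diag <- cand$diag[ord]; start <- cand$start[ord]; mism <- cand$mismatch[ord]
  # cluster: same diagonal, successive qualifying starts within 2 monomers
  brk <- c(TRUE, diff(diag) != 0 | diff(start) > 2L * L)
  grp <- cumsum(brk)
  for (g in split(seq_along(grp), grp)) {
    d <- diag[g[1]]
    s_all <- start[g]
    m_all <- mism[g]
    s_best <- s_all[which.min(m_all)]
    lo <- max(0L, min(s_all) - 2L * L)
    hi <- min(G, max(s_all) + 3L * L)
    mm <- .diag_mismatch_cpp(sseq, family$consensus, d, lo, hi)
    A <- refine_left(mm, lo, s_best)
    B <- refine_right(mm, lo, s_best + L)
    n <- as.integer(round((B - A) / L))
    if (n < 1L) { A <- s_best; B <- s_best + L; n <- 1L }
    # Anchor the monomer grid at whichever refined boundary explains the
    # region better: mutation clumps at an array edge can stall one
    # change-point a fraction of a monomer short, and (B - A) need not be an
    # exact multiple of the monomer length. Ties go to the left anchor.
    tile_score <- function(a0) {
      st <- a0 + (seq_len(n) - 1L) * L
      if (any(st < lo) || any(st + L > hi)) return(Inf)
      sum(vapply(st, function(s) sum(mm[(s - lo + 1L):(s - lo + L)]), numeric(1)))
    }
    cand <- unique(as.integer(c(A, B - n * L)))
    scores <- vapply(cand, tile_score, numeric(1))
    A <- cand[which.min(scores)]
    starts <- A + (seq_len(n) - 1L) * L
    starts <- starts[starts >= lo & starts + L <= hi]
    if (!length(starts)) next
    mmc <- vapply(starts, function(s) sum(mm[(s - lo + 1L):(s - lo + L)]),
                  numeric(1))
    keep <- mmc <= max_mm
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      start = starts[keep], end = starts[keep] + L,
      divergence = mmc[keep] / L,
      rotation = ((starts[keep] - d) %% L + L) %% L,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      divergence = numeric(0), rotation = integer(0)))
  }
  do.call(rbind, out)
}

# Change-point boundary: walking left from `anchor`, the cumulative sum of
# (match - 1/2) rises inside the array (match rate >= 0.55 within the
# ceiling) and falls in background (rate ~ 1/4); the array start is the
# position where the cumulative sum peaks. The peak must clear a margin
# (default 3, i.e. six net matching bases) so that short chance runs of
# background matches next to the boundary do not drag it outward; any real
# extension by array sequence gains far more than the margin.
refine_left <- function(mm, lo, anchor, margin = 3) {
  if (anchor <= lo) return(anchor)
  xs <- seq(anchor - 1L, lo, by = -1L)
  sc <- cumsum(0.5 - mm[xs - lo + 1L])
  best <- which.max(sc)
  if (sc[best] <= margin) anchor else xs[best]
}

refine_right <- function(mm, lo, anchor, margin = 3) {
  hi <- lo + length(mm)
  if (anchor >= hi) return(anchor)
  xs <- seq(anchor, hi - 1L)
  sc <- cumsum(0.5 - mm[xs - lo + 1L])
  best <- which.max(sc)
  if (sc[best] <= margin) anchor else xs[best] + 1L
}

# Greedy non-overlap resolution per family: ascending divergence, ties by
# leftmost start, then + strand first.
resolve_overlaps <- function(hits) {
  if (nrow(hits) < 2L) return(hits)
  out <- list()
  for (chrom in unique(hits$seq_id)) {
    h <- hits[hits$seq_id == chrom, , drop = FALSE]
    h <- h[order(h$divergence, h$start, h$strand != "+"), , drop = FALSE]
    taken_start <- integer(0)
    taken_end <- integer(0)
    keep <- logical(nrow(h))
    for (i in seq_len(nrow(h))) {
      if (!length(taken_start) ||
          all(h$end[i] <= taken_start | h$start[i] >= taken_end)) {
        keep[i] <- TRUE
        taken_start <- c(taken_start, h$start[i])
        taken_end <- c(taken_end, h$end[i])
      }
    }
    h <- h[keep, , drop = FALSE]
    out[[chrom]] <- h[order(h$start), , drop = FALSE]
  }
  do.call(rbind, out)
}

#' Merge monomer hits into arrays
#'
#' Maximal runs of same-family, same-strand hits on one chromosome whose
#' inter-hit gap is at most \code{gap_tolerance} become one array; singleton
#' hits become arrays of one monomer. The sum of \code{n_monomers} over
#' arrays always equals the number of hits.
#'
#' @param hits Hit table from \code{\link{find_monomers}} (any families).
#' @param gap_tolerance Maximum gap in bp; default one monomer length
#'   (\code{aligned_length}) per hit, so a single lost or fully degenerate
#'   monomer does not split an array.
#' @return Array data.frame: \code{seq_id}, \code{start}, \code{end},
#'   \code{strand}, \code{family_id}, \code{n_monomers}, \code{array_id};
#'   plus the input hits with an \code{array_id} column, as attribute
#'   \code{"hits"}.
#' @export
build_arrays <- function(hits, gap_tolerance = NULL) {
  if (nrow(hits) == 0L) {
    out <- data.frame(seq_id = character(0), start = integer(0), end = integer(0),
                      strand = character(0), family_id = character(0),
                      n_monomers = integer(0), array_id = integer(0))
    attr(out, "hits") <- hits
    return(out)
  }
  ord <- order(hits$family_id, hits$seq_id, hits$start)
  if (is.unsorted(ord)) {
    sat_log("build_arrays: input not sorted by (family, seq_id, start); sorting")
  }
  hits <- hits[ord, , drop = FALSE]
  tol <- if (is.null(gap_tolerance)) hits$aligned_length else rep(gap_tolerance, nrow(hits))
  same_run <- c(FALSE,
                hits$family_id[-1] == hits$family_id[-nrow(hits)] &
                hits$seq_id[-1] == hits$seq_id[-nrow(hits)] &
                hits$strand[-1] == hits$strand[-nrow(hits)] &
                (hits$start[-1] - hits$end[-nrow(hits)]) <= tol[-1])
  hits$array_id <- cumsum(!same_run)
  arrays <- do.call(rbind, lapply(split(hits, hits$array_id), function(h) {
    data.frame(seq_id = h$seq_id[1], start = min(h$start), end = max(h$end),
               strand = h$strand[1], family_id = h$family_id[1],
               n_monomers = nrow(h), array_id = h$array_id[1],
               stringsAsFactors = FALSE)
  }))
  rownames(arrays) <- NULL
  attr(arrays, "hits") <- hits
  arrays
}

#' Annotate a whole satellitome
#'
#' Runs \code{\link{find_monomers}} and \code{\link{build_arrays}} for every
#' family.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param families List of \code{\link{sat_family}} (e.g.
#'   \code{\link{read_families}}).
#' @param config A \code{\link{sat_config}}.
#' @return List with \code{hits} (all families) and \code{arrays}.
#' @export
annotate_genome <- function(genome, families, config = sat_config()) {
  hits <- do.call(rbind, lapply(families, function(fam) {
    find_monomers(genome, fam, config$max_divergence)
  }))
  if (is.null(hits)) hits <- empty_hits()
  rownames(hits) <- NULL
  arrays <- build_arrays(hits, config$gap_tolerance)
  list(hits = attr(arrays, "hits"), arrays = arrays)
}

#' Per-family satellitome summary
#'
#' The reported unit of a satellitome scan: per family, the total monomer
#' count, presence on each chromosome, monomer count on unplaced scaffolds,
#' and the genome fraction occupied.
#'
#' @param hits Hit table (all families).
#' @param genome Named character vector of the assembly sequences, or a named
#'   numeric vector of their lengths.
#' @param families Optional list of \code{\link{sat_family}} fixing the row
#'   order (families without hits get all-zero rows).
#' @param unplaced_pattern Regex identifying unplaced scaffolds by name.
#' @return List with \code{table} (per-family data.frame: family_id,
#'   n_monomers, n_chromosomes, n_unplaced_monomers, genome_fraction) and
#'   \code{presence} (family x sequence logical matrix).
#' @export
summarize_satellitome <- function(hits, genome, families = NULL,
                                  unplaced_pattern = "^(scaffold|unplaced|SCAF)") {
  lens <- if (is.numeric(genome)) genome else nchar(genome)
  total_len <- sum(as.numeric(lens))
  fam_ids <- if (is.null(families)) sort(unique(hits$family_id)) else
    vapply(families, `[[`, character(1), "family_id")
  seq_ids <- names(lens)
  presence <- matrix(FALSE, nrow = length(fam_ids), ncol = length(seq_ids),
                     dimnames = list(fam_ids, seq_ids))
  rows <- lapply(fam_ids, function(f) {
    h <- hits[hits$family_id == f, , drop = FALSE]
    if (nrow(h)) presence[f, unique(h$seq_id)] <<- TRUE
    unplaced <- grepl(unplaced_pattern, h$seq_id)
    data.frame(family_id = f,
               n_monomers = nrow(h),
               n_chromosomes = length(unique(h$seq_id[!unplaced])),
               n_unplaced_monomers = sum(unplaced),
               genome_fraction = sum(h$end - h$start) / total_len,
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), presence = presence)
}
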