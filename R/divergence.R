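#' Kimura 2-parameter distance between two aligned sequences
#'
#' Counts transitions and transversions over ungapped aligned columns and
#' applies the K2P multiple-hit correction
#' \deqn{d = -\tfrac{1}{2}\ln\left[(1-2P-Q)\sqrt{1-2Q}\right]}
#' with \eqn{P} the transition and \eqn{Q} the transversion proportion.
#' Columns containing a gap (\code{-}) or \code{N} in either sequence are
#' excluded from the counts.
#'
#' @param a,b Equal-length aligned strings over \{A,C,G,T,N,-\}.
#' @return A list of class \code{"divergence_record"} with \code{P}, \code{Q},
#'   \code{d}, \code{compared_sites}. In the saturated regime (log argument
#'   \eqn{\le 0}) \code{d} is \code{Inf}.
#' @examples
#' k2p_distance(paste(rep("ACGT", 25), collapse = ""),
#'              paste(rep("ACGT", 25), collapse = ""))$d  # 0
#' @export
k2p_distance <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("aligned sequences must have equal length")
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  ok <- av %in% DNA_BASES_ & bv %in% DNA_BASES_
  n <- sum(ok)
  if (n == 0L) stop("no comparable (ungapped, unambiguous) sites")
  av <- av[ok]; bv <- bv[ok]
  diff <- av != bv
  purine_a <- av %in% c("A", "G")
  purine_b <- bv %in% c("A", "G")
  ts <- sum(diff & purine_a == purine_b)   # A<->G, C<->T
  tv <- sum(diff & purine_a != purine_b)
  P <- ts / n
  Q <- tv / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  d <- if (arg1 <= 0 || arg2 <= 0) Inf else -0.5 * log(arg1 * sqrt(arg2))
  structure(list(P = P, Q = Q, d = d, compared_sites = n),
            class = "divergence_record")
}

# Vectorised K2P from precomputed proportions (used by landscapes and the
# distance matrix; identical formula to k2p_distance).
k2p_from_pq <- function(P, Q) {
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  d <- suppressWarnings(-0.5 * log(arg1 * sqrt(arg2)))
  d[arg1 <= 0 | arg2 <= 0] <- Inf   # saturated: distance undefined
  d
}

#' K2P divergence of annotated monomers from their family consensus
#'
#' Each hit's genomic sequence is compared to the consensus rotated by the
#' hit's reported rotation. Hits whose length equals the monomer length are
#' compared position-wise (the annotator is ungapped); length-discrepant hits
#' are globally aligned first (match +1, mismatch -1, gap open -2, extend -1)
#' and gap columns excluded.
#'
#' @param hits Monomer hit table from \code{\link{find_monomers}}.
#' @param genome Named character vector of chromosome sequences.
#' @param family A \code{\link{sat_family}}.
#' @return \code{hits} with columns \code{P}, \code{Q}, \code{k2p},
#'   \code{compared_sites} appended. Saturated distances are \code{Inf}.
#' @export
monomer_divergence <- function(hits, genome, family) {
  if (nrow(hits) == 0L) {
    hits$P <- hits$Q <- hits$k2p <- numeric(0)
    hits$compared_sites <- integer(0)
    return(hits)
  }
  seqs <- extract_hit_seqs(hits, genome)
  L <- family$monomer_length
  P <- Q <- numeric(nrow(hits))
  n_sites <- integer(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ref <- rotate_seq(family$consensus, hits$rotation[i])
    s <- seqs[i]
    if (nchar(s) != L) {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(s), Biostrings::DNAString(ref),
        type = "global", substitutionMatrix = sat_submat(),
        gapOpening = 2, gapExtension = 1)
      s <- as.character(Biostrings::alignedPattern(al))
      ref <- as.character(Biostrings::alignedSubject(al))
    }
    rec <- k2p_distance(s, ref)
    P[i] <- rec$P; Q[i] <- rec$Q; n_sites[i] <- rec$compared_sites
  }
  hits$P <- P
  hits$Q <- Q
  hits$k2p <- k2p_from_pq(P, Q)
  hits$compared_sites <- n_sites
  hits
}

# Vectorised K2P of many equal-length sequences against one reference.
k2p_to_ref <- function(seqs, ref) {
  rv <- strsplit(ref, "")[[1]]
  m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
              ncol = length(rv), byrow = TRUE)
  refm <- matrix(rv, nrow = nrow(m), ncol = length(rv), byrow = TRUE)
  ok <- m %in% c("A", "C", "G", "T") & refm %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  pur <- m %in% c("A", "G"); dim(pur) <- dim(m)
  pur_ref <- refm %in% c("A", "G"); dim(pur_ref) <- dim(m)
  diff <- ok & m != refm
  n <- rowSums(ok)
  P <- rowSums(diff & pur == pur_ref) / n
  Q <- rowSums(diff & pur != pur_ref) / n
  k2p_from_pq(P, Q)
}

# scoring scheme shared by all pairwise alignments in the package
sat_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = FALSE)
}

rotate_seq <- function(x, r) {
  L <- nchar(x)
  r <- ((r %% L) + L) %% L
  if (r == 0) x else paste0(substr(x, r + 1L, L), substr(x, 1L, r))
}

extract_hit_seqs <- function(hits, genome) {
  vapply(seq_len(nrow(hits)), function(i) {
    s <- substr(genome[[hits$seq_id[i]]], hits$start[i] + 1L, hits$end[i])
    if (hits$strand[i] == "-") revcomp(s) else s
  }, character(1))
}

#' Build a divergence landscape
#'
#' Bins finite divergence values into fixed-width classes; bin \eqn{k}
#' (0-based) covers \eqn{[k w, (k+1) w)}. Infinite (saturated) values are
#' excluded with a logged count.
#'
#' @param d Numeric divergences (typically \code{$k2p} from
#'   \code{\link{monomer_divergence}}).
#' @param bin_width Bin width as a fraction; default 0.01 (1\% bins).
#' @param n_bins Number of bins; default covers \[0, 0.75).
#' @param weights Optional per-monomer weights (e.g. hit lengths for a
#'   bp-weighted landscape); default 1 per monomer (count mode).
#' @param family_id Optional label stored on the landscape.
#' @return Object of class \code{"divergence_landscape"}: list with
#'   \code{values} (abundance per bin), \code{bin_width}, \code{family_id},
#'   \code{n_excluded}.
#' @export
build_landscape <- function(d, bin_width = 0.01, n_bins = ceiling(0.75 / bin_width),
                            weights = NULL, family_id = NA_character_) {
  if (is.null(weights)) weights <- rep(1, length(d))
  stopifnot(length(weights) == length(d))
  keep <- is.finite(d)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    sat_log("landscape %s: %d saturated/non-finite distance(s) excluded",
            family_id, n_excluded)
  }
  d <- d[keep]; weights <- weights[keep]
  idx <- pmin(floor(d / bin_width), n_bins - 1L) + 1L
  values <- numeric(n_bins)
  if (length(idx)) {
    agg <- tapply(weights, factor(idx, levels = seq_len(n_bins)), sum)
    values <- as.numeric(ifelse(is.na(agg), 0, agg))
  }
  structure(list(values = values, bin_width = bin_width,
                 family_id = family_id, n_excluded = n_excluded),
            class = "divergence_landscape")
}

#' @export
print.divergence_landscape <- function(x, ...) {
  cat(sprintf("divergence landscape%s: %d bins of width %.3g, total abundance %.4g\n",
              if (is.na(x$family_id)) "" else paste0(" for ", x$family_id),
              length(x$values), x$bin_width, sum(x$values)))
  invisible(x)
}

#' Call peaks in a divergence landscape
#'
#' A peak is a maximal admissible run of consecutive bins \eqn{[i..j]} in
#' which every bin value is at least \code{peak_factor} times the bin
#' preceding the run and at least \code{peak_factor} times the bin following
#' it. Bins outside the landscape count as 0, so edge conditions are
#' one-sided. Two further conditions make the rule coherent on real
#' histograms:
#' \itemize{
#'   \item at least one of the two neighbouring bins must be positive --
#'     being "50\% higher" must be demonstrated against some real abundance,
#'     otherwise any run bounded by zeros (including the entire landscape)
#'     would qualify vacuously;
#'   \item the run must be \emph{admissible}: it may not contain an internal
#'     valley bin whose flanking apexes (the run maxima on each side of it)
#'     both exceed it and reach \code{peak_factor} times its value. Such a
#'     valley separates two peaks, and without this condition any two modes
#'     bridged by low but non-zero bins would merge into one run (the outer
#'     neighbour comparison never looks inside the run).
#' }
#' All-zero runs never qualify. Maximal admissible qualifying runs are
#' returned left to right; in the rare event of two overlapping maximal runs
#' the leftmost wins, keeping peaks disjoint.
#'
#' \code{min_fraction} additionally drops peaks whose apex falls below that
#' fraction of the total abundance; it exists to ignore isolated
#' sampling-noise bins in the tail of count histograms and plays no part in
#' the run-qualification rule itself.
#'
#' @param landscape A \code{"divergence_landscape"} or bare numeric vector.
#' @param peak_factor Neighbour ratio a run must reach; default 1.5.
#' @param min_fraction Apex floor as a fraction of total abundance; default 0
#'   (strict rule only).
#' @param rule \code{"every_bin"} (default): every bin of the run must clear
#'   the factor against both neighbours. \code{"run_max"}: only the run
#'   maximum must. The default is the literal reading of "a series of
#'   neighboring bins exhibited 50\% higher values".
#' @return data.frame with one row per peak: \code{from}, \code{to} (0-based
#'   bin indices), \code{apex_bin}, \code{apex_value}.
#' @examples
#' call_peaks(c(1, 1, 10, 1, 1))          # single peak at bin 2
#' call_peaks(c(0, 1, 1.4, 1, 0))         # none: 1.4 < 1.5 * 1
#' @export
call_peaks <- function(landscape, peak_factor = 1.5, min_fraction = 0,
                       rule = c("every_bin", "run_max")) {
  rule <- match.arg(rule)
  v <- if (inherits(landscape, "divergence_landscape")) landscape$values else as.numeric(landscape)
  K <- length(v)
  if (K == 0L) stop("empty landscape")
  # For each start i the scan kernel finds the largest admissible qualifying
  # end bj(i); a run [i..j] is maximal iff no i' <= i reaches an end >= j,
  # so runs whose best end exceeds every earlier start's best end are
  # exactly the maximal ones, with overlaps resolved leftmost-first.
  m <- .peak_runs_cpp(as.numeric(v), peak_factor, rule == "every_bin")
  if (!nrow(m)) {
    return(data.frame(from = integer(0), to = integer(0),
                      apex_bin = integer(0), apex_value = numeric(0)))
  }
  apex_bin <- apply(m, 1, function(r) (r[1]:r[2])[which.max(v[r[1]:r[2]])])
  out <- data.frame(from = m[, 1] - 1L, to = m[, 2] - 1L,
                    apex_bin = apex_bin - 1L, apex_value = v[apex_bin])
  if (min_fraction > 0) {
    out <- out[out$apex_value >= min_fraction * sum(v), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Call peaks by apex prominence
#'
#' A formalisation of the same "50\% higher than preceding and following
#' bins" idea that remains robust on smooth count histograms, where the
#' run-qualification rule of \code{\link{call_peaks}} can miss a genuine
#' secondary mode (no single cut point of a smooth hump clears the factor
#' against both of its immediate neighbours once sampling noise is present).
#'
#' Local-maximum plateaus are candidate peaks. Two adjacent candidates merge
#' into one peak whenever the smaller apex is below \code{peak_factor} times
#' the saddle (minimum bin) between them -- they are then "a series of
#' neighboring bins" acting as one peak, not two separated ones. Each
#' surviving group's run is the contiguous contour around its apex with
#' values at least \code{apex / peak_factor}, which guarantees the apex
#' exceeds \code{peak_factor} times the bins just outside the run; a group
#' only counts when at least one of those bins is positive, and
#' \code{min_fraction} drops groups whose apex falls below that fraction of
#' total abundance. On the worked examples of \code{\link{call_peaks}} both
#' callers agree; they differ on noisy multi-modal histograms, where this
#' one recovers the modes.
#'
#' @inheritParams call_peaks
#' @return data.frame with one row per peak: \code{from}, \code{to} (0-based
#'   contour run), \code{apex_bin}, \code{apex_value}, \code{basin_from},
#'   \code{basin_to} (the peak's catchment between saddles), and
#'   \code{centroid} (abundance-weighted mean bin coordinate over the basin,
#'   continuous; multiply by the bin width for a divergence-scale mode
#'   estimate).
#' @export
call_peaks_prominence <- function(landscape, peak_factor = 1.5,
                                  min_fraction = 0) {
  v <- if (inherits(landscape, "divergence_landscape")) landscape$values else as.numeric(landscape)
  K <- length(v)
  if (K == 0L) stop("empty landscape")
  # candidate apexes: local-maximum plateaus of positive value
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  apex_pos <- integer(0)
  for (p in seq_along(r$values)) {
    val <- r$values[p]
    if (val <= 0) next
    leftv <- if (p > 1) r$values[p - 1] else -Inf
    rightv <- if (p < length(r$values)) r$values[p + 1] else -Inf
    if (val > leftv && val > rightv) {
      apex_pos <- c(apex_pos, as.integer(floor((starts[p] + ends[p]) / 2)))
    }
  }
  if (!length(apex_pos)) {
    return(data.frame(from = integer(0), to = integer(0),
                      apex_bin = integer(0), apex_value = numeric(0),
                      basin_from = integer(0), basin_to = integer(0),
                      centroid = numeric(0)))
  }
  groups <- lapply(apex_pos, function(p) list(apex = p, value = v[p]))
  # merge adjacent groups across under-separated saddles, best-supported
  # (highest-saddle) pair first for determinism
  repeat {
    if (length(groups) < 2L) break
    saddles <- vapply(seq_len(length(groups) - 1L), function(g) {
      min(v[groups[[g]]$apex:groups[[g + 1L]]$apex])
    }, numeric(1))
    mergeable <- which(vapply(seq_along(saddles), function(g) {
      min(groups[[g]]$value, groups[[g + 1L]]$value) < peak_factor * saddles[g]
    }, logical(1)))
    if (!length(mergeable)) break
    g <- mergeable[which.max(saddles[mergeable])]
    a <- groups[[g]]; b <- groups[[g + 1L]]
    keep <- if (a$value >= b$value) a else b
    groups[[g]] <- keep
    groups[[g + 1L]] <- NULL
  }
  # basins: split at the (leftmost) minimum between adjacent apexes
  n_g <- length(groups)
  cuts <- integer(0)
  if (n_g > 1L) {
    cuts <- vapply(seq_len(n_g - 1L), function(g) {
      span <- groups[[g]]$apex:groups[[g + 1L]]$apex
      span[which.min(v[span])]
    }, integer(1))
  }
  basin_from <- c(1L, cuts + 1L)
  basin_to <- c(cuts, K)
  rows <- lapply(seq_len(n_g), function(g) {
    apex <- groups[[g]]$apex
    val <- groups[[g]]$value
    thr <- val / peak_factor
    i <- apex
    while (i > basin_from[g] && v[i - 1L] >= thr) i <- i - 1L
    j <- apex
    while (j < basin_to[g] && v[j + 1L] >= thr) j <- j + 1L
    ln <- if (i > 1L) v[i - 1L] else 0
    rn <- if (j < K) v[j + 1L] else 0
    if (ln <= 0 && rn <= 0) return(NULL)
    k <- basin_from[g]:basin_to[g]
    data.frame(from = i - 1L, to = j - 1L, apex_bin = apex - 1L,
               apex_value = val,
               basin_from = basin_from[g] - 1L, basin_to = basin_to[g] - 1L,
               centroid = sum(v[k] * (k - 0.5)) / sum(v[k]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(from = integer(0), to = integer(0),
                      apex_bin = integer(0), apex_value = numeric(0),
                      basin_from = integer(0), basin_to = integer(0),
                      centroid = numeric(0)))
  }
  if (min_fraction > 0) {
    out <- out[out$apex_value >= min_fraction * sum(v), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Classify a landscape by its peak structure
#'
#' Shape labels follow the recurring landscape archetypes: a single dominant
#' peak at low divergence (recent amplification), a single peak shifted to
#' higher divergence (aged family), two distinct peaks, or several.
#'
#' @param peaks Peak table from \code{\link{call_peaks}}.
#' @param low_bin_cutoff Apex bin (0-based) below which a single peak is
#'   "low"; default 10, i.e. below 10\% divergence with 1\% bins.
#' @return One of \code{"flat"}, \code{"unimodal_low"},
#'   \code{"unimodal_shifted"}, \code{"bimodal"}, \code{"multimodal"}.
#' @export
classify_landscape <- function(peaks, low_bin_cutoff = 10L) {
  n <- nrow(peaks)
  if (n == 0L) {
    sat_log("no qualifying peaks: landscape classified as flat")
    return("flat")
  }
  if (n == 1L) {
    return(if (peaks$apex_bin[1] < low_bin_cutoff) "unimodal_low" else "unimodal_shifted")
  }
  if (n == 2L) return("bimodal")
  "multimodal"
}

#' Landscape of a whole annotated family, end to end
#'
#' Convenience wrapper: divergence records, landscape, peaks and shape label
#' for one family's hits. Shape classification uses the prominence caller
#' (\code{\link{call_peaks_prominence}}), which recovers smooth secondary
#' modes that the literal run rule can miss; the strict-rule peaks are
#' available via \code{\link{call_peaks}} on the returned landscape.
#'
#' @inheritParams monomer_divergence
#' @param config A \code{\link{sat_config}}.
#' @param min_fraction Apex floor passed to the peak caller.
#' @return List with \code{hits} (divergence-annotated), \code{landscape},
#'   \code{peaks} (prominence caller), \code{shape}.
#' @export
family_landscape <- function(hits, genome, family, config = sat_config(),
                             min_fraction = 0.01) {
  hits <- monomer_divergence(hits, genome, family)
  ls <- build_landscape(hits$k2p, bin_width = config$bin_width,
                        family_id = family$family_id)
  peaks <- call_peaks_prominence(ls, peak_factor = config$peak_factor,
                                 min_fraction = min_fraction)
  list(hits = hits, landscape = ls, peaks = peaks,
       shape = classify_landscape(peaks))
}

#' Write a landscape (and optional peak table) as TSV
#'
#' @param landscape A \code{"divergence_landscape"}.
#' @param path Output TSV.
#' @param peaks Optional peak table; written next to it as
#'   \code{<path>.peaks.tsv}.
#' @return \code{path}, invisibly.
#' @export
write_landscape <- function(landscape, path, peaks = NULL) {
  k <- seq_along(landscape$values) - 1L
  df <- data.frame(family = landscape$family_id,
                   bin_low = k * landscape$bin_width,
                   bin_high = (k + 1L) * landscape$bin_width,
                   abundance = landscape$values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(peaks)) {
    write.table(peaks, paste0(path, ".peaks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
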