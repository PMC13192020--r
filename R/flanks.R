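# Array flank extraction and conservation profiling: the genomic-context
# analysis for families organised in a small number of short arrays.

#' Extract flanking sequences around arrays
#'
#' Returns \code{flank_length} bp upstream and downstream of each array,
#' oriented 5'->3' relative to the array strand: for a minus-strand array the
#' genomic right side is the upstream flank and both flanks are
#' reverse-complemented. Flanks truncated by a contig edge are flagged; an
#' array starting at position 0 yields a zero-length, flagged upstream flank.
#'
#' @param arrays Array table from \code{\link{build_arrays}} (one family or
#'   several).
#' @param genome Named character vector of chromosome sequences.
#' @param flank_length Flank length in bp; default 1000.
#' @return data.frame of class \code{"flank_set"}: \code{family_id},
#'   \code{array_id}, \code{seq_id}, \code{array_start}, \code{side}
#'   (\code{"upstream"}/\code{"downstream"}), \code{seq}, \code{length},
#'   \code{truncated}.
#' @export
extract_flanks <- function(arrays, genome, flank_length = 1000L) {
  stopifnot(flank_length > 0)
  rows <- lapply(seq_len(nrow(arrays)), function(i) {
    a <- arrays[i, ]
    G <- nchar(genome[[a$seq_id]])
    left_start <- max(0L, a$start - flank_length)
    left_seq <- substr(genome[[a$seq_id]], left_start + 1L, a$start)
    right_end <- min(G, a$end + flank_length)
    right_seq <- substr(genome[[a$seq_id]], a$end + 1L, right_end)
    left_trunc <- (a$start - left_start) < flank_length
    right_trunc <- (right_end - a$end) < flank_length
    if (a$strand == "+") {
      up <- left_seq; down <- right_seq
      up_tr <- left_trunc; down_tr <- right_trunc
    } else {
      up <- revcomp(right_seq); down <- revcomp(left_seq)
      up_tr <- right_trunc; down_tr <- left_trunc
    }
    if (up_tr || down_tr) {
      sat_log("flank of %s array %s truncated at contig edge",
              a$family_id, a$array_id)
    }
    data.frame(family_id = a$family_id, array_id = a$array_id,
               seq_id = a$seq_id, array_start = a$start,
               side = c("upstream", "downstream"),
               seq = c(up, down), length = c(nchar(up), nchar(down)),
               truncated = c(up_tr, down_tr), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("flank_set", class(out))
  out
}

#' Conservation profile of a flank set
#'
#' Aligns every flank of one side to a deterministic reference flank (the
#' longest member, ties broken by source array coordinate) and measures, in
#' sliding windows walking away from the array boundary, the fraction of
#' members whose windowed identity to the reference reaches
#' \code{identity_threshold}. The conserved block length is the largest L
#' such that every \code{window}-bp window inside \[0, L) keeps at least
#' \code{member_fraction} of the members above the identity threshold.
#' Members with failing windows inside the conserved block are reported as
#' outliers, classified as carrying an insertion, being truncated, or losing
#' similarity early.
#'
#' Positions are measured from the array boundary outward: position 1 of an
#' upstream flank is the base immediately 5' of the array.
#'
#' @param flank_set A \code{"flank_set"} (or compatible data.frame)
#'   restricted to the members to profile; must be a single side of a single
#'   family, with at least 2 members.
#' @param identity_threshold Windowed identity a member must reach;
#'   default 0.95.
#' @param member_fraction Fraction of members that must reach it;
#'   default 0.75.
#' @param window Window size in bp; default 100.
#' @param min_insertion Insertion size (bp) in the member-vs-reference
#'   alignment that classifies an outlier as "insertion"; default 20.
#' @return List of class \code{"conservation_profile"}:
#'   \code{conserved_block_length}, \code{position_fraction} (per-position
#'   fraction of members identical to the reference), \code{reference}
#'   (array_id of the reference member), \code{outliers} (data.frame:
#'   array_id, reason).
#' @export
conservation_profile <- function(flank_set, identity_threshold = 0.95,
                                 member_fraction = 0.75, window = 100L,
                                 min_insertion = 20L) {
  if (length(unique(flank_set$side)) > 1L) {
    stop("profile one side at a time (upstream or downstream)")
  }
  n <- nrow(flank_set)
  if (n < 2L) stop("conservation profile undefined for fewer than 2 flanks")
  # flanks oriented 5'->3'; index from the array boundary outward
  boundary_first <- function(seq, side) {
    if (side == "upstream") {
      paste(rev(strsplit(seq, "")[[1]]), collapse = "")
    } else {
      seq
    }
  }
  seqs <- mapply(boundary_first, flank_set$seq, flank_set$side)
  ids <- flank_set$array_id
  ref_chars_of <- function(x) strsplit(x, "")[[1]]
  # Reference member: modal length first (an insertion- or truncation-bearing
  # member must not become the yardstick merely by being longest), then the
  # longest, then source array coordinate.
  ord <- order(flank_set$seq_id, flank_set$array_start)
  len_tab <- table(nchar(seqs))
  modal_len <- as.integer(names(len_tab)[len_tab == max(len_tab)])
  modal_len <- max(modal_len)
  cand <- ord[nchar(seqs)[ord] == modal_len]
  ref_i <- cand[1]
  ref <- seqs[[ref_i]]
  R <- nchar(ref)
  match_mat <- matrix(FALSE, nrow = n, ncol = R)
  for (i in seq_len(n)) {
    if (i == ref_i) {
      match_mat[i, ] <- TRUE
      next
    }
    if (nchar(seqs[[i]]) == 0L) next
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seqs[[i]]), Biostrings::DNAString(ref),
      type = "global", substitutionMatrix = sat_submat(),
      gapOpening = 2, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    ref_pos <- cumsum(s != "-")
    keep <- s != "-"
    match_mat[i, ref_pos[keep]] <- p[keep] == s[keep]
  }
  # windowed identity per member via cumulative sums
  w <- min(window, R)
  cums <- cbind(0, t(apply(match_mat, 1, cumsum)))
  starts <- seq_len(R - w + 1L)
  win_id <- (cums[, starts + w] - cums[, starts]) / w   # n x n_starts
  pass <- win_id >= identity_threshold
  frac_ok <- colMeans(pass)
  fail_start <- which(frac_ok < member_fraction)
  block <- if (!length(fail_start)) R else max(0L, min(fail_start) - 1L + w - 1L)
  # outliers: members with a failing window inside the conserved block.
  # An "insertion" is recognised when similarity to the reference resumes at
  # a positional offset of at least min_insertion past the failure point
  # (the member is the reference shifted by the inserted length) -- more
  # robust than gap-run lengths, which mild gap penalties fragment.
  outliers <- data.frame(array_id = integer(0), reason = character(0))
  if (block >= w) {
    in_block <- starts <= block - w + 1L
    ref_chars <- ref_chars_of(ref)
    for (i in seq_len(n)) {
      if (i == ref_i) next
      if (all(pass[i, in_block])) next
      fail_from <- starts[in_block][which(!pass[i, in_block])[1]]
      reason <- if (flank_set$truncated[i] || nchar(seqs[[i]]) < block) {
        "truncation"
      } else if (has_insertion_offset(ref_chars_of(seqs[[i]]), ref_chars,
                                      fail_from, min_insertion)) {
        "insertion"
      } else {
        "low_similarity"
      }
      outliers <- rbind(outliers,
                        data.frame(array_id = ids[i], reason = reason))
    }
    outliers <- outliers[order(outliers$array_id), , drop = FALSE]
    rownames(outliers) <- NULL
  }
  structure(list(conserved_block_length = as.integer(block),
                 position_fraction = colMeans(match_mat),
                 reference = ids[ref_i],
                 outliers = outliers,
                 identity_threshold = identity_threshold,
                 member_fraction = member_fraction,
                 window = w),
            class = "conservation_profile")
}

# Does member[j + o] track ref[j] beyond the failure point for some shift
# o >= min_insertion? The shifted diagonal is scanned with a sliding window:
# an insertion resumes high identity only downstream of the inserted block,
# so the whole-diagonal mean would dilute it.
has_insertion_offset <- function(mem, ref, fail_from, min_insertion,
                                 min_span = 50L, min_identity = 0.8) {
  start_j <- max(1L, fail_from - 20L)
  max_o <- min(length(mem) - start_j - min_span, 600L)
  if (max_o < min_insertion) return(FALSE)
  for (o in seq(min_insertion, max_o)) {
    j <- start_j:min(length(ref), length(mem) - o)
    if (length(j) < min_span) next
    eq <- mem[j + o] == ref[j]
    cs <- c(0, cumsum(eq))
    w <- min_span
    win <- (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
    if (max(win) >= min_identity) return(TRUE)
  }
  FALSE
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("conserved block: %d bp from the array boundary (window %d, identity >= %.2f in >= %.0f%% of members)\n",
              x$conserved_block_length, x$window, x$identity_threshold,
              100 * x$member_fraction))
  if (nrow(x$outliers)) {
    cat("outliers:\n")
    for (i in seq_len(nrow(x$outliers))) {
      cat(sprintf("  array %s: %s\n", x$outliers$array_id[i], x$outliers$reason[i]))
    }
  }
  invisible(x)
}
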