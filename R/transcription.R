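# Transcription quantification against satellite dimer references. Reads are
# counted by an explicit ungapped end-to-end matcher rather than a gapped
# mapper: at a one-mismatch ceiling over a dimer reference gaps are outside
# the acceptance region, and the matcher is exhaustively verifiable.

#' Head-to-tail dimer reference of a family
#'
#' The consensus concatenated with itself, so reads spanning the junction
#' between two monomer copies align end-to-end without clipping.
#'
#' @param family A \code{\link{sat_family}}.
#' @return List with \code{family_id}, \code{dimer}, \code{length}.
#' @export
dimer_reference <- function(family) {
  list(family_id = family$family_id,
       dimer = paste0(family$consensus, family$consensus),
       length = 2L * family$monomer_length)
}

#' Count reads matching each family's dimer reference
#'
#' A read counts for a family when it aligns end-to-end, ungapped, at any
#' offset of the family's dimer on either strand with at most
#' \code{mismatch_limit} mismatches. A read counts at most once per family
#' but may count for several families (all-alignments semantics). With
#' paired-end input a fragment counts once if either mate matches. Reads
#' longer than a dimer are skipped for that family with a logged count.
#'
#' @param reads Character vector of read sequences (or a
#'   \code{DNAStringSet}); mate 1 for paired-end data.
#' @param families List of \code{\link{sat_family}}.
#' @param mismatch_limit Maximum mismatches; default 1.
#' @param reads2 Optional mate-2 sequences, parallel to \code{reads}.
#' @return Named integer vector: fragments counted per family.
#' @export
count_matching_reads <- function(reads, families, mismatch_limit = 1L,
                                 reads2 = NULL) {
  reads <- toupper(as.character(reads))
  if (!is.null(reads2)) {
    reads2 <- toupper(as.character(reads2))
    stopifnot(length(reads2) == length(reads))
  }
  counts <- integer(length(families))
  names(counts) <- vapply(families, `[[`, character(1), "family_id")
  for (k in seq_along(families)) {
    ref <- dimer_reference(families[[k]])
    too_long <- nchar(reads) > ref$length
    if (any(too_long)) {
      sat_log("%d read(s) longer than the %s dimer skipped",
              sum(too_long), ref$family_id)
    }
    hit <- .read_matches_cpp(reads, ref$dimer, revcomp(ref$dimer),
                             as.integer(mismatch_limit))
    if (!is.null(reads2)) {
      hit2 <- .read_matches_cpp(reads2, ref$dimer, revcomp(ref$dimer),
                                as.integer(mismatch_limit))
      hit <- hit | hit2
    }
    counts[k] <- sum(hit)
  }
  counts
}

#' FPKM normalisation
#'
#' Fragments per kilobase of feature per million library fragments:
#' \deqn{FPKM = C_s \cdot 10^9 / (L_s \cdot N)}
#' with \eqn{C_s} the fragment count for the satellite, \eqn{L_s} the dimer
#' reference length in bp, and \eqn{N} the library-size denominator. Owing to
#' copy-number differences between satellites, FPKM values are comparable
#' only longitudinally (one family across libraries), never between
#' families.
#'
#' @param C_s Fragment count(s).
#' @param L_s Feature (dimer) length in bp.
#' @param N Library-size denominator in fragments (total QC-passing
#'   fragments, or genome-mapped fragments if an external mapping supplies
#'   it).
#' @return FPKM value(s).
#' @examples
#' fpkm(1000, 284, 1e7)  # 352.1127
#' @export
fpkm <- function(C_s, L_s, N) {
  stopifnot(all(L_s > 0))
  if (any(N == 0)) stop("empty library: N must be positive")
  C_s * 1e9 / (L_s * N)
}

#' Quantify satellite transcription across libraries
#'
#' Counts dimer-matching fragments and FPKM-normalises them for every
#' family x library combination.
#'
#' @param read_sets Named list of read sets (character vectors), one per
#'   library.
#' @param families List of \code{\link{sat_family}}.
#' @param meta data.frame with columns \code{library_id}, \code{stage},
#'   \code{sex}; row order irrelevant. Stages use the life-cycle labels
#'   egg, early_larva, mid_larva, late_larva, early_pupa, late_pupa,
#'   early_adult, late_adult; sex is F, M or unknown.
#' @param mismatch_limit Maximum mismatches per read; default 1.
#' @param N Optional named vector of library-size denominators; defaults to
#'   the number of reads supplied per library.
#' @return data.frame of expression records: \code{family_id},
#'   \code{library_id}, \code{stage}, \code{sex}, \code{count}, \code{N},
#'   \code{fpkm}.
#' @export
quantify_expression <- function(read_sets, families, meta, mismatch_limit = 1L,
                                N = NULL) {
  stopifnot(all(c("library_id", "stage", "sex") %in% names(meta)),
            all(names(read_sets) %in% meta$library_id))
  if (is.null(N)) N <- vapply(read_sets, length, integer(1))
  rows <- lapply(names(read_sets), function(lib) {
    counts <- count_matching_reads(read_sets[[lib]], families, mismatch_limit)
    m <- meta[match(lib, meta$library_id), ]
    data.frame(family_id = names(counts), library_id = lib,
               stage = m$stage, sex = m$sex, count = as.integer(counts),
               N = N[[lib]],
               fpkm = fpkm(counts,
                           vapply(families, function(f) 2L * f$monomer_length,
                                  integer(1)),
                           N[[lib]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-family stage-by-sex expression profile
#'
#' Mean FPKM, sample standard deviation and replicate count per family,
#' stage and sex. Libraries below \code{min_depth} fragments are excluded
#' with a log message (a simple stand-in for full library QC). Single
#' replicates report \code{NA} standard deviation. Cross-family ranking is
#' refused unless \code{force = TRUE}: FPKM is valid longitudinally only.
#'
#' @param records Expression records from \code{\link{quantify_expression}}.
#' @param min_depth Minimum library size (fragments); default 0.
#' @return data.frame: \code{family_id}, \code{stage}, \code{sex},
#'   \code{mean_fpkm}, \code{sd_fpkm}, \code{n_replicates}.
#' @export
expression_profile <- function(records, min_depth = 0) {
  shallow <- unique(records$library_id[records$N < min_depth])
  if (length(shallow)) {
    sat_log("excluding %d low-depth librar%s: %s", length(shallow),
            if (length(shallow) == 1) "y" else "ies",
            paste(shallow, collapse = ", "))
    records <- records[!records$library_id %in% shallow, , drop = FALSE]
  }
  key <- interaction(records$family_id, records$stage, records$sex, drop = TRUE)
  rows <- lapply(split(records, key), function(r) {
    data.frame(family_id = r$family_id[1], stage = r$stage[1], sex = r$sex[1],
               mean_fpkm = mean(r$fpkm),
               sd_fpkm = if (nrow(r) > 1) sd(r$fpkm) else NA_real_,
               n_replicates = nrow(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$family_id, out$stage, out$sex), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stage/sex with the highest mean expression per family
#'
#' @param profile Output of \code{\link{expression_profile}}.
#' @return data.frame: \code{family_id}, \code{stage}, \code{sex},
#'   \code{mean_fpkm} at the per-family maximum.
#' @export
expression_argmax <- function(profile) {
  rows <- lapply(split(profile, profile$family_id), function(p) {
    p[which.max(p$mean_fpkm), c("family_id", "stage", "sex", "mean_fpkm")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate stage- and sex-structured RNA-seq read sets
#'
#' Draws each family's reads uniformly from all end-to-end positions of the
#' family's dimer on both strands (so a fraction spans the monomer
#' junction), applies a uniform per-base substitution error, and adds random
#' background reads. True planted fragment counts per family and library are
#' recorded.
#'
#' @param families List of \code{\link{sat_family}}.
#' @param expression Matrix of true fragment counts, families x libraries
#'   (dimnames required).
#' @param meta data.frame: \code{library_id}, \code{stage}, \code{sex}.
#' @param read_length Read length in bp (must be at most the shortest dimer).
#' @param n_background Background reads per library; default 1000.
#' @param error_rate Per-base substitution error; default 0.002.
#' @param seed Integer seed.
#' @return List of class \code{"sat_read_sim"}: \code{read_sets} (named list
#'   per library), \code{truth} (long data.frame family_id, library_id,
#'   true_count), \code{meta}.
#' @export
simulate_reads <- function(families, expression, meta, read_length = 100L,
                           n_background = 1000L, error_rate = 0.002,
                           seed = NULL) {
  fam_ids <- vapply(families, `[[`, character(1), "family_id")
  stopifnot(!is.null(rownames(expression)), !is.null(colnames(expression)),
            all(rownames(expression) %in% fam_ids),
            all(colnames(expression) %in% meta$library_id))
  dimers <- lapply(families, dimer_reference)
  names(dimers) <- fam_ids
  min_dimer <- min(vapply(dimers, `[[`, integer(1), "length"))
  if (read_length >= min_dimer) {
    stop("read_length must be shorter than the shortest dimer (", min_dimer, " bp)")
  }
  with_seed(seed, {
    read_sets <- list()
    truth <- list()
    for (lib in colnames(expression)) {
      reads <- character(0)
      for (f in rownames(expression)) {
        cnt <- expression[f, lib]
        if (cnt > 0) {
          dm <- dimers[[f]]$dimer
          starts <- sample.int(nchar(dm) - read_length + 1L, cnt, replace = TRUE)
          rd <- substring(dm, starts, starts + read_length - 1L)
          minus <- runif(cnt) < 0.5
          rd[minus] <- revcomp(rd[minus])
          reads <- c(reads, apply_read_errors(rd, error_rate))
        }
        truth[[length(truth) + 1L]] <- data.frame(
          family_id = f, library_id = lib, true_count = as.integer(cnt),
          stringsAsFactors = FALSE)
      }
      bg <- random_dna(rep(read_length, n_background))
      reads <- c(reads, bg)
      names(reads) <- sprintf("%s_read%06d", lib, seq_along(reads))
      read_sets[[lib]] <- reads
    }
    structure(list(read_sets = read_sets,
                   truth = do.call(rbind, truth), meta = meta),
              class = "sat_read_sim")
  })
}

# uniform per-base substitution errors (to a uniformly random different base)
apply_read_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || !length(reads)) return(reads)
  rl <- nchar(reads[1])
  n <- length(reads)
  err <- matrix(runif(n * rl) < error_rate, nrow = n)
  if (!any(err)) return(reads)
  m <- matrix(unlist(strsplit(reads, ""), use.names = FALSE),
              nrow = n, byrow = TRUE)
  idx <- which(err)
  cur <- m[idx]
  repl <- vapply(cur, function(b) sample(setdiff(DNA_BASES_, b), 1L), character(1))
  m[idx] <- repl
  out <- apply(m, 1, paste, collapse = "")
  names(out) <- names(reads)
  out
}
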