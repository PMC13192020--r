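# Shared fixtures and independent oracles. Oracles are deliberately written
# as direct enumerations, structurally unlike the package implementations
# they check.

options(satkit.quiet = TRUE)

random_consensus <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

rotate_str <- function(x, r) {
  L <- nchar(x)
  r <- r %% L
  if (r == 0) x else paste0(substr(x, r + 1, L), substr(x, 1, r))
}

revcomp_str <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# ---- peak-calling oracle: exhaustive run enumeration -----------------------
# qualification: every bin of [i..j] >= factor * both neighbours (out-of-range
# = 0), at least one neighbouring bin positive, run not all-zero, and no
# internal valley whose flanking run maxima both strictly exceed it and reach
# factor * its value (such a valley separates two peaks); maximal = contained
# in no other admissible qualifying run; overlaps resolved leftmost-first.
peak_oracle <- function(v, factor = 1.5) {
  K <- length(v)
  admissible <- function(i, j) {
    if (j - i < 2) return(TRUE)
    for (k in (i + 1):(j - 1)) {
      a_l <- max(v[i:k])
      a_r <- max(v[k:j])
      fl <- min(a_l, a_r)
      if (fl > v[k] && fl >= factor * v[k]) return(FALSE)
    }
    TRUE
  }
  runs <- list()
  for (i in seq_len(K)) {
    for (j in i:K) {
      run <- v[i:j]
      ln <- if (i > 1) v[i - 1] else 0
      rn <- if (j < K) v[j + 1] else 0
      if (any(run > 0) && (ln > 0 || rn > 0) &&
          all(run >= factor * ln) && all(run >= factor * rn) &&
          admissible(i, j)) {
        runs[[length(runs) + 1]] <- c(i, j)
      }
    }
  }
  if (!length(runs)) {
    return(data.frame(from = integer(0), to = integer(0)))
  }
  m <- do.call(rbind, runs)
  maximal <- vapply(seq_len(nrow(m)), function(k) {
    !any(m[, 1] <= m[k, 1] & m[, 2] >= m[k, 2] &
           !(m[, 1] == m[k, 1] & m[, 2] == m[k, 2]))
  }, logical(1))
  m <- m[maximal, , drop = FALSE]
  m <- m[order(m[, 1]), , drop = FALSE]
  keep <- logical(nrow(m))
  last_end <- 0
  for (k in seq_len(nrow(m))) {
    if (m[k, 1] > last_end) {
      keep[k] <- TRUE
      last_end <- m[k, 2]
    }
  }
  m <- m[keep, , drop = FALSE]
  data.frame(from = m[, 1] - 1L, to = m[, 2] - 1L)
}

# ---- annotation oracle: all positions x all rotations x both strands ------
# returns every window within the mismatch ceiling, per strand-local scan.
annotation_oracle <- function(genome, consensus, max_divergence) {
  L <- nchar(consensus)
  max_mm <- floor(max_divergence * L)
  cons_chars <- lapply(0:(L - 1), function(r) strsplit(rotate_str(consensus, r), "")[[1]])
  out <- list()
  for (chrom in names(genome)) {
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") genome[[chrom]] else revcomp_str(genome[[chrom]])
      G <- nchar(sseq)
      if (G < L) next
      gv <- strsplit(sseq, "")[[1]]
      for (s in 0:(G - L)) {
        win <- gv[(s + 1):(s + L)]
        for (r in 0:(L - 1)) {
          mm <- sum(win != cons_chars[[r + 1]] | win == "N")
          if (mm <= max_mm) {
            st <- if (strand == "+") s else G - s - L
            out[[length(out) + 1]] <- data.frame(
              seq_id = chrom, start = st, end = st + L, strand = strand,
              rotation = r, divergence = mm / L, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(seq_id = character(0), start = integer(0), end = integer(0),
                      strand = character(0), rotation = integer(0),
                      divergence = numeric(0)))
  }
  do.call(rbind, out)
}

# ---- read-count oracle: all offsets, both strands, explicit loops ---------
read_count_oracle <- function(reads, dimer, limit) {
  dchars <- strsplit(dimer, "")[[1]]
  rcchars <- strsplit(revcomp_str(dimer), "")[[1]]
  vapply(reads, function(rd) {
    rv <- strsplit(rd, "")[[1]]
    m <- length(rv)
    if (m > length(dchars)) return(FALSE)
    for (ref in list(dchars, rcchars)) {
      for (off in 0:(length(ref) - m)) {
        if (sum(rv != ref[(off + 1):(off + m)] | rv == "N") <= limit) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
}

# ---- age oracle: max pairwise divergence time from path lengths -----------
age_oracle <- function(tree, taxa) {
  if (length(taxa) < 2) return(0)
  coph <- ape::cophenetic.phylo(tree$phylo)
  max(coph[taxa, taxa]) / 2
}

# reciprocal-overlap matching of hit tables against truth (>= 90% both ways)
match_truth <- function(hits, truth, min_overlap = 0.9) {
  matched <- logical(nrow(truth))
  used <- logical(nrow(hits))
  for (i in seq_len(nrow(truth))) {
    t1 <- truth[i, ]
    cand <- which(!used & hits$seq_id == t1$seq_id &
                    hits$start < t1$end & hits$end > t1$start &
                    hits$family_id == t1$family_id)
    for (k in cand) {
      ov <- min(hits$end[k], t1$end) - max(hits$start[k], t1$start)
      if (ov >= min_overlap * (t1$end - t1$start) &&
          ov >= min_overlap * (hits$end[k] - hits$start[k])) {
        matched[i] <- TRUE
        used[k] <- TRUE
        break
      }
    }
  }
  list(recall = mean(matched), precision = sum(matched) / nrow(hits),
       matched = matched)
}

fig7a_tree <- function() {
  read_newick_dated(system.file("extdata", "insect_orders_timetree.nwk",
                                package = "satkit"))
}

presence_from_taxa <- function(taxa, family = "fam", focal = NULL) {
  filter_presence(data.frame(taxon = taxa, family = family,
                             query_coverage = 0.9, stringsAsFactors = FALSE),
                  focal_taxon = focal)
}
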