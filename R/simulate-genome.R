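# Synthetic satellitome generator: genomes with planted arrays and
# machine-readable truth tables, the ground truth for every downstream stage.

#' Mutate a monomer to a target K2P divergence
#'
#' Applies the two-rate (transition/transversion) substitution process at the
#' branch length equal to \code{target_divergence}, so the expected K2P
#' distance of the result from the input equals the target. \code{kappa} is
#' the expected transition:transversion \emph{count} ratio; at
#' \code{kappa = 2} roughly two thirds of substitutions are transitions.
#' Substitution-only: no indels are introduced.
#'
#' @param consensus DNA string.
#' @param target_divergence Expected K2P distance, in \[0, 0.75).
#' @param kappa Transition:transversion ratio; default 2.
#' @param seed Optional integer seed.
#' @return Mutated DNA string of the same length.
#' @examples
#' mutate_monomer("ACGTACGTACGT", 0)  # identical
#' @export
mutate_monomer <- function(consensus, target_divergence, kappa = 2, seed = NULL) {
  with_seed(seed, mutate_many(consensus, target_divergence, kappa))[1]
}

# Vectorised core: one mutated copy per element of `targets`.
# K80 site-category probabilities at branch length d with count ratio kappa:
#   alpha*t = d*kappa/(kappa+1), beta*t = d/(2*(kappa+1))
#   P(transition)       = 1/4 + 1/4 e^{-4 beta t} - 1/2 e^{-2(alpha+beta)t}
#   P(each transversion)= 1/4 - 1/4 e^{-4 beta t}
# Plugging the expected (P, Q) into the K2P formula returns d exactly, so the
# generator is unbiased for the estimator it feeds.
mutate_many <- function(consensus, targets, kappa = 2) {
  if (any(targets < 0 | targets >= 0.75)) {
    stop("target divergence must lie in [0, 0.75): the K2P transform saturates")
  }
  if (kappa <= 0) stop("kappa must be positive")
  L <- nchar(consensus)
  n <- length(targets)
  base <- strsplit(consensus, "")[[1]]
  at <- targets * kappa / (kappa + 1)
  bt <- targets / (2 * (kappa + 1))
  P <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  Q <- 0.5 - 0.5 * exp(-4 * bt)
  u <- matrix(runif(n * L), nrow = n)
  Pm <- matrix(P, nrow = n, ncol = L)
  Qm <- matrix(Q, nrow = n, ncol = L)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C", N = "N")
  tv1_map <- c(A = "C", G = "C", C = "A", T = "A", N = "N")
  tv2_map <- c(A = "T", G = "T", C = "G", T = "G", N = "N")
  out <- matrix(rep(base, each = n), nrow = n)
  is_ts <- u < Pm
  is_tv1 <- !is_ts & u < Pm + Qm / 2
  is_tv2 <- !is_ts & !is_tv1 & u < Pm + Qm
  bm <- matrix(rep(base, each = n), nrow = n)
  out[is_ts] <- ts_map[bm[is_ts]]
  out[is_tv1] <- tv1_map[bm[is_tv1]]
  out[is_tv2] <- tv2_map[bm[is_tv2]]
  apply(out, 1, paste, collapse = "")
}

#' Simulation spec for one satDNA family
#'
#' Describes how a family's arrays are planted: the chromosomal organisation
#' class, array sizes, and the divergence mixture its monomers are drawn
#' from. The organisation classes mirror the archetypes seen in real
#' satellitomes: many interspersed arrays across most chromosomes, large
#' (sub)telomeric terminal blocks, a single large block, or arrays confined
#' to a single chromosome.
#'
#' @param family A \code{\link{sat_family}}.
#' @param placement_mode One of \code{"interspersed"},
#'   \code{"terminal_blocks"}, \code{"single_block"},
#'   \code{"restricted_chromosome"}.
#' @param n_arrays Number of arrays (forced to 1 for \code{single_block}).
#' @param array_length_range \code{c(min, max)} array size in monomers.
#' @param divergence_mixture data.frame with columns \code{weight},
#'   \code{mean}, \code{sd}: each monomer's target divergence is drawn from a
#'   mixture of normals truncated to \[0, 0.45\]. Default: one component at
#'   0.03 with sd 0.01.
#' @param kappa Transition:transversion count ratio; default 2.
#' @param divergence_cap Hard ceiling applied to drawn divergences;
#'   default 0.45 (the annotation screen's ceiling).
#' @param flank_cassette Optional DNA string planted immediately on both
#'   sides of every array (conserved flanking cassette).
#' @param chromosome Optional chromosome name(s) restricting placement: the
#'   single chromosome of a restricted/single-block family, or the candidate
#'   pool for the other modes.
#' @return List of class \code{"family_sim_spec"}.
#' @export
family_sim_spec <- function(family,
                            placement_mode = c("interspersed", "terminal_blocks",
                                               "single_block", "restricted_chromosome"),
                            n_arrays = 10L,
                            array_length_range = c(2L, 9L),
                            divergence_mixture = data.frame(weight = 1, mean = 0.03, sd = 0.01),
                            kappa = 2,
                            flank_cassette = NULL,
                            chromosome = NULL,
                            divergence_cap = 0.45) {
  placement_mode <- match.arg(placement_mode)
  stopifnot(inherits(family, "sat_family"),
            n_arrays >= 1L,
            length(array_length_range) == 2L,
            array_length_range[1] >= 1L,
            array_length_range[1] <= array_length_range[2])
  if (abs(sum(divergence_mixture$weight) - 1) > 1e-8) {
    stop("divergence mixture weights must sum to 1")
  }
  if (any(divergence_mixture$mean < 0 | divergence_mixture$mean > 0.45)) {
    stop("mixture component means must lie in [0, 0.45]")
  }
  if (placement_mode == "single_block") n_arrays <- 1L
  if (!is.null(flank_cassette)) flank_cassette <- check_dna(flank_cassette, "flank cassette")
  stopifnot(divergence_cap > 0, divergence_cap <= 0.45)
  structure(list(family = family, placement_mode = placement_mode,
                 n_arrays = as.integer(n_arrays),
                 array_length_range = as.integer(array_length_range),
                 divergence_mixture = divergence_mixture,
                 kappa = kappa, flank_cassette = flank_cassette,
                 chromosome = chromosome,
                 divergence_cap = divergence_cap),
            class = "family_sim_spec")
}

draw_mixture <- function(mix, n, cap = 0.45) {
  comp <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
  d <- rnorm(n, mean = mix$mean[comp], sd = mix$sd[comp])
  pmin(pmax(d, 0), cap)
}

#' Simulate a genome with planted satDNA arrays
#'
#' Background sequence is i.i.d. uniform DNA. Every planted monomer is
#' recorded in the truth table with its family, strand, rotation offset and
#' true target divergence; arrays are recorded separately. Deterministic
#' under a fixed seed. Placement is rejection-sampled with a minimum gap of
#' \code{min_gap} bp between planted blocks; failure to place raises an
#' error naming the offending family.
#'
#' @param specs List of \code{\link{family_sim_spec}} objects.
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#' @param seed Integer seed.
#' @param min_gap Minimum distance between planted blocks (default 500 bp).
#' @return List of class \code{"sat_genome_sim"}: \code{genome} (named
#'   character vector), \code{truth} (per-monomer data.frame: seq_id, start,
#'   end, strand, family_id, divergence, rotation, array_id), \code{arrays}
#'   (per-array data.frame with n_monomers), \code{specs}, \code{seed}.
#' @export
simulate_genome <- function(specs, chrom_lengths, seed = NULL, min_gap = 500L) {
  if (inherits(specs, "family_sim_spec")) specs <- list(specs)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  with_seed(seed, {
    genome <- setNames(random_dna(chrom_lengths), names(chrom_lengths))
    occupied <- lapply(chrom_lengths, function(...) {
      data.frame(start = integer(0), end = integer(0))
    })
    truth <- list()
    arrays <- list()
    aid <- 0L
    for (sp in specs) {
      fam <- sp$family
      L <- fam$monomer_length
      n_arr <- sp$n_arrays
      chroms <- placement_chromosomes(sp, names(chrom_lengths))
      len_rng <- seq(sp$array_length_range[1], sp$array_length_range[2])
      lens <- len_rng[sample.int(length(len_rng), n_arr, replace = TRUE)]
      for (k in seq_len(n_arr)) {
        aid <- aid + 1L
        n_mono <- lens[k]
        divs <- draw_mixture(sp$divergence_mixture, n_mono, sp$divergence_cap)
        rot <- sample.int(L, 1L) - 1L
        rot_cons <- rotate_seq(fam$consensus, rot)
        monomers <- mutate_many(rot_cons, divs, sp$kappa)
        arr_seq <- paste(monomers, collapse = "")
        strand <- sample(c("+", "-"), 1L)
        cass <- sp$flank_cassette
        block <- if (is.null(cass)) arr_seq else paste0(cass, arr_seq, cass)
        if (strand == "-") block <- revcomp(block)
        chrom <- chroms[k]
        pos <- place_block(occupied[[chrom]], chrom_lengths[[chrom]],
                           nchar(block), min_gap,
                           terminal = sp$placement_mode == "terminal_blocks")
        if (is.na(pos)) {
          stop(sprintf("placement overflow: cannot place array %d of %s (%d bp) on %s",
                       k, fam$family_id, nchar(block), chrom))
        }
        occupied[[chrom]] <- rbind(occupied[[chrom]],
                                   data.frame(start = pos, end = pos + nchar(block)))
        substr(genome[[chrom]], pos + 1L, pos + nchar(block)) <- block
        cass_len <- if (is.null(cass)) 0L else nchar(cass)
        arr_start <- pos + cass_len
        arr_end <- arr_start + n_mono * L
        starts <- arr_start + (seq_len(n_mono) - 1L) * L
        mono_idx <- if (strand == "+") seq_len(n_mono) else rev(seq_len(n_mono))
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = chrom, start = starts, end = starts + L,
          strand = strand, family_id = fam$family_id,
          divergence = divs[mono_idx], rotation = rot,
          array_id = aid, stringsAsFactors = FALSE)
        arrays[[length(arrays) + 1L]] <- data.frame(
          seq_id = chrom, start = arr_start, end = arr_end, strand = strand,
          family_id = fam$family_id, n_monomers = n_mono, array_id = aid,
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
    arrays <- do.call(rbind, c(arrays, list(make.row.names = FALSE)))
    truth <- truth[order(truth$seq_id, truth$start), ]
    rownames(truth) <- NULL
    structure(list(genome = genome, truth = truth, arrays = arrays,
                   specs = specs, seed = seed),
              class = "sat_genome_sim")
  })
}

placement_chromosomes <- function(sp, chrom_names) {
  n_arr <- sp$n_arrays
  pool <- if (is.null(sp$chromosome)) chrom_names else sp$chromosome
  if (!all(pool %in% chrom_names)) {
    stop("unknown chromosome in spec: ",
         paste(setdiff(pool, chrom_names), collapse = ", "))
  }
  switch(sp$placement_mode,
    interspersed = {
      # round-robin over a shuffled chromosome list: guarantees coverage of
      # min(n_arrays, n_chrom) chromosomes with no terminal bias
      rep(sample(pool), length.out = n_arr)
    },
    terminal_blocks = {
      k <- min(length(pool), max(3L, ceiling(n_arr / 2)))
      rep(sample(pool, k), length.out = n_arr)
    },
    single_block = ,
    restricted_chromosome = {
      chrom <- if (length(pool) == 1L) pool else sample(pool, 1L)
      rep(chrom, n_arr)
    })
}

place_block <- function(occ, chrom_len, block_len, min_gap, terminal = FALSE,
                        max_tries = 200L) {
  if (block_len > chrom_len) return(NA_integer_)
  for (i in seq_len(max_tries)) {
    pos <- if (terminal) {
      # 4% end window: inside the 5% band the organisation classifier uses
      window <- max(1L, floor(0.04 * chrom_len))
      if (runif(1) < 0.5) {
        sample.int(min(window, max(1L, chrom_len - block_len)), 1L) - 1L
      } else {
        max(0L, chrom_len - block_len - (sample.int(window, 1L) - 1L))
      }
    } else {
      sample.int(chrom_len - block_len + 1L, 1L) - 1L
    }
    lo <- pos - min_gap
    hi <- pos + block_len + min_gap
    if (!nrow(occ) || all(occ$end <= lo | occ$start >= hi)) return(pos)
  }
  NA_integer_
}

#' @export
print.sat_genome_sim <- function(x, ...) {
  cat(sprintf("simulated genome: %d chromosome(s), %d planted monomers in %d arrays\n",
              length(x$genome), nrow(x$truth), nrow(x$arrays)))
  invisible(x)
}

#' Write a simulated genome and its truth tables to a directory
#'
#' @param sim A \code{"sat_genome_sim"}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_genome_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fasta"))
  write_bed(sim$truth, file.path(dir, "truth_monomers.bed"))
  write.table(sim$truth, file.path(dir, "truth_monomers.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$arrays, file.path(dir, "truth_arrays.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
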