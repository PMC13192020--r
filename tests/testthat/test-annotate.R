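test_that("a perfect head-to-tail array yields one exact hit per monomer", {
  cons <- random_consensus(60, seed = 201)
  fam <- sat_family("F1", cons)
  genome <- c(chr1 = strrep(cons, 5))
  hits <- find_monomers(genome, fam, 0.45)
  expect_identical(nrow(hits), 5L)
  expect_true(all(hits$divergence == 0))
  expect_true(all(hits$rotation == 0))
  expect_true(all(hits$strand == "+"))
  expect_identical(hits$start, (0:4) * 60L)
})

test_that("embedded perfect arrays keep exact divergence up to boundary ambiguity", {
  # a background base that happens to continue the periodic pattern makes the
  # boundary genuinely unidentifiable, so starts may jitter by a few bases;
  # divergence 0 and the monomer count must survive regardless
  cons <- random_consensus(60, seed = 201)
  fam <- sat_family("F1", cons)
  genome <- c(chr1 = paste0(random_consensus(500), strrep(cons, 5), random_consensus(500)))
  hits <- find_monomers(genome, fam, 0.45)
  expect_identical(nrow(hits), 5L)
  expect_true(all(hits$divergence == 0))
  expect_true(all(abs(hits$start - (500L + (0:4) * 60L)) <= 3L))
  expect_true(all(hits$rotation %in% c(0L, (60L - (1:3)), 1:3)))
})

test_that("reverse-complemented arrays are found on the minus strand", {
  cons <- random_consensus(60, seed = 202)
  fam <- sat_family("F1", cons)
  genome <- c(chr1 = paste0(random_consensus(300), revcomp_str(strrep(cons, 3)),
                            random_consensus(300)))
  hits <- find_monomers(genome, fam, 0.45)
  expect_identical(nrow(hits), 3L)
  expect_true(all(hits$strand == "-"))
  expect_true(all(hits$divergence == 0))
  expect_identical(min(hits$start), 300L)
})

test_that("segments beyond the divergence ceiling are not reported", {
  cons <- random_consensus(100, seed = 203)
  fam <- sat_family("F1", cons)
  # plant a copy with exactly 60% of positions substituted
  set.seed(7)
  cv <- strsplit(cons, "")[[1]]
  idx <- sample(100, 60)
  cv[idx] <- vapply(cv[idx], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  genome <- c(chr1 = paste0(random_consensus(200), paste(cv, collapse = ""),
                            random_consensus(200)))
  expect_identical(nrow(find_monomers(genome, fam, 0.45)), 0L)
  # but a 30%-substituted copy is reported
  cv2 <- strsplit(cons, "")[[1]]
  idx2 <- sample(100, 30)
  cv2[idx2] <- vapply(cv2[idx2], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  genome2 <- c(chr1 = paste0(random_consensus(200), paste(cv2, collapse = ""),
                             random_consensus(200)))
  h <- find_monomers(genome2, fam, 0.45)
  expect_identical(nrow(h), 1L)
  expect_equal(h$divergence, 0.30)
})

test_that("empty and invalid inputs are rejected cleanly", {
  fam <- sat_family("F1", random_consensus(40, seed = 204))
  expect_warning(h <- find_monomers(character(0), fam), "empty genome")
  expect_identical(nrow(h), 0L)
  expect_error(find_monomers(c(chr1 = "ACGT"), sat_family("S", "ACGTACGTACGTACGT")),
               "shorter than 20")
})

test_that("annotation matches the exhaustive alignment oracle on small genomes", {
  cons <- random_consensus(25, seed = 205)
  fam <- sat_family("F1", cons)
  spec <- family_sim_spec(fam, "interspersed", n_arrays = 5,
                          array_length_range = c(1, 3),
                          divergence_mixture = data.frame(weight = 1, mean = 0.15, sd = 0.03))
  sim <- simulate_genome(list(spec), c(chr1 = 1500, chr2 = 1200), seed = 51,
                         min_gap = 60)
  hits <- find_monomers(sim$genome, fam, 0.45)
  oracle <- annotation_oracle(sim$genome, cons, 0.45)
  # every reported hit is a qualifying window with the oracle's divergence
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    m <- oracle[oracle$seq_id == h$seq_id & oracle$start == h$start &
                  oracle$strand == h$strand & oracle$rotation == h$rotation, ]
    expect_identical(nrow(m), 1L)
    expect_equal(h$divergence, m$divergence)
  }
  # nothing the oracle can align was missed entirely
  for (i in seq_len(nrow(oracle))) {
    o <- oracle[i, ]
    expect_true(any(hits$seq_id == o$seq_id &
                      hits$start < o$end & hits$end > o$start),
                label = sprintf("oracle window %s:%d covered", o$seq_id, o$start))
  }
})

test_that("annotating the reverse-complemented genome mirrors coordinates", {
  cons <- random_consensus(60, seed = 206)
  fam <- sat_family("F1", cons)
  spec <- family_sim_spec(fam, "interspersed", n_arrays = 4,
                          array_length_range = c(1, 3),
                          divergence_mixture = data.frame(weight = 1, mean = 0.08, sd = 0.01))
  sim <- simulate_genome(list(spec), c(chr1 = 4000), seed = 52, min_gap = 100)
  hits <- find_monomers(sim$genome, fam, 0.45)
  G <- nchar(sim$genome[["chr1"]])
  rc <- c(chr1 = revcomp_str(sim$genome[["chr1"]]))
  hits_rc <- find_monomers(rc, fam, 0.45)
  expect_identical(nrow(hits_rc), nrow(hits))
  # mirror-image coordinates with flipped strands, up to the few-bp boundary
  # ambiguity of periodic arrays (tie-breaks are orientation-dependent)
  flip <- c("+" = "-", "-" = "+")
  mirrored <- data.frame(start = sort(G - hits_rc$end))
  expect_true(all(abs(mirrored$start - sort(hits$start)) <= 3L))
  expect_identical(sum(hits_rc$strand == "-"), sum(hits$strand == "+"))
})

test_that("rotating the consensus shifts rotations but not spans", {
  cons <- random_consensus(30, seed = 207)
  spec <- family_sim_spec(sat_family("F1", cons), "interspersed", n_arrays = 4,
                          array_length_range = c(2, 4),
                          divergence_mixture = data.frame(weight = 1, mean = 0.05, sd = 0.01))
  sim <- simulate_genome(list(spec), c(chr1 = 5000), seed = 53, min_gap = 100)
  hits <- find_monomers(sim$genome, sat_family("F1", cons), 0.45)
  k <- 7L
  hits_rot <- find_monomers(sim$genome, sat_family("F1", rotate_str(cons, k)), 0.45)
  expect_identical(nrow(hits_rot), nrow(hits))
  # hit spans agree within one-monomer boundary jitter at array edges
  span <- function(h) tapply(h$start, h$seq_id, min)
  expect_true(all(abs(sort(hits_rot$start) - sort(hits$start)) <= 30L))
  # rotations shift by -k (mod L): same genomic window starts k bases later
  # into the rotated consensus
  m <- merge(hits, hits_rot, by = c("seq_id", "start"))
  expect_true(all((m$rotation.x - m$rotation.y) %% 30L == k))
})

test_that("planted monomers are recovered with high recall and precision", {
  cons <- random_consensus(142, seed = 208)
  fam <- sat_family("F1", cons)
  spec <- family_sim_spec(fam, "interspersed", n_arrays = 40,
                          array_length_range = c(1, 8),
                          divergence_mixture = data.frame(
                            weight = c(0.6, 0.4), mean = c(0.05, 0.25), sd = c(0.02, 0.03)))
  sim <- simulate_genome(list(spec), setNames(rep(60000, 5), paste0("chr", 1:5)),
                         seed = 54)
  hits <- find_monomers(sim$genome, fam, 0.45)
  m <- match_truth(hits, sim$truth)
  expect_gte(m$recall, 0.995)
  expect_gte(m$precision, 0.995)
  # measured (alignment) divergence sits just below the K2P targets in the
  # mean: the raw mismatch fraction is the uncorrected distance
  expect_lt(mean(hits$divergence), mean(sim$truth$divergence))
  expect_lt(abs(mean(hits$divergence) - mean(sim$truth$divergence)), 0.03)
})

test_that("hits of one family never overlap", {
  cons <- random_consensus(60, seed = 209)
  fam <- sat_family("F1", cons)
  spec <- family_sim_spec(fam, "restricted_chromosome", n_arrays = 10,
                          array_length_range = c(1, 6),
                          divergence_mixture = data.frame(weight = 1, mean = 0.2, sd = 0.05))
  sim <- simulate_genome(list(spec), c(chr1 = 30000), seed = 55, min_gap = 150)
  hits <- find_monomers(sim$genome, fam, 0.45)
  h <- hits[order(hits$start), ]
  expect_true(all(h$start[-1] >= h$end[-nrow(h)]))
})

test_that("arrays merge by gap tolerance and conserve monomer counts", {
  hits <- data.frame(
    seq_id = "chr1", start = c(0L, 40L, 80L, 120L, 160L, 10200L, 10260L),
    end = c(40L, 80L, 120L, 160L, 200L, 10240L, 10300L),
    strand = "+", family_id = "F1", divergence = 0,
    rotation = 0L, aligned_length = 40L)
  arr <- build_arrays(hits, gap_tolerance = 40L)
  expect_identical(nrow(arr), 2L)
  expect_identical(arr$n_monomers, c(5L, 2L))
  expect_identical(sum(arr$n_monomers), nrow(hits))
  # 10 kb separation always splits with tolerance of one monomer
  arr2 <- build_arrays(hits)
  expect_identical(nrow(arr2), 2L)
  # strand changes always split
  hits$strand[2] <- "-"
  arr3 <- build_arrays(hits, gap_tolerance = 40L)
  expect_identical(nrow(arr3), 4L)
  expect_identical(sum(arr3$n_monomers), nrow(hits))
})

test_that("planted array counts are reconstructed exactly", {
  cons <- random_consensus(142, seed = 210)
  fam <- sat_family("F1", cons)
  spec <- family_sim_spec(fam, "restricted_chromosome", n_arrays = 12,
                          array_length_range = c(2, 9),
                          divergence_mixture = data.frame(weight = 1, mean = 0.08, sd = 0.02))
  sim <- simulate_genome(list(spec), c(chrY = 80000), seed = 56)
  ann <- annotate_genome(sim$genome, list(fam), sat_config())
  expect_identical(nrow(ann$arrays), 12L)
  expect_identical(sum(ann$arrays$n_monomers), nrow(sim$truth))
})

test_that("satellitome summaries report counts, presence and genome fraction", {
  empty <- summarize_satellitome(satkit:::empty_hits(), c(chr1 = 1000),
                                 families = list(sat_family("F1", random_consensus(30))))
  expect_identical(empty$table$n_monomers, 0L)
  expect_identical(empty$table$genome_fraction, 0)

  hits <- data.frame(seq_id = "chr1", start = (0:4) * 142L, end = (1:5) * 142L,
                     strand = "+", family_id = "F1", divergence = 0,
                     rotation = 0L, aligned_length = 142L)
  s <- summarize_satellitome(hits, c(chr1 = 100000))
  expect_equal(s$table$genome_fraction, 710 / 100000)
  expect_identical(s$table$n_monomers, 5L)
  expect_true(s$presence["F1", "chr1"])

  hits2 <- rbind(hits, within(hits[1, ], seq_id <- "scaffold_12"))
  s2 <- summarize_satellitome(hits2, c(chr1 = 100000, scaffold_12 = 5000))
  expect_identical(s2$table$n_unplaced_monomers, 1L)
  expect_identical(s2$table$n_chromosomes, 1L)
})
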