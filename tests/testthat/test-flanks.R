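test_that("flank coordinates follow the worked example", {
  genome <- c(chr1 = random_consensus(10000, seed = 301))
  arrays <- data.frame(seq_id = "chr1", start = 5000L, end = 5710L,
                       strand = "+", family_id = "F1", n_monomers = 5L,
                       array_id = 1L)
  fl <- extract_flanks(arrays, genome, 1000L)
  up <- fl[fl$side == "upstream", ]
  down <- fl[fl$side == "downstream", ]
  expect_identical(up$seq, substr(genome[["chr1"]], 4001, 5000))
  expect_identical(down$seq, substr(genome[["chr1"]], 5711, 6710))
  expect_false(any(fl$truncated))
})

test_that("minus-strand arrays swap and reverse-complement their flanks", {
  genome <- c(chr1 = random_consensus(10000, seed = 302))
  plus <- data.frame(seq_id = "chr1", start = 5000L, end = 5710L, strand = "+",
                     family_id = "F1", n_monomers = 5L, array_id = 1L)
  minus <- within(plus, strand <- "-")
  fp <- extract_flanks(plus, genome, 1000L)
  fm <- extract_flanks(minus, genome, 1000L)
  expect_identical(fm$seq[fm$side == "upstream"],
                   revcomp_str(fp$seq[fp$side == "downstream"]))
  expect_identical(fm$seq[fm$side == "downstream"],
                   revcomp_str(fp$seq[fp$side == "upstream"]))
})

test_that("contig edges truncate flanks with a flag", {
  genome <- c(chr1 = random_consensus(2000, seed = 303))
  arrays <- data.frame(seq_id = "chr1", start = c(0L, 1800L), end = c(200L, 2000L),
                       strand = "+", family_id = "F1", n_monomers = 1L,
                       array_id = 1:2)
  fl <- extract_flanks(arrays, genome, 1000L)
  up1 <- fl[fl$array_id == 1 & fl$side == "upstream", ]
  expect_identical(up1$length, 0L)
  expect_true(up1$truncated)
  down2 <- fl[fl$array_id == 2 & fl$side == "downstream", ]
  expect_identical(down2$length, 0L)
  expect_true(down2$truncated)
})

test_that("planted cassettes make all flanks identical across arrays", {
  cons <- random_consensus(120, seed = 304)
  cassette <- random_consensus(1500, seed = 305)
  fam <- sat_family("F1", cons)
  spec <- family_sim_spec(fam, "restricted_chromosome", n_arrays = 12,
                          array_length_range = c(2, 9),
                          divergence_mixture = data.frame(weight = 1, mean = 0.02, sd = 0.01),
                          flank_cassette = cassette)
  sim <- simulate_genome(list(spec), c(chrY = 150000), seed = 57, min_gap = 800)
  # at truth coordinates all 24 flanks are byte-identical cassette slices
  fl <- extract_flanks(sim$arrays, sim$genome, 1000L)
  expect_identical(nrow(fl), 24L)
  for (side in c("upstream", "downstream")) {
    seqs <- fl$seq[fl$side == side]
    expect_identical(length(unique(seqs)), 1L)
    expect_identical(nchar(seqs[1]), 1000L)
  }
  # the upstream flank is the cassette tail
  expect_identical(fl$seq[fl$side == "upstream"][1], substr(cassette, 501, 1500))
  # annotation-derived flanks may jitter by a few bases at the array
  # boundary but stay essentially identical across arrays
  ann <- annotate_genome(sim$genome, list(fam), sat_config())
  expect_identical(nrow(ann$arrays), 12L)
  fl2 <- extract_flanks(ann$arrays, sim$genome, 1000L)
  prof <- conservation_profile(fl2[fl2$side == "upstream", ])
  expect_gte(prof$conserved_block_length, 950L)
})

test_that("identical flanks give a full-length conserved block, no outliers", {
  cassette <- random_consensus(1000, seed = 306)
  fs <- data.frame(family_id = "F1", array_id = 1:5, seq_id = "chr1",
                   array_start = (1:5) * 3000L, side = "downstream",
                   seq = cassette, length = 1000L, truncated = FALSE)
  prof <- conservation_profile(fs)
  expect_identical(prof$conserved_block_length, 1000L)
  expect_identical(nrow(prof$outliers), 0L)
  expect_true(all(prof$position_fraction == 1))
  expect_error(conservation_profile(fs[1, ]), "fewer than 2")
})

test_that("a planted insertion is reported as an insertion outlier", {
  cassette <- random_consensus(1000, seed = 307)
  # a 430-bp insertion after 300 bp pushes the cassette tail out of the
  # extracted 1000-bp window
  with_ins <- substr(paste0(substr(cassette, 1, 300),
                            random_consensus(430, seed = 308),
                            substr(cassette, 301, 1000)), 1, 1000)
  fs <- data.frame(family_id = "F1", array_id = 1:6, seq_id = "chr1",
                   array_start = (1:6) * 3000L, side = "downstream",
                   seq = c(rep(cassette, 5), with_ins),
                   length = 1000L, truncated = FALSE)
  prof <- conservation_profile(fs)
  expect_false(prof$reference == 6L)   # the aberrant member is not the yardstick
  expect_identical(prof$outliers$array_id, 6L)
  expect_identical(prof$outliers$reason, "insertion")
  # the other members keep the block conserved
  expect_gte(prof$conserved_block_length, 900L)
})

test_that("conservation breaks where similarity ends", {
  head_part <- random_consensus(600, seed = 309)
  fs <- data.frame(family_id = "F1", array_id = 1:4, seq_id = "chr1",
                   array_start = (1:4) * 3000L, side = "downstream",
                   seq = vapply(1:4, function(i)
                     paste0(head_part, random_consensus(400)), ""),
                   length = 1000L, truncated = FALSE)
  set.seed(310)
  prof <- conservation_profile(fs, window = 100L)
  expect_gte(prof$conserved_block_length, 500L)
  expect_lte(prof$conserved_block_length, 700L)
})

test_that("conserved block length is monotone in its thresholds", {
  head_part <- random_consensus(700, seed = 311)
  set.seed(312)
  noisy <- function(s, p) {
    v <- strsplit(s, "")[[1]]
    idx <- which(runif(length(v)) < p)
    v[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
    paste(v, collapse = "")
  }
  fs <- data.frame(family_id = "F1", array_id = 1:5, seq_id = "chr1",
                   array_start = (1:5) * 3000L, side = "downstream",
                   seq = c(head_part,
                           vapply(c(0.01, 0.02, 0.05, 0.1), function(p)
                             noisy(head_part, p), "")),
                   length = 700L, truncated = FALSE)
  b1 <- conservation_profile(fs, identity_threshold = 0.90)$conserved_block_length
  b2 <- conservation_profile(fs, identity_threshold = 0.97)$conserved_block_length
  expect_lte(b2, b1)
  b3 <- conservation_profile(fs, member_fraction = 0.5)$conserved_block_length
  b4 <- conservation_profile(fs, member_fraction = 0.9)$conserved_block_length
  expect_lte(b4, b3)
})

test_that("profiles are invariant to member input order", {
  cassette <- random_consensus(800, seed = 313)
  set.seed(314)
  members <- vapply(1:5, function(i) {
    v <- strsplit(cassette, "")[[1]]
    idx <- sample(800, 8)
    v[idx] <- sample(c("A", "C", "G", "T"), 8, replace = TRUE)
    paste(v, collapse = "")
  }, "")
  fs <- data.frame(family_id = "F1", array_id = 1:5, seq_id = "chr1",
                   array_start = (1:5) * 3000L, side = "downstream",
                   seq = members, length = 800L, truncated = FALSE)
  p1 <- conservation_profile(fs)
  p2 <- conservation_profile(fs[c(4, 2, 5, 1, 3), ])
  expect_identical(p1$conserved_block_length, p2$conserved_block_length)
  expect_identical(p1$reference, p2$reference)
  expect_equal(p1$position_fraction, p2$position_fraction)
})

test_that("unrelated cassettes from two families share no conserved block", {
  c1 <- random_consensus(1000, seed = 315)
  c2 <- random_consensus(1000, seed = 316)
  fs <- data.frame(family_id = "mix", array_id = 1:4, seq_id = "chr1",
                   array_start = (1:4) * 3000L, side = "downstream",
                   seq = c(c1, c1, c2, c2), length = 1000L, truncated = FALSE)
  prof <- conservation_profile(fs, member_fraction = 0.9)
  expect_lt(prof$conserved_block_length, 100L)
})
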