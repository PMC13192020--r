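test_that("dimer references double the consensus", {
  fam <- sat_family("F1", "ACGTACGTACGTACGTACGTACGT")
  dr <- dimer_reference(fam)
  expect_identical(dr$length, 48L)
  expect_identical(dr$dimer, strrep(fam$consensus, 2))
})

test_that("exact substrings and junction-spanning reads are counted", {
  cons <- random_consensus(142, seed = 401)
  fam <- sat_family("F1", cons)
  dimer <- strrep(cons, 2)
  exact <- substr(dimer, 20, 119)                      # 100 bp inside
  junction <- substr(dimer, 142 - 29, 142 - 30 + 100)  # spans monomer junction
  two_mm <- exact
  substr(two_mm, 10, 10) <- "N"; substr(two_mm, 50, 50) <- "N"
  counts <- count_matching_reads(c(exact, junction, revcomp_str(exact), two_mm),
                                 list(fam), mismatch_limit = 1)
  expect_identical(unname(counts), 3L)
  # the junction read is NOT a substring of the monomer itself: the dimer is
  # what rescues it
  expect_false(grepl(junction, cons, fixed = TRUE))
  # brute-force confirmation
  expect_identical(unname(read_count_oracle(c(exact, junction, two_mm), dimer, 1)),
                   c(TRUE, TRUE, FALSE))
})

test_that("counting matches the brute-force oracle on random read sets", {
  set.seed(402)
  cons <- random_consensus(150)
  fam <- sat_family("F1", cons)
  dimer <- strrep(cons, 2)
  reads <- character(50)
  for (i in 1:50) {
    kind <- sample(3, 1)
    if (kind == 1) {                      # planted, light damage
      s <- sample(nchar(dimer) - 80, 1)
      rd <- substr(dimer, s, s + 79)
      v <- strsplit(rd, "")[[1]]
      nmm <- sample(0:2, 1)
      if (nmm > 0) {
        idx <- sample(80, nmm)
        v[idx] <- vapply(v[idx], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
      }
      reads[i] <- paste(v, collapse = "")
    } else if (kind == 2) {               # planted, minus strand
      s <- sample(nchar(dimer) - 80, 1)
      reads[i] <- revcomp_str(substr(dimer, s, s + 79))
    } else {
      reads[i] <- random_consensus(80)    # background
    }
  }
  want <- read_count_oracle(reads, dimer, 1)
  got <- count_matching_reads(reads, list(fam), mismatch_limit = 1)
  expect_identical(unname(got), sum(want))
  # and per-read agreement through the internal matcher
  per_read <- satkit:::.read_matches_cpp(reads, dimer, revcomp_str(dimer), 1L)
  expect_identical(per_read, unname(want))
})

test_that("paired fragments count once if either mate matches", {
  cons <- random_consensus(100, seed = 403)
  fam <- sat_family("F1", cons)
  dimer <- strrep(cons, 2)
  m1 <- c(substr(dimer, 1, 60), random_consensus(60), random_consensus(60))
  m2 <- c(random_consensus(60), substr(dimer, 50, 109), random_consensus(60))
  counts <- count_matching_reads(m1, list(fam), 1, reads2 = m2)
  expect_identical(unname(counts), 2L)
})

test_that("reads longer than the dimer are skipped", {
  fam <- sat_family("F1", random_consensus(30, seed = 404))
  long_read <- strrep(fam$consensus, 3)
  expect_identical(unname(count_matching_reads(long_read, list(fam), 1)), 0L)
})

test_that("FPKM follows its closed form", {
  expect_identical(fpkm(0, 284, 1e7), 0)
  expect_equal(fpkm(1000, 284, 1e7), 352.1127, tolerance = 1e-4)
  expect_equal(fpkm(1000, 284, 2e7), fpkm(1000, 284, 1e7) / 2)
  expect_error(fpkm(10, 284, 0), "empty library")
})

test_that("expression profiles aggregate replicates with sd", {
  rec <- data.frame(family_id = "F1", library_id = c("a", "b", "c"),
                    stage = c("egg", "egg", "late_pupa"), sex = "unknown",
                    count = c(10L, 20L, 5L), N = 1000,
                    fpkm = c(10, 20, 5))
  prof <- expression_profile(rec)
  egg <- prof[prof$stage == "egg", ]
  expect_equal(egg$mean_fpkm, 15)
  expect_equal(egg$sd_fpkm, sd(c(10, 20)))
  expect_identical(egg$n_replicates, 2L)
  single <- prof[prof$stage == "late_pupa", ]
  expect_true(is.na(single$sd_fpkm))
  # low-depth libraries are excluded
  rec$N[3] <- 10
  prof2 <- expression_profile(rec, min_depth = 100)
  expect_false("late_pupa" %in% prof2$stage)
})

test_that("simulated error-free reads are recovered exactly and the planted peak stage wins", {
  cons <- random_consensus(142, seed = 405)
  fam <- sat_family("F1", cons)
  stages <- c("egg", "late_larva", "late_pupa", "early_adult")
  meta <- data.frame(library_id = paste0("lib", 1:8),
                     stage = rep(stages, each = 2),
                     sex = rep(c("F", "M"), 4))
  expr <- matrix(100L, nrow = 1, ncol = 8,
                 dimnames = list("F1", meta$library_id))
  expr[1, meta$stage == "late_pupa" & meta$sex == "M"] <- 500L
  sim <- simulate_reads(list(fam), expr, meta, read_length = 100,
                        n_background = 300, error_rate = 0, seed = 71)
  rec <- quantify_expression(sim$read_sets, list(fam), meta)
  expect_identical(rec$count, unname(expr[1, rec$library_id]))
  am <- expression_argmax(expression_profile(rec))
  expect_identical(am$stage, "late_pupa")
  expect_identical(am$sex, "M")
})

test_that("read simulation is deterministic and refuses over-long reads", {
  cons <- random_consensus(80, seed = 406)
  fam <- sat_family("F1", cons)
  meta <- data.frame(library_id = "lib1", stage = "egg", sex = "unknown")
  expr <- matrix(50L, 1, 1, dimnames = list("F1", "lib1"))
  s1 <- simulate_reads(list(fam), expr, meta, read_length = 60, seed = 8)
  s2 <- simulate_reads(list(fam), expr, meta, read_length = 60, seed = 8)
  expect_identical(s1$read_sets, s2$read_sets)
  expect_error(simulate_reads(list(fam), expr, meta, read_length = 160),
               "shorter than the shortest dimer")
})

test_that("sequencing errors lose reads at the binomial two-error rate", {
  cons <- random_consensus(142, seed = 407)
  fam <- sat_family("F1", cons)
  meta <- data.frame(library_id = "lib1", stage = "egg", sex = "unknown")
  n <- 6000L
  expr <- matrix(n, 1, 1, dimnames = list("F1", "lib1"))
  p <- 0.002
  rl <- 100
  sim <- simulate_reads(list(fam), expr, meta, read_length = rl,
                        n_background = 0, error_rate = p, seed = 72)
  counts <- count_matching_reads(sim$read_sets$lib1, list(fam), 1)
  # P(>= 2 errors) = 1 - (1-p)^rl - rl p (1-p)^(rl-1); losses within 3 SE
  loss_expected <- 1 - (1 - p)^rl - rl * p * (1 - p)^(rl - 1)
  se <- sqrt(loss_expected * (1 - loss_expected) / n)
  observed_loss <- (n - counts[["F1"]]) / n
  expect_lt(abs(observed_loss - loss_expected), 3 * se + 1e-9)
})
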