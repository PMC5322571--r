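spec <- default_library_spec()
pol <- trim_policy_from_spec(spec)

test_that("read_fastq handles empty, valid, and malformed files", {
  f <- tempfile(fileext = ".fastq")
  file.create(f)
  expect_equal(nrow(read_fastq(f)), 0)

  writeLines(c("@r1", "ACGTN", "+", "IIIII"), f)
  recs <- read_fastq(f)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$bases, "ACGTN")  # N preserved

  writeLines(c("@r1", "ACGT", "+", "III"), f)  # ragged quality
  expect_error(read_fastq(f), "line")
  writeLines(c("r1", "ACGT", "+", "IIII"), f)  # missing @ header
  expect_error(read_fastq(f), "line 1")
  expect_error(read_fastq(tempfile()), "no such file")
})

test_that("anchored flank trimming returns the interior or rejects", {
  x25 <- strrep("A", 25)
  read <- paste0(spec$forward_primer, x25, spec$reverse_tail)
  expect_equal(trim_flanks(read, pol), x25)

  # one substitution in the forward flank, within max_mismatches = 2;
  # Hamming oracle: exactly 1 mismatch at position 1
  read1 <- paste0("T", substr(spec$forward_primer, 2, 20), x25,
                  spec$reverse_tail)
  expect_equal(trim_flanks(read1, pol), x25)
  # three substitutions exceed the tolerance
  read3 <- paste0("TTT", substr(spec$forward_primer, 4, 20), x25,
                  spec$reverse_tail)
  expect_true(is.na(trim_flanks(read3, pol)))

  # a 40-mer of random bases matches no flank
  set.seed(1)
  expect_true(is.na(trim_flanks(rnd_dna(40), pol)))
  # shorter than the two flanks combined: rejection, not error
  expect_true(is.na(trim_flanks("ACGT", pol)))

  # reverse-complement retry recovers flipped reads
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  expect_equal(trim_flanks(rc, pol), x25)
  pol_norc <- trim_policy(spec$forward_primer, spec$reverse_tail,
                          try_reverse_complement = FALSE)
  expect_true(is.na(trim_flanks(rc, pol_norc)))
})

test_that("re-attaching flanks to a trimmed read stays within the mismatch bound", {
  set.seed(42)
  for (i in 1:20) {
    region <- rnd_dna(25)
    fp <- mutate_dna(spec$forward_primer, sample(0:2, 1))
    rt <- mutate_dna(spec$reverse_tail, sample(0:2, 1))
    read <- paste0(fp, region, rt)
    out <- trim_flanks(read, pol)
    expect_equal(out, region)
    rebuilt <- paste0(spec$forward_primer, out, spec$reverse_tail)
    d <- sum(strsplit(rebuilt, "")[[1]] != strsplit(read, "")[[1]])
    expect_lte(d, 2 * pol$max_mismatches)
  }
})

test_that("length filter keeps 25 +/- 2 and drops everything else", {
  lens <- 22:28
  expect_equal(length_filter(strrep("A", lens)),
               c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  # window is configurable
  expect_true(length_filter("ACGTA", center = 5, tol = 0))
  expect_false(length_filter("ACGTAA", center = 5, tol = 0))
})

test_that("count_and_rank produces order-invariant, conservative tables", {
  p <- count_and_rank(c("AAA", "AAA", "CCC"), "toy")
  expect_equal(p$counts, c(AAA = 2L, CCC = 1L))
  expect_equal(names(p$counts)[1], "AAA")  # rank 1 = most abundant
  expect_equal(p$total_reads, 3L)

  expect_equal(count_and_rank(character(0))$total_reads, 0L)

  set.seed(3)
  seqs <- sample(rep(c("GG", "TT", "AA", "CC"), c(5, 3, 3, 1)))
  p1 <- count_and_rank(seqs)
  p2 <- count_and_rank(rev(seqs))
  expect_identical(p1$counts, p2$counts)
  # ties broken lexicographically: AA before TT at count 3
  expect_equal(names(p1$counts), c("GG", "AA", "TT", "CC"))
})

test_that("duplication percentage matches hand-computed values and properties", {
  expect_equal(duplication_percent(count_and_rank(c("A", "B", "C"))), 0)
  expect_equal(duplication_percent(count_and_rank(c("A", "A", "B", "C"))), 25)
  expect_equal(duplication_percent(count_and_rank(rep("A", 4))), 75)
  expect_error(duplication_percent(count_and_rank(character(0))), "empty")

  # reorder invariance and strict increase when a count goes beyond 1
  set.seed(8)
  seqs <- replicate(30, rnd_dna(6))
  d1 <- duplication_percent(count_and_rank(seqs))
  d2 <- duplication_percent(count_and_rank(sample(seqs)))
  expect_equal(d1, d2)
  d3 <- duplication_percent(count_and_rank(c(seqs, seqs[1])))
  expect_gt(d3, d1)
})

test_that("prep_round round-trips simulated FASTQ and tallies rejections", {
  sp <- tiny_spec()
  tp <- trim_policy_from_spec(sp)
  pool <- generate_library(sp, 400, seed = 21)
  f <- tempfile(fileext = ".fastq")
  write_round_fastq(pool, f, seed = 21)
  got <- prep_round(f, tp, "R0", center = sp$random_len, tol = 2)
  regions <- substr(names(pool$counts), 11, nchar(names(pool$counts)) - 10)
  want <- count_and_rank(rep(regions, pool$counts), "R0")
  expect_identical(got$counts, want$counts)
  expect_equal(got$n_rejected_primer + got$n_rejected_length, 0L)

  # N in the random region -> primer rejection; bad length -> length rejection
  reads <- c(paste0(sp$forward_primer, strrep("A", 8), sp$reverse_tail),
             paste0(sp$forward_primer, "ACGTNCGT", sp$reverse_tail),
             paste0(sp$forward_primer, strrep("A", 20), sp$reverse_tail),
             rnd_dna(28))
  p <- prep_round(reads, tp, "mix", center = 8, tol = 2)
  expect_equal(p$total_reads, 1L)
  expect_equal(p$n_rejected_primer, 2L)  # N-region + unmatched flanks
  expect_equal(p$n_rejected_length, 1L)
  expect_equal(p$total_reads + p$n_rejected_primer + p$n_rejected_length,
               length(reads))
})
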