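test_that("identity follows the CD-HIT convention", {
  s <- strrep("ACGTA", 13)  # a 65-mer
  expect_equal(seq_identity(s, s), 1)

  # 65-mers differing at exactly 13 scattered positions, no indels:
  # Hamming oracle gives 52/65 = 0.8
  set.seed(5)
  s2 <- mutate_dna(s, 13)
  d <- sum(strsplit(s, "")[[1]] != strsplit(s2, "")[[1]])
  expect_equal(d, 13)
  expect_equal(seq_identity(s, s2), 52 / 65)

  # denominator is the shorter sequence: a contained subsequence scores 1
  expect_equal(seq_identity("ACGTACGT", "ACGTACG"), 1)

  # symmetry on random pairs
  set.seed(6)
  for (i in 1:10) {
    a <- rnd_dna(sample(15:30, 1))
    b <- rnd_dna(sample(15:30, 1))
    expect_equal(seq_identity(a, b), seq_identity(b, a))
  }
})

test_that("alignment scores agree with an independent Needleman-Wunsch oracle", {
  # the best-alignment score (matches - gaps) must match the DP oracle;
  # identity equals max_matches/min_len whenever the optimum is unambiguous
  set.seed(12)
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(1, 0, baseOnly = TRUE)
  for (i in 1:25) {
    a <- rnd_dna(sample(8:20, 1))
    b <- if (i %% 2) mutate_dna(a, sample(0:3, 1)) else rnd_dna(sample(8:20, 1))
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = sub_mat, gapOpening = 0, gapExtension = 1)
    oracle <- nw_align_oracle(a, b, gap = 1)
    expect_equal(Biostrings::score(aln), oracle$score)
    expect_lte(round(seq_identity(a, b) * min(nchar(a), nchar(b))),
               oracle$max_matches)
  }
})

test_that("attach_primers rebuilds the 65-mer library structure", {
  spec <- default_library_spec()
  x <- strrep("A", 25)
  full <- attach_primers(x, spec)
  expect_equal(full, paste0("AGCAGCACAGAGGTCAGATG", x, "CCTATGCGTGCTACCGTGAA"))
  expect_equal(nchar(full), 65)
  expect_equal(attach_primers("", spec),
               paste0(spec$forward_primer, spec$reverse_tail))
  for (l in c(1, 10, 25)) {
    expect_equal(nchar(attach_primers(strrep("G", l), spec)), 40 + l)
  }
})

test_that("greedy clustering partitions, respects the threshold, and is greedy", {
  # all-identical input collapses to one cluster
  cl <- greedy_cluster(rep("ACGTACGTACGT", 5), threshold = 0.8)
  expect_equal(unique(cl$cluster_id), 1L)
  expect_equal(nrow(cl), 5)

  # identity just below threshold -> two singletons (boundary is >=)
  s <- strrep("ACGTA", 13)
  set.seed(31)
  s13 <- mutate_dna(s, 13)  # identity 0.8 exactly (checked above)
  s14 <- mutate_dna(s, 14)
  while (seq_identity(s, s14) >= 0.8) s14 <- mutate_dna(s, 14)
  expect_equal(max(greedy_cluster(c(s, s13), 0.8)$cluster_id), 1L)
  expect_equal(max(greedy_cluster(c(s, s14), 0.8)$cluster_id), 2L)

  # a sequence joins the representative of highest identity, not the first
  set.seed(32)
  rep1 <- rnd_dna(40)
  rep2 <- rnd_dna(40)
  s3 <- mutate_dna(rep2, 4)  # ~0.9 to rep2, far from rep1
  stopifnot(seq_identity(rep1, s3) < 0.8)
  cl3 <- greedy_cluster(c(rep1, rep2, s3), threshold = 0.8)
  expect_equal(cl3$cluster_id[cl3$sequence == s3], 2L)

  # empty input
  expect_equal(nrow(greedy_cluster(character(0))), 0)
  expect_error(greedy_cluster("ACGT", threshold = 0), "threshold")
})

test_that("every input sequence lands in exactly one cluster", {
  set.seed(33)
  seqs <- make_cluster_instance(40, len = 30, n_families = 4)
  cl <- greedy_cluster(seqs, threshold = 0.8)
  expect_equal(sort(cl$sequence), sort(seqs))
  expect_equal(nrow(cl), length(seqs))
  expect_true(all(cl$identity >= 0.8 | cl$is_representative))
  # each cluster's representative is its own member at identity 1
  reps <- cl[cl$is_representative, ]
  expect_equal(nrow(reps), max(cl$cluster_id))
  expect_true(all(reps$identity == 1))
})

test_that("raising the threshold never merges clusters", {
  set.seed(34)
  seqs <- make_cluster_instance(30, len = 25, n_families = 3)
  n_clusters <- vapply(c(0.6, 0.75, 0.9, 1.0), function(th) {
    max(greedy_cluster(seqs, threshold = th)$cluster_id)
  }, numeric(1))
  expect_true(all(diff(n_clusters) >= 0))
})

test_that("greedy clustering matches the brute-force re-implementation", {
  set.seed(35)
  for (i in 1:3) {
    seqs <- make_cluster_instance(30, len = 28, n_families = 5)
    cl <- greedy_cluster(seqs, threshold = 0.8)
    want <- brute_greedy_cluster(seqs, threshold = 0.8)
    # compare assignment by original input position
    got2 <- integer(length(seqs))
    for (j in seq_along(seqs)) {
      hit <- cl$cluster_id[cl$sequence == seqs[j]]
      got2[j] <- hit[1]
    }
    expect_equal(got2, want)
  }
})

test_that("cluster TSV and representative FASTA are written", {
  set.seed(36)
  seqs <- make_cluster_instance(12, len = 20, n_families = 2)
  cl <- greedy_cluster(seqs, threshold = 0.8)
  tsv <- tempfile(fileext = ".tsv")
  fa <- tempfile(fileext = ".fasta")
  write_cluster_tsv(cl, tsv, fa)
  back <- read.delim(tsv)
  expect_equal(nrow(back), nrow(cl))
  reps <- Biostrings::readDNAStringSet(fa)
  expect_length(reps, max(cl$cluster_id))
})
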