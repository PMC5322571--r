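# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (except where noted) so that agreement is a real
# cross-check, not a tautology.

# Needleman-Wunsch DP: maximal global alignment score under match = +1,
# mismatch = 0, linear gap penalty; also the maximal number of matches among
# score-optimal alignments.
nw_align_oracle <- function(a, b, gap = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  S <- matrix(-Inf, n + 1, m + 1)
  M <- matrix(0, n + 1, m + 1)
  S[1, ] <- -gap * (0:m)
  S[, 1] <- -gap * (0:n)
  for (i in 1:n) {
    for (j in 1:m) {
      mt <- as.integer(x[i] == y[j])
      cand_s <- c(S[i, j] + mt, S[i, j + 1] - gap, S[i + 1, j] - gap)
      cand_m <- c(M[i, j] + mt, M[i, j + 1], M[i + 1, j])
      best <- max(cand_s)
      S[i + 1, j + 1] <- best
      M[i + 1, j + 1] <- max(cand_m[cand_s == best])
    }
  }
  list(score = S[n + 1, m + 1], max_matches = M[n + 1, m + 1])
}

# Brute-force greedy clustering: a plain re-derivation of the assignment
# rule (scan in order; join the representative of highest identity when
# >= threshold, ties to the lowest cluster id; else found a new cluster),
# recomputing every representative identity at each step one pair at a time.
# Identities come from the exported metric so that the check isolates the
# assignment logic.
brute_greedy_cluster <- function(sequences, threshold, gap_penalty = 1) {
  reps <- character(0)
  assign <- integer(length(sequences))
  for (i in seq_along(sequences)) {
    ids <- numeric(length(reps))
    for (r in seq_along(reps)) {
      ids[r] <- seq_identity(reps[r], sequences[i], gap_penalty = gap_penalty)
    }
    joined <- FALSE
    if (length(ids) > 0 && max(ids) >= threshold) {
      assign[i] <- which(ids == max(ids))[1]
      joined <- TRUE
    }
    if (!joined) {
      reps <- c(reps, sequences[i])
      assign[i] <- length(reps)
    }
  }
  assign
}

# compScore by direct product evaluation (no log-space tricks)
brute_comp_score <- function(folds) log10(prod(folds) * folds[length(folds)])

rnd_dna <- function(l) {
  paste0(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
}

mutate_dna <- function(s, k) {
  x <- strsplit(s, "")[[1]]
  pos <- sample(length(x), k)
  for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
  paste0(x, collapse = "")
}

# a clusterable instance: f families of mutated copies of family seeds
make_cluster_instance <- function(n, len = 30, n_families = 5,
                                  max_mut = 12) {
  seeds <- replicate(n_families, rnd_dna(len))
  vapply(seq_len(n), function(i) {
    mutate_dna(sample(seeds, 1), sample.int(max_mut, 1))
  }, character(1))
}
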