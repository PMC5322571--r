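#' Specification of a random ssDNA library
#'
#' Describes the structure of a combinatorial SELEX library in read
#' orientation: a constant forward primer, a random region of `random_len`
#' nucleotides, and a constant 3' tail (the reverse complement of the
#' reverse primer). Per-position base probabilities model synthesis bias in
#' the random region.
#'
#' @param forward_primer Constant 5' flank (ACGT string).
#' @param reverse_tail Constant 3' flank in read orientation (ACGT string).
#' @param random_len Length of the random region in nt (default 25).
#' @param base_weights Probabilities for G, A, T, C (in that order) at each
#'   random-region position. Must sum to 1 within 1e-9.
#' @return An object of class `library_spec`.
#' @seealso [default_library_spec()] for the N25 library used throughout the
#'   package examples.
#' @export
library_spec <- function(forward_primer, reverse_tail, random_len = 25,
                         base_weights = rep(0.25, 4)) {
  forward_primer <- toupper(forward_primer)
  reverse_tail <- toupper(reverse_tail)
  assert_dna(forward_primer, what = "forward_primer")
  assert_dna(reverse_tail, what = "reverse_tail")
  if (length(base_weights) != 4) {
    stop("base_weights must have length 4 (G, A, T, C)", call. = FALSE)
  }
  if (any(base_weights < 0)) stop("base_weights must be non-negative", call. = FALSE)
  if (abs(sum(base_weights) - 1) > 1e-9) {
    stop("base_weights must sum to 1 (within 1e-9); got ",
         format(sum(base_weights), digits = 12), call. = FALSE)
  }
  if (random_len < 1) stop("random_len must be >= 1", call. = FALSE)
  structure(
    list(forward_primer = forward_primer,
         reverse_tail = reverse_tail,
         random_len = as.integer(random_len),
         base_weights = setNames(as.numeric(base_weights), DNA_BASES)),
    class = "library_spec")
}

#' Default N25 ssDNA library specification
#'
#' The 65-nt library used in the package examples: a 20-nt forward primer,
#' a 25-nt random region, and a 20-nt constant tail (reverse complement of
#' the reverse primer). By default the random-region base weights reproduce
#' the mild synthesis bias typical of hand-mixed library preparations
#' (G 24.3%, A 23.8%, T 27.4%, C 24.4%, renormalized to sum to 1); pass
#' `biased = FALSE` for an ideal uniform library.
#'
#' @param biased Use the hand-mixed bias weights (default) or uniform 0.25.
#' @return A [library_spec].
#' @export
default_library_spec <- function(biased = TRUE) {
  w <- if (biased) c(0.243, 0.238, 0.274, 0.244) else rep(0.25, 4)
  library_spec(
    forward_primer = "AGCAGCACAGAGGTCAGATG",
    reverse_tail   = "CCTATGCGTGCTACCGTGAA",
    random_len = 25,
    base_weights = w / sum(w))
}

#' Ground-truth affinity table for simulated selection
#'
#' Maps sequences to a latent affinity in `[0, 1]`, interpreted as the
#' per-wash retention probability of a molecule bound to the immobilized
#' target. Sequences missing from the table are assigned
#' `background_affinity`. Planted winners are high-affinity sequences whose
#' recovery by the downstream ranking is the simulator's testable ground
#' truth.
#'
#' @param sequence Character vector of sequences.
#' @param affinity Numeric vector in `[0, 1]`, same length.
#' @param planted_winners Subset of `sequence` flagged as planted winners.
#' @param background_affinity Affinity assigned to sequences absent from the
#'   table (default 0.3).
#' @return An object of class `truth_table` (a data frame with attributes).
#' @export
truth_table <- function(sequence, affinity, planted_winners = character(0),
                        background_affinity = 0.3) {
  stopifnot(length(sequence) == length(affinity))
  if (any(affinity < 0 | affinity > 1)) {
    stop("affinities must lie in [0, 1]", call. = FALSE)
  }
  if (background_affinity < 0 || background_affinity > 1) {
    stop("background_affinity must lie in [0, 1]", call. = FALSE)
  }
  if (!all(planted_winners %in% sequence)) {
    stop("planted_winners must be present in the truth table", call. = FALSE)
  }
  structure(
    data.frame(sequence = as.character(sequence), affinity = as.numeric(affinity),
               stringsAsFactors = FALSE),
    planted_winners = as.character(planted_winners),
    background_affinity = background_affinity,
    class = c("truth_table", "data.frame"))
}

#' @rdname truth_table
#' @param truth A `truth_table`.
#' @param path TSV path (columns `sequence`, `affinity`; winners flagged in a
#'   third column `planted_winner`).
#' @export
write_truth_tsv <- function(truth, path) {
  stopifnot(inherits(truth, "truth_table"))
  df <- as.data.frame(truth)
  df$planted_winner <- df$sequence %in% attr(truth, "planted_winners")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname truth_table
#' @export
read_truth_tsv <- function(path, background_affinity = 0.3) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  truth_table(df$sequence, df$affinity,
              planted_winners = df$sequence[as.logical(df$planted_winner)],
              background_affinity = background_affinity)
}

#' Round schedule for a simulated SELEX experiment
#'
#' @param n_rounds Number of selection rounds (default 4).
#' @param washes_per_round Integer vector, one entry per round, non-decreasing
#'   (the wash count sets the selective pressure; default 6, 9, 12, 15).
#' @param reads_per_round Sequencing depth per output pool (default 1e5).
#' @param seed Base seed; round `k` uses `seed + k`.
#' @return An object of class `round_schedule`.
#' @export
round_schedule <- function(n_rounds = 4, washes_per_round = c(6, 9, 12, 15),
                           reads_per_round = 1e5, seed = 1) {
  if (length(washes_per_round) != n_rounds) {
    stop("washes_per_round must have length n_rounds", call. = FALSE)
  }
  if (is.unsorted(washes_per_round)) {
    stop("washes_per_round must be non-decreasing", call. = FALSE)
  }
  structure(
    list(n_rounds = as.integer(n_rounds),
         washes_per_round = as.integer(washes_per_round),
         reads_per_round = as.integer(reads_per_round),
         seed = as.integer(seed)),
    class = "round_schedule")
}

#' Draw an unselected library pool
#'
#' Samples `n_molecules` full-length molecules (forward primer + random
#' region + tail) with i.i.d. per-position base weights in the random region.
#' Duplication arises naturally when `n_molecules` approaches the effective
#' diversity of the library.
#'
#' @param spec A [library_spec].
#' @param n_molecules Number of molecules to draw (>= 1).
#' @param seed RNG seed for this operation.
#' @param label Pool label (default `"R0"`).
#' @return A [round_pool] of full-length sequences totalling `n_molecules`.
#' @examples
#' p <- generate_library(default_library_spec(), 1000, seed = 7)
#' p$total_reads
#' @export
generate_library <- function(spec, n_molecules, seed, label = "R0") {
  stopifnot(inherits(spec, "library_spec"))
  if (n_molecules < 1) stop("n_molecules must be >= 1", call. = FALSE)
  n_molecules <- as.integer(n_molecules)
  regions <- with_seed(seed, random_regions(spec, n_molecules))
  full <- paste0(spec$forward_primer, regions, spec$reverse_tail)
  count_and_rank(full, label = label)
}

# internal: vector of n random-region strings drawn under spec (uses the
# current RNG state; callers wrap in with_seed)
random_regions <- function(spec, n) {
  mat <- matrix(sample(DNA_BASES, n * spec$random_len, replace = TRUE,
                       prob = spec$base_weights),
                nrow = n, ncol = spec$random_len)
  do.call(paste0, lapply(seq_len(spec$random_len), function(j) mat[, j]))
}

#' Simulate one SELEX round: wash-based selection plus resampling
#'
#' Each molecule in the input pool is retained in the bound fraction with
#' probability `affinity^washes` (its per-wash retention probability raised
#' to the number of wash steps), otherwise it joins the unbound fraction.
#' Both fractions are then resampled with replacement to `reads_out` reads,
#' collapsing PCR amplification and sequencing depth into a single
#' multinomial step. An optional per-base substitution rate emulates
#' sequencing error (off by default; 0.001 is a typical Illumina-scale
#' value).
#'
#' Before resampling, bound + unbound molecule counts exactly conserve the
#' input pool; the pre-resampling counts are attached to each output pool as
#' attribute `"molecules"` so conservation can be audited.
#'
#' @param pool Input [round_pool] (non-empty).
#' @param truth A [truth_table] supplying per-sequence affinities.
#' @param washes Number of wash steps (>= 0).
#' @param reads_out Sequencing depth of each output pool (>= 1).
#' @param seed RNG seed for this operation.
#' @param error_rate Per-base substitution probability applied to output
#'   reads (default 0, i.e. no sequencing error).
#' @param round_label Label stem, e.g. `"R1"`; pools are labelled
#'   `"R1+"`/`"R1-"`.
#' @return `list(bound = round_pool, unbound = round_pool)`.
#' @export
simulate_round <- function(pool, truth, washes, reads_out, seed,
                           error_rate = 0, round_label = "R1") {
  stopifnot(inherits(pool, "round_pool"), inherits(truth, "truth_table"))
  if (pool$total_reads < 1) stop("input pool is empty", call. = FALSE)
  if (washes < 0) stop("washes must be >= 0", call. = FALSE)
  if (reads_out < 1) stop("reads_out must be >= 1", call. = FALSE)

  seqs <- names(pool$counts)
  aff <- truth$affinity[match(seqs, truth$sequence)]
  aff[is.na(aff)] <- attr(truth, "background_affinity")
  p_keep <- aff^washes

  with_seed(seed, {
    retained <- rbinom(length(seqs), pool$counts, p_keep)
    unbound <- pool$counts - retained
    bound_pool <- resample_pool(setNames(retained, seqs), reads_out,
                                paste0(round_label, "+"), error_rate)
    unbound_pool <- resample_pool(setNames(unbound, seqs), reads_out,
                                  paste0(round_label, "-"), error_rate)
  })
  attr(bound_pool, "molecules") <- setNames(as.integer(retained), seqs)
  attr(unbound_pool, "molecules") <- setNames(as.integer(unbound), seqs)
  list(bound = bound_pool, unbound = unbound_pool)
}

# internal: multinomial resampling of a molecule-count vector to depth
# reads_out, with optional per-read substitution noise
resample_pool <- function(molecules, reads_out, label, error_rate = 0) {
  molecules <- molecules[molecules > 0]
  if (length(molecules) == 0) {
    return(round_pool(label, integer(0)))
  }
  counts <- as.integer(rmultinom(1, reads_out, prob = molecules)[, 1])
  names(counts) <- names(molecules)
  counts <- counts[counts > 0]
  if (error_rate > 0) {
    counts <- apply_sequencing_error(counts, error_rate)
  }
  round_pool(label, counts)
}

# internal: per-base substitution noise on an expanded read multiset
apply_sequencing_error <- function(counts, error_rate) {
  len <- nchar(names(counts)[1])
  # number of reads carrying >= 1 substitution, drawn per unique sequence
  n_mut <- rbinom(length(counts), counts, 1 - (1 - error_rate)^len)
  keep <- counts - n_mut
  mutated <- character(0)
  idx <- which(n_mut > 0)
  if (length(idx) > 0) {
    mutated <- unlist(lapply(idx, function(i) {
      vapply(seq_len(n_mut[i]), function(j) {
        s <- strsplit(names(counts)[i], "")[[1]]
        # at least one substitution; each position flips independently
        pos <- which(runif(len) < error_rate)
        if (length(pos) == 0) pos <- sample.int(len, 1)
        for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1)
        paste0(s, collapse = "")
      }, character(1))
    }))
  }
  tab <- table(c(rep(names(counts), keep), mutated))
  setNames(as.integer(tab), names(tab))
}

#' Run a full multi-round SELEX simulation
#'
#' Iterates [simulate_round()] over a [round_schedule], feeding each round's
#' bound pool (resampled to sequencing depth) forward as the next round's
#' input, mirroring a selection in which the binding DNA from round k is the
#' input to round k + 1.
#'
#' @param pool0 Unselected library [round_pool] (round 0).
#' @param truth A [truth_table].
#' @param schedule A [round_schedule].
#' @param error_rate Per-base substitution rate passed to [simulate_round()].
#' @return `list(library = pool0, rounds = list of list(bound, unbound))`,
#'   one entry per round in order.
#' @export
simulate_selex <- function(pool0, truth, schedule, error_rate = 0) {
  stopifnot(inherits(schedule, "round_schedule"))
  rounds <- vector("list", schedule$n_rounds)
  pool <- pool0
  for (k in seq_len(schedule$n_rounds)) {
    rounds[[k]] <- simulate_round(
      pool, truth,
      washes = schedule$washes_per_round[k],
      reads_out = schedule$reads_per_round,
      seed = schedule$seed + k,
      error_rate = error_rate,
      round_label = paste0("R", k))
    pool <- rounds[[k]]$bound
  }
  names(rounds) <- paste0("R", seq_len(schedule$n_rounds))
  list(library = pool0, rounds = rounds)
}

#' Build a planted-winner SELEX experiment
#'
#' Constructs an initial pool of `n_background` distinct full-length
#' background sequences plus `n_winners` planted high-affinity winners, with
#' initial molecule counts drawn multinomially at depth `depth` (each winner
#' guaranteed at least one molecule, so planted winners are always present
#' in the initial pool). Background affinities are drawn uniformly on
#' `background_range`; winners receive `winner_affinity`.
#'
#' @param spec A [library_spec].
#' @param n_background Number of distinct background sequences (default 1e4).
#' @param n_winners Number of planted winners (default 3).
#' @param winner_affinity Per-wash retention probability of winners
#'   (default 0.9).
#' @param background_range Range of background affinities (default
#'   `c(0.05, 0.55)`, mean 0.3).
#' @param depth Initial pool depth in molecules (default 1e5).
#' @param seed RNG seed.
#' @return `list(pool0 = round_pool, truth = truth_table)`.
#' @export
plant_selex_experiment <- function(spec, n_background = 1e4, n_winners = 3,
                                   winner_affinity = 0.9,
                                   background_range = c(0.05, 0.55),
                                   depth = 1e5, seed = 1) {
  stopifnot(inherits(spec, "library_spec"))
  with_seed(seed, {
    # oversample then deduplicate to reach the requested distinct count
    need <- n_background + n_winners
    regions <- character(0)
    while (length(regions) < need) {
      regions <- unique(c(regions, random_regions(spec, ceiling(1.1 * need))))
    }
    regions <- regions[seq_len(need)]
    full <- paste0(spec$forward_primer, regions, spec$reverse_tail)
    winners <- full[seq_len(n_winners)]
    background <- full[-seq_len(n_winners)]
    aff <- c(rep(winner_affinity, n_winners),
             runif(n_background, background_range[1], background_range[2]))
    truth <- truth_table(full, aff, planted_winners = winners,
                         background_affinity = mean(background_range))
    counts <- as.integer(rmultinom(1, depth, prob = rep(1, need))[, 1])
    names(counts) <- full
    counts[winners] <- pmax(counts[winners], 1L)
  })
  list(pool0 = round_pool("R0", counts), truth = truth)
}

#' Write a pool to FASTQ with constant quality
#'
#' Expands the pool's count table into individual reads, shuffles the read
#' order under the given seed (so the file resembles an unsorted sequencer
#' output while staying byte-reproducible), and writes Sanger/Phred+33
#' FASTQ with a constant per-base quality.
#'
#' @param pool A non-empty [round_pool].
#' @param path Output FASTQ path.
#' @param quality Constant Phred quality score (default 30).
#' @param seed RNG seed controlling read order.
#' @return `path`, invisibly.
#' @export
write_round_fastq <- function(pool, path, quality = 30, seed = 1) {
  stopifnot(inherits(pool, "round_pool"))
  if (pool$total_reads < 1) stop("cannot write an empty pool", call. = FALSE)
  reads <- rep(names(pool$counts), pool$counts)
  ord <- with_seed(seed, sample.int(length(reads)))
  reads <- reads[ord]
  ids <- sprintf("%s_%06d", gsub("[^A-Za-z0-9]", "", pool$label),
                 seq_along(reads))
  qchar <- rawToChar(as.raw(as.integer(quality) + 33L))
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- ids
  quals <- Biostrings::BStringSet(strrep(qchar, nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}
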