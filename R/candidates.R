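AVOGADRO <- 6.02214076e23

#' Base composition of sequences
#'
#' Percent G, A, T, C plus GC and AT content of each sequence, as exact
#' (unrounded) percentages `100 * count / length`. Use [composition_report()]
#' for the integer-rounded presentation.
#'
#' @param seqs Character vector of ACGT sequences (non-empty).
#' @return Data frame with columns `sequence`, `length`, `pct_g`, `pct_a`,
#'   `pct_t`, `pct_c`, `pct_gc`, `pct_at`.
#' @examples
#' base_composition("AAAA")  # 100% A
#' @export
base_composition <- function(seqs) {
  if (any(is.na(seqs) | !nzchar(seqs))) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  seqs <- toupper(seqs)
  assert_dna(seqs)
  counts <- t(vapply(strsplit(seqs, ""), function(ch) {
    c(G = sum(ch == "G"), A = sum(ch == "A"),
      T = sum(ch == "T"), C = sum(ch == "C"))
  }, numeric(4)))
  len <- nchar(seqs)
  pct <- 100 * counts / len
  data.frame(sequence = seqs, length = len,
             pct_g = pct[, "G"], pct_a = pct[, "A"],
             pct_t = pct[, "T"], pct_c = pct[, "C"],
             pct_gc = pct[, "G"] + pct[, "C"],
             pct_at = pct[, "A"] + pct[, "T"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Integer-rounded base-composition table
#'
#' The reporting form of [base_composition()]: percentages rounded to the
#' nearest integer. Before rounding the four base percentages sum to exactly
#' 100; after rounding the sum can drift by a point or two.
#'
#' @inheritParams base_composition
#' @return Data frame like [base_composition()] with integer percentages.
#' @export
composition_report <- function(seqs) {
  df <- base_composition(seqs)
  pct <- grep("^pct_", names(df))
  df[pct] <- lapply(df[pct], function(x) as.integer(round(x)))
  df
}

#' Library diversity and coverage statistics
#'
#' For a random region of `N` nt, the theoretical diversity is `4^N`
#' sequences. Given an input amount in pmol, the number of input molecules
#' is `pmol * 1e-12 * N_A` (Avogadro), and the expected per-sequence
#' abundance in the initial pool is `molecules / diversity`. Exact values
#' are returned; the print method also shows the conventional
#' one-significant-figure presentation (see [format_sig1()]).
#'
#' @param N Random-region length in nt (>= 1).
#' @param input_pmol Input DNA amount in pmol (> 0; default 50).
#' @return An object of class `library_stats`: list with `N`, `diversity`,
#'   `input_pmol`, `input_molecules`, `expected_abundance`.
#' @examples
#' library_stats(25, 50)
#' @export
library_stats <- function(N, input_pmol = 50) {
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  if (input_pmol <= 0) stop("input_pmol must be > 0", call. = FALSE)
  diversity <- 4^N  # exact in double precision for N <= 26
  molecules <- input_pmol * 1e-12 * AVOGADRO
  structure(
    list(N = as.integer(N), diversity = diversity,
         input_pmol = input_pmol, input_molecules = molecules,
         expected_abundance = molecules / diversity),
    class = "library_stats")
}

#' One-significant-figure rounding
#'
#' The conventional presentation of library coverage numbers (e.g. a
#' diversity of 1.13e15 is quoted as ~1e15, an expected abundance of 0.027
#' as 0.03).
#'
#' @param x Numeric vector.
#' @return `signif(x, 1)`.
#' @export
format_sig1 <- function(x) signif(x, 1)

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf("Random region N = %d\n", x$N))
  cat(sprintf("  diversity 4^N        = %s (~%s)\n",
              format(x$diversity, big.mark = ","),
              format(format_sig1(x$diversity))))
  cat(sprintf("  input %g pmol        = %.4g molecules (~%s)\n",
              x$input_pmol, x$input_molecules,
              format(format_sig1(x$input_molecules))))
  cat(sprintf("  expected abundance   = %.4g (~%s)\n",
              x$expected_abundance, format(format_sig1(x$expected_abundance))))
  invisible(x)
}

#' Candidate report: the top-scoring aptamer candidates
#'
#' Selects the top `k` sequences by compScore and annotates each with its
#' final-round fold enrichment, enrichment rank, cluster membership, and
#' base composition. Candidates are named `<prefix>_<enrichment rank>`,
#' where the enrichment rank is the 1-based rank by final-round fold
#' enrichment over all sequences (so the most enriched sequence in the
#' final round is `<prefix>_1`, whether or not it also tops the compScore
#' ranking). Rows are ordered by descending compScore.
#'
#' @param profiles Data frame from [enrichment_table()].
#' @param clusters Optional `aptamer_clusters` from [greedy_cluster()];
#'   when it was computed on primer-attached sequences, pass `spec` so the
#'   lookup can re-attach primers.
#' @param k Number of candidates (> 0).
#' @param prefix Name prefix (default `"APT"`).
#' @param spec Optional [library_spec] for primer re-attachment in the
#'   cluster lookup.
#' @return Data frame with columns `id`, `random_region`, `enrichment_rank`,
#'   `enrichment` (final fold), `comp_score`, `cluster_id` (NA when
#'   unclustered), and integer composition percentages.
#' @export
build_report <- function(profiles, clusters = NULL, k = 10, prefix = "APT",
                         spec = NULL) {
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  by_comp <- rank_by(profiles, "comp_score")
  by_enr <- rank_by(profiles, "final_fold")
  sel <- head(by_comp, k)
  enr_rank <- by_enr$rank[match(sel$sequence, by_enr$sequence)]

  cluster_id <- rep(NA_integer_, nrow(sel))
  if (!is.null(clusters)) {
    key <- if (!is.null(spec)) attach_primers(sel$sequence, spec) else sel$sequence
    m <- match(key, clusters$sequence)
    cluster_id <- clusters$cluster_id[m]
  }
  comp <- composition_report(sel$sequence)
  out <- data.frame(
    id = sprintf("%s_%d", prefix, enr_rank),
    random_region = sel$sequence,
    enrichment_rank = enr_rank,
    enrichment = sel$final_fold,
    comp_score = sel$comp_score,
    cluster_id = cluster_id,
    stringsAsFactors = FALSE)
  cbind(out, comp[, grep("^pct_", names(comp)), drop = FALSE])
}

#' Write a candidate report as TSV
#'
#' @param report Data frame from [build_report()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  df <- report
  for (cl in c("enrichment", "comp_score")) {
    df[[cl]] <- format(df[[cl]], digits = 15, trim = TRUE)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
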