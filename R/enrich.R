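#' Pseudocount policy for frequency computation
#'
#' Round-0 libraries are sampled far below their diversity, so sequences
#' enriched in later rounds are often unobserved in round 0; their fold
#' enrichment would be infinite. Under `add_constant` (the default), every
#' per-sequence frequency is computed as `(count + constant) /
#' (total + constant)`, keeping every frequency strictly positive. Under
#' `reject`, raw frequencies are used and any required zero frequency is an
#' error.
#'
#' @param mode `"add_constant"` or `"reject"`.
#' @param constant Pseudocount in reads (default 0.5; must be > 0).
#' @return An object of class `pseudocount_policy`.
#' @export
pseudocount_policy <- function(mode = c("add_constant", "reject"),
                               constant = 0.5) {
  mode <- match.arg(mode)
  if (mode == "add_constant" && constant <= 0) {
    stop("pseudocount constant must be > 0", call. = FALSE)
  }
  structure(list(mode = mode, constant = constant),
            class = "pseudocount_policy")
}

# internal: assemble a sequence x round count matrix + per-round totals from
# a list of pools (round 0 first)
pool_count_matrix <- function(pools) {
  if (length(pools) < 2) {
    stop("need round 0 plus at least one selection round", call. = FALSE)
  }
  lapply(pools, function(p) stopifnot(inherits(p, "round_pool")))
  seqs <- unique(unlist(lapply(pools, function(p) names(p$counts))))
  C <- vapply(pools, function(p) {
    v <- p$counts[match(seqs, names(p$counts))]
    v[is.na(v)] <- 0L
    as.numeric(v)
  }, numeric(length(seqs)))
  if (is.null(dim(C))) C <- matrix(C, nrow = length(seqs))
  rownames(C) <- seqs
  list(counts = C, totals = vapply(pools, function(p) p$total_reads, numeric(1)))
}

#' Per-sequence per-round frequencies
#'
#' For every sequence observed in any round, computes its frequency `R_i`
#' in each round i = 0..n (reads of the sequence divided by total accepted
#' reads in the round), applying the [pseudocount_policy()] so that `R_i > 0`
#' everywhere under `add_constant`.
#'
#' @param pools List of [round_pool]s in round order; the first element must
#'   be the unselected library (round 0). Enrichment is conventionally
#'   computed over the bound (+) pools.
#' @param policy A [pseudocount_policy].
#' @return Numeric matrix (sequences x rounds) of frequencies, with column
#'   names `R0, R1, ...`.
#' @export
enrich_frequencies <- function(pools, policy = pseudocount_policy()) {
  stopifnot(inherits(policy, "pseudocount_policy"))
  pm <- pool_count_matrix(pools)
  k <- if (policy$mode == "add_constant") policy$constant else 0
  Fq <- sweep(pm$counts + k, 2, pm$totals + k, "/")
  colnames(Fq) <- paste0("R", seq_along(pools) - 1)
  Fq
}

#' Composite enrichment score (compScore)
#'
#' The compScore of a sequence with per-round fold enrichments
#' `f_i = R_i / R_0` (i = 1..n) is
#' `log10( (prod_i f_i) * f_n )`: the log10 of the product of every round's
#' fold enrichment, with double weight given to the final round, in which
#' the selective pressure is most stringent. Computed in log space as
#' `sum(log10(f_i)) + log10(f_n)` for numerical stability.
#'
#' @param fold_enrichments Numeric vector of per-round fold enrichments
#'   (rounds 1..n, in order; all > 0).
#' @return The compScore (a real number).
#' @examples
#' comp_score(c(10, 100, 1000, 10000))  # 14
#' comp_score(100)                      # 4: single round counted twice
#' @export
comp_score <- function(fold_enrichments) {
  if (length(fold_enrichments) < 1) {
    stop("need at least one round of fold enrichment", call. = FALSE)
  }
  if (any(fold_enrichments < 0)) {
    stop("fold enrichments must be non-negative", call. = FALSE)
  }
  if (any(fold_enrichments == 0)) {
    stop("zero fold enrichment: compScore is undefined without a ",
         "pseudocount; use pseudocount_policy(\"add_constant\")",
         call. = FALSE)
  }
  lf <- log10(fold_enrichments)
  sum(lf) + lf[length(lf)]
}

#' Build the full enrichment table for a SELEX series
#'
#' Combines [enrich_frequencies()] with per-round fold enrichments and the
#' [comp_score()] into one table. Sequences absent from the final round
#' cannot be candidates and receive `comp_score = -Inf` (they are dropped by
#' [rank_by()]).
#'
#' @inheritParams enrich_frequencies
#' @return Data frame with columns `sequence`, `freq_0..freq_n`,
#'   `fold_1..fold_n`, `final_fold`, `count_final` (raw final-round count),
#'   and `comp_score`.
#' @export
enrichment_table <- function(pools, policy = pseudocount_policy()) {
  pm <- pool_count_matrix(pools)
  if (policy$mode == "reject" && any(pm$counts == 0)) {
    stop("zero counts present under pseudocount mode 'reject'; ",
         "use pseudocount_policy(\"add_constant\")", call. = FALSE)
  }
  Fq <- enrich_frequencies(pools, policy)
  n <- ncol(Fq) - 1
  fold <- Fq[, -1, drop = FALSE] / Fq[, 1]
  lf <- log10(fold)
  comp <- rowSums(lf) + lf[, n]
  comp[pm$counts[, n + 1] == 0] <- -Inf

  out <- data.frame(sequence = rownames(Fq), stringsAsFactors = FALSE,
                    row.names = NULL)
  for (i in 0:n) out[[paste0("freq_", i)]] <- unname(Fq[, i + 1])
  for (i in 1:n) out[[paste0("fold_", i)]] <- unname(fold[, i])
  out$final_fold <- unname(fold[, n])
  out$count_final <- as.integer(pm$counts[, n + 1])
  out$comp_score <- unname(comp)
  out
}

#' Rank sequences by an enrichment metric
#'
#' Orders the enrichment table by the chosen metric, descending. Ties are
#' broken by a secondary metric (`final_fold` when ranking by `comp_score`,
#' `comp_score` otherwise) and then by ascending lexicographic sequence
#' order, so ranks are deterministic. Sequences with `comp_score = -Inf`
#' (absent from the final round) are excluded. Ranks are 1-based.
#'
#' @param profiles Data frame from [enrichment_table()].
#' @param metric `"comp_score"`, `"final_fold"`, or `"round_count"` (raw
#'   final-round read count).
#' @return The table sorted with a `rank` column prepended.
#' @export
rank_by <- function(profiles,
                    metric = c("comp_score", "final_fold", "round_count")) {
  metric <- match.arg(metric)
  col <- switch(metric, comp_score = "comp_score",
                final_fold = "final_fold", round_count = "count_final")
  tie <- if (metric == "comp_score") "final_fold" else "comp_score"
  keep <- is.finite(profiles$comp_score)
  df <- profiles[keep, , drop = FALSE]
  ord <- order(-df[[col]], -df[[tie]], df$sequence, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  cbind(rank = seq_len(nrow(df)), df)
}

#' Most-enriched sequence set
#'
#' Selects the `k` most enriched sequences: by `comp_score` over the whole
#' series by default, or — when `per_round = TRUE` — the union of the top
#' `k` sequences of each round ranked by that round's fold enrichment
#' (mirroring a per-round clustering input of the most enriched sequences).
#'
#' @param profiles Data frame from [enrichment_table()].
#' @param k Number of sequences (default 1000); the whole table when fewer.
#' @param per_round Take top-k per round by `fold_i` instead (default FALSE).
#' @return Character vector of sequences.
#' @export
top_k <- function(profiles, k = 1000, per_round = FALSE) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (!per_round) {
    ranked <- rank_by(profiles, "comp_score")
    return(head(ranked$sequence, k))
  }
  fold_cols <- grep("^fold_", names(profiles), value = TRUE)
  sel <- lapply(fold_cols, function(cl) {
    ord <- order(-profiles[[cl]], profiles$sequence, method = "radix")
    head(profiles$sequence[ord], k)
  })
  unique(unlist(sel))
}

#' Write / read an enrichment table as TSV
#'
#' @param profiles Data frame from [enrichment_table()] (or [rank_by()]).
#' @param path File path.
#' @return `write_enrichment_tsv` returns `path` invisibly;
#'   `read_enrichment_tsv` returns the data frame.
#' @export
write_enrichment_tsv <- function(profiles, path) {
  df <- profiles
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_enrichment_tsv
#' @export
read_enrichment_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
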