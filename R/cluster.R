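#' Pairwise sequence identity (CD-HIT convention)
#'
#' Identity between two sequences is the number of matched bases in the best
#' global alignment, divided by the length of the shorter sequence — the
#' convention used by CD-HIT-EST. The alignment maximizes matches under unit
#' match score, zero mismatch score, and a linear gap penalty
#' (`gap_penalty` per gapped position, default 1).
#'
#' @param a Character vector of sequences (vectorized side).
#' @param b A single sequence.
#' @param gap_penalty Linear per-position gap cost (default 1).
#' @return Numeric vector of identities in `[0, 1]`, one per element of `a`.
#' @examples
#' seq_identity("ACGTACGT", "ACGTACGT")  # 1
#' @export
seq_identity <- function(a, b, gap_penalty = 1) {
  stopifnot(length(b) == 1, all(nzchar(a)), nzchar(b))
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = 0, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = sub_mat,
    gapOpening = 0, gapExtension = gap_penalty)
  Biostrings::nmatch(aln) / pmin(nchar(a), nchar(b))
}

#' Greedy representative-based clustering at an identity threshold
#'
#' Emulates CD-HIT-EST's greedy scheme: scan the input in the caller's
#' order (conventionally descending enrichment, so each cluster's
#' representative is its most enriched member); compare each sequence to
#' every existing cluster representative; join the cluster of highest
#' identity if that identity is at or above `threshold` (ties go to the
#' lowest cluster id), otherwise found a new cluster with the sequence as
#' its own representative. Cluster ids number clusters by creation order,
#' starting at 1.
#'
#' @param sequences Character vector, pre-sorted by the caller's metric.
#'   Duplicate sequences are clustered like any other member.
#' @param threshold Identity threshold in `(0, 1]` (default 0.8; membership
#'   requires identity `>= threshold`).
#' @param gap_penalty Passed to [seq_identity()].
#' @return An object of class `aptamer_clusters`: a data frame with columns
#'   `cluster_id`, `sequence`, `identity` (to the cluster representative;
#'   1 for the representative itself), `is_representative`.
#' @examples
#' greedy_cluster(c("ACGTACGTAC", "ACGTACGTAA", "TTTTGGGGCC"), threshold = 0.8)
#' @export
greedy_cluster <- function(sequences, threshold = 0.8, gap_penalty = 1) {
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  n <- length(sequences)
  cluster_id <- integer(n)
  identity <- numeric(n)
  reps <- character(0)
  rep_index <- integer(0)  # input position that founded each cluster
  for (i in seq_len(n)) {
    if (length(reps) > 0) {
      ids <- seq_identity(reps, sequences[i], gap_penalty = gap_penalty)
      best <- which.max(ids)  # ties -> lowest cluster id
      if (ids[best] >= threshold) {
        cluster_id[i] <- best
        identity[i] <- ids[best]
        next
      }
    }
    reps <- c(reps, sequences[i])
    rep_index <- c(rep_index, i)
    cluster_id[i] <- length(reps)
    identity[i] <- 1
  }
  out <- data.frame(cluster_id = cluster_id, sequence = sequences,
                    identity = identity,
                    is_representative = seq_len(n) %in% rep_index,
                    stringsAsFactors = FALSE)
  ord <- order(out$cluster_id, !out$is_representative, -out$identity,
               out$sequence, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("aptamer_clusters", "data.frame")
  attr(out, "representatives") <- reps
  attr(out, "threshold") <- threshold
  out
}

#' Re-attach constant primers to a random region
#'
#' Clustering is performed on full-length sequences (primers attached), so
#' that the constant flanks anchor the alignment; this reconstructs the
#' full-length sequence from a trimmed random region.
#'
#' @param random_region Character vector of random regions (may be empty
#'   strings).
#' @param spec A [library_spec].
#' @return `forward_primer + random_region + reverse_tail` for each input.
#' @export
attach_primers <- function(random_region, spec) {
  stopifnot(inherits(spec, "library_spec"))
  paste0(spec$forward_primer, random_region, spec$reverse_tail)
}

#' Write clusters as TSV, and representatives as FASTA
#'
#' @param clusters An `aptamer_clusters` object from [greedy_cluster()].
#' @param path Output TSV path.
#' @param fasta_path Optional FASTA path for cluster representatives.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(clusters, path, fasta_path = NULL) {
  stopifnot(inherits(clusters, "aptamer_clusters"))
  df <- as.data.frame(clusters)
  df$identity <- format(df$identity, digits = 10, trim = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta_path)) {
    reps <- attr(clusters, "representatives")
    x <- Biostrings::DNAStringSet(reps)
    names(x) <- sprintf("cluster_%d", seq_along(reps))
    Biostrings::writeXStringSet(x, fasta_path)
  }
  invisible(path)
}
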