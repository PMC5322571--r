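#' Deduplicated sequence count table for one SELEX round/pool
#'
#' A `round_pool` holds the exact multiset of sequences observed in one
#' sequencing pool (e.g. the unselected library `R0`, or the bound `R2+` /
#' unbound `R2-` fraction of a selection round), as a named integer count
#' vector sorted into rank order (rank 1 = most abundant; ties broken by
#' ascending lexicographic order so that the ranking is deterministic).
#'
#' @param label Pool identifier, e.g. `"R0"`, `"R1+"`, `"R3-"`.
#' @param counts Named integer vector: sequence -> read count. Need not be
#'   sorted; the constructor sorts it into rank order.
#' @param n_rejected_primer Number of ingested reads rejected because a
#'   primer flank could not be matched (or the random region contained N).
#' @param n_rejected_length Number of reads rejected by the length filter.
#'
#' @return An object of class `round_pool`: a list with elements `label`,
#'   `counts` (named, rank-ordered), `total_reads` (accepted reads, i.e.
#'   `sum(counts)`), `n_rejected_primer`, `n_rejected_length`.
#' @examples
#' p <- round_pool("R0", c(AAA = 2L, CCC = 1L))
#' p$counts
#' duplication_percent(p)
#' @export
round_pool <- function(label, counts,
                       n_rejected_primer = 0L, n_rejected_length = 0L) {
  if (length(counts) == 0) {
    counts <- integer(0)
  } else {
    if (is.null(names(counts)) || any(names(counts) == "")) {
      stop("'counts' must be a named vector (names are sequences)", call. = FALSE)
    }
    if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
    counts <- counts[counts > 0]
    storage.mode(counts) <- "integer"
    ord <- order(-counts, names(counts), method = "radix")
    counts <- counts[ord]
  }
  structure(
    list(label = as.character(label),
         counts = counts,
         total_reads = sum(counts),
         n_rejected_primer = as.integer(n_rejected_primer),
         n_rejected_length = as.integer(n_rejected_length)),
    class = "round_pool")
}

#' @export
print.round_pool <- function(x, ...) {
  cat(sprintf("<round_pool %s> %d reads, %d distinct sequences",
              x$label, x$total_reads, length(x$counts)))
  if (x$total_reads > 0) {
    cat(sprintf(", duplication %.2f%%", duplication_percent(x)))
  }
  cat("\n")
  if (x$n_rejected_primer + x$n_rejected_length > 0) {
    cat(sprintf("  rejected: %d primer, %d length\n",
                x$n_rejected_primer, x$n_rejected_length))
  }
  invisible(x)
}

#' Count and rank a set of processed sequences
#'
#' Tallies exact multiset counts of the (already trimmed and filtered)
#' sequences and ranks them by abundance. Rank 1 is the most abundant
#' sequence; ties are broken by ascending lexicographic order so that the
#' table is identical regardless of input order.
#'
#' @param seqs Character vector of sequences (trimmed random regions).
#' @param label Pool identifier.
#' @inheritParams round_pool
#' @return A [round_pool].
#' @examples
#' count_and_rank(c("AAA", "AAA", "CCC"), "R1+")
#' @export
count_and_rank <- function(seqs, label = "pool",
                           n_rejected_primer = 0L, n_rejected_length = 0L) {
  if (length(seqs) == 0) {
    return(round_pool(label, integer(0), n_rejected_primer, n_rejected_length))
  }
  tab <- table(seqs)
  counts <- setNames(as.integer(tab), names(tab))
  round_pool(label, counts, n_rejected_primer, n_rejected_length)
}

#' Sequence duplication percentage of a pool
#'
#' The fraction of reads in a pool that are not unique, expressed as a
#' percentage: `100 * (1 - distinct / total)`. This is the headline
#' duplication number in FastQC-style sequencing QC reports; it rises across
#' SELEX rounds as selective pressure collapses library diversity.
#'
#' @param pool A [round_pool].
#' @return Percentage in `[0, 100)`.
#' @examples
#' duplication_percent(count_and_rank(c("A", "A", "B", "C")))  # 25
#' @export
duplication_percent <- function(pool) {
  stopifnot(inherits(pool, "round_pool"))
  if (pool$total_reads < 1) {
    stop("duplication_percent is undefined for an empty pool", call. = FALSE)
  }
  100 * (1 - length(pool$counts) / pool$total_reads)
}

#' Write / read a per-round count table as TSV
#'
#' Columns: `rank`, `sequence`, `count`, `frequency` (count / total accepted
#' reads). Rejection tallies and the label are stored as `#`-prefixed header
#' comments so a pool round-trips losslessly.
#'
#' @param pool A [round_pool].
#' @param path Output file path.
#' @return `write_pool_tsv` returns `path` invisibly; `read_pool_tsv`
#'   returns a [round_pool].
#' @export
write_pool_tsv <- function(pool, path) {
  stopifnot(inherits(pool, "round_pool"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# label=%s", pool$label),
    sprintf("# n_rejected_primer=%d", pool$n_rejected_primer),
    sprintf("# n_rejected_length=%d", pool$n_rejected_length),
    "rank\tsequence\tcount\tfrequency"), con)
  if (length(pool$counts) > 0) {
    df <- data.frame(rank = seq_along(pool$counts),
                     sequence = names(pool$counts),
                     count = unname(pool$counts),
                     frequency = unname(pool$counts) / pool$total_reads)
    write.table(format(df, scientific = FALSE, trim = TRUE, digits = 15),
                con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_pool_tsv
#' @export
read_pool_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(m) == 0) return(default)
    sub(paste0("^# ", key, "="), "", m[1])
  }
  body <- lines[!grepl("^#", lines)]
  label <- get("label", "pool")
  rp <- as.integer(get("n_rejected_primer", "0"))
  rl <- as.integer(get("n_rejected_length", "0"))
  if (length(body) <= 1) {
    return(round_pool(label, integer(0), rp, rl))
  }
  df <- read.delim(text = body, stringsAsFactors = FALSE)
  round_pool(label, setNames(as.integer(df$count), df$sequence), rp, rl)
}
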