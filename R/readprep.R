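#' Read a FASTQ file into a data frame of records
#'
#' Parses Sanger/Phred+33 FASTQ via Biostrings, preserving N bases and file
#' order. Malformed files (ragged records, missing `@`/`+` headers,
#' sequence/quality length mismatch) raise a parse error naming the first
#' offending line.
#'
#' @param path FASTQ file path.
#' @return Data frame with columns `read_id`, `bases`, `quality` (quality as
#'   the raw ASCII string).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  validate_fastq_structure(path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      stop(sprintf("FASTQ parse error in '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  data.frame(read_id = names(x) %||% character(length(x)),
             bases = as.character(x),
             quality = as.character(mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

# internal: structural check of 4-line FASTQ records; errors name the first
# offending line (wrapped multi-line FASTQ is out of scope: Illumina-style
# reads are always 4-line records)
validate_fastq_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  if (n == 0) return(invisible(TRUE))
  bad <- function(line, why) {
    stop(sprintf("FASTQ parse error in '%s' at line %d: %s", path, line, why),
         call. = FALSE)
  }
  if (n %% 4 != 0) bad(4 * (n %/% 4) + 1, "truncated record")
  hdr <- seq(1, n, by = 4)
  i <- which(!startsWith(lines[hdr], "@"))
  if (length(i) > 0) bad(hdr[i[1]], "expected '@' header")
  i <- which(!startsWith(lines[hdr + 2], "+"))
  if (length(i) > 0) bad(hdr[i[1]] + 2, "expected '+' separator")
  i <- which(nchar(lines[hdr + 1]) != nchar(lines[hdr + 3]))
  if (length(i) > 0) bad(hdr[i[1]] + 3, "sequence/quality length mismatch")
  invisible(TRUE)
}

#' Primer-trimming policy
#'
#' Flank matching is anchored: the forward primer must match the read prefix
#' and the reverse tail the read suffix, each within `max_mismatches`
#' Hamming distance (substitutions only — no indels inside the constant
#' regions, so the trimmed interior length stays meaningful for the length
#' filter). Optionally the reverse complement of the read is tried when the
#' forward orientation fails.
#'
#' @param forward_primer,reverse_tail Constant flanks (ACGT strings).
#' @param max_mismatches Allowed substitutions per flank (default 2; must be
#'   `< nchar(flank)`).
#' @param try_reverse_complement Retry on the reverse-complemented read
#'   (default TRUE).
#' @return An object of class `trim_policy`.
#' @export
trim_policy <- function(forward_primer, reverse_tail, max_mismatches = 2,
                        try_reverse_complement = TRUE) {
  forward_primer <- toupper(forward_primer)
  reverse_tail <- toupper(reverse_tail)
  assert_dna(forward_primer, what = "forward_primer")
  assert_dna(reverse_tail, what = "reverse_tail")
  if (max_mismatches < 0 ||
      max_mismatches >= min(nchar(forward_primer), nchar(reverse_tail))) {
    stop("max_mismatches must be >= 0 and < flank length", call. = FALSE)
  }
  structure(
    list(forward_primer = forward_primer, reverse_tail = reverse_tail,
         max_mismatches = as.integer(max_mismatches),
         try_reverse_complement = isTRUE(try_reverse_complement)),
    class = "trim_policy")
}

#' @rdname trim_policy
#' @param spec A [library_spec] whose flanks seed the policy.
#' @param ... Passed on to [trim_policy()].
#' @export
trim_policy_from_spec <- function(spec, ...) {
  stopifnot(inherits(spec, "library_spec"))
  trim_policy(spec$forward_primer, spec$reverse_tail, ...)
}

# internal: anchored Hamming mismatch counts of equal-length strings x
# against a single pattern (N counts as a mismatch)
hamming_to_pattern <- function(x, pattern) {
  if (length(x) == 0) return(integer(0))
  pl <- strsplit(pattern, "")[[1]]
  m <- matrix(unlist(strsplit(x, ""), use.names = FALSE), nrow = length(pl))
  as.integer(colSums(m != pl))
}

#' Trim constant flanks off reads, returning random regions
#'
#' Vectorized over reads. A read is accepted when its prefix is within
#' `max_mismatches` of the forward primer and its suffix within
#' `max_mismatches` of the reverse tail (anchored Hamming matching; see
#' [trim_policy()]); the interior substring is returned. Reads failing in
#' forward orientation are retried as reverse complements when the policy
#' allows. Rejected reads (including reads shorter than the two flanks
#' combined) yield `NA`.
#'
#' @param bases Character vector of read sequences (ACGTN; case-insensitive).
#' @param policy A [trim_policy].
#' @return Character vector of random regions, `NA` where rejected.
#' @examples
#' pol <- trim_policy_from_spec(default_library_spec())
#' trim_flanks(paste0("AGCAGCACAGAGGTCAGATG", strrep("T", 25),
#'                    "CCTATGCGTGCTACCGTGAA"), pol)
#' @export
trim_flanks <- function(bases, policy) {
  stopifnot(inherits(policy, "trim_policy"))
  bases <- toupper(bases)
  out <- trim_one_orientation(bases, policy)
  if (policy$try_reverse_complement && anyNA(out)) {
    miss <- which(is.na(out))
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(bases[miss])))
    out[miss] <- trim_one_orientation(rc, policy)
  }
  out
}

# internal: anchored trim in a single orientation
trim_one_orientation <- function(bases, policy) {
  nf <- nchar(policy$forward_primer)
  nr <- nchar(policy$reverse_tail)
  len <- nchar(bases)
  out <- rep(NA_character_, length(bases))
  ok_len <- len >= nf + nr
  if (!any(ok_len)) return(out)
  idx <- which(ok_len)
  pre <- substr(bases[idx], 1L, nf)
  suf <- substr(bases[idx], len[idx] - nr + 1L, len[idx])
  # group by prefix/suffix length classes is unnecessary: both are fixed-width
  dm_f <- hamming_to_pattern(pre, policy$forward_primer)
  dm_r <- hamming_to_pattern(suf, policy$reverse_tail)
  hit <- dm_f <= policy$max_mismatches & dm_r <= policy$max_mismatches
  out[idx[hit]] <- substr(bases[idx[hit]], nf + 1L, len[idx[hit]] - nr)
  out
}

#' Random-region length filter
#'
#' Keeps sequences whose length is within `tol` of `center`; everything else
#' is discarded (the default window 25 +/- 2 tolerates the small indels that
#' PCR and synthesis introduce into a nominally 25-nt random region).
#'
#' @param seq Character vector of trimmed random regions.
#' @param center Nominal random-region length (default 25).
#' @param tol Allowed deviation in nt (default 2).
#' @return Logical vector: TRUE = keep.
#' @examples
#' length_filter(strrep("A", 22:28))  # FALSE TRUE TRUE TRUE TRUE TRUE FALSE
#' @export
length_filter <- function(seq, center = 25, tol = 2) {
  if (any(!nzchar(seq) & !is.na(seq))) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  abs(nchar(seq) - center) <= tol
}

#' Preprocess one round's FASTQ into a ranked count table
#'
#' Reads a FASTQ file (or takes pre-read records), trims the constant flanks
#' ([trim_flanks()]), applies the random-region length filter
#' ([length_filter()]), and tallies the surviving random regions into a
#' ranked [round_pool]. Reads whose flanks cannot be matched, and reads
#' whose trimmed region contains N (counts must key exact sequences), are
#' tallied as primer rejections; reads trimmed to an out-of-window length as
#' length rejections. Identical reads are deduplicated before trimming, so
#' cost scales with distinct reads.
#'
#' @param fastq FASTQ path, or a data frame from [read_fastq()], or a
#'   character vector of read sequences.
#' @param policy A [trim_policy].
#' @param label Pool label, e.g. `"R1+"`.
#' @param center,tol Length-filter window (see [length_filter()]).
#' @return A [round_pool] with rejection tallies.
#' @export
prep_round <- function(fastq, policy, label, center = 25, tol = 2) {
  bases <- if (is.character(fastq) && length(fastq) == 1 && file.exists(fastq)) {
    read_fastq(fastq)$bases
  } else if (is.data.frame(fastq)) {
    fastq$bases
  } else {
    as.character(fastq)
  }
  if (length(bases) == 0) {
    return(round_pool(label, integer(0)))
  }
  tab <- table(toupper(bases))
  uniq <- names(tab)
  n_per <- as.integer(tab)

  region <- trim_flanks(uniq, policy)
  has_n <- !is.na(region) & grepl("N", region, fixed = TRUE)
  region[has_n] <- NA_character_
  rej_primer <- sum(n_per[is.na(region)])

  ok <- !is.na(region)
  keep_len <- logical(length(region))
  keep_len[ok] <- length_filter(region[ok], center, tol)
  rej_length <- sum(n_per[ok & !keep_len])

  kept <- ok & keep_len
  counts <- integer(0)
  if (any(kept)) {
    agg <- tapply(n_per[kept], region[kept], sum)
    counts <- setNames(as.integer(agg), names(agg))
  }
  round_pool(label, counts,
             n_rejected_primer = rej_primer, n_rejected_length = rej_length)
}
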