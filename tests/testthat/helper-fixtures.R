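# Small library spec for fast simulations: short flanks, short random region.
tiny_spec <- function(random_len = 8) {
  library_spec(forward_primer = "ACGTACGTAC",
               reverse_tail = "TTGGCCAATT",
               random_len = random_len)
}

# The four aptamer candidate random regions characterized in vitro (25-26 nt),
# used as known-composition example sequences throughout.
candidate_regions <- c(
  apt_1  = "ACTAGCTCCGATCTTTCTTATCTAC",
  apt_2  = "CACTCTTTCATTTTATTTATAATTAT",
  apt_3  = "TTCAATATTACTTATCTTTTTTTTT",
  apt_12 = "TGCCTTATTACTCTCTCCTGTTAAC")

# A deterministic small set of round pools for enrichment tests:
# round 0 plus n selection rounds over a fixed sequence universe.
toy_pools <- function(counts_by_round, labels = NULL) {
  n <- length(counts_by_round)
  if (is.null(labels)) labels <- c("R0", paste0("R", seq_len(n - 1), "+"))
  mapply(function(cts, lab) round_pool(lab, cts),
         counts_by_round, labels, SIMPLIFY = FALSE)
}
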