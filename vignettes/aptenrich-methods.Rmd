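---
title: "Models and methods behind aptenrich"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aptenrich}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptenrich)
```

# Scope

`aptenrich` analyzes high-throughput sequencing of SELEX experiments: it
turns per-round FASTQ files into ranked, clustered aptamer candidates, and
fits saturation binding isotherms to titration data. This vignette explains
the models, the tunable parameters and their defaults, the numerical
choices, and what the bundled simulator can and cannot validate. It states
no results beyond what the package's tests compute.

# Read preprocessing

## Primer trimming

Library molecules are `forward_primer + N-mer random region + reverse
tail` (the tail is the reverse complement of the reverse PCR primer, as it
appears in read orientation). Trimming is **anchored**: the forward primer
is matched against the read prefix and the tail against the suffix, each
within a Hamming distance of `max_mismatches` (default 2 per 20-nt flank,
i.e. 10% per flank). Substitutions only — no indels are allowed inside the
constant regions. The reasoning: an anchored match keeps the interior
length exactly interpretable, so the downstream length filter does all the
work of absorbing the small indels that PCR and synthesis introduce; a
gapped primer match would silently shift interior coordinates. Reads
failing both orientations (the reverse complement is retried by default)
count as primer rejections and are never partially trimmed, which keeps
length-rejection statistics uncontaminated. Trimmed regions containing `N`
are also counted as primer rejections, because count tables must key exact
sequences. Input is case-insensitive; storage is uppercase.

## Length filter

Trimmed regions are kept when their length is within `tol` of `center`
(default 25 ± 2 nt). The window is a configurable parameter: some reported
analyses tolerate only ±1, but ±2 is the more inclusive convention for an
N25 design and is the package default; narrow it via `length_tol = 1` when
stricter behavior is wanted.

## Duplication metric

`duplication_percent` is `100 · (1 − distinct/total)` over the accepted
reads of a pool — the fraction of reads that are not unique, the headline
number of FastQC-style duplication reports. It is a reimplementation of
that summary on the trimmed count table, not a FastQC clone (FastQC
estimates from the first 100k reads and bins by duplication level); the
qualitative behavior — rising duplication as selection collapses diversity
— is what the number is used for here.

# Enrichment and the compScore

Frequencies are used instead of raw counts because sequencing depth differs
across rounds; a sequence's frequency in round *i* is `R_i = count /
accepted reads`. Fold enrichment is `R_i / R_0` against the unselected
library (round 0), and the composite score is

$$\mathrm{compScore} = \log_{10}\left[\left(\prod_{i=1}^{n}
\frac{R_i}{R_0}\right)\cdot\frac{R_n}{R_0}\right]$$

the log10 of the product of every round's fold enrichment with the final
round — the round under the most stringent selective pressure — counted
twice. It is computed in log space (`sum(log10(fold)) + log10(fold_n)`) to
avoid overflow for strongly enriched sequences; a brute-force product
evaluation agrees to 1e-12 in the test suite.

**Pseudocounts.** Round 0 samples the library at depths far below its
diversity, so winning sequences are routinely unobserved there, making
`R_0 = 0` and the score infinite. Under the default
`pseudocount_policy("add_constant", 0.5)`, every frequency is computed as
`(count + 0.5) / (total + 0.5)`, keeping each per-sequence frequency
strictly positive while changing observed frequencies negligibly at
realistic depths. The `reject` mode disables the adjustment and errors on
zeros, for analyses that prefer explicit handling. Sequences absent from
the **final** round cannot be candidates regardless of pseudocounting; they
receive a `-Inf` sentinel and are excluded from ranking.

**Which pools.** Enrichment runs over round 0 plus the bound (+) pools:
the bound fraction is what is carried forward between rounds, so it is the
population on which selective pressure acts. Unbound (−) pools are
preprocessed and tallied for diagnostics (their duplication trend is
informative) but do not enter the score.

**Determinism.** All rankings break ties by a secondary metric
(`final_fold` for compScore ranks and vice versa) and then ascending
lexicographic sequence order, so every table is reproducible byte for byte.

# Clustering

Identity between two sequences follows the CD-HIT-EST convention: the
number of matched bases in the best global alignment divided by the length
of the **shorter** sequence. The alignment maximizes matches under unit
match score, zero mismatch score, and a linear gap penalty (default 1 per
gapped position). The metric had to be pinned down somewhere: identity
thresholds are only meaningful relative to a fixed alignment convention,
and this is the documented one for the tool the field uses. When distinct
optimal alignments tie in score, the alignment engine's choice decides the
match count; the test suite therefore cross-checks the alignment *score*
against an independent dynamic-programming oracle and pins identity values
on unambiguous (ungapped-optimal) instances.

Clustering is the greedy representative scheme: scan sequences in
descending enrichment order; join the representative of highest identity if
that identity is ≥ 0.8 (ties to the lowest cluster id), else found a new
cluster. Enrichment ordering (rather than CD-HIT's length ordering, which
is nearly degenerate for fixed-design libraries) makes each representative
the most enriched member of its cluster — the natural candidate to
characterize. Sequences are clustered with primers attached; the 40
identical flanking nt mean two 25-nt random regions need roughly half their
positions to co-align for the 65-mer identity to reach 0.8, so the
threshold is permissive by design — clusters group related *motifs*, not
near-duplicates. No word-count prefiltering is used: at the ~1000-sequence
scale fed to clustering, all-pairs-to-representative alignment is fast, and
fidelity to the definition beats speed.

# Candidate reporting and library arithmetic

Candidates are the top-k sequences by compScore, named
`<prefix>_<enrichment rank>` where the rank is by final-round fold
enrichment over all sequences (so `APT_1` is the most enriched sequence in
the final round, whether or not it tops the compScore list). Composition
percentages are reported as integers (`round()`); exact values are
available from `base_composition()`. Library statistics are exact —
`diversity = 4^N` is representable exactly in doubles up to N = 26,
molecules are `pmol · 1e-12 · 6.02214076e23` — with the conventional
one-significant-figure presentation (`format_sig1`) applied only for
display.

# Binding isotherms

Titrations are fit to the simplified single-site saturation isotherm
`response = constant · T/(Kd + T)` by unweighted Levenberg–Marquardt least
squares, with starting values `Kd = median(T)` and `constant =
max(response)`. The simplified form (no ligand-depletion quadratic) is
appropriate when the target is quantified in immunoassay units: U/mL and
molar aptamer concentrations cannot be combined in one conservation
equation, so the aptamer concentration is accepted in configuration but
deliberately unused. Standard errors are Wald errors from the fit
covariance; no replicate weighting is applied because replicate structure
is typically shallow (duplicate–quadruplicate wells). Non-convergence and
degenerate data (e.g. all-zero responses) set `converged = FALSE` with a
diagnostic rather than raising.

Responses are deltas against the zero-concentration point. For
fluorescence anisotropy, `r = (I∥ − g·I⊥)/(I∥ + 2g·I⊥)` (the standard
definition; g-factor default 1) and the fitted response is `r − r0`. For
APCE, the measured free-aptamer peak *falls* with target concentration
while the isotherm's right-hand side rises; the package reconciles the two
by fitting the depletion `ratio(0) − ratio(T)` by default, with
`fit_raw_ratio` available as a switch for users who prefer the raw
convention.

# The simulator and what it validates

`selex_sim` exists so that every downstream stage has testable ground
truth. Its model is deliberately minimal:

* Each sequence has a latent affinity `a ∈ [0, 1]`, interpreted as a
  per-wash retention probability; a molecule survives `w` washes with
  probability `a^w`. This is the simplest monotone link between wash count
  and selective pressure — no kinetic or equilibrium model is implied.
* PCR amplification and sequencing depth are collapsed into one multinomial
  resampling of the retained molecules to a fixed read count. PCR byproduct
  formation, amplification bias and barcode handling are bench artifacts
  outside the model.
* Sequencing error is off by default; an optional per-base substitution
  rate (0.001 is a typical setting) exercises the duplication metric's
  sensitivity to near-duplicate reads.
* Quality scores are constant (Q30) because the analysis never consumes
  quality values.
* Every stochastic operation takes an explicit seed and restores global RNG
  state; there is no hidden state anywhere in the package.

The default experiment plants 3 winners (affinity 0.9) among 10^4 distinct
background sequences (affinities uniform on 0.05–0.55, mean 0.3) at 10^5
reads per pool over the 4-round, 6/9/12/15-wash schedule. These scales were
chosen to make per-sequence starting copy numbers (~10) and round-over-round
enrichment ratios realistic for a desk-scale emulation while keeping the
full 10-seed recovery experiment in the test suite under a minute; real
selections sequence millions of reads against libraries of ~10^15, so
absolute duplication levels and round-0 frequencies differ by orders of
magnitude. Consequently the tests assert *structural* properties —
planted winners reach the top of the compScore ranking, bound-pool
duplication is non-decreasing across rounds, molecule counts are conserved
before resampling — and never the absolute duplication percentages or read
totals of any real experiment. A passing suite shows the pipeline's logic
is sound under the model's assumptions, not that the retention model
captures real binding kinetics.

The `tiny` fixture (300 background sequences, 5000 reads/pool) uses a depth
at which each planted winner starts with ~16 copies; at much lower depths
winner lineages can stochastically go extinct in round 1, which is a real
feature of shallow selections but an unhelpful one in a smoke-test fixture.

# Degenerate inputs and edge behavior

* Empty FASTQ files parse to empty record sets; malformed records raise
  errors naming the offending line.
* Reads shorter than the combined flanks are rejections, not errors.
* Empty pools: `duplication_percent` errors (undefined); `simulate_round`
  refuses an empty input pool; a bound pool can legitimately resample to
  emptiness only when no molecule survives, in which case it is returned
  empty rather than invented.
* `comp_score` on any zero fold enrichment errors with a pointer to the
  pseudocount policy rather than returning `-Inf` silently.
* Isotherm fits require ≥ 4 distinct concentrations; with fewer the problem
  is under-determined for a 2-parameter curve plus noise estimation.

# Known limitations

* The greedy clustering is order-dependent by construction (as is
  CD-HIT's); a different input ordering can change cluster boundaries.
* Identity at score-tied alignments inherits the alignment engine's
  tie-break; thresholds exactly at a tie boundary can differ from other
  implementations by one match.
* The isotherm module fits single-site binding only — no Hill coefficients,
  two-site models, or ligand depletion.
* The simulator does not model secondary structure, inter-sequence
  competition for binding sites, or PCR efficiency differences; enrichment
  in the simulation is driven purely by the planted affinity landscape.
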