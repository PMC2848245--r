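---
title: "Quantifying LTR retrotransposon transcription under multi-mapping ambiguity"
author: "ltrquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying LTR retrotransposon transcription under multi-mapping ambiguity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Long terminal repeat (LTR) retrotransposons occur in compact fungal genomes
in two forms: full-length elements, whose internal coding sequence (reverse
transcriptase, RNase H, integrase) is flanked by two near-identical LTRs,
and solitary LTRs left behind by recombination between the two LTRs of a
full-length copy. In fission yeast the full-length family members are
nearly identical to one another, and the solitary LTRs share common
ancestry, so a short sequencing read or a 60-mer tiling probe rarely
identifies a single genomic locus. Any attempt to measure *which* LTR loci
are transcribed, and *how much*, must therefore treat multi-mapping as a
first-class feature of the data rather than a nuisance to be filtered away.

`ltrquant` implements an analysis built around that constraint:

1. partition annotated LTR features into full-length elements and solitary
   LTRs;
2. map reads and strand-tagged probes by **exact** matching on both genome
   strands, keeping only queries whose hits are confined to the analysis
   set (exclusive) or to a single locus (unique);
3. bracket per-locus activity between an equal-split scenario and a
   per-locus upper bound;
4. project signal onto family alignments and flank coordinate frames;
5. test locus-level expression variance and LTR-gene time-course coupling
   with dedicated permutation procedures.

A synthetic-data generator emulates all the input types with known ground
truth, so every stage is testable without external downloads.

## Genome model

Coordinates are 0-based half-open throughout; GFF3's 1-based inclusive
convention is converted at the I/O boundary only. This makes interval
arithmetic (lengths, containment, complements) free of off-by-one
corrections.

`partition_ltrs()` pairs each retrotransposon internal sequence with the
nearest LTR on each side, within a `gap_tol` of 50 bp by default. The
tolerance is an annotation-dependent choice: curated annotations place
flanking LTRs immediately adjacent to the internal sequence, so any small
positive tolerance gives the same answer; 50 bp absorbs minor annotation
slack without ever bridging unrelated features, which in practice sit
hundreds of base pairs away. A chimeric
LTR-internal-LTR-internal-LTR arrangement is modelled as **two elements
sharing the middle LTR**: each internal sequence with both its nearest
LTRs defines an element, and the shared LTR appears once as a locus while
being referenced by both elements. This bookkeeping is what makes 13
elements hold 25 rather than 26 element-resident LTRs. An internal
sequence lacking an adjacent LTR on either side is excluded with a warning
and its neighbours stay solitary.

Background reference sets follow the rule of omitting 240 bp on both sides
of protein-coding genes (putative UTRs) from intergenic sequence and
keeping only pieces of at least 100 bp. Retrotransposon internal regions
are subtracted along with LTRs, tRNAs and snoRNAs: retroelement coding
sequence is not intergenic by any definition, even though it is the LTR
features that delimit it.

## Exact mapping and exclusivity

Only perfect matches count; queries containing an ambiguous call (N) are
dropped and logged. A query hits the forward strand where its sequence
occurs verbatim and the reverse strand where its reverse complement
occurs. Palindromic queries would otherwise be reported twice per
position; they are deduplicated to a single forward-strand hit
(configurable).

A hit is *in-set* only when its full interval lies inside one feature of
the target set — partial overlap is out-of-set. This is the strictest
reading of "mapping within a sequence set" and matches probe-level
resolution: a probe half inside an LTR does not interrogate the LTR's
transcript cleanly. With all hits in-set a query is `unique` (one hit) or
`exclusive` (several); any stray hit excludes it. For solitary-LTR probes
and for all non-LTR reference features the stricter `unique_only` mode
demotes exclusive records to excluded.

The matching engine seeds candidate positions with a fixed-width
dictionary over query prefixes and verifies every candidate against the
full query, so its semantics are exactly those of a naive every-offset
scan; the test suite asserts that equivalence on random genomes, both
strands, including planted multi-copy queries.

Reads are matched strand-agnostically (the library protocol does not
preserve strand) and probes report transcription on the strand they are
tagged with: only the direct-hybridization assay resolves strand.

## Bounding per-locus activity

Two assignment scenarios bracket the unknown truth:

* **equal_split** — a query hitting *k* loci contributes `signal / k` to
  each (a read shared by two LTRs is worth 0.5 read to each). Summed over
  loci this conserves the total assigned signal; it is exact if all family
  members are transcribed equally.
* **single_locus_max** — each locus is granted the full signal of every
  query that *could* map to it. This is computed independently per locus,
  deliberately not as one globally consistent allocation: the quantity of
  interest is a per-locus upper bound ("if one locus produced everything
  it could, how much would that be?"), and a consistent joint allocation
  would pose an assignment-optimization problem the analysis never needs.
* **unique_only** — uniquely mapping evidence is a floor.

For every locus `unique_only <= equal_split <= single_locus_max`; the test
suite asserts the bracketing on random instances and checks
`single_locus_max` against brute-force enumeration of all single-locus
allocations.

For probe intensity *distributions* the per-probe analogue divides each
probe's intensity by its number of possible mappings (hits). Intensities
are log2 ratios against background and may be negative; conservation
properties are therefore asserted on read counts only.

Read abundance is summarised both as density (count per bp) and as log10
of the absolute count. Under 3'-biased protocols (cDNA primed with
poly(dT)) reads concentrate near the 3' end, so counts do not grow with
transcript length and density systematically penalizes long transcripts —
full-length retrotransposons among them. The log-count is the
length-unbiased measure; the generator-based test demonstrates the bias
and its absence directly. The default pseudocount of 1 only matters for
zero-count loci, which the analysis sets of interest do not contain.

## Alignment projections, clustering and flanks

Pairwise identity comes from a global alignment with match +1, mismatch
-1, gap -2 per gapped position, and is defined as matched positions over
*all* aligned columns — gap columns count in the denominator. This
penalizes length differences, which is the desired behaviour when
deciding whether two LTR copies belong to one alignable family.
Solitary LTRs are clustered by single linkage at a 70% identity cut-off:
clusters merge whenever *any* member of one is similar enough to any
member of another. Output order is canonical (clusters by smallest member
id), so clustering is invariant to input order.
`cluster_threshold_sweep()` reports cluster counts and largest-cluster
size across thresholds — the diagnostic used to choose a cut-off by
watching where cluster sizes change — without codifying a selection rule.

Mappings are projected onto alignment columns by taking the midpoint
residue of the hit on the chosen row and transferring it through the
row's residue-to-column map. For even-length queries the midpoint takes
the left-of-center residue (`floor((start + end - 1) / 2)`); the choice is
arbitrary but fixed. When a query hits several rows, the "first instance"
in the supplied row order is used. The aligned input is consumed as
given: the package does not re-implement a multiple aligner (an optional
`align_external()` hook can call one, e.g. mafft), and the generator's
substitution-only families are already valid alignments at equal length.

Flank coordinate frames take up to 500 bp on each side of a solitary LTR;
if another annotated feature sits closer than 1000 bp only half the
distance is used, and when that half drops below 60 bp the side gets no
flank at all. Flanks truncate at chromosome edges. The flank contrast then
compares uniquely mapping probe intensities inside LTRs with each flank
compartment via one-sided Mann-Whitney tests (flank lower than in-LTR), U
reported for the flank group so that complete separation yields U = 0.

The sliding-window density over alignment columns (default 301 columns,
odd by construction) divides per-column counts by the number of aligned
sequences. At the alignment ends the window truncates and the average is
taken over the columns actually available — this keeps a uniform profile
exactly flat at the edges, at the cost of a single isolated count
producing slightly higher values near an edge than in the interior. The
direct-loop oracle in the tests uses the same definition.

## Permutation machinery

**Mann-Whitney.** U for the first-named group counts pairs won, ties 0.5.
For `n_x + n_y <= 12` the p-value is computed by exhaustive enumeration of
all group assignments of the pooled values (ties handled exactly); larger
samples use the normal approximation with tie and continuity correction
(delegated to `stats::wilcox.test`). The acceptance suite verifies that
the two paths agree in U exactly and in p within the approximation error
observed at these sample sizes (about 0.1 absolute).

**Between-locus variance test.** The statistic is the sample variance
(n-1 denominator; the field's default estimator) of per-locus mean probe
intensities, forward and reverse strands as separate invocations. Null
sets shuffle the pooled intensities while preserving each locus's probe
count. When the count-preserving assignment space is small (at most 1e5
distinct assignments) the null is enumerated exhaustively; otherwise
10,000 random shuffles are drawn by default. The reported p uses the
add-one convention `(1 + #{null >= observed}) / (N + 1)` in both modes —
in exhaustive mode the observed assignment is itself a member of the
enumerated space, so the convention stays consistent and the p-value for
the three-assignment toy instance is (1+2)/(3+1) = 0.75. The test is
calibrated: over 1000 simulated null data sets (20 loci x 5 probes,
Gaussian intensities) the rejection rate at alpha = 0.05 falls inside the
95% binomial interval, and a single locus shifted by 3 pooled SDs is
detected with over 80% power.

**Time-course coupling test.** LTR-gene pairs are selected by uniquely
mapped read counts (at least 30 over all stages, at least 10 in growth
phase) and position (within 1000 bp upstream of a protein-coding gene,
relative to gene orientation). Each profile is the log2 ratio of a
meiosis stage's count to the growth count; growth itself is the baseline
and excluded from correlations, so each pair contributes five points. The
observed statistic is the median over pairs of the per-pair Pearson
correlation. Null sets shuffle the LTR values among LTRs *within each
stage* independently, keeping the per-stage value multisets intact, and
record the median correlation against the unshuffled gene profiles. The
two-sided p doubles the smaller tail proportion (`count / n_perm`),
floored at `1 / n_perm` — one exceedance among 10,000 permutations
reports 2e-4. Log-ratio pseudocounts default to 0 because the selection
thresholds guarantee nonzero growth counts; a configurable pseudocount
handles zero stage counts (e.g. an empty stage library), and pairs with
non-finite ratios are otherwise dropped with a log message.

Set-level stage profiles divide reads mapping exclusively to an LTR set
by the stage's total library size before forming log2 ratios against
growth, making stages with different sequencing depths comparable.

## The synthetic-data generator

`generate_genome()` plants, on i.i.d. uniform background sequence (no GC
model — none is needed for exact-matching behaviour), a family of
full-length elements (ancestral LTR and internal sequence, per-element
private substitutions, the two LTRs of an element nearly identical),
optionally one chimeric LTR-int-LTR-int-LTR arrangement, solitary LTRs
drawn from the same LTR ancestor at 10% divergence (alignable, clusterable
at 70%, yet rich in unique 60-mers), genes with introns, and a few tRNAs
and snoRNAs. Transcripts run from the middle of the 5' LTR to the middle
of the 3' LTR for elements (the transcription start sits roughly halfway
into the LTR), span exactly the LTR for solitary loci (both strands), and
are spliced for genes. Element sense transcripts and mRNAs are
polyadenylated; solitary-LTR and antisense transcripts are not, and the
poly(A)-selection mode downweights them by a configurable factor (default
0.1).

Probe intensities follow `log2((sum of rates of same-strand transcripts
containing the probe + b) / b)` plus Gaussian noise (default SD 0.25 on
the log2 scale), with `b` the background rate — a locus transcribed at the
background rate yields intensity exactly 1 in the noise-free limit. Reads
are Poisson per transcript with mean `rate x stage multiplier x depth`,
lengths uniform on 30-51 nt, and start positions weighted by
`exp(beta x relative position toward 3')`. The exponential form of the
bias law is an artifact choice — the real protocols document only the
existence and direction of the 3' bias — and `beta = 0` recovers uniform
starts exactly, which the tests verify distributionally. A small fraction
of reads receives an injected N to exercise the ambiguity filter.

The **hot-locus regime** (`hot_fraction`) concentrates a configurable
share (default 95%) of the family-wide rate in a few elements. By default
(`hot_diverged = TRUE`) the private substitutions of the family are
carried by the hot elements while the cold copies remain identical to the
family consensus. This mirrors the situation in fission yeast, where most
full-length copies are recent, nearly identical duplicates and the
uniquely probed, sequence-distinguishable copies are also the
transcriptionally active ones; without that coupling unique probes would
mostly interrogate silent consensus copies and carry no signal about the
hot minority, and no probe-level analysis could recover it. The per-element
divergence default in the hot-regime tests (0.004 per site)
keeps the uniquely mapping fraction of 60-mer probes near 4-5%, the
resolution regime typical of a young retrotransposon family such as Tf2
(copies well above 99% identical).

What the generator deliberately does **not** model: sequencing errors and
quality scores, paired ends, indel divergence (so family members stay
equal length and alignable by construction), GC composition, and any
repeat structure beyond the planted families. Passing tests therefore
demonstrate the correctness and calibration of the *procedures* under
controlled conditions, not robustness to alignment gaps, error-containing
reads or genomic base composition — on real data those effects are
absorbed by the exact-match filters (an error simply unmaps a read).

Stage multipliers are log2-normal per locus and stage (SD 1 by default);
for planted LTR-gene pairs the gene's multipliers correlate with the
LTR's at `gene_coupling_rho`. A lightweight count-level generator
(`simulate_coupled_profiles()`) draws Poisson counts around those
multipliers directly and is used for the statistical calibration studies,
where thousands of replicates at sequence level would add nothing but
runtime.

## Problem sizes and seeds

All tests run on desk-scale instances chosen to keep the full suite in a
few minutes while leaving the statistical assertions well-powered: toy
genomes of 40-100 kb with 2-13 elements and 6-40 solitary LTRs; 1000
random queries against the naive-scan oracle on two chromosomes totalling
100 kb; 50 sequences for the clustering closure check; 1000 null and 500
shifted data sets at 199 permutations each for the variance-test
calibration (the add-one p at 199 permutations gives an exact 0.05
rejection mass under the null); 500 replicates at 400 permutations for
the null-uniformity of the coupling test; and 2000 permutations for the
single coupled recovery run. Every stochastic test fixes its seed; the
generator guarantees byte-identical outputs for identical seed and
configuration.

## Limitations

* The exclusivity filter is binary: a single stray exact hit discards a
  query even if that hit lies in an unannotated copy of the family.
* `single_locus_max` bounds each locus independently; summing it over
  loci overcounts by design.
* The variance test conditions on the observed per-locus probe counts;
  it does not model probe-level spatial correlation within an LTR.
* The coupling test's null preserves per-stage marginals but assumes
  exchangeability of LTRs within a stage; strong shared trends across all
  LTRs are part of the null, not the signal.
* Identity scores from global alignment with fixed scores are not
  evolutionary distances; the 70% threshold is a pragmatic clustering
  cut-off, not a phylogenetic statement.
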