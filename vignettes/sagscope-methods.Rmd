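---
title: "Methods: marker completeness, fragment recruitment and comparative proteomics for single amplified genomes"
author: "sagscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker completeness, fragment recruitment and comparative proteomics for single amplified genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and scientific setting

Single amplified genomes (SAGs) are partial genome assemblies obtained
from individual flow-sorted cells after multiple displacement
amplification (MDA). They are the main window onto uncultivated
lineages such as the Marine Group I Thaumarchaeota that dominate the
dark ocean, but they come with two structural problems: each assembly
recovers an unknown fraction of its genome, and each cell is a single
point sampled from a diverse wild population. `sagscope` implements
the comparative analyses that deal with both: marker-based
completeness estimation, metagenomic fragment recruitment, BLAST Score
Ratio (BSR) proteome partitioning, zero-recruitment genomic-island
calling with COG-category enrichment, and SSU rRNA phylotype
clustering.

Because the real cell-sorting and sequencing data behind such studies
are far beyond desk scale, the package carries a first-class
synthetic-data module. Every generator is a pure function of its
arguments including a seed, and every generator emits ground truth
(source intervals, junk-read classes, planted marker sets, homology
labels, shielded islands) out-of-band, in sidecar tables that the
analysis code never reads. All empirical statements in this vignette
are computed by the test suite or by `scripts/acceptance.R`; nothing
here is quoted from external data.

# Marker-based completeness

## Model

Let an occurrence matrix record, for a collection of finished
reference genomes, the copy number of every gene family (COG-style
annotation is an input, not computed here). A conserved single-copy
gene (CSCG) is a family present *exactly once* in at least a fraction
$t$ of the genomes; the default $t = 0.98$. Completeness of an
assembly is then

$$\hat{c} \;=\; \frac{\lvert \text{CSCGs detected} \rvert}{\lvert \text{CSCGs} \rvert},
\qquad
\widehat{G} \;=\; \frac{L_{\text{assembly}}}{\hat{c}},$$

with $\widehat{G}$ the genome-size estimate. Three deliberate choices:

* **Ceiling rule.** "98% of the genomes" is a count of genomes, so the
  cutoff is $\lceil t\,n \rceil$; rounding down would admit families
  absent from more than $1 - t$ of the references.
* **Presence/absence detection.** A marker found in several copies
  (a common MDA artifact) counts once. `estimateCompleteness()` can
  therefore never exceed 1 and is never truncated.
* **Size estimator.** $L/\hat c$ is the only estimator consistent with
  the ratio definition of $\hat c$; a completeness of zero leaves the
  size undefined and is reported as `NA`, not infinity.

## What the simulation shows

With 94 markers placed uniformly on a 100 kbp genome and assemblies of
10 contigs, the mean absolute error of $\hat c$ across a completeness
grid of 0.1–0.9 (200 replicates per point) is about 0.01–0.02, and the
median genome-size estimate is within a few percent of truth for
completeness at or above 0.3. The binomial sampling error of 94
markers is the dominant noise source; contig placement adds mild
clustering variance. Real SAGs add biological noise the simulation
does not model — lineage-specific marker loss, chimeric MDA products,
contaminating contigs — so these figures are an upper bound on what
the estimator itself contributes, not a field accuracy claim.

# Read quality control

Four pre-recruitment filters are applied in a fixed order — minimum
length (default 100 bp), ambiguity (any non-A/C/G/T character),
replicate/duplicate removal, trinucleotide entropy — and every read is
accounted under the *first* rule it fails, so `QcReport` counts always
reconcile to the input count. The retained set is order-invariant;
only the attribution of removals depends on rule order.

The entropy score is defined normatively so results are reproducible
without any external tool: for a read of length $L$ with overlapping
3-mer distribution $p$,

$$\text{score} = 100 \cdot
\frac{-\sum_i p_i \log_2 p_i}{\log_2 \min(L - 2, 64)} .$$

A homopolymer scores 0; a read in which all 64 trimers are equally
frequent scores 100; the repeat `ACGTACGT...` scores $\approx 33.3$
(four near-equiprobable trimers, 2 bits of a 6-bit ceiling). The
default threshold of 70 targets the low-complexity artifacts of
pyrosequencing chemistry; random uniform reads of 200 bp or more pass
it with frequency above 0.99, so the filter is sharp against
homopolymer junk without biting real sequence. The filter applies to
all read sets by default and can be disabled (`entropy = FALSE`) for
chemistry without this failure mode.

"Replicate and duplicate" reads are interpreted as the deterministic
triad: exact copy, exact 5' prefix of an already retained read, and
exact reverse complement of one, keeping the first occurrence in input
order. No fuzzy (k-mismatch) collapsing is attempted; `dup_classes`
allows exact-only mode since the inclusion of reverse complements in
historical pipelines is not documented.

# Fragment recruitment

## Aligner

Recruitment asks, per read and per target assembly independently: does
the best local alignment of the read (or its reverse complement) reach
at least 200 alignment columns at 95% identity or more? The scoring
scheme is match +1, mismatch −1, affine gap open −2 / extend −1 —
the weights of the classic BLASTN 1/−1 mode — and identity counts gap
columns in the denominator (the BLAST convention). "Alignment length"
means alignment columns, not read length. Heuristic E-values and
masking are deliberately absent: at desk scale an optimal
Smith–Waterman alignment is affordable, fully deterministic, and
testable against an exhaustive dynamic-programming oracle, which the
test suite does on a thousand random short pairs.

The default engine is a seed-and-extend fast path: exact 14-mer seeds
located through a position index, clustered into diagonal bands, and
each candidate window scored with the same optimal aligner
(`Biostrings::pairwiseAlignment`). A window of ±60 bp around the
seeded diagonal is generous against the few gap columns the scoring
scheme tolerates, and an alignment that passes the 200-column /
95%-identity filter without containing a single exact 14-mer is not a
realistic event (at 5% divergence a 300 bp read preserves ~50
consecutive-14-mer chances). `method = "full"` aligns against whole
contigs and must agree with the fast path — asserted in the tests.
Ties between equal-scoring alignments resolve to the leftmost contig
start, then the + strand.

## Normalization and behavior

The abundance of target $g$ in sample $s$ is

$$A_{gs} = 100 \cdot \frac{n_{gs}}{N_s} \cdot \frac{10^6}{L_g},$$

the percentage of the sample's post-QC reads recruited per Mbp of
assembly — the quantity shown in recruitment depth-profile heatmaps.
The post-QC denominator follows from the filters being defined as
removal "from further analysis". Doubling $L_g$ with fixed hits
exactly halves $A_{gs}$; equal-length targets reduce to read-count
ratios.

Because identity is binomial in the population-to-reference divergence
$d$, the recruited fraction of $\ell$-bp reads is approximately
$P\!\left[\mathrm{Bin}(\ell, 1-d) \ge \lceil 0.95\,\ell\rceil\right]$:
near 1 at $d = 0.02$, near 0.5 at $d = 0.05$, near 0 at $d = 0.10$.
The measured fractions track this within a few percent; the small
positive excess at $d = 0.05$ comes from the aligner's freedom to trim
a read's worst-scoring ends. This sharp identity cliff is exactly what
makes the 95% filter a population-resolution instrument.

# BLAST Score Ratio

For every query protein $p$, the self score $S(p,p)$ and the best
local-alignment scores against two reference proteomes are computed
under BLOSUM62 with gap open −11 / extend −1 (the BLASTP default
scheme); the ratios $S(p, R)/S(p,p)$, floored at 0, classify $p$ as
shared with both references, with exactly one, or unique (neither
ratio above the threshold). Following the convention that BSR > 0.4
(roughly 30% protein identity) marks homology, the comparison is
strict. Raw scores, not bitscores, are used in both numerator and
denominator — the ratio is invariant to that choice as long as the two
match, and the substitution scheme is configurable but declared rather
than inferred. Ambiguous residues (X and friends) are rejected
loudly, never silently scored. Non-redundant input construction is
exact-sequence deduplication only; clustering-based redundancy removal
is out of scope.

The synthetic proteome triplet plants homolog pairs at about 90%
amino-acid identity, far above the 0.4-ratio cliff, so end-to-end
category recovery of at least 38/40 on a balanced 10/10/10/10 truth
set is a check of the machinery, not a statement about borderline
homology calls.

# Genomic islands

A coding locus is a putative genomic island when *zero* filtered
recruits overlap any part of it — a single overlapping recruit, even
by one base pair, disqualifies it. This is deliberately conservative
(no fractional-coverage relaxation) to keep false positives out, at
the cost of sensitivity in low-coverage regions; island calls are only
meaningful when surrounding coverage is deep. Recruitment hits from
several metagenomes are pooled before calling, matching the use of a
combined mesopelagic 454 read set. Recruitment is nucleotide-space;
protein loci are carried as intervals (BED at the file boundary,
`GRanges` internally).

Enrichment of the island set in a functional category is tested with
the one-sided hypergeometric tail (the standard exact test for
over-representation of a category in a subset, since no test is
canonical in the source protocols), Benjamini–Hochberg corrected
across the tested categories, flagged at $q \le 0.05$. Under null
simulations (islands drawn uniformly from the background) the fraction
of raw $p \le 0.05$ category tests stays in the 4–5% range, within the
expected type-I band; the discreteness of the hypergeometric makes the
test slightly conservative.

In the simulation, islands are planted by *shielding* intervals from
read generation; shields extend 10 bp past the designated locus so a
read ending flush against an island cannot leak alignment columns into
it through a chance-matching end. With about 20× coverage outside the
shields, sensitivity and specificity are both exactly 1 — again a
machinery check: real islands are defined against a wild population,
not a generator, and coverage there is never uniform.

# Phylotypes and screening tables

SSU rRNA sequences are clustered at ≥99% identity by greedy centroid
(representative-linkage) clustering: sequences in decreasing length
order (ties by id) either join the first phylotype whose
representative they match at or above threshold or found a new one.
Identity is computed from an ends-free global alignment (match +1,
mismatch −1, gap −2 per column) with terminal-gap columns excluded, so
partial-length amplicons compare over their overlap; internal gaps
count as mismatching columns. Pairwise identity over the overlap is
used (rather than a multiple-alignment column identity) because it is
self-contained and deterministic. Greedy clustering is
order-dependent for chains of sequences straddling the threshold — an
intrinsic property of any greedy scheme — so exact-recovery claims are
made, and tested, only for well-separated mutational clouds.

Screening summaries tabulate per-site and pooled gene-detection counts
with nearest-integer percentages, rounding halves away from zero; the
six worked percentages of the two-station amoA/nirK screen (60/48,
81/62, 69/54) reproduce exactly under this rule.

# The synthetic-data generator

What it emulates: archaeal-like GC content (~34%), SAG assemblies
spanning the 2–95% completeness range, depth-structured community
abundances, population-to-reference divergence of 0–10% (exposed as a
free parameter, since the field value is not established),
pyrosequencing read lengths of 100–800 bp with the four junk classes
the QC filters target, proteomes with shared/specific/unique families,
and designated island loci excluded from the read-generating
population.

What it does not: indels (substitution-only mutation keeps identity
analytically binomial; the aligner's gap handling is exercised
separately), MDA chimeras, quality scores (the filters are
sequence-level only), uneven within-genome coverage, and real
phylogenetic structure. Tests passing on this generator validate the
pipeline's arithmetic and filters, not its robustness to artifacts the
generator does not produce.

Two engineering details matter for exact truth accounting. First,
duplicates are exact copies of earlier *clean* reads, so their QC
attribution is unambiguous. Second, the generator resamples any read
that would accidentally collide with an earlier read under the
duplicate relations (exact / 5'-prefix / reverse complement) — without
this, two reads sampled from the same genome start would make the
truth table and the QC report disagree by construction.

Genomes default to tens of kbp rather than the 1–3 Mbp of real
thaumarchaeal genomes: every statistic in the package is rate-based
and scale-free, and this keeps a full pipeline run in minutes. The
problem sizes used by the tests and the acceptance script — 200
replicates per completeness point, 1500 reads per recruitment
condition, 1000 aligner-oracle pairs, 500 null enrichment simulations,
100 clustering permutations — were chosen once as the smallest sizes
at which the asserted 3-standard-deviation and exact-recovery bands
are statistically comfortable.

# Numerical and degenerate-input policy

* All generators run under an isolated RNG scope: they never disturb
  the caller's random stream, and a single pipeline seed is fanned out
  per stage by stable string hashing (`stageSeed`), so toggling one
  stage never changes another stage's stream.
* Interval conventions: 0-based half-open in every file format (BED,
  truth tables, hit tables) and in user-facing coordinates of
  `localAlign()`; 1-based closed inside `GRanges`/`IRanges`
  containers, converted only at boundaries.
* Empty cases are defined, not errors, where a value exists: an empty
  reference proteome gives all-zero scores; an empty island set gives
  an empty enrichment table with a warning; a completeness of zero
  gives `NA` genome size. Genuinely undefined requests (empty query
  proteome, empty assembly, zero reads in a sample) raise errors.
* Tie-breaks are fixed everywhere randomness could leak in:
  best-alignment ties by leftmost start then + strand; clustering
  order by length then id; category partition by the strict `> 0.4`
  rule.

# Configuration and pipeline

`runPipeline()` executes simulate → QC → completeness → recruitment →
islands → BSR → phylotyping from a single validated YAML/list config
whose analysis defaults are the protocol constants (100 bp, entropy
70, 200 bp, 95%, 0.98, 0.4, 0.99). Unknown keys are rejected and all
range violations are reported together. The run manifest records the
config snapshot, md5 checksums of every output, wall time per stage
and package versions; identical configs reproduce identical checksums,
which the test suite asserts byte-for-byte. A thin command-line
wrapper (`inst/scripts/sagscope`) exposes `run`, `simulate` and `qc`
for shell use; the R functions are the primary interface.

# Known limitations

* The recruitment fast path indexes every contig position; for
  targets far beyond desk scale (hundreds of Mbp) a production system
  would use a sparser index or an external mapper.
* Greedy phylotype clustering is order-dependent near the threshold by
  design; consumers needing order-free behavior should cluster at a
  safety margin from their expected divergence structure.
* The zero-recruitment island rule has no notion of coverage
  sufficiency; callers must check surrounding depth before
  interpreting island calls, as the enrichment stage does not do it
  for them.
* Substitution-only simulation means indel robustness of the
  recruitment thresholds is asserted only via the aligner oracle, not
  end-to-end.
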