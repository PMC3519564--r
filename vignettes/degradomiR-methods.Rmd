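---
title: "Small RNA and degradome analysis with degradomiR: models, parameters and design"
author: "degradomiR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small RNA and degradome analysis with degradomiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degradomiR)
```

# The analysis problem

Plant miRNAs direct endonucleolytic cleavage of their targets at a
fixed register: the slice falls between the target bases paired to
miRNA positions 10 and 11. Degradome (PARE) sequencing reads out the 5'
ends of uncapped decay intermediates genome-wide, so miRNA-guided
cleavage appears as a localized peak of tag 5' ends at the predicted
position. Combining a two-condition small-RNA experiment with paired
degradome libraries lets one (i) catalogue the expressed known and
novel miRNAs, (ii) call which respond to the treatment, and (iii) tie
them to the transcripts they actually slice. `degradomiR` implements
this workflow end to end, with a seeded synthetic-data generator in
place of external downloads.

# Read cleaning and partitioning

Raw reads are insert + 3' adapter. Trimming cuts at the leftmost exact
match of the adapter's first 8 nt (configurable; the full adapter is
used when shorter). The minimum insert length is 15 nt: the removal
rule is "fewer than 15 bases after the adapter cut", so a 15-nt insert
is kept. Reads without the adapter cannot be position-trimmed and are
rejected with their own counter, as are junk inserts — more than 10% N,
one base covering more than 80% of the insert, or tandem dinucleotide
repeats covering more than 90%. These three junk thresholds are
heuristics chosen to catch synthesis/ligation artifacts; all are
configurable. Every input read lands in exactly one place (a unique
sequence count or one rejection counter), an invariant asserted by the
tests on fuzzed input.

Unique sequences are partitioned with a fixed priority — mRNA, then
structural ncRNA (an Rfam stand-in), then repeats, then genome-mapped
miRNA candidates, then no-hit — so classes are disjoint and exhaustive.
Matching is exact substring search on both strands. This is a
deliberate desk-scale choice: it is deterministic, dependency-free and
sufficient for synthetic references; plugging a real aligner behind
`partitionByAnnotation()` is the documented extension point for
genome-scale data. Report tables carry percentages against both the
raw-read and mapped-read denominators because published read-
distribution tables commonly mix the two conventions; emitting both
avoids guessing.

# Hairpin evaluation and the built-in folder

Novel-miRNA evaluation needs a secondary-structure engine. The built-in
folder maximizes a weighted pair count by dynamic programming — G:C
pairs score 3, A:U 2, G:U wobbles 1, with a minimum hairpin loop of 3
unpaired bases — and reports minus the total as an energy-like score.
This is not a thermodynamic nearest-neighbour model; it is a
deterministic, oracle-verifiable stand-in whose optima the test suite
checks against an independent brute-force recursion on hundreds of
random sequences. The contract (`sequence -> dot-bracket + energy`) is
the plug-in point for a thermodynamic folder. Traceback is
deterministic, preferring the leftmost pairing on ties.

A precursor candidate passes when:

* the mature lies on one arm — no complete terminal loop (`(...)`)
  inside the mature span;
* at least 75% of mature bases are paired;
* the region spanning mature and star contains at most one terminal
  loop. When the star span is unknown it is inferred from the mature's
  pairing partners; stray partners rerouted into flanking context are
  excluded by keeping the largest positional cluster (gap > 8 nt splits
  clusters), which keeps the criterion about the duplex rather than
  about unrelated context structure;
* MFEI = (100·|dG|/L)/GC% is at least 0.5. The default is anchored to
  the low end of MFEI values observed for accepted plant pre-miRNA
  hairpins; because the folder's score is a stand-in for dG, the MFEI
  threshold acts as a relative, not absolute, filter and is
  configurable.

Star strands are located from the structure by the Dicer geometry:
each strand's 3' end overhangs the base paired to the partner's 5' end
by exactly 2 nt. With spans $X=(x_1,x_2)$ and $Y=(y_1,y_2)$, the duplex
check is $partner(y_1) = x_2 - 2$ and $partner(x_1) = y_2 - 2$ (exact
by default, tolerance configurable). Reads placing on the opposite arm
within 4 nt of the predicted star start are aggregated as `<name>-p5`
or `<name>-p3`; when star reads outnumber the mature the call is
flagged rather than suppressed, since such loci may have been
mis-annotated as to which arm is the mature.

# Differential expression

With library sizes $N_f$ and $N_t$ (defaulting to total
miRNA-assigned reads, overridable), each library is scaled by
$s_i = \sqrt{N_f N_t} / N_i$, which makes the two scale factors
reciprocal and preserves the geometric mean. Rows are floored on raw
counts — known miRNAs need 10, novel 20 — applied to the **maximum**
across the two libraries: a row passing in either library survives,
which is the reading consistent with published tables that retain rows
like (4, 29). Calling is a pure threshold rule, up if
$\log_2(t/f) > 1$, down if $< -1$; no pseudocount is added, rows with
a zero normalized count on either side are flagged (`zero_norm`)
rather than imputed, and no replicate-based statistics are attempted
(single libraries per condition carry no within-condition variance
information). The `2^{-\Delta\Delta Ct}` helper implements the
standard relative-quantification formula for qPCR validation data.

# Degradome processing and target calling

Degradome tags are the inserts upstream of the first CAGCAG adaptor
occurrence; reads without the motif, or with nothing upstream of it,
are dropped and counted. Tags map by exact sense-strand search; a tag
hitting $k$ transcripts contributes $1/k$ of its count to each
(deterministic and conservative), taking the leftmost occurrence
within a transcript. The per-transcript vector of tag-5'-end counts is
the T-plot profile; `plotTranscriptProfile()` renders it with the
cleavage site marked.

Alignment scoring penalizes mismatches and single-nucleotide bulges by
1 and G:U wobbles by 0.5, doubling penalties within the core (miRNA
positions 2–13 from the 5' end). At most one single-nucleotide bulge
is allowed on either strand — the pricing only defines single-nt
bulges, so larger gaps are out of scope. Alignments above the score
cap (4.5) are discarded and overlapping hits are deduplicated keeping
the lowest score (leftmost on ties). The expected cleavage site is the
target base paired to miRNA position 10; a bulge disrupting the 10–11
register leaves the site undefined and the alignment flagged. Because
a peak may sit one base off the predicted register, the observed site
is taken as the maximum within ±1 nt of the expected position
(tolerance configurable).

Categories are computed over **occupied** positions only (positions
with at least one tag): I means the site equals a unique transcript
maximum, II a shared maximum, III above the median, IV at or below it
(a site with no tags is IV). Computing max/median over all positions
instead would make category III nearly universal on long transcripts.
One consequence worth knowing: adding tags to an *already occupied*
off-site position can only demote a site through the I→IV ordering
(max and median are non-decreasing), but seeding a *previously empty*
position can lower the occupied-position median and lift a borderline
site from IV to III. The property tests state the monotonicity
guarantee for occupied positions. Categories are computed per library;
acceptance applies the per-category score thresholds (I: 4.5, II: 4.0,
III: 3.5, IV: 3.0), so boundary scores such as 3.5 are accepted in
categories II and III but rejected in IV. Site abundance is reported
as a percentage of the transcript's tags and as tags-per-billion,
$tpb = 10^9 \cdot a_{site} / T$ with $T$ the library-wide mapped-tag
total (the denominator choice is recorded here because published tpb
columns cannot be reverse-engineered without the per-library totals).
Cleavage-site coordinates in all outputs are tag 5'-end positions,
equal to the base paired to miRNA position 10.

# The synthetic-data generator

`generateReference()` writes perfect Dicer-style hairpins into random
chromosomes:

```
5'-[A flank]-[C5 ... G]-[AA]-[A loop]-[rc(stem)]-[AA]-[A flank]-3'
```

The mature strand is stem + 2-nt overhang (20–24 nt, arm alternating
5p/3p per locus); the star is the reverse-complement arm with its own
2-nt 3' overhang. The sequence design makes the planted duplex the
*unique* optimum of the base-pair-maximisation folder: flanks, loop
and overhangs are A-runs (A pairs with nothing else present at equal
score) and the stem boundaries are strong C/G blocks, so any
re-routing of a stem pair to an external base strictly loses score.
This matters because the downstream tests assert structural
properties (overhangs, star spans) of the *folded* structure, not the
designed one.

Two-condition abundances plant the study conditions: a base depth of
600 expected reads per mature, four-fold up- and down-regulation for
two thirds of the loci (cycling up/down/unchanged), and a star
fraction of 0.1 — star strands of regulated miRNAs are therefore
regulated alongside, as real p3/p5 strands are. Counts are Poisson
around the expected abundance (the standard count model; variance is
testable), drawn in a documented RNG order so tests can re-derive
them independently. Noise is per read: a junk fraction (homopolymer or
dinucleotide-repeat inserts that still carry the adapter, so they
survive trimming and die in the junk filter, as the report tables
expect) and an adapterless fraction (mature + random filler). Target
sites written into transcripts are reverse complements of the mature
with two mismatches at miRNA positions 16 and 19 — outside the core,
so the alignment scores 2 and is accepted in every category — which
also prevents matures from matching transcripts exactly and being
removed as mRNA during partitioning. Degradome libraries emit
`peakReads` tags at the planted site (opposite miRNA position 10) and
`backgroundReads` tags uniformly over the transcript; with the default
100-over-50 geometry on 500-nt transcripts the planted sites are
category I with overwhelming probability. Tags are fixed 20 nt (PARE
tags are near-uniform in length); the CAGCAG motif is scrubbed from
transcripts so tag extraction is unambiguous.

What the generator does **not** emulate: sequencing errors and quality
scores, RNA degradation kinetics, expression heterogeneity across a
realistic transcriptome, multi-locus miRNA families, or imperfect
(wobble-containing) hairpins. Passing tests on this data demonstrates
the correctness of the pipeline's logic and arithmetic under planted
truth, not its robustness to real-library artifacts such as
sequencing error or cross-mapping between paralogues.

# Pipeline orchestration and reproducibility

`runPipeline()` executes simulate → preprocess → catalog → express →
degradome from a single config with one seed. Per-stage child seeds
are derived as `(seed * 1013 + stageIndex) mod (2^31 - 1)` so any
stage can be rerun standalone and reproduce its part. All string
orderings use locale-independent (radix) sorting, so outputs are
byte-identical across environments; report percentages round half-up
to 2 decimals. Counts reconcile across every stage boundary and the
run report records per-stage counts, the parameter echo and wall
time. The CLI (`inst/scripts/pipeline.R`) is a thin wrapper over the
stage functions; its subcommands compose to exactly the `run` output.

Problem sizes in the shipped tests and acceptance runs: 12 planted
miRNA loci (half entered in the known reference) on three 20-kb
chromosomes, 16 transcripts of 500 nt, ~30k reads per small-RNA
library; oracle checks use 500 random sequences up to 30 nt for the
folder and 300 random miRNA/transcript pairs up to 60 nt for the
aligner — sizes at which exhaustive reference implementations are
feasible and the full suite runs in a few minutes.

# Known limitations

* The folder is a base-pair-maximisation model; energies are
  rank-useful, not thermodynamic. MFEI values are comparable within
  this package, not across folders.
* Exact-substring annotation matching does not model mismatched or
  spliced alignments; it is an extension point, not a general aligner.
* Known-miRNA assignment takes the best reference per query
  (fewest mismatches, then name order); co-optimal multi-family
  assignments are not enumerated.
* Conservation grouping of known miRNAs (conserved vs legume- vs
  species-specific) is treated as a user-supplied annotation, not an
  algorithm.
* Single libraries per condition: the ±1 log2FC rule is a threshold,
  not a statistical test, and should be read accordingly.
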