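---
title: "Methods: mapping-by-sequencing of point mutations and insertions"
author: "mapbyseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping-by-sequencing of point mutations and insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `mapbyseq`, in the spirit of a methods supplement: it
states what each stage assumes, which knobs matter, and what the
simulation-based tests do and do not demonstrate about real data.

## Linkage mapping model

A recessive mutation induced by EMS is mapped by bulked segregant
analysis. The F1 of a cross between the mutant and a non-mutant parent
is selfed; F2 individuals showing the mutant phenotype are pooled and
sequenced. At a biallelic marker with recombination fraction $r$ to the
causal locus, the expected frequency of the mutant-parent allele in the
selected pool is

$$\mathrm{AF}(r) = 1 - r \quad \text{(mutant pool)}, \qquad
  \mathrm{AF}(r) = \tfrac{1 + r}{3} \quad \text{(phenotypically
  wild-type siblings)},$$

both obtained by exact enumeration of the sixteen F1-gamete
combinations conditioned on the pool's selection rule
(`expected_pool_af()`). Unlinked markers sit at $r = 0.5$, hence AF 0.5
in the mutant pool. The mapping signal is therefore a ridge of elevated
(or, depending on design, depressed) AF around the causal locus.

Four experimental designs are supported (`design_spec()`); each fixes
the control sample, the set rule that turns two variant lists into
markers, and the orientation of the AF signal:

| design | cross | background | control | markers | orientation |
|---|---|---|---|---|---|
| A | backcross | reference | parental line | test \\ control | maximise AF |
| B | outcross | reference | polymorphic parent | test ∩ control | minimise AF |
| C | backcross | non-reference | wild-type F2 siblings | test ∩ control | maximise AF(test) − AF(control) |
| D | outcross | non-reference | mutagenized parent | test ∩ control | maximise AF |

For design D the test-only variants are additionally retained as the
EMS-candidate pool; this "test-only" rule is this package's choice where
alternatives (re-calling at higher stringency) would also be defensible.
For designs A, B and D the candidate list is likewise drawn from
test-only variants, since the control there is a parent that cannot
carry the new EMS alleles; design C controls are siblings that *do*
carry them, so candidates come from the full test list.

### Window profile and smoothing

Marker values are averaged in overlapping sliding windows. The window
geometry is not part of the underlying method's definition, so it is
exposed and defaulted as: window size = interval size / 8, step = half a
window, and at least 5 markers per window (windows below that are
flagged empty and excluded from peak calling). The profile is then
corrected by a weighted average over up to six adjacent windows — three
on each side, triangular weights $(4,3,2,1)$ by distance, renormalised
over the non-empty windows actually present, so chromosome edges and
gaps are handled without padding. Triangular weights are the simplest
kernel consistent with "compare up to six neighbours"; the weight vector
is pluggable (`smooth_profile(weights =)`). Constant profiles are fixed
points of the smoother, and the test suite holds the implementation to a
brute-force oracle at $10^{-12}$ absolute tolerance.

The winning window is the argmax of the smoothed, orientation-
transformed profile (`minimize_af` scores $1 - \mathrm{AF}$; design C
scores the stored delta); ties break deterministically to the earliest
chromosome and lowest start. The candidate interval around the window
midpoint defaults to 4 Mb for genomes under 200 Mb, 10 Mb up to 1 Gb and
20 Mb beyond — thresholds chosen so that *Arabidopsis*-, rice- and
maize-sized genomes receive 4, 10 and 20 Mb respectively — and may be
overridden (toy genomes in the tests use 2 Mb and below). Intervals are
shifted, not shrunk, at chromosome ends. Candidates are the EMS-type
(G>A / C>T) variants in the interval with AF ≥ 0.75; the default floor
reflects the homozygous expectation of 1.0 minus sampling and
contamination slack, and every variant genome-wide is still written to
the all-variants report with its EMS flag.

## Variant calling

The internal caller is a deliberate desk-scale stand-in for a full
aligner/caller stack: a 2-bit k-mer hash index (default $k = 16$) drives
seed-and-extend alignment, end-to-end with a mismatch budget (default 3;
reads of at least $(\text{budget}+1)k$ nt get a pigeonhole guarantee
that some seed window is clean, shorter reads fall back to denser
seeding), or local with X-drop extension (drop 12, match +1, mismatch
−3, minimum matched block 20 nt) and soft-clipped ends. Ties break to
the lowest chromosome/position/strand; reads whose best score is shared
by more than 4 locations are unmapped; unique placements get MAPQ 42,
ambiguous ones MAPQ 3.

Pileups keep dense per-strand depth plus sparse non-reference tallies;
N bases are never evidence for either allele. A site is emitted only
when polymorphic under the active stringency preset:

* low — depth ≥ 4, alt reads ≥ 2, alt fraction ≥ 0.15, MAPQ ≥ 0;
* high — depth ≥ 8, alt reads ≥ 3, alt fraction ≥ 0.25, MAPQ ≥ 20,
  alt support on both strands.

The two named levels mirror the common practice of a permissive and a
conservative SNP-selection pass; the numbers themselves are this
package's calibration and every field is configurable. AF is always
recomputed as alt/(ref+alt) from the stored per-strand depths, never
trusted from a file.

For deep-coverage simulations the package fuses read construction,
alignment and pileup reduction in one C++ pass
(`call_from_fragments()`/`simulate_and_call()`): reads are built from
fragment coordinates and an edit list and reduced on the fly, which
avoids materialising millions of R strings. The fused route is held
equal, record for record, to the modular
simulate/align/pileup/call route in the test suite. Its one semantic
difference is documented: sequencing errors are planted on the fragment,
so overlapping mates share them, akin to pre-sequencing template damage.

## Insertion mapping

Junction reads are found by local alignment against the known insert: a
read qualifies when its alignment reaches an insert terminus (tolerance
3 bp) and leaves a soft-clipped end of at least 15 nt; the clipped part
is the genomic probe. Discordant pairs contribute the unaligned mate of
an insert-internal read, with the side inferred from the aligned mate's
strand under inward-facing library geometry. Probes re-align to the
genome end-to-end (mismatch budget 2); junction probes anchor an exact
junction coordinate, discordant probes an interval of width one
insert-size envelope (default 500 bp). A junction probe hitting the
reverse strand flips its genome side (its orientation is tied to the
insert's); discordant probes keep theirs, which is exact for
forward-orientation integrations and swaps the two sides coherently for
reverse integrations, leaving cluster detection and classification
unaffected.

Mapped evidence is clustered by single linkage along each chromosome
(maximum anchor gap 500 bp, minimum support 4). The junction estimate is
the median junction-read coordinate, or the midpoint between the
innermost left and right discordant anchors when no junction read
survived. A cluster is called genuine when its support reaches 6 (paired
data; 4 for single-end), evidence exists on both sides (junction
evidence on both sides for single-end data), and the span is at most
2 kb; anything else is retained as a labelled false positive so the
read-depth histograms can be inspected. None of these thresholds is
dictated by the method's description; they are surfaced in the
configuration and the report.

Coordinate convention: an insert placed "at" position $p$ occupies the
gap before the original base $p$, so the last untouched base is $p - 1$
and the reported junction coordinate is $p$. Partially known inserts are
supported implicitly: probes only arise from termini present in the
supplied sequence.

## The experiment simulator

The simulator is first-class, tested code; its defaults are the
conditions the analyses are designed for. EMS mutagenesis draws distinct
sites, a binomial share `ems_fraction` of them G>A or C>T (both strands
count as EMS-type). Cross simulation uses a uniform genetic map
(default 4 cM/Mb, a plant-like average) with the Haldane map function;
gametes are founder mosaics with Poisson crossover counts and uniform
breakpoints, and phenotypic selection is applied by rejection at the
causal locus. Outcross designs give the distant parent natural
polymorphisms at one per 2 kb. Read simulation samples fragments
uniformly (insert size normal, mean 300 sd 50, truncated at the read
length), emits inward-facing 2x75 pairs by default, plants haplotype
alleles, injects i.i.d. substitution errors, and writes constant Q35
qualities.

What it deliberately does not emulate: repeat structure and composition
bias of real genomes (references are i.i.d. uniform), machine-specific
error and quality profiles, indels, PCR duplicates, and coverage biases.
Passing the recovery tests therefore demonstrates the correctness of the
algorithms under their stated model — not robustness to repetitive
genomes or messy libraries, where the multi-mapping cap and the
stringency presets carry more of the load.

## Problem sizes and determinism

The recovery studies run at the analyses' stated operating points scaled
to desk size: linkage on a 10 Mb single-chromosome genome with 400 EMS
mutations, a pool of 50, error-free 2x75 reads at 25x for test and
control, a 2 Mb interval override and 250 kb / 125 kb windows, over 20
seeds; insertion mapping on a 500 kb genome with three 5 kb inserts at
10x (the advisable per-mutant minimum), both as one triple-insert mutant
and as a pool of three single-insert mutants, over 20 seeds, with a
no-insert control each time. Every stochastic step takes an explicit
seed, RNG state is restored on exit, and all tabular outputs are pure
functions of inputs and configuration — the acceptance suite checks
byte-identity of reports across repeated runs.

## Known limitations

* The linkage workflow reports point mutations only; insertions,
  deletions and rearrangements inside the interval are out of scope, as
  is discriminating which of several insertions causes a phenotype
  (that requires a cross and the linkage workflow).
* The aligner is exact-seeded and ungapped; indels and spliced reads are
  not modelled. Externally produced SAM/VCF (e.g. from a spliced
  aligner for RNA-seq) can be supplied in place of the internal stages.
* The primer designer is a deterministic Wallace-rule heuristic
  (2(A+T) + 4(G+C), GC 40–60%, no homopolymer ≥ 5, product ≤ 800 bp),
  not a thermodynamic nearest-neighbour model; failures are reported
  with a reason rather than silently relaxed.
* Expected pool AFs assume a single recessive causal locus and unbiased
  sampling of gametes; segregation distortion is not modelled.
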