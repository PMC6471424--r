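---
title: "Models and methods behind chaovir"
author: "chaovir authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chaovir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`chaovir` analyses the genomes of headful-packaged viruses — circular
unit genomes packaged as linear, terminally redundant, circularly
permuted virion DNA.  This vignette explains the models the package
implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical conventions we
fixed where the underlying methodology leaves them open.

## The headful packaging model

A packaging model is the quadruple (*L*, *r*, *pac*, series
distribution): unit length in nt, terminal redundancy as a fraction of
*L*, the 1-based position of the packaging-initiation terminal base,
and a distribution over the number of headfuls a single concatemer
yields.  Every virion has length *w* = round(*L*(1 + *r*)).  The first
virion of a series starts at *pac*; virion *k* starts where virion
*k* − 1 ended, so start offsets advance by *w* mod *L*.

`predict_band_table()` classifies each fragment of the circular
digest and computes its **molarity**, defined as the probability that
a randomly drawn virion contains the fragment intact.  A fragment of
length `len` whose first base sits `t` bases into a virion is intact
iff `t <= w - len`; molarity is the probability of that event under a
model of virion starts:

* **series** (default): starts occupy the lattice
  `pac + (k-1) w mod L`, where the probability that a virion is the
  *k*-th headful of its series is `P(S >= k)/E[S]`.  The molarity is
  computed exactly by enumeration over this (at most `max(S)`-point)
  support.  This is the model that matches the gel behaviour of real
  headful virion preparations: the fragment spanning the linearisation point appears only
  when the redundancy reaches past its end, i.e. only in
  longer-than-unit genomes.
* **uniform**: fully circularly permuted starts; molarity has the
  closed form `min(1, (w - len + 1)/L)`.  We use the exact discrete
  count (`+1` in the numerator), which the tests verify against
  exhaustive enumeration over all *L* starts with sequence-level
  containment checks.  A uniform start distribution is the
  infinite-series limit of processive packaging; with short series the
  lattice (series) model and the uniform model genuinely differ, which
  is why both are exposed.
* **fixed**: every virion starts at *pac*; the two deterministic end
  pieces are emitted explicitly as `terminal_submolar` records.  At
  *r* = 0 this reduces to a plain linear digest of the unit genome
  opened at *pac*.

Classes: `core` (molarity 1), `terminal_submolar` (0 < molarity < 1 —
the faint "white triangle" bands), and `junction_only` (spans the
linearisation point; absent from the unit-length linear digest and
emitted only when *r* > 0 — the "blue triangle" bands).  Fragments
with zero molarity are not emitted.  Fragments under 100 nt are kept
but flagged unresolvable, since agarose gels do not separate them.

Cut coordinates refer to the top-strand phosphodiester break, 1-based
("after base *c*"); for non-palindromic sites both strands are
searched and the bottom-strand geometry is mapped to its top-strand
break.  Overhang geometry is stored but ignored for sizing.

`match_gel()` works in log-size space because agarose mobility is
approximately log-linear; the default relative tolerance of 5 % is a
typical agarose sizing error (no standard value exists).  Matching is
greedy one-to-one, so every observed band is consumed at most once;
afterwards a predicted fragment indistinguishable in size from an
already-matched one is marked as sharing that fragment's band, which
is how co-migration shows up on real gels.  `fit_packaging()` scores a
(*pac*, *r*) grid by total unmatched bands; the spacing of the pac
grid bounds the recovery precision, since molarity patterns change
only when the virion-end lattice crosses cut sites.

## Composition statistics

AT skew is `(A − T)/(A + T)` per window (0 where A + T = 0),
accumulated from base 1; window and step default to 500 nt, a
resolution that shows arm-level trends on a 55-kb genome without
window noise.  The underlying pattern — cumulative AT-skew parallels
transcription direction — arises because coding strands are A-biased.

The spacing census pools both strands, sorts records by leftmost
coordinate, and reports the signed gap `start[i+1] − stop[i] − 1`;
"overlapping" means any negative gap.  This operationalisation
reproduces the published count of 31 overlapping pairs on the packaged
85-CDS table.  The census is linear: the circular closure pair across
the origin is not counted.  The printed companion count of "30 CDS
separated by 0–15 nt" is *not* reproducible from the table under any
obvious gap definition (we obtain 29); the census therefore reports
the full gap list so users can apply their own cutoff, and we do not
force agreement.

Stop codons are read as the final codon of each CDS on its coding
strand; a CDS whose final codon is not a stop is excluded from the
counts and listed in an attribute rather than silently dropped —
pseudogene fragments are expected to do this.

## The acidic SDS-PAGE correction

Sequence masses use average (isotope-averaged) residue masses plus one
water, because the quantity is compared with gel sizing, and the
published 42 / 46.1 / 14.8-kDa values are average-mass values.  The
apparent mass adds `len × (276.5 x − 31.33)` Da, with `x` the Asp+Glu
fraction; the shift crosses zero at `x ≈ 0.113` and is negative below
it.  We apply the formula in Daltons with no intermediate rounding
(whether the original analysis rounded first is unstated; final
comparisons are made at 0.1 kDa).  Initiator-methionine processing and other post-translational
modifications are ignored.

## Whole-genome comparisons

**ANIb** follows the standard fragment-based convention: consecutive
1,020-nt query fragments, local alignment against the reference (both
strands; match +1, mismatch −1, gap open 5, extend 2), fragments
retained at ≥ 30 % identity over ≥ 70 % coverage, ANIb = mean retained
identity.  The published values come from a web-server implementation,
so exact equality with any particular server is not expected; the
measure here is asymmetric and
all parameters are exposed.

**genome_diff** anchors the two versions on shared unique 20-mers,
keeps a collinear chain (longest increasing subsequence), aligns the
inter-anchor gaps globally and merges runs of adjacent gap columns
into single indel events — necessary for an 18-base indel to count as
one event, not eighteen.

**locate_pac** transfers a known pac coordinate through a local
alignment of the pac-proximal windows (±300 nt default), requiring
50 % alignment identity for a call; multiple references vote.

**spacer_scan** reports all positions on both strands with at most 2
mismatches (no indels), annotated with the genome arm using a 28-kb
default boundary between the morphogenesis and replication arms.

## Homology, synteny, shading

Protein pairs are aligned by Smith–Waterman under BLOSUM62 with affine
gaps 11/1; E-values use the Karlin–Altschul formula with the published
gapped constants (λ = 0.267, K = 0.041) and an effective database size
equal to the summed target proteome length.  Homologs are accepted at
E ≤ 10⁻¹⁰; pairs with 10⁻¹⁰ < E ≤ 10⁻⁵ are rescued when a locus
within ±2 positions on each genome already holds a strict match — the
"conserved gene neighborhood" relaxation, with both thresholds and the
window exposed as arguments since the original analysis states no
numbers.  Assignment is one-to-one by best bitscore (ties: lower
E-value, then lower locus index); beaten above-threshold pairs are
kept as secondary matches rather than dropped, which is also how
paralogs (e.g. the two tail-fiber copies in a self-comparison) are
surfaced for invertible-region detection.  No compositional-bias
masking is applied by default; strongly biased proteomes can produce
spurious high-scoring pairs, and users can tighten `strict` for that
case.

Translated shading compares all six reading frames through
non-overlapping 100-codon tiles locally aligned against whole frames —
full six-frame Smith–Waterman of two 55-kb genomes is unnecessary at
desk scale.  A tile hit must reach the identity floor (30 % over
≥ 30 aa) *and* a Karlin–Altschul E ≤ 10⁻³; without the significance
filter, 30 %-identity 30-aa alignments arise by chance throughout
compositionally biased sequence.  The scan runs in both directions and
merges the reconciled hits, so the segment set is symmetric by
construction.

## Phylogenetics

Progressive alignment builds a UPGMA guide tree on 3-mer distances and
merges profiles with an affine-gap Gotoh profile aligner (open 10,
extend 1, gap columns score 0).  Distances are p-distances with pairwise deletion, the usual
companion of CLUSTALW-plus-NJ workflows, with a Poisson correction as
an option.  Neighbor-joining follows
the canonical Saitou–Nei agglomeration; a negative branch length is
clamped to zero and its deficit moved to the sister branch, preserving
the path length between the joined pair, so additive matrices are
still inverted exactly.  Bootstrap resamples alignment columns with
replacement, builds one NJ tree per replicate, and returns the
majority-rule (> 50 %) consensus with supports as percentages;
ties resolve toward polytomy, and the whole procedure is deterministic
under its seed.

## The synthetic-data generator

`simulate_genome()` emulates the features the analyses rely on: a
circular genome at a target G+C (halovirus-like 65 % default), a
forward-strand morphogenesis arm, a reverse-strand replication arm, a
short accessory module, TGA-biased stop codons (0.65/0.22/0.12), a
controlled share of 4-nt `ATGA` stop/start overlaps, a coding-strand
A/T asymmetry (default 0.15) that makes cumulative AT-skew parallel
transcription, and an optional invertible region (fiber gene,
integrase, inverted frame-disrupted paralog in two codon-clean
pseudogene fragments).  Genes are sampled at codon level so G+C and
stop-codon bias can be co-controlled; because rejecting AT-rich stop
codons inflates G+C by about one percent, the per-base weights are
corrected by inverting the expected non-stop-codon G+C, and the
realised genome lands within ±1 % of target (re-measured from the
output, never trusted from the generator).  Divergence
(`mutate_family`) is substitution-only by default so identity targets
are exact under global alignment; the protein noise floor is 8 %
identity.  Headful series lengths default to uniform over 1–5
headfuls — the literature gives no distribution — and the redundancy
*r* is a free parameter, likewise unreported for this virus family.

What the generator does **not** emulate: real codon usage tables,
rate heterogeneity or codon models of divergence, repeats and mobile
elements beyond the explicit IS-insertion operation, tRNA genes,
sequencing error, and genuine phylogenetic correlation structure.
Green tests therefore demonstrate algorithmic correctness and
statistical calibration on idealised genomes, not robustness to every
property of real data.

## Problem sizes

The test and acceptance workloads are sized for a desk machine:
synthetic genomes of 2–30 kb, proteomes of 8–16 genes, 10⁵
Monte-Carlo virions for molarity calibration, 100-replicate
bootstraps, and (pac, r) grids of ~200 points.  All operations scale
to real 55-kb genomes; the six-frame shading scan is the slowest
(minutes for a 55-kb pair on one core).

## Known limitations

* E-values use fixed Karlin–Altschul constants rather than per-matrix
  estimation; they are calibrated for BLOSUM62 11/1 only.
* ANIb values differ from server implementations at the percent level
  (different aligners and fragment handling); the published "≥ 74 %"
  bound is the meaningful comparison, not exact equality.
* `locate_pac` assumes the pac-proximal window is alignable
  (≥ 50 % identity); it makes no call otherwise rather than guessing.
* The spacing census and skew profiles treat the deposited linear
  rendition as the frame of reference; only the explicit wrap-around
  record crosses the origin.
* Restriction sites containing long ambiguous stretches (e.g.
  interrupted palindromes with N runs) are matched but overhang
  chemistry is not modelled.
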