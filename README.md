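# chaovir

Comparative genome analysis of headful-packaged archaeal viruses in R.

Tailed viruses of haloarchaea such as *Halobacterium* virus ChaoS9 and
its relatives phiH1 and phiCh1 package DNA by the *headful* mechanism:
a terminase starts filling the capsid at a *pac* site on a genome
concatemer and stops when the head is full, slightly past one unit
genome.  The virion DNA is therefore linear, **terminally redundant**
(a fraction *r* of the unit length *L* is duplicated at the ends) and
**circularly permuted** (different virions open the same circle at
different points), even though the unit genome is a circle.  This
single fact shapes most of the analyses a virologist runs on such a
genome, and `chaovir` implements them end to end for people
characterising new isolates or proviruses:

* **Restriction digest modelling** — for a circular unit genome, an
  enzyme and a packaging model (*L*, *r*, *pac*, headful-series
  distribution), predict the virion population's band table.  Each
  circular-digest fragment gets a class and a molarity
  (P(fragment intact in a random virion)):
  - *core* — present in every virion;
  - *terminal_submolar* — truncated at virion ends in part of the
    population, hence faint or invisible on gels (the "white
    triangle" bands of published digest figures); under uniformly distributed permutation
    starts the molarity has the closed form `min(1, (w − len + 1)/L)`
    with `w = L(1 + r)` the packaged length;
  - *junction_only* — the fragment spanning the linearisation point,
    which only exists in longer-than-unit-length DNA ("blue
    triangle" bands, present only when r > 0).
  `match_gel()` compares predictions with observed band sizes in
  log-space, and `fit_packaging()` estimates (*pac*, *r*) from gels by
  grid search.
* **Composition statistics** — G+C, cumulative AT-skew
  `Σ (A−T)/(A+T)` per window (whose slope tracks transcription
  direction), stop-codon and codon usage, and a census of CDS spacing
  including stop/start overlaps.
* **Acidic-proteome SDS-PAGE correction** — haloarchaeal proteins are
  extremely acidic and run anomalously slowly; the apparent gel mass is
  `MW_app = MW_real + len × (276.5x − 31.33)` Da, with `x` the Asp+Glu
  fraction.  `apparent_mw()` composes translation, average-mass
  computation and this shift; `assign_bands()` matches predictions to
  observed virion protein bands.
* **Whole-genome comparison** — fragment-based average nucleotide
  identity (ANIb: 1,020-nt query fragments locally aligned to the
  reference, retained at ≥30 % identity / ≥70 % coverage), exact-match
  dotplot segments, base-level diffs between genome versions (indel
  runs merged into single events), pac-site transfer by anchored
  alignment, and CRISPR-spacer scans with mismatches.
* **Homology and synteny** — all-vs-all protein alignment (BLOSUM62,
  affine gaps, Karlin–Altschul E-values), one-to-one homolog maps with
  E ≤ 10⁻¹⁰ acceptance plus neighborhood-relaxed rescue of borderline
  genes in conserved gene order, synteny blocks, six-frame translated
  similarity shading, and detection of invertible tail-fiber regions
  (inverted paralogs flanking a recombinase, transposon insertions
  included).
* **Phylogenetics** — progressive multiple alignment, p-distances,
  neighbor-joining, and majority-rule bootstrap consensus trees with
  support percentages.
* **Synthetic data** — `simulate_genome()` builds annotated virus
  genomes with controlled G+C, stop-codon bias, coding-strand AT-skew,
  gene spacing (including 4-nt `ATGA` overlaps) and an optional
  invertible region; `mutate_family()` diverges sequences to an exact
  identity target; `simulate_virion_population()` emits headful virion
  series.  Everything downstream is testable without external data.

The published 85-CDS annotation table of the ChaoS9 genome ships as a
plain-TSV fixture (`inst/extdata/chaos9_cds_table.tsv`).

## Worked example

```r
library(chaovir)

spec <- genome_spec(20000, gc_target = 0.65, seed = 42,
                    invertible_region = TRUE)
sim  <- simulate_genome(spec)
sim$genome
#> <genome> synth: 20,000 nt, circular
round(gc_content(sim$genome), 1)
#> [1] 64.8
stop_codon_usage(sim$genome, sim$features)[1:3]
#> TGA TAA TAG
#>  12   8   2
spacing_census(sim$features)
#> <spacing_census> 23 consecutive pairs: 6 overlapping, 9 separated by 0-15 nt, 8 further apart
```

The genome honours the generator's targets: G+C within one point of
65 %, TGA-dominated stop codons, and closely spaced genes (the 6
overlaps are `ATGA`-type stop/start junctions).

Digest the virion population.  With every virion opened exactly at
*pac* and no redundancy (`r = 0`), the fragment spanning the
linearisation point is split into two end pieces:

```r
sacII <- enzyme_def("SacII", "CCGCGG", 4, 2)
pm0 <- packaging_model(20000, redundancy = 0, pac_position = 46)
bt0 <- predict_band_table(sim$genome, sacII, pm0, start_model = "fixed")
bt0[bt0$cls == "terminal_submolar", c("start", "length", "cls", "molarity")]
#>    start length               cls molarity
#> 11    46    743 terminal_submolar        1
#> 19 19909    137 terminal_submolar        1
```

With 10 % terminal redundancy the packaged length exceeds the unit and
the intact 880-nt (= 743 + 137) junction fragment appears — a band
predicted to occur only in longer-than-unit-length genomes:

```r
pm <- packaging_model(20000, redundancy = 0.1, pac_position = 46)
bt <- predict_band_table(sim$genome, sacII, pm)
bt[bt$cls == "junction_only", c("start", "length", "cls", "molarity")]
#>    start length           cls molarity
#> 10 19909    880 junction_only        1
```

Protein sizing with the acidic correction (here a mildly acidic
protein, x ≈ 0.077, migrates *below* its real mass):

```r
apparent_mw(sim$genome, sim$features[3, ])
#>   locus_tag len          x  mw_real    shift   mw_app
#> 1 synth_015 377 0.07692308 40111.13 -3792.91 36318.22
```

Whole-genome identity against a 10 %-diverged relative:

```r
div <- genome("relative",
              mutate_family(sim$genome$seq, 0.90, seed = 7,
                            alphabet = "dna"))
anib(sim$genome, div)
#> <anib_result> synth vs relative: ANIb = 90.0% (19/19 fragments retained)
```

`run_report()` orchestrates all stages over a set of annotated genomes
and writes TSV/JSON outputs plus a provenance manifest.

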