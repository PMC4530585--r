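---
title: "Positioning of meiotic axis proteins and cohesin: models and methods"
author: "axispattern"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positioning of meiotic axis proteins and cohesin: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axispattern)
```

# The biological model

Meiotic chromosomes are organized as chromatin loops anchored to an
axial element. In budding yeast the anchor points are cohesin
(Rec8)-associated sites on which the axis proteins Red1 and Hop1
assemble. Their positions are shaped by transcription: an elongating RNA
polymerase cannot pass through the cohesin ring and instead pushes it
along the DNA, so cohesin — and the axis built on top of it —
accumulates just downstream of the points where transcription ends.

This single mechanism predicts a set of quantitative signatures that the
package's analysis operations are built to measure:

* between **convergent gene pairs** with overlapping 3' UTRs, two
  occupancy peaks sit ~150 bp downstream of the two transcript 3' ends,
  so their separation is `tx_overlap + 2 × 150` bp;
* pairs with little or no transcript overlap show a **single peak** at
  the midpoint between the transcript ends (the two pushed positions
  collide);
* when the two genes are unequally transcribed, occupancy is **biased
  toward the weakly transcribed gene's side** in proportion to the
  stronger promoter's activity;
* axis signal per bp is ~**2.5-fold higher on the three shortest
  chromosomes**, a Hop1-dependent bias that falls to ~1.25-fold in
  *hop1Δ*;
* **centromeres** sit in a transcript-free pocket flanked by a doublet:
  axis proteins at ±270 bp, cohesin slightly wider at ±345 bp, with the
  centromeric doublet ~4-fold stronger in *hop1Δ*;
* without cohesin (*rec8Δ*), positioning by transcript ends is lost and
  residual axis binding instead follows **local coding density**, with
  longer ORFs binding more per kb.

# The synthetic-data generator

`simulation_config()` fixes the study conditions; `simulate_genome()`,
`simulate_expression()`, `build_occupancy()` /
`build_occupancy_rec8_delta()` and `simulate_reads()` realize them. The
generator's purpose is parameter recovery, not sequence realism: it
produces no nucleotides (the motif module is exercised on sequences
generated in its own tests), no mappability or GC structure, and a
deliberately simple noise model (uniform background mixture, normal
fragment lengths). Passing recovery tests therefore demonstrates that
the estimators are unbiased and correctly calibrated under the stated
model — not that they are robust to every artefact of real sequencing
data.

Key parameters, defaults, and the reasoning behind them:

| parameter | default | rationale |
|---|---|---|
| `chromosome_lengths` | 3 × 120–140 kb + 5 × 300–340 kb | a desk-scale genome (~2.2 Mb, ~1100 genes) keeping a 3-vs-rest size split |
| `overlap_fraction` | 0.79 | fraction of convergent transcript pairs with overlapping 3' UTRs |
| `offset_mean`, `offset_sd` | 150, 50 bp | downstream accumulation point; the spread makes end-aligned profiles realistically broad |
| `tandem_mass_factor` | 0.25 | tandem 3' ends are enriched but clearly below convergent ends; the exact value is a free choice |
| `small_chrom_factor` | 2.5 (1.25 in `hop1_delta`) | small-chromosome bias |
| `cen_flank_axis` / `cen_flank_cohesin` | 270 / 345 bp | doublet half-spacings |
| `centromere_boost` | 4 | `hop1_delta` centromere gain |
| `cen_mass_factor` | 3 | centromere site mass in units of the mean convergent site mass on unbiased chromosomes — big enough that the averaged doublet dominates local gene signal, as it does in averaged centromere profiles |
| `n_reads`, `read_length` | 5e5, 51 bp | 51-bp single-end geometry; recovery tests raise depth to 1e6 |
| `fragment_mean`, `fragment_sd` | 200, 20 bp | matches the 200-bp extension convention |
| `background_fraction` | 0.2 | uniform read fraction; the background-ratio estimator must recover the implied factor |
| `rec8_smooth_window`, `rec8_exponent` | 2 kb, 2 | coding-indicator smoothing and a cluster-forming exponent; the exponent is an invented device to reproduce qualitative clustering and is exposed in the config |

Specific generator choices worth knowing:

* **Merge rule.** A convergent pair's two sites exist only when the
  transcripts overlap (`tx_overlap > 0`). Any non-overlapping pair —
  whether the would-be sites would collide (gap < 300 bp) or sit apart
  (gap ≥ 300 bp) — receives a single merged site at the transcript-end
  midpoint carrying the full pair mass. This operationalizes the single
  central peak observed at little-or-no-overlap pairs with one rule
  instead of two.
* **Mass bookkeeping.** Each site's mass is the pushing gene's RPKM
  (tandem sites additionally scaled by `tandem_mass_factor`), so the
  expression-skew and induction scenarios are forced by construction.
* **Chromosome bias as an exact truth.** Gene-derived site masses are
  rescaled per chromosome so that the per-bp density *outside* the
  ±25-kb centromere windows hits the small/rest target ratio exactly.
  Centromere-flank sites are excluded from this rescaling and anchored
  to the mean convergent site mass of the *unbiased* chromosomes, which
  is identical across modes — so the `hop1Δ` centromere boost is a clean
  factor of 4 relative to wild type rather than being entangled with the
  chromosome-bias change.
* **Centromere pocket.** Each centromere sits in a 500-bp
  transcript-free pocket near mid-chromosome. The two genes flanking the
  pocket are laid divergently (5' ends facing it) so that no transcript
  and no convergent-pair geometry crosses the pocket; this keeps the
  overlap-fraction statistic exact and the pocket genuinely
  transcript-free.
* **Seed splitting.** One seed governs everything; each stage
  (genome/expression/occupancy/reads) derives its own stream as
  `(seed × 1009 + stage × 9973) mod (2^31 − 1)`, so regenerating reads
  never perturbs the genome.
* **Cross-strain comparisons.** Read counts are compositional: with
  equal sequencing depth, a strain with 4× more centromeric mass does
  not show 4× more centromeric reads. Real experiments recover absolute
  comparability through background (NCIS-type) scaling between
  experiments; the simulator's equivalent is to calibrate the mutant's
  read depth to its total occupancy mass
  (`n_reads × mass_mutant / mass_wt`), which the acceptance code does
  explicitly. Within-strain statistics (density ratios, peak distances)
  are depth-invariant and need no calibration.

# Analysis conventions and numerical choices

* **Coordinates** are 0-based, half-open everywhere inside the package;
  GFF (1-based closed) and SAM are converted at the parser boundary and
  nowhere else. Intergenic midpoints of even length take the floor of
  the boundary mean.
* **Two reference frames.** ORF-frame analyses (midpoint profiles, peak
  classification) use stop/start codons; transcript-frame analyses
  (end-aligned profiles, overlap ranking) use transcript ends. Both are
  kept because the two frames answer different questions.
* **Median normalization** divides each track by its genome-wide (not
  per-chromosome) median before subtraction; the choice is exposed by
  construction and flagged here because a per-chromosome variant would
  absorb the chromosome-size bias that the analysis is meant to measure.
* **Background scaling** is a one-step estimator: the median ChIP/control
  ratio over bins whose ChIP count lies below the genome-wide bin
  median. It is deliberately simpler than the iterative original it
  stands in for; on the generator's mixtures it recovers the true factor
  within a few percent. Negative values after subtraction are floored at
  0 for peak calling; use `floor_at_zero = FALSE` to export faithful
  residuals.
* **Peak calling** is a transparent Poisson scan so that an exact
  brute-force oracle exists: window sums are tested against
  `Poisson(max(genome mean, 10-kb local mean) × window)` at P ≤ 1e-15,
  significant footprints are unioned, gaps ≤ 200 bp merged, intervals
  < 100 bp dropped, and the summit is the leftmost track maximum in the
  interval. Summit ties break leftmost; classification priority is
  convergent > divergent > 3' > 5' > other (the priority order is a
  package choice; the categories are near-disjoint in practice).
* **Plateau-centroid peak location.** Extending 51-bp reads to a fixed
  200 bp turns a point source into a ~200-bp flat-topped plateau, so a
  raw argmax wanders uniformly across the top. All peak-location
  estimators (`profile_peak_offset()`, `centromere_profile()`, the
  doublet-separation search) therefore report the centroid of the
  contiguous region within 90% of the maximum: for a plateau this is its
  centre, for a sharp spike it reduces to the argmax. On read-level
  centromere profiles this recovers ±270/±345 bp to within a base pair.
* **Doublet separation.** Row-wise separation in
  `overlap_ranked_matrix()` takes the two highest interior local maxima
  (plateau-aware), optionally requiring a minimum separation
  (`min_separation`, recommended 150 bp on read-level data) so noise
  ripples on one plateau are not mistaken for a doublet; each maximum is
  then refined to its plateau centroid. The separation law
  `separation = tx_overlap + 300` is exact on truth occupancy for
  windows containing only the pair's own two sites; windows invaded by a
  neighbouring pair's site are identified from the truth registry and
  excluded when the law is tested, since interference there is a fact of
  the geometry, not an estimator error.
* **Averaging conventions.** Per-offset means ignore positions falling
  off chromosome ends (varying denominators) rather than zero-padding;
  metagene averaging weights genes equally regardless of length;
  smoothing is a centred boxcar with reflected edges (effective odd
  width `2⌊w/2⌋+1`).
* **Quantile conventions.** ΔRPKM = RPKM(forward, `+`/left gene) −
  RPKM(reverse); quantile 1 holds the most negative ΔRPKM, sizes differ
  by ≤ 1, ties break by stable pair order. The skew statistic
  `(Σ signal at offsets > 0 − Σ at < 0)/Σ` is positive when signal sits
  downstream of the forward gene; it therefore *increases* from
  quantile 1 to quantile 6 — toward the weakly transcribed gene's side,
  as the sliding model requires. Expression strata use strict percentile
  inequalities, so fully tied expression tables produce empty strata
  rather than arbitrary ones.
* **Extension-size estimation** cross-correlates `+`- and `-`-strand
  read-start densities per 10-kb window on a 1-bp shift grid; the
  genome-wide estimate is the argmax of the pooled correlation
  (5-bp-smoothed). Degeneracy — uniform strand-independent reads carry
  no fragment-length signal — is detected by split-half argmax
  disagreement (> 25 bp), which triggers a logged fallback to 200 bp.

# Problem sizes

The bundled tests run the toy-genome oracles at ≤ 10 genes, the module
simulations at a four-chromosome ~300-kb genome with 2–30 × 10^4 reads,
and the recovery suite at the default eight-chromosome ~2.2-Mb genome
with 10^6 reads (the expression-skew analysis doubles the genome to
reach 500 convergent pairs). These sizes give sampling errors well
inside the stated tolerances while keeping a full test run within a few
minutes; the same code scales unchanged to a 12-Mb genome at 10^7 reads.

# Known limitations

* The read model ignores duplicates, mappability, GC bias and
  paired-end geometry; the background estimator is one-step, not the
  iterative original.
* Occupancy sites are points (spatial spread comes only from offset
  jitter and fragment geometry); real binding footprints have intrinsic
  width.
* The *rec8Δ* coding-density exponent is a qualitative device; only the
  sign and ordering of its correlations are meaningful.
* Real-data peak counts depend on caller internals and data depth; the
  bespoke Poisson scan makes no attempt to reproduce any particular
  historical peak count.
* `hop1Δ` is modelled as redistribution (bias flattening + centromere
  boost); absolute protein-abundance changes are out of scope.
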