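---
title: "Calling microsatellite instability from repeat-length histograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling microsatellite instability from repeat-length histograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msipeaks)
library(dplyr)
```

## The problem and the model

Mismatch-repair-deficient tumors are hypermutable at microsatellites, and the
clinical gold standard for detecting this — PCR amplification of a marker
panel followed by capillary electrophoresis — reduces each marker to a small
set of allele-length *peaks* that an expert compares between tumor and
matched normal tissue. `msipeaks` reproduces that peak-counting readout from
aligned sequencing reads over a panel of six poly-A/poly-T mononucleotide
markers (Bat25, Bat26, Mono27, NR21, NR24, NR27).

The method treats each marker's read population as an empirical distribution
over repeat-tract lengths. A read contributes one observation: the length of
the maximal run of the repeat base found between the marker's two flanking
anchor sequences (tried in forward orientation first, then as the reverse
complement). Because the length is measured *within* the read, insertions and
deletions in the tract move the observation — which is exactly the somatic
signal. The resulting histogram is the NGS analogue of an electropherogram,
with PCR stutter and sequencing error broadening each true allele into a
down-biased cluster of nearby lengths.

Peak discovery then proceeds in a fixed order:

1. **Densify and pad.** Counts are laid out on the contiguous integer length
   range, one zero bin added at each end so terminal alleles can still be
   local maxima.
2. **Smooth** (optional, hyperparameter 1): window-3 moving average
   $h_n \leftarrow (h_{n-1}+h_n+h_{n+1})/3$, with bins outside the series
   treated as true zeros and the range extended one bin per side, so total
   mass is conserved exactly.
3. **Detect.** A candidate peak is a value strictly greater than both
   neighbors; a maximal plateau of equal values with strictly lower flanks is
   one candidate at its center bin.
4. **Filter** (hyperparameter 2): each candidate's relative height
   $rh_n = h_n / d$ must reach the threshold $R_h$; smaller candidates are
   discarded as technical noise.

Markers are compared tumor versus normal: different retained-peak counts, or
equal counts with an order-paired maximum position gap of two or more repeat
units, make the marker *unstable*. A patient with at least two unstable
markers is *MSI-H*, otherwise *MSI-L* (the binary scheme that folds MSS into
MSI-L; `n_unstable` is reported so the three-level Bethesda split can be
recovered).

## Design choices where the design was open

**Order of operations.** Both noise-control strategies — thresholding and
smoothing — act on the *same* final series: the pipeline smooths first, then
detects, then filters. Filtering presupposes detected candidates, and
detecting on the raw series while filtering on the smoothed one would let the
two strategies disagree about what a peak even is.

**The relative-height denominator.** Two conventions are implemented.
`peak_sum` divides a candidate's height by the summed heights of all
candidates; it is self-normalizing (a single candidate always has
$rh = 1$) but caps $rh$ at 1, which makes thresholds above 1.0 on the tuning
grid unusable. The default, `mean_nonzero_bins`, divides by the mean height
over nonzero bins of the current series — a per-marker average depth — under
which the full grid $0.1,\dots,3.0$ is meaningful and a threshold of 0.2
reads as "20% of average depth". Both modes are invariant under uniform
scaling of the histogram, so peak calls depend on shape, not coverage.

**Plateau representation.** Exact ties are rare in raw counts but systematic
after smoothing: a lone single-length allele becomes an exactly equal
width-3 plateau. Representing a plateau by its center bin keeps such an
allele at its true length; a leftmost convention would shift every isolated
spike one unit left. The choice is position-relevant because the marker
comparison is a positional gap rule; the center convention is also symmetric,
so it cancels in tumor-normal comparison.

**Threshold comparison tolerance.** $rh_n \ge R_h$ is evaluated with an
absolute tolerance of $10^{-9}$ so grid-valued thresholds do not flap on
floating-point representation.

**Depth floor.** Markers where either sample has fewer than `min_reads`
(default 20) anchor-matched reads are reported *uninformative* and excluded
from the unstable count rather than being called on noise; a patient with no
informative markers is an explicit error, never a silent MSI-L. The floor is
a quality-control addition beyond the core decision rules and is clearly
labeled in the output.

**Read filters.** Unmapped, secondary and supplementary alignments are always
excluded; duplicate-flagged reads are excluded by default (matching pipelines
that deduplicate upstream) and `min_mapq` defaults to 1. An `N` inside the
repeat tract breaks the run and, with the flank no longer adjacent, the read
simply fails to match — a conservative choice that avoids fabricating
lengths. When a read contains several anchor occurrences the leftmost wins,
and a read is counted at most once per marker.

**Loss normalization.** The tuning loss is
$\mathrm{diff} = \sum_i \sum_t |P^{i,t}_{NGS} - P^{i,t}_{PCR}| / S$ with $S$
the number of sample units, i.e. the average per-sample total peak-count
discrepancy across the panel. Units are distinct `(sample_id, tissue)` pairs
present in the PCR truth table, so tumor-only training is expressed by
subsetting the truth (the `tissues` argument of `grid_search()`). Ties in the
grid break toward smoothing on, then toward the lowest threshold, since a
lower threshold retains sensitivity to minor alleles.

## What the simulator emulates — and what it does not

`simulate_histogram()` draws, per allele, a Poisson number of reads around
the target depth; each read's length is the allele's modal length minus a
geometric down-stutter offset plus a geometric up-stutter offset, and a small
fraction of reads are replaced by uniform stray lengths within ±15 units.
This reproduces the three features the method must cope with: a dominant
modal bin, a down-biased stutter shoulder, and isolated one-read noise
spikes.

Default rates are `stutter_down_rate = 0.10`, `stutter_up_rate = 0.05`,
`noise_rate = 0.01`, with per-marker depth 200 in cohort simulation. The
down/up asymmetry mirrors PCR slippage, but the rates are deliberately kept
in the regime where the smoothed mode stays at the true allele length: after
window-3 averaging, the sign of $s(m) - s(m-1)$ equals the sign of
$h(m{+}1) - h(m{-}2)$, so when the minus-2 stutter mass rivals the plus-1
mass the detected position dithers between $m$ and $m-1$ under Poisson noise.
Heavier stutter regimes are realistic for long mononucleotide runs but make
single-unit position accuracy intrinsically unstable; the gap-≥2 rule absorbs
that jitter in marker comparison, and the parameter-recovery tests use depth
400 so that modal positions are recovered deterministically.

Cohorts plant truth: MSI-H pairs gain a novel shorter tumor allele (4–7
repeat units below the reference, half depth each) at 2–3 markers; MSI-L
pairs at 0–1 markers; normals carry a single reference-length allele per
marker. The simulator does *not* model base-call errors inside flanks,
alignment artifacts, tumor purity, or inter-marker coverage variation — so
passing tests demonstrate correctness of the decision rules and robustness to
stutter-like noise, not clinical performance on real libraries.

`write_fixture_bam()` realizes any per-marker length plan as a sorted,
indexed BAM whose reads embed `flank5 + base×k + flank3` in neutral padding
at the marker locus, closing the loop so extraction itself is tested against
known truth.

## The planted tuning optimum

`plant_grid_optimum()` builds a deterministic training set whose true peak
count (two alleles per marker) is recovered *only* at (smoothing on,
$R_h = 0.2$). Each marker histogram holds a major allele triplet
(360, 720, 360), a minor allele triplet (20, 40, 20) seven units below, and
two isolated 40-read noise spikes. Under smoothing the spikes collapse to
relative height $2/15 \approx 0.133$ (killed at 0.2, kept at 0.1) while the
minor allele keeps $4/15 \approx 0.267$ (kept at 0.2, killed at 0.3); without
smoothing the spikes tie the minor allele at $rh = 0.2$, so no unsmoothed
threshold on the grid yields exactly two peaks. Grid search therefore returns
(on, 0.2) with `diff = 0`, exercising the loss, the full 60-combination grid,
and the tie-breaking in one construction.

## Problem sizes and numerical checks

The test suite verifies, among others: anchor measurement against a
character-scanning oracle on 10,000 constructed reads (half
reverse-complemented, random padding); local-maximum detection against a
brute-force plateau enumerator on 1,000 random series; exact mass
conservation of smoothing on 1,000 random histograms; monotone peak retention
across the full threshold grid on 100 histograms; exact modal-length recovery
on seeded bimodal stutter fixtures (depth 400); and end-to-end MSI status
recovery on a seeded 60-pair cohort at the default noise settings, required
to agree with planted truth for at least 57 of 60 pairs. Degenerate inputs
are defined, not exceptional: empty histograms yield empty peak sets, empty
BAM regions yield empty histograms, and an all-uninformative panel raises an
explicit uncallable error.

## Known limitations

* Peak discovery has no prominence or minimum-separation parameters; two true
  alleles one unit apart merge under smoothing.
* Position accuracy is one repeat unit at best; comparisons rely on the
  gap-≥2 rule rather than sub-unit calibration, and both tissues being
  NGS-derived means systematic PCR-vs-NGS length offsets cancel rather than
  being modeled.
* The caller is binary (MSI-H / MSI-L) with a fixed ≥2-unstable cutoff; it
  does not produce a continuous instability score or model tumor purity.
* CRAM input and realignment around the repeat are out of scope; inputs are
  assumed coordinate-sorted, indexed, and already deduplicated (or
  duplicate-flagged).
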