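# msipeaks

Microsatellite instability (MSI) calling from paired tumor/normal
next-generation sequencing data.

Tumors with deficient mismatch repair accumulate length changes at
microsatellites — short tandem repeats such as the 25-T mononucleotide run of
BAT-25. The PCR gold standard detects this by fragment-length analysis:
capillary electrophoresis of marker amplicons, with an expert counting allele
peaks in tumor versus matched normal electropherograms. `msipeaks` emulates
that readout directly from aligned sequencing reads:

1. **Depth extraction.** For each marker in a six-marker mononucleotide panel
   (Bat25, Bat26, Mono27, NR21, NR24, NR27), reads overlapping the locus are
   matched against flanking *anchor* sequences (forward or
   reverse-complement); the length of the repeat-base run between the flanks
   is the read's measured repeat length. Counts per length form a repeat-length
   histogram — the NGS analogue of an electropherogram.
2. **Peak discovery.** The histogram is zero-padded, optionally smoothed with
   a window-3 moving average (`h_n = (h_{n-1} + h_n + h_{n+1})/3`), and
   scanned for local maxima. Each candidate peak's *relative height*
   `rh_n = h_n / d` (with denominator `d` a depth summary, by default the mean
   over nonzero bins) must reach a threshold `R_h`; lower peaks are discarded
   as PCR-stutter / sequencing noise.
3. **Marker comparison.** A marker is **unstable** if tumor and normal retain
   different numbers of peaks, or if, with equal counts, position-paired
   peaks differ by a gap of ≥ 2 repeat units.
4. **Patient classification.** ≥ 2 unstable markers → **MSI-H**; otherwise
   **MSI-L** (MSS is merged into MSI-L).
5. **Tuning.** The two hyperparameters (smoothing on/off, `R_h` over the grid
   0.1, 0.2, …, 3.0) are chosen by grid search minimizing the loss
   `diff = Σ_i Σ_t |P_NGS^{i,t} − P_PCR^{i,t}| / S` against PCR truth peak
   counts, with ties broken toward smoothing and the lowest threshold. The
   shipped defaults are smoothing on, `R_h = 0.2`.

A seeded simulator (`simulate_histogram()`, `simulate_cohort()`,
`write_fixture_bam()`) generates stutter-broadened histograms, whole cohorts
with known MSI truth, and real indexed BAM fixtures, so the entire pipeline is
testable without any sequencing data.

## Worked example

```r
library(msipeaks)
library(dplyr)

co <- simulate_cohort(1, fraction_msih = 1, seed = 42)
co$truth
#> # A tibble: 1 × 3
#>   sample_id true_status shifted_markers
#> 1 sim001    MSI-H       Bat25,NR27

call <- call_sample_pair(filter(co$depth, tissue == "tumor"),
                         filter(co$depth, tissue == "normal"))
call
#> MSI patient call: sim001
#>   status:      MSI-H
#>   unstable:    2 of 6 informative markers
#>   markers:     Bat25, NR27

tidy(call)[, c("marker", "status", "tumor_peak_count", "normal_peak_count")]
#> 1 Bat25  unstable 2 1
#> 2 Bat26  stable   1 1
#> 3 Mono27 stable   1 1
#> 4 NR21   stable   1 1
#> 5 NR24   stable   1 1
#> 6 NR27   unstable 2 1
```

The planted MSI-H sample gains a shorter tumor allele at Bat25 and NR27; the
caller finds a second peak at exactly those markers (tumor 2 peaks vs normal
1) and classifies the patient MSI-H. Stochastic one-unit jitter of a peak
position (as Bat26 above, max gap 1) is tolerated by the gap-≥2 rule.

Tuning against PCR truth:

```r
planted <- plant_grid_optimum()
grid_search(planted$depth, planted$pcr)
#> MSI hyperparameter grid search (60 combinations)
#>   best: smoothing=TRUE, r_h=0.2  (diff = 0)
```

From the shell (`exec/msipeaks`): `msipeaks extract`, `msipeaks call`,
`msipeaks tune`, `msipeaks simulate`; `msipeaks call` accepts either BAMs or
depth files and writes a JSON evidence report plus a one-line TSV summary.

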