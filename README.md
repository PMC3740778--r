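# spreadfactory

Quantitative analysis of how transcriptionally active, hyperacetylated
(H4K16ac) chromatin is organised — linearly, as tracks and clusters on
spread chromatin fibres, and spatially, as near-spherical foci in the
nucleus — together with a lattice Monte-Carlo model of the rod-coil
multi-block copolymer mechanism proposed to connect the two.

The package is aimed at chromatin biologists and modellers who want a
tested, fully synthetic re-implementation of this analysis chain: every
input the original study obtained by microscopy or microarray is
replaced by a seeded generator with known ground truth, so each
measurement stage can be validated by parameter recovery.

## What it computes

**Spread morphometrics.** H4K16ac track lengths follow a lognormal with
arithmetic mean ~15 Kb; gaps between consecutive tracks within a cluster
are lognormal with mean ~30 Kb. Clusters are maximal runs of ≥ 2 tracks
with consecutive gaps strictly under 100 Kb; at the calibrated
composition they hold 8 ± 2 transcription units and span a few hundred
Kb. Physical lengths convert at 3.9 Kb/μm, estimated from repeated
measurements of a 47.26 Kb probe. Marks per track (nascent transcripts,
elongating polymerase) are Poisson-like with means 0.7 and 0.8.

**Co-expression windows.** A 500 Kb window slides in 5 Kb steps along
each chromosome; the expressed-gene count per window is compared against
a label-permutation null, and windows whose observed statistic exceeds
the null's 0.95 quantile are merged into significant co-expression
regions.

**Focus statistics.** Nuclear foci are segmented by Otsu threshold and
connected components; circularity is the shape factor `4πA/P²` (≈ 0.93
for the measured foci, 1 for a circle) with a contour-based perimeter
estimator calibrated so discs score ≈ 1. Focus disassembly is scored by
the coefficient of variation (SD/mean) of nuclear pixel intensity.

**Copolymer simulation.** Chromatin as a single self-avoiding (rod-coil)ₙ
chain on a cubic lattice, 1 bead ≈ 1 Kb: stiff rod blocks (15 beads, 8
per cluster, 12% of the chain) attract at ε = 3 kT with a 2 kT bending
penalty. Metropolis dynamics (kink-jump, crankshaft, end rotation) shows
microphase separation of rods into compact domains, their dispersal when
the attraction is switched off (the formamide analogue), and their
stability under treatments that do not touch the acetylation-driven
interaction (DRB, heat shock, NaCl).

## Worked example

```r
library(spreadfactory)

fib <- generate_spread_fibres(spread_gen_params(n_clusters = 500, seed = 42))
fib
#> <spread_fibre_set> 50 fibres, 500 clusters, 4033 tracks

cl <- detect_clusters(fib)                 # the <100 Kb rule
cluster_statistics(cl, fib)
#> Cluster statistics over 500 clusters
#>   TUs/cluster: 8.07 +/- 2.09 (range 2-14)
#>   span: 326.6 +/- 101 Kb (range 34.16-647.9)
#>   marks/track: 0.709 transcripts, 0.824 pol II

fit_lognormal(track_lengths(fib))
#> Lognormal MLE: meanlog 2.526, sdlog 0.6096; arithmetic mean 15.06 (n = 4033)

active_fraction(fib)
#> [1] 0.122
```

The detected clusters carry ~8 transcription units spanning ~330 Kb, the
fitted track-length distribution has its arithmetic mean back at ~15 Kb,
and 12% of the synthetic genome is covered by active tracks — the
measured organisation the generator was calibrated to. On the imaging
side:

```r
imgs <- generate_nucleus_images(image_gen_params(n_images = 20, seed = 42))
sf <- unlist(lapply(imgs, function(im)
  measure_foci(segment_foci(im$image, im$mask), im$image)$shape_factor))
mean(sf)
#> [1] 0.921   # 240 segmented foci, near the 0.93 target
```

`run_pipeline(pipeline_config(seed = 1), "out/")` runs every stage
(spreads → morphometrics, expression → windows, images → focus stats,
copolymer → domain metrics) and writes the tables plus a manifest;
rerunning the same configuration reproduces them byte-identically.

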