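---
title: "Methods: synthetic chromatin spreads, co-expression windows and the rod-coil copolymer model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic chromatin spreads, co-expression windows and the rod-coil copolymer model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spreadfactory)
```

# The biological picture

On spread chromatin fibres, transcriptionally active chromatin carrying
H4K16 acetylation appears as discrete *tracks* (one track roughly one
transcription unit), which group into *clusters* along the genomic axis.
In intact nuclei the same chromatin forms near-circular foci. The package
models both views and the bridge between them: a multi-block rod-coil
copolymer in which acetylated, stiffened chromatin segments ("rods")
attract each other and microphase-separate into near-spherical domains
when the rod fraction is low.

Because the original micrographs and in-house microarrays are not
available, every analysis here runs on synthetic data with known ground
truth, generated at the calibrated values of the measured system. The
tests then ask a parameter-recovery question: does the measurement
pipeline read those values back?

# The spread-fibre generator

`spread_gen_params()` fixes the linear model of a fibre:

* **Track lengths** — lognormal with *arithmetic* mean 15 Kb. Only the
  arithmetic mean of this skewed distribution is known; the log-scale SD
  defaults to 0.6, which gives the visibly skewed, unimodal length
  histogram characteristic of spread measurements, and is exposed as a
  parameter.
* **Intra-cluster gaps** — lognormal, arithmetic mean 30 Kb,
  rejection-truncated strictly below the 100 Kb cluster bound. Truncation
  makes ground-truth clusters exactly recoverable by the cluster rule, so
  recovery tests are well-posed. The price is a small shift of the
  realised mean to `30 * pnorm((log(100) - mu - s^2)/s) / pnorm((log(100) -
  mu)/s)` ≈ 28.99 Kb, a 3% effect we accept and document rather than
  re-centre, since the untruncated parent mean is the stated 30 Kb.
* **Tracks per cluster** — `round(Normal(8, 2))`, truncated at a minimum
  of 2 (a cluster needs two tracks by definition).
* **Spacers** — lognormal, arithmetic mean 670 Kb, truncated strictly
  above 100 Kb so clusters never merge. The 670 Kb default is chosen so
  one cluster-plus-spacer unit is `8*15 + 7*30 + 670 = 1000` Kb of which
  120 Kb is track: a 12% genome-wide active fraction, matching the rod
  proportion the copolymer argument uses. Each fibre is a whole number of
  such units (every cluster is followed by its spacer), which makes the
  active fraction of a generated fibre well defined.
* **Marks** — transcript and phosphorylated-polymerase counts per track
  are Poisson with means 0.7 and 0.8. The measured SDs (±1 and ±0.9)
  are mildly overdispersed relative to Poisson; the default generator
  keeps plain Poisson as a documented approximation and exposes a
  negative-binomial option (`marks_dispersion`) for the overdispersed
  case. Mark positions are uniform within their track.
* **Calibration** — 3.9 Kb/μm with 5% multiplicative measurement noise
  when probe measurements are simulated.

Coordinates are real-valued Kb, 0-based, half-open throughout. All
generation is seeded and bit-reproducible.

# Morphometrics

`detect_clusters()` implements the cluster definition literally: maximal
runs of at least two tracks whose consecutive gaps (next start minus
previous end) are *strictly* below 100 Kb; a gap of exactly 100 Kb
splits. Clusters never span fibres. `fit_lognormal()` is the closed-form
lognormal MLE (mean and population SD of the logs) and reports the
fitted arithmetic mean `exp(mu + sigma^2/2)`; a brute-force likelihood
grid search serves as its independent oracle in the tests. Reported
summary SDs use the sample (n-1) convention, appropriate for the small
track counts (150-200) of real spread experiments.
`estimate_calibration()` divides the known 47.26 Kb probe length by the
mean measured micron length, with the standard error propagated by the
delta method.

# The sliding-window co-expression test

A 500 Kb window slides in 5 Kb steps; the statistic per window is the
number of expressed genes whose midpoints it contains. Significance is
assessed against a permutation null in which expressed labels are
reshuffled among gene positions. The original analysis states the window
and step and the "p > 0.95" call but neither the statistic, the null
model, nor the permutation count, so these are explicit design choices
here:

* statistic = expressed count (a fraction option is exposed);
* null = label permutation within each chromosome (preserves the
  per-chromosome expressed count; genome-wide scope exposed);
* 1000 permutations by default;
* "p > 0.95" is read as: the observed statistic exceeds the 0.95
  quantile of its permutation null, i.e. the empirical CDF of the
  observed value is above 0.95. `empirical_p` is the fraction of
  permutations *strictly below* the observed statistic, which makes the
  call slightly conservative for a discrete count statistic (ties count
  against significance). Under random labels the per-window significance
  rate measures ~4% at the 0.95 quantile rather than the nominal 5%;
  the calibration test asserts the rate in [2%, 8%] on disjoint windows.
* no multiple-testing correction beyond the quantile, mirroring the
  original display; a max-statistic family-wise option exists but is off
  by default.

Gene membership is by midpoint, which assigns each gene to exactly one
window boundary side and avoids edge double counting. Power at the
planted-cluster design point (8 expressed genes in 500 Kb over 2%
background, 2000 genes) exceeds 0.9 at 1000 permutations.

# Nucleus images and focus statistics

The image generator renders a circular nuclear mask (background 500,
16-bit scale) with 12 non-overlapping elliptical foci (level 3000,
Gaussian pixel noise SD 100, geometric-mean radius 8 px). Aspect ratios
are lognormal around 1 with log-SD 0.468, solved numerically so that the
*analytic* mean circularity `4*pi*A/P^2` (Ramanujan perimeter) is 0.93 —
the generator encodes the measured mean shape factor as ground truth
rather than fitting it afterwards. Foci are placed largest-first by
bounded rejection wholly inside the mask; non-overlap is the default so
each segmented object corresponds to one true focus. The generator does
not simulate optical blur, chromatic shift or 3D stacks; passing
recovery tests therefore show correctness of the measurement chain on
idealised raster ellipses, not robustness to microscope physics.

Segmentation thresholds within-mask intensities by Otsu's bimodal split
and labels 8-connected components above 5 px. The shape factor uses a
perimeter estimator chosen against two oracles: a rasterised disc of
radius ≥ 10 px must score ≥ 0.98 and a large square π/4. Plain
pixel-edge counting fails both badly, so the estimator traces the Moore
contour through pixel centres, smooths it with a circular moving average
of window 3 to remove staircase jitter, and takes the polygon length;
the matching area is the Pick's-theorem area of the traced lattice
polygon (`pixels - boundary/2 - 1`), which is the area the contour
actually encloses. With both referred to the same polygon the disc and
square oracles hold (squares converge to π/4 from above, within 0.02 at
side 80). Regions under 4 px are flagged `NA` rather than scored.

The disassembly score is the coefficient of variation (population
SD/mean) of masked pixel intensity: high for focal signal, low for
dispersed. `disperse_signal()` convolves an image with Gaussian kernels
of increasing width — same integrated signal, progressively flatter — and
CV falls strictly monotonically along that series.
`treatment_comparison()` summarises per-cell CVs by group (flagging
groups under 200 cells) and bootstraps pairwise differences of means.

# The lattice copolymer simulation

No simulation formalism exists in the source analysis — the copolymer
argument is made from the polymer-physics literature — so the simulator
is the minimal model embodying "stiff, self-attracting rods in a
flexible matrix", and all conclusions drawn from it are qualitative
analogues, not measured results. The model: a single self-avoiding chain
on a cubic lattice (hard walls, one bead ≈ 1 Kb) with

```
E = -epsilon_rr * (# non-bonded rod-rod nearest-neighbour contacts)
    + kappa_rod * (# non-collinear bond pairs centred at a rod bead)
```

at temperature 1 kT, with `epsilon_rr = 3` and `kappa_rod = 2` by
default — attraction strong enough to phase-separate and stiffness enough
to keep rods semi-rigid at desk scale (single chain, ≤ 5000 beads). The
default composition reuses the linear calibration: 15-bead rods, 30-bead
gaps, 8 rods per cluster, 670-bead spacers, i.e. exactly 12% rod.

Moves are Metropolis with symmetric proposals: end-bead rotation,
kink-jump (corner flip), and a two-bead crankshaft; reptation is exposed
but off by default because sliding the chain moves the rod/coil label
pattern relative to the backbone geometry, making its energy change
non-local (it is recomputed in full when used). The initial conformation
is an extended diagonal zig-zag staircase: dilute, self-avoiding, and
with every interior bead at a corner so local moves act immediately — a
dense row-by-row fill, by contrast, starts effectively frozen. Local
moves conserve the sublattice parity of the chain (each bead stays on
its parity class), so the detailed-balance test enumerates the reachable
parity class of a 3-bead chain exhaustively and compares the empirical
visit distribution to Boltzmann weights (total variation ≈ 0.01 over
174 states).

Domain metrics treat rod beads as a graph under lattice adjacency:
connected components are domains; asphericity is the normalised
gyration-tensor invariant `[(l1-l2)^2 + (l2-l3)^2 + (l1-l3)^2] /
(2(l1+l2+l3)^2)` (0 for a sphere, 1 for a line), size-weighted across
domains. The property suite runs 2e8 proposal steps for the 2000-bead
default chain (a few tens of seconds compiled) and averages metrics over
the last five coordinate snapshots; full equilibrium is not claimed —
the asserted properties are orderings (attraction grows domains above
the athermal control; the 12% chain's domains are more spherical than a
50%-rod chain's; zeroing the attraction re-disperses domains while
leaving it intact does not), which are stable well before equilibrium.

Treatments map onto parameters by mechanism: formamide destroys the
acetylation-driven self-assembly, so it zeroes `epsilon_rr`; DRB, heat
shock and NaCl extraction strip polymerases or labile protein but leave
the acetylation interaction, so they change nothing — matching the
observed resistance of foci to those treatments and their disassembly by
formamide.

# Problem sizes and reproducibility

Defaults used by the recovery analyses: 10,000 tracks (1250 clusters)
for length/gap/mark recovery; 500 clusters for span and TU statistics; a
~100 Mb single-fibre chromosome (100 cluster units) for the active
fraction; 200 nucleus images (2400 foci) for the shape factor; 100
probe measurements for the calibration; 20 replicates at 1000
permutations for window-test calibration and power; 2000-bead chains at
2e8 Monte-Carlo steps for the copolymer orderings. Every stochastic
stage takes an explicit integer seed and is bit-reproducible;
`run_pipeline()` derives all stage seeds from one global seed and
rerunning a configuration reproduces byte-identical tables.

# Known limitations

* The generator's lognormal dispersions are conventions (the measured
  system reported only means), so recovery tests validate the pipeline,
  not those dispersion values.
* Poisson marks understate the reported mark-count SDs; use
  `marks_dispersion` for matched overdispersion.
* The image model omits PSF blur and uneven illumination; segmentation
  performance on real micrographs will be worse than on these rasters.
* The copolymer model is single-chain (cis interactions only), with no
  liquid-crystalline order parameter and no field-theoretic phase
  diagram; it demonstrates regimes, not quantitative phase boundaries.
* Whether the measured "shape factor" was circularity `4*pi*A/P^2` or an
  axis-ratio measure is not stated; circularity is assumed throughout.
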