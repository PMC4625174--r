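---
title: "Segmenting and tracking fluorescent membrane microdomains with raftrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and tracking fluorescent membrane microdomains with raftrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raftrack)
```

## The problem

Plasma-membrane receptors such as the HDL receptor SR-B1 reside in
cholesterol-rich microdomains (lipid rafts) and appear in live-cell
fluorescence movies as bright puncta. Ligand binding can reorganize
these domains: receptors cluster into fewer, larger, brighter puncta
whose motion changes from free membrane diffusion to confined jitter
around an anchoring site. raftrack quantifies both sides of that
phenotype from calibrated time-lapse movies:

* **morphometrics** — domain area, mean brightness and count, measured
  on segmented frames;
* **dynamics** — per-track mean speed and the confinement ratio
  $\rho$, measured on automatically detected and linked puncta;
* **statistics** — a permutation test for means to compare two
  conditions without normality assumptions.

Because raw movies for this kind of experiment are rarely deposited,
the package ships a ground-truthed synthetic movie generator that
emulates the untreated (diffusive) and treated (clustered) conditions,
so every stage is testable end to end.

## Segmentation and morphometrics

Each frame is processed as: rolling-ball background subtraction
(grayscale opening with a disc, default radius 50 px — the de-facto
standard for diffuse fluorescence background in interactive tools),
then a large-radius unsharp mask,

$$\mathrm{out} = \mathrm{in} + a\,(\mathrm{in} - G_r(\mathrm{in})),$$

with Gaussian radius $r = 25$ px and amount $a = 0.9$. The radius is
chosen much larger than the point-spread function so that puncta are
lifted against the diffuse membrane signal while the image mean is
essentially preserved. A threshold turns the filtered image into a
segment mask; thresholding of this kind is inherently a manual,
per-experiment choice, so the threshold is a required configuration
value, with an automatic Otsu fallback for unattended runs that is
flagged in the output metadata. 8-connected components of at least 4 px
become domains, and area, centroid and mean intensity are measured on
the background-subtracted image (not the contrast-enhanced one, which
exists only to make the mask). Domains are assigned to cells by the
cell label under their centroid when a cell mask is supplied; without
one, each imaged field/frame is the counting unit.

## Spot detection

Tracking needs subpixel centers of mass, produced by an à-trous
(undecimated) B3-spline wavelet decomposition with the separable kernel
$\tfrac{1}{16}[1,4,6,4,1]$ and hole spacing doubling per level. The
transform is exactly invertible (input = residual + sum of detail
planes), which the tests assert to floating precision. Detection
hard-thresholds the level-2 detail plane at $k\hat\sigma$ with $k = 3$,
where $\hat\sigma = \mathrm{MAD}/0.6745$ is estimated per frame so that
bleaching or illumination drift does not bias the threshold.
Supra-threshold 8-connected components become spots; the subpixel
position is the intensity-weighted centroid on the detail plane, which
is background-free by construction.

One numerical choice deserves a note: the smoothed detail plane has
spatially correlated noise, so rare noise excursions can span a few
pixels. A minimum component area of 8 px separates them from real
spots — in noise-only frames at the default camera model the largest
correlated excursion over 60 frames spans ~6 px, while a
diffraction-limited spot at the default signal-to-noise ratio spans at
least ~13 px. The default is therefore placed between the two
populations; it is exposed as an argument.

## Track linking

Frame-to-frame correspondence is posed as an exact linear assignment
problem: linking spot $a$ to spot $b$ costs the squared displacement
(the maximum-likelihood cost under Gaussian motion), admissible only if
the implied speed does not exceed 42 µm/min; every spot may instead
terminate (death) or start (birth) at $1.05 \times$ the squared maximum
displacement, so that any admissible link is preferred to a birth/death
pair. The solver is an $O(n^3)$ Hungarian algorithm (shortest
augmenting paths with dual potentials), and its optimality is verified
in the tests against brute-force enumeration of all admissible partial
matchings.

Gap closing is deliberately not performed: a spot that disappears and
reappears starts a new track. Under that rule the movie-wide linking
problem decomposes exactly into independent per-frame-pair assignment
problems, so per-pair optimal assignment reproduces the movie-wide
optimum — this equivalence is the module's core engineering claim.
Ties between equal-cost optima are broken deterministically by the
solver's fixed scan order; with continuous coordinates exact ties do
not occur in practice.

At the default calibration (0.16 µm/px, 2 s frames) the 42 µm/min cap
corresponds to $42 \cdot (2/60)/0.16 = 8.75$ px per frame interval.

## Dynamics

Tracks observed in at least 5 frames enter the dynamics analysis
(reading "a lifetime of over four frames" as $\ge 5$ track points; the
threshold is exposed for the alternative $\ge 6$ reading). Per track:

* mean speed: mean frame-to-frame step $\times$ pixel size $/$ (frame
  interval in minutes);
* confinement ratio: $\rho = |p_{\mathrm{last}} - p_{\mathrm{first}}| /
  \sum_i |p_{i+1} - p_i|$, in $[0, 1]$ — near 1 for directed motion,
  near 0 for confined or random motion.

Before $\rho$ is computed, stationary tracks — mean step below
1 px/frame, boundary inclusive — are excluded, mirroring the analysis
convention of excluding stationary areas. By default the exclusion
applies to $\rho$ only, not to speed (a flag applies it to both): the
speed comparison is expected to show arrested domains, whereas $\rho$
is only well defined for things that move. Condition summaries report
median, quartiles and the 10th/90th percentiles (linear interpolation
between closest ranks, recorded in metadata since percentile
conventions differ), matching the box-plot convention used for this
kind of data.

## Condition comparison

Five endpoints are compared between conditions: domain area and domain
brightness (domains present in the first segmented frame of each
movie, matching the convention of measuring the domains of the first
image of a series), domains per cell (or per field/frame), per-track
mean speed, and per-track $\rho$. Each comparison uses a permutation
test for the difference of means: group labels are re-randomized
preserving group sizes, and the two-sided Monte-Carlo p-value carries
the +1 correction, $p = (\#\{|T^\ast| \ge |T|\} + 1)/(B + 1)$, which
guarantees $p \in (0, 1]$ and validity at any $B$. When the total
number of distinct label assignments is at most 20,000 the test
enumerates all of them and the p-value is exact. Defaults are 10,000
permutations, two-sided. The permutation unit is whatever observational
unit is supplied (tracks or domains here); with nested data the caller
can aggregate to cells first.

Both conditions must be processed with identical analysis parameters;
`compareConditions()` refuses to compare otherwise, since a threshold
or cap differing between conditions would confound every endpoint.

## The synthetic generator

`simulateMovie()` renders ground-truthed movies at the acquisition
geometry of the emulated experiment: 60 frames at a 2 s lapse
(a 2-minute movie), 256 × 256 px. The pixel size is not part of the
emulated acquisition record, so a typical 100× confocal value of
0.16 µm/px is the default; all physical thresholds are specified in
physical units, so this default is not load-bearing.

* **Untreated condition** — `nSpots = 60` spots diffuse freely at
  $D = 0.01$ µm²/s (per-axis steps $\mathcal N(0, \sqrt{2D\Delta t})$,
  reflected at the borders). This gives a mean 2-D step of ~1.6 px per
  frame: visibly mobile, comfortably under the speed cap, and above the
  1 px/frame stationarity screen.
* **Treated condition** — a `clusterFraction = 0.8` share of the same
  spots is bound to one of `nClusterCenters = 20` anchored domains.
  Each domain jitters as a rigid body: its center moves with the free
  diffusion step size but is tethered, excursions folded back into a
  disc of radius 0.25 µm around the anchor, and bound spots ride at
  fixed offsets within the half-tether disc. Bound spots therefore stay
  within the 0.5 µm capture zone of their center for the whole movie.
  The generator models the steady state reached ~24 h after treatment;
  capture kinetics (an approach phase) are deliberately not simulated,
  as transient directed approaches would contaminate $\rho$ with
  artifactual linear segments.

The tether model, rather than a full freeze, is a deliberate choice:
a completely frozen cluster (centroid jitter well below 1 px/frame)
would be removed by the stationarity screen before $\rho$ is ever
computed, leaving the treated $\rho$ sample identical in law to the
untreated one — and because $\rho$ of a free random walk is
scale-invariant, merely slowing diffusion cannot lower it either. Only
spatial confinement produces the low-$\rho$, low-speed signature that
treated receptor domains show, so confinement is what the generator
implements. The tether radius (0.25 µm) is of the order of a raft
domain and keeps the cluster's detected centroid above the stationarity
screen while bounding its net displacement.

Rendering: each spot is an isotropic Gaussian (PSF sigma 1.3 px) with
peak amplitude 90 over a constant background of 100; Poisson shot noise
plus Gaussian read noise (sd 5) give a peak signal to background-noise
ratio of ~8, a realistic mid-range SNR for live-cell confocal imaging
(no SNR is part of the emulated record; this default is asserted, not
derived). Rendering is linear, 16-bit clipped, and with noise disabled
conserves total intensity to the truncated Gaussian tails (< 0.5%).
The ground truth carries every true trajectory, the spot-to-cluster
assignment, and per-frame label images of the noiseless ≥ 50%-of-peak
regions.

What the generator does **not** emulate: photobleaching, blinking,
3-D optics and defocus, camera gain calibration, cell shapes and
cell-to-cell variability, receptor exchange between clusters, and
capture/release kinetics. Passing the packaged tests therefore shows
that the pipeline recovers the clustered-vs-diffusive phenotype from
images with realistic point-spread and noise statistics — not that it
is robust to every pathology of real microscopy data. Thresholds (the
segmentation threshold above all) remain experiment-specific choices
on real data.

## Numerical and degenerate-input choices

* Identical parameters (including seeds) give bit-identical movies,
  ground truth and reports; seeded functions restore the caller's RNG
  state.
* A displacement exactly at the speed cap is admissible (compared with
  a $1 + 10^{-9}$ relative tolerance so the boundary case links).
* Empty masks, empty spot lists and frames without detections are
  valid inputs yielding empty outputs; zero-path tracks are an error
  for $\rho$ but are removed by the stationary filter first.
* The morphology and blur steps run on EBImage, with intensities
  rescaled around the calls since EBImage's grayscale morphology
  operates on [0, 1]; opening commutes with increasing affine maps, so
  the result is exact.
* Degenerate flat images threshold to empty-or-full masks with a
  warning; the Otsu fallback on a constant image returns that constant.

## Problem sizes used by the packaged checks

The packaged tests and the acceptance script run at sizes chosen to
exercise the defaults while staying desk-scale: paired
256 × 256 × 60-frame movies over 10 seeds for the phenotype-recovery
check (condition-level tests pool the movies of each condition, the way
multi-movie experiments are analyzed), 200 random instances of up to 6
spots per frame for assignment optimality, 1000 null replications
(n = 30 per group, 999 permutations) for test calibration, and 30
isolated-spot frames for localization accuracy.

## Known limitations

* Cell segmentation is out of scope; per-cell counts need a supplied
  label mask.
* No gap closing means fragmented tracks under blinking or occlusion —
  matching the analysis convention this package reproduces, but a
  limitation on data where occlusion is common.
* The linker uses position-only costs; intensity similarity is not
  used.
* Spot size/shape estimation, MSD-based motion classification and
  confinement-radius fitting are not provided.
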