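---
title: "Models and methods: correlative chromatin mobility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: correlative chromatin mobility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromomotion)
```

## The scientific problem

Replication-labeled chromatin in a living nucleus appears as sparse,
diffraction-limited foci whose motion reports on the physical state of the
genome at the scale of the imaging resolution: super-resolution (SIM-like,
~120 nm lateral) foci correspond to loop-scale domains of roughly 100 kbp,
conventional-resolution (WF-like, ~240 nm) foci to TAD-like domains of
roughly 200 kbp, and after several divisions the segregated label marks
whole chromosome territories. `chromomotion` implements the complete
quantification chain for such data: registration of the moving, deforming
cell; spot detection; trajectory linking; mean-squared-displacement (MSD)
model fitting; zonal (nuclear-shell) statistics; motion-subpopulation
classification; and DNA-content quantification of the labeled foci in
fixed cells. Because suitable public raw data do not exist at desk scale,
the package also contains a ground-truthed synthetic-microscopy generator,
and every stage is validated by parameter recovery against that ground
truth.

## Motion models and the MSD estimators

Trajectories are modeled as fractional Brownian motion parameterized so
that the per-axis MSD is $2 D \Delta t^{\alpha}$; a $d$-dimensional track
has $\mathrm{MSD}(\Delta t) = 2 d D \Delta t^{\alpha}$. Brownian motion is
$\alpha = 1$, constrained (sub-diffusive) motion $\alpha < 1$, directed
motion $\alpha > 1$; an explicit drift term is available for directed
tracks, and immobile tracks have $D = 0$.

The generator synthesizes exact fractional Gaussian increments by Cholesky
factorization of the closed-form increment covariance
$\gamma(k) = D\,\mathrm{d}t^{\alpha}\left(|k+1|^{\alpha} + |k-1|^{\alpha} -
2|k|^{\alpha}\right)$. Exactness was preferred over speed (an $O(n^3)$
factorization is irrelevant at the 12–100 frames simulated here), because
the generator's law is what all recovery targets assume. The test suite
verifies the generated increments against this covariance entrywise.

Two models are fitted to every MSD curve, independently, by `msd_fit()`:

* **diffusion**: a weighted least-squares slope through the origin,
  $\mathrm{MSD} = 2 d D \Delta t$, weights = per-lag pair counts. The
  dimensionality convention ($6 D \Delta t$ for 3D foci, $4 D \Delta t$
  for 2D territories) is declared here and used consistently, so that
  simulation and fitting are self-consistent whatever convention the
  numbers are later compared to.
* **anomalous**: a weighted regression of $\log \mathrm{MSD}$ on
  $\log \Delta t$; the slope is $\alpha$ and $e^{\mathrm{intercept}}$ the
  generalized coefficient $\Gamma$ (µm²/s^α).

Fit ranges: ensemble curves from 12-frame movies use all 11 lags; the
end-to-end territory analysis fits the diffusion model on lags up to 40 s
(the same duration threshold the track filter uses) because the long-lag
points of a 25-track ensemble are few-pair averages that dominate the
estimator variance — in repeat simulations the all-lag fit has a ~16%
relative sd versus ~10% for the 40 s range. Per-track fits use lags up to
half the track duration and at most the first 10 lags: the log of a
few-pair MSD average is biased downward (Jensen), and capping the range
measurably reduces both the bias (mean fitted $\alpha$ 1.624 versus 1.584
at a true 1.66 for 100-frame tracks) and the sd (0.11 versus 0.18). No
localization-noise offset term is included in either model; consequently a
fitted $\alpha$ on noisy immobile data is meaningless, which is why the
fixed-control check below is stated on the raw MSD ratio instead.

Per-track motion properties are the radius of gyration (RMS distance from
the track centroid), mean velocity over consecutive steps, start-to-end
distance, and straightness (start-to-end distance over path length). Group
comparisons use two-sided Wilcoxon rank-sum tests (exact for the smaller
group ≤ 8 without ties, normal approximation with tie correction
otherwise).

Only tracks spanning at least 4 inter-frame steps (40 s at the 10 s frame
interval) enter the motion analysis.

## The synthetic-microscopy generator

`scene_config()` defaults encode the acquisition the pipeline targets:
12 frames at 10 s, 7 z-sections, voxel 41 × 41 × 125 nm, and two Gaussian
PSF regimes (SIM-like σ ≈ 51/127 nm lateral/axial, WF-like σ ≈
102/255 nm, i.e. FWHM ≈ 120/300 and 240/600 nm). The nucleus is an
axis-aligned ellipsoid with a soft edge and a fixed multi-scale sinusoidal
internal texture that moves rigidly with it — a stand-in for the granular
appearance of a replication-machinery marker channel, and the signal the
registration stage estimates from. Tracks are *not* reflected at the
nucleus boundary; over 12 frames the excursions are far smaller than the
nucleus, and the unreflected process keeps the generative MSD exactly
equal to the closed form the recovery targets assume.

Photon statistics for the emulated movies are not published, so spot
amplitude, background and noise are configuration, not constants. The
defaults (peak amplitude 150 counts over background 20, Poisson noise then
Gaussian read noise of sd 2 — the standard sCMOS approximation) give a
peak SNR of ~11. Global cell motion is a per-frame affine series composed
with a smooth, band-limited sinusoidal deformation field (composition
order: affine, then deformation — matching the order in which the
registration stage estimates and removes them); frame 1 is always
untouched, and the ground truth stores everything needed to score
registration, detection and tracking.

Fixed-cell DNA scenes (`make_dna_scene()`) are constructed so that the
DAPI-channel sum-intensity fraction of each focus equals its requested
value *exactly* before noise, which is what makes the 2% recovery
criterion on the quantification meaningful. These full-nucleus volumetric
scenes default to a coarser voxel (250 × 100 × 100 nm) than the live
movies so that a > 500 µm³ nucleus fits in a workable array.

What the generator deliberately omits: structured-illumination
reconstruction artifacts, photobleaching, chromatin polymer mechanics, and
axial global motion. Passing recovery tests therefore demonstrates the
correctness of the estimators under the stated models, not robustness to
every property of real reconstructed SIM data.

## Registration

Transforms are estimated on the nucleus channel's maximum-intensity
projection and applied to every z-slice of the requested channels, all
frames to frame 1 (the thin 7-section stacks carry too little axial
information to warrant a 3D transform). The affine stage minimizes the
mean squared intensity difference over a coarse-to-fine pyramid
(Nelder–Mead per level with restarts, initialized by an integer-shift scan
and a 1D rotation scan at the coarsest level — plain simplex descent from
the identity stalls on both axes). Both frames are pre-smoothed (σ = 1.5
px) at every level before the cost is evaluated: with raw noisy frames the
MSE rewards the incidental noise averaging performed by bilinear
resampling and acquires a spurious optimum near half-pixel shifts.

The non-rigid stage is a fluid-like demons estimator run at a reduced
scale (default 0.25; coarse-to-fine from half that scale): the
gradient-normalized intensity force is smoothed (σ = 4.5 px at the reduced
scale) before being added to the field, and only a light diffusion (σ =
0.5) is applied to the accumulated field — smoothing the accumulated field
heavily, as in classical elastic demons, prevents it from ever reaching
the true displacement amplitude. Estimating at reduced scale and upscaling
the field guarantees the result is band-limited; the downscale factor is
exposed as configuration (no published value exists for it).

Registration never makes a frame worse: the composed transform is kept
only if it reduces the projection dissimilarity to frame 1, otherwise the
frame is passed through untouched rather than resampled. Intensities are
interpolated linearly and out-of-view pixels filled with the background
median, avoiding ringing that would create false detections downstream.

## Detection and tracking

Foci are detected with the spot-enhancing filter: an anisotropic
Laplacian-of-Gaussian (axial σ scaled by the voxel anisotropy),
sign-flipped so bright spots give positive peaks, thresholded at
mean(|response|) + k·sd(|response|) with one k per sequence, followed by
26-connectivity local maxima and sub-voxel refinement by an
intensity-weighted centroid over the 3×3×3 response neighborhood. Maxima
inside the filter support of the lateral image border are discarded
(replicate padding inflates the response variance there). No lateral σ or
k is published for this filter; σ defaults to 60 nm (of the order of the
SIM-like spot width) and k was calibrated the way the original control
experiment prescribes — raising k until noise-only control scenes yield
essentially no detections — which lands at k = 7 under the default noise
model (the |response| statistics make the effective threshold roughly
0.8σ + 0.6kσ of the signed response, so values of k that look large are
not). At the defaults, detection achieves ≥ 0.9 recall and precision on
rendered ground truth, and an empty control frame yields zero detections
on ≥ 95% of seeds.

Linking is motion-predictive: each live track carries a per-axis
constant-velocity Kalman state, and each frame-pair correspondence is
solved as an optimal one-to-one assignment (an O(n³) shortest
augmenting-path solver written for this package and tested against
brute-force enumeration) on the distance between predictions and
candidate detections, gated at `gate_um`; unmatched detections seed
tracks, and a track coasts through up to `max_gap` missed frames. This is
a deliberately simpler stand-in for full Bayesian multi-sensor trackers:
the downstream analysis depends on the *output* contract (reliable 3D
linking with motion memory), which is validated directly — ≥ 0.95 link
purity on 1000-track ground truth, and crossing tracks that defeat a
nearest-neighbor linker are resolved without identity switches. No gating
radius or gap setting is published; both are configuration.

Chromosome territories are segmented per frame on WF max-projections with
a difference-of-Gaussians band-pass and Otsu threshold, reduced to
intensity-weighted centroids, and linked 2D by mutual nearest neighbor
with a gate — territory motion per frame (≈ 36 nm at the published
territory mobility) is far below territory separation, so nearest
neighbor suffices there.

## Nuclear shells and subpopulations

The nucleus mask (Otsu on the projection, largest component, holes
filled) is reduced to its convex hull by gift wrapping; scaling the hull
about its area centroid by $\sqrt{i/N}$ produces $N$ nested polygons whose
consecutive rings enclose exactly equal areas — the area law is the unique
scaling for which the equality holds, and it holds to machine precision
for any convex hull and any $N$. Shell 1 is the outermost ring. Each
trajectory is assigned to the shell holding the majority of its x–y
points; points outside the hull (possible after registration resampling)
count as peripheral (shell 1), and majority ties break toward the outer
shell — deterministic, and conservative with respect to the border effect
the shell analysis tests. Per-shell statistics compare shell 1 against
every other shell by rank-sum tests. The construction is 2D by design
(the published procedure scales a 2D polygon); z is ignored.

Motion subpopulations are obtained by 1D k-means (k = 2) on per-track
$\alpha$, initialized by k-means++ (D²-weighted sampling from the data
values) and refined by Lloyd iterations to a fixed point, best of 10
restarts; labels are ordered so population 0 has the lower centroid
(constrained) and population 1 the higher (directed). k-means assignment
is authoritative — no additional $\alpha$-threshold is applied to the
boundary tracks. The within-cluster sum of squares is cross-checked
against `stats::kmeans` in the tests; the hand-rolled implementation
exists because the k-means++ seeding from the data points is part of the
described procedure.

## DNA quantification

Fixed-cell stacks are segmented in two steps. The nucleus: intensity
threshold, slice-wise hole filling, 3D connected components, objects
under 500 µm³ discarded. The foci: triangle auto-threshold on the
256-bin full-stack histogram (forced to the bright tail — the textbook
"longer tail" rule is a coin flip on a symmetric noise histogram),
mask-combined with the original intensities by voxel-wise minimum,
components split at distance-transform maxima (seeds must reach 60% of
the component inradius and be separated by at least the inradius, with
plateau maxima collapsed to their centroid first — a raw distance
transform of a digitized blob has many spurious ridge maxima), and foci
not touching the nucleus removed. Because the triangle threshold adapts
to the histogram, on a pure-noise stack it necessarily sits at a noise
quantile; zero false foci on noise-only controls are achieved by the
minimum-size exclusion (default 20 voxels: suprathreshold noise clusters
stay below ~15 voxels while a diffraction-limited focus at the intended
sampling spans hundreds).

Each focus's DAPI sum intensity over the nuclear total gives its DNA
fraction; multiplying by the stage's cell-cycle correction factor
(G1 = 1, eS = 1.06, mS = 1.27, lS = 1.71, G2 = 1.98) and the genome size
(9.682 × 10⁶ kbp) converts it to kbp. The histogram summary reports the
mode bin ± 5 bins (default bin width 10 kbp — no published width exists)
and the median. The quantification is ratio-based and therefore invariant
to global intensity rescaling. Double-pulse colocalization counts an
object as overlapping if at least one voxel intersects the other set;
combed-fiber lengths convert at 2 kbp/µm, with the calibration defined as
48.5 kbp divided by the mean measured lambda-fiber length.

Real-image medians per focus (210 kbp WF vs 110 kbp SIM in the source
data) depend on real optics and chromatin, and are not reproduced; the
synthetic scenes demonstrate that constructed fractions are recovered
within 2% and that the conversion arithmetic is exact.

## Problem sizes, determinism, limitations

The validation suite simulates 1000 tracks per recovery condition
(12 frames, dt = 10 s), renders end-to-end movies of 45 spots on
256 × 256 × 7 voxel grids, uses 5 movies × 5 blobs for the territory
chain, 600 hundred-frame tracks for the subpopulation recovery, and 100
random convex masks for the shell geometry — sizes at which the
estimator sds measured in repeat simulation are several times smaller
than the recovery tolerances. Every stochastic stage takes an explicit
seed; a fixed configuration reproduces byte-identical CSV outputs, and
`run_all()` stamps outputs with a configuration hash.

Known limitations: the registration model is 2D (constant over z); the
detector's sub-voxel accuracy in z is limited by the 7-section geometry;
the tracker handles no merging, splitting or re-identification after long
gaps; the shell construction assumes a convex nucleus; and the noise
model omits SIM reconstruction artifacts, so thresholds tuned here should
be re-calibrated on real reconstructed data with the same fixed-cell
control procedure the package implements.
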