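---
title: "Methods: single-molecule TIRF and membrane-patterning analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-molecule TIRF and membrane-patterning analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhopatterns)
```

rhopatterns analyses the membrane dynamics of Rho-family GTPases as seen in
dual-colour single-molecule TIRF microscopy of supported lipid bilayers
(SLBs) and in wounded cells: where molecules land, whether they arrive in
complex with their cytosolic chaperone (RhoGDI), how fast they diffuse, how
long they stay, and how strongly they enrich inside membrane domains where
they are activated. This vignette documents the models, the estimators, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## The generative model

`simulate_tracks()` implements the statistical structure of a
single-molecule recruitment movie:

* **Landings** form a spatio-temporal Poisson process with rate $\lambda$
  (s$^{-1}\mu$m$^{-2}$) over the field of view; the number of tracks in a
  movie of area $A$ and duration $T$ is Poisson with mean $\lambda A T$,
  and landing times are uniform.
* **Diffusion** is 2-D Brownian motion: per-frame displacements are
  Gaussian with variance $2 D \Delta t$ per axis.
* **Dwell times** are exponential with dissociation rate $k_{\mathrm{off}}$;
  the survival fraction is $S(t) = e^{-k_{\mathrm{off}} t}$.
* **Co-labeling**: with probability $f$ a landing carries a second-channel
  partner at the same true position (the GDI-complexed state), which
  disappears after an exponential single-step photobleach time.
* **Localization noise** adds isotropic Gaussian error $\sigma$ per axis
  to every observed position.

Time is discretized at the frame interval (default 22 ms, matching
streamed acquisition with continuous illumination): a landing occurs at
the start of its birth frame, and a dwell of $\tau$ seconds occupies
$\lceil \tau / \Delta t \rceil$ frames, at least one. Consequences of this
choice: dwell times are quantized upward by on average half a frame, so
rate estimates from frame-quantized dwells carry a relative bias of order
$k_{\mathrm{off}} \Delta t / 2$; at the regimes simulated here that is
below one percent. Walkers that cross the FOV boundary are terminated at
their last in-bounds frame and flagged `left_fov` in the ground truth, so
analyses can exclude them; tracks alive in the final frame are flagged
`censored`.

The pixel size is a free parameter (default 0.1 µm/px) — it is an optical
property of the instrument, not something the analysis can infer — and all
coordinates, thresholds and rates are metric (µm, s).

What the generator deliberately does **not** emulate: multi-step or
blinking photophysics, anomalous or state-switching diffusion, EMCCD gain
and shot noise (camera noise is additive Gaussian), motion blur within a
frame, and chromatic or registration offsets between the two channels.
Passing the recovery tests therefore demonstrates that the estimators are
correct for the stated model, not that they are robust to every artifact
of real microscope data.

## Spot detection and linking

The paper's original workflow delegates detection and linking to
TrackMate; rhopatterns re-implements both so the pipeline is
self-contained and its contracts testable.

* `detect_spots()` is Laplacian-of-Gaussian blob detection: each frame is
  filtered with a zero-sum, negated LoG kernel at the PSF scale, strict
  8-neighbour local maxima above a response threshold are kept, and each
  peak is refined by an intensity-weighted centre of mass over a
  $(2\lceil 2\sigma\rceil + 1)^2$ window. The window minimum is subtracted
  before the centre-of-mass step: on a constant background a raw
  first-moment estimate is pulled toward the window centre, and the
  sub-pixel contract (error $< 0.1$ px on noiseless spots) is only
  attainable with a background-free moment.
* `link_tracks()` uses greedy nearest-neighbour assignment: all candidate
  (track end, spot) pairs within `max_disp` are sorted by distance (ties:
  lower spot index) and accepted one-to-one. Tracks may survive `max_gap`
  missed frames and compete for resumption in the same pool. At
  single-molecule densities the greedy solution coincides with the
  minimal-total-distance assignment; the test suite checks this against
  an exhaustive oracle on small crossing configurations. Global LAP or
  Kalman linking is out of scope.

`crop_fov()` implements the convention of analysing only the top-left
portion of the field of view: both axes are scaled by the fraction (0.75
by default, hence 56.25% of the area), bounds are half-open so a
coordinate exactly on the crop line is excluded, and the stored FOV
metadata is rescaled so that landing rates computed afterwards are per
*analysed* area automatically.

## Colocalization and co-recruitment

Two spots in the same frame are colocalized when their centroid distance
is at most 0.5 µm — the threshold is inclusive, and matching is
A-to-nearest-B without exclusivity (two A spots may share a B partner;
at the densities of interest this is immaterial and the distance rule is
the entire criterion). A track is *co-recruited* when it is colocalized
in at least one of its first three observed frames (birth frame plus the
next two observations; gap frames do not count). Whether "any" or "all"
of the window frames should be required is genuinely ambiguous; `any` is
the default and `window_rule = "all"` is available.

In `experiment` mode only new landing events — tracks born after the
first movie frame — enter the denominator; in `control` mode tracks
already present in frame 0 (e.g. surface-immobilized positive controls)
are included, each exactly once. The expected colocalization level for
unrelated channels is the spatial-Poisson null
$p = 1 - e^{-\rho \pi r^2}$ (`chance_colocalization()`), where $\rho$ is
the partner density; a co-recruitment fraction is only meaningful when
this chance level is small against the binomial error, which is exactly
the regime single-molecule experiments are run in (instantaneous
densities around $10^{-3}$–$10^{-2}$ µm$^{-2}$). The recovery tests
simulate in that regime on purpose.

`coloc_probability_by_position()` resolves colocalization along the track
lifetime: for each offset $k$ since recruitment, the fraction of tracks
still alive at $k$ that are colocalized at $k$. Genuine co-recruitment
shows a peak at offset 0 that decays with the partner bleach rate; random
encounters give a flat profile at the chance level.

## Lipid-pattern segmentation and the patterning index

The segmentation pipeline follows denoise → equalize → seeded
random-walker → morphological clean-up:

1. **Non-local means** (`nlm_denoise()`): patch-based weighted averaging
   with weights $e^{-d^2/h^2}$, where $d^2$ is the mean squared difference
   between 3×3 patches within an 11×11 search window. Implemented by
   shifting the frame over all search offsets and box-filtering the
   squared difference, which is exact. Default strength
   $h = 0.8\,\mathrm{sd}$(frame). A constant frame is a fixed point.
2. **CLAHE** (via EBImage): contrast-limited adaptive histogram
   equalization on the min-max-scaled frame (default 4×4 tiles, clip
   limit 4). Equalization serves segmentation only.
3. **Random walker** (`random_walker()`): pixels are nodes of a
   4-connected lattice with edge weights $e^{-\beta (g_i - g_j)^2}$ on the
   $[0,1]$-scaled image; unlabeled pixels get the probability that a
   walker reaches an inside seed first, i.e. the solution of the sparse
   Dirichlet problem, solved with Matrix. $\beta = 130$ is a tuning
   default, not derived from any measurement.
4. **Clean-up** (`clean_mask()`): five iterations of binary closing then
   five of binary opening with a 3×3 element. Erosion is padded with
   `TRUE` at the frame border so border-touching domains are not eaten.
   Note the cumulative structuring element is effectively 11×11: domains
   whose radius of curvature is below ~5 px get visibly trimmed, which is
   a resolution artifact, not a property of real micrometre-scale domains
   imaged at 0.1 µm/px. Test problem sizes (96×96 px frames with domain
   radii ≥ 12 px) are chosen to stay in the regime the morphology was
   designed for.

**Seeding.** The seeds bracket a splitting point of the intensity
histogram. The default places the split at the Otsu threshold and leaves
an unlabeled margin band (25% of the distance to each extreme) around it.
A fixed-quantile alternative (`seeds = "quantile"`, P25/P75 bands) is
provided, but it implicitly assumes the two domains occupy comparable
areas: when the pattern covers, say, 20% of the frame, the upper quartile
necessarily contains outside pixels and the walker inherits false hard
constraints. The Otsu band tracks the actual intensity split regardless
of area fraction, and is scale-free like the rest of the pipeline (the
whole segmentation is invariant to multiplying the raw frame by a
positive constant). A frame with no contrast raises an explicit error
rather than returning an arbitrary mask.

The **patterning index** is computed on *raw* intensities — never on the
equalized image, which destroys exactly the ratio the statistic measures:
$PI = \langle I_\mathrm{in}\rangle / \langle I_\mathrm{out}\rangle$, with
1.0 meaning equal partitioning. Frames with an empty region yield `NA`
with a warning rather than being dropped. `normalize_pi()` rescales a
series by its mean over a pre-perturbation baseline window. Segmentation
is per-frame with no temporal smoothing.

## Diffusion statistics

Step sizes are per-frame displacements of linked tracks; steps across
linking gaps are excluded so all steps share one time base. For Brownian
motion steps are Rayleigh with mode $\sqrt{2 D \Delta t}$. The MSD is
**time-averaged within each track, then ensemble-averaged across tracks**
(unweighted across tracks); whether the original analysis time-averages,
ensemble-averages, or both is not stated anywhere, and the both-averaged
estimator is the standard low-variance choice. Pairs are matched on true
frame separation, so gaps contribute to their actual lag rather than
polluting shorter ones. For 2-D Brownian motion with static localization
noise,

$$\mathrm{MSD}(k\Delta t) = 4 D k \Delta t + 4\sigma^2,$$

so `fit_diffusion()` (OLS over the first 4 lags by default) reports
$D = \mathrm{slope}/4$ and an intercept estimating $4\sigma^2$. Motion
blur, which reduces the intercept in real data, is not modelled. Region
contrasts (inside vs outside GEF-containing domains) assign each step by
the region of its *starting* spot.

## Kinetic fits

All kinetics — FRET exchange decays, dwell-time survival, flow-out
dissociation, FRAP recovery, photoactivation disappearance — share one
fitting layer: $y = C + A e^{-kt}$ (decay) or $y = C + A(1 - e^{-kt})$
(growth), fitted by Levenberg–Marquardt (minpack.lm's `nls.lm`).
Initialization unless overridden: $C$ from the data floor/ceiling, $A$
from the range, $k$ from a log-linear regression on the first half of
the baseline-subtracted data. Convergence at relative tolerance
$10^{-12}$ within 500 iterations, else an explicit error — never silent
defaults. A non-positive rate at the optimum is flagged `degenerate`.
Standard errors come from the residual covariance; on an exactly
noise-free trace the covariance is singular and `se_k` is `NA`. Fits are
unweighted by default ($\sigma$-weights optional). Every fit satisfies
$t_{1/2} k = \ln 2$ identically, because $t_{1/2}$ is derived, not
fitted.

Survival curves use the $\ge$ convention at observed dwell times, so
$S(\min \mathrm{dwell}) = 1$. Right-censored dwells (tracks alive at
movie end) are **excluded** from the fraction and reported in
`n_censored`: the original analysis does not describe censoring handling,
and transparent exclusion with a reported count was preferred over a
silent Kaplan–Meier estimator the source never describes. The bias is
bounded by the censored fraction, which the caller can check.
`fit_survival()` fixes $C = 0$ since survival fractions decay to zero.

## Wound analysis

`radial_kymograph()` bins pixels by distance to the wound centre into
half-open annuli $[k w, (k+1) w)$ and averages per annulus and frame.
The wound centre is supplied by the user (automatic detection is not
attempted; wounds in the source system are laser-placed and the centre is
known). `zone_profile()` takes the column at the frame nearest a
requested time, rounding down at midpoints. The in vivo patterning index
divides the radial peak at a chosen time by the mean over all annuli at
least 30 µm from the centre — a region mean, not a single bin, because
"at least 30 µm" denotes a background zone. Cortical-flow registration
(advection correction) is out of scope.

## Equilibria and geometry

`equilibrium_free()` solves the 1:1 binding equilibrium
$(\mathrm{A_t}-x)(\mathrm{B_t}-x) = K_D x$ in the numerically stable form
$x = 2ab/(S + \sqrt{S^2 - 4ab})$, $S = \mathrm{A_t}+\mathrm{B_t}+K_D$ —
the naive quadratic root cancels catastrophically in the regime of
interest, where $K_D$ is roughly four orders of magnitude below the
totals (90 pM against 600 nM, giving ~7.3 nM free). Conservation holds to
$10^{-9}$ relative across twelve decades of parameters (property-tested).

`extrapolate_landing_rate()` scales a reference landing rate linearly in
solution concentration. Whether the physiological extrapolation should
scale in total complex or in free GTPase is not specified by the source;
linear scaling in the supplied concentration is implemented and the
caller chooses which concentration to pass (scaling in total reproduces
the published bound).

`footprint_diameter()` takes the maximum pairwise distance of a
coordinate set (exact all-pairs up to $10^4$ points; extreme-point
reduction above) as the diameter of a circular molecular footprint, and
`surface_coverage()` converts a surface density to percent area. The
circular footprint deliberately overestimates the true molecular area —
fidelity to the published procedure over realism.

## Problem sizes and tolerances in the test suite

The packaged tests run the full recovery suite in a few minutes on one
CPU: co-recruitment at ~1000 tracks per condition in the sparse regime
(chance level ≲ 0.5%), the Poisson landing check over 300 replicate
seeds, dwell KS tests at n = 5000, MSD recovery at ~1000 tracks,
segmentation Dice on 20 frames per contrast at 96×96 px, 100 seeded
exponential fits, and $10^3$ random equilibrium systems. These sizes are
the package's choice of a demonstrably sufficient statistical resolution
for each contract (3 binomial SDs, 5–15% relative bands, Dice ≥ 0.95,
$10^{-9}$ conservation); larger simulations sharpen nothing qualitative.

## Known limitations

* Greedy linking is not globally optimal at high densities; the package
  targets single-molecule regimes.
* Censored-dwell exclusion biases survival fits when censoring is heavy
  (short movies relative to dwell time); inspect `n_censored`.
* The additive-Gaussian camera model understates noise correlations of
  EM-CCDs; detection thresholds on real data need empirical tuning.
* CLAHE parameters, NLM strength and the random-walker $\beta$ are
  config-level defaults chosen on synthetic data, not values inherited
  from any instrument.
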