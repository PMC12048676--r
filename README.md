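# rhopatterns

Analysis of Rho GTPase membrane dynamics from single-molecule TIRF
microscopy and membrane-patterning experiments.

Rho-family GTPases (Rho, Rac, Cdc42) cycle between a cytosolic pool —
bound to their chaperone RhoGDI — and the plasma membrane, where GEFs
activate them and effectors retain them, producing the membrane activity
patterns that drive cell division, migration and wound repair. The
experiments that dissect this cycle produce a recurring set of
quantitative questions: at what rate do single molecules land on a
supported lipid bilayer, do they arrive in complex with RhoGDI
(dual-colour co-recruitment), how fast do they diffuse, how long do they
dwell, how strongly do they enrich inside lipid domains where a GEF is
anchored, and what do mass-action equilibria predict for the free
concentrations feeding the membrane? rhopatterns implements that entire
desk-side pipeline for R, together with a synthetic-data generator with
full ground truth, so every estimator in the package is verifiable
without microscope data.

The package is tidyverse-native: spot tables are tibbles, results are
tibbles, fitted objects have `tidy()`/`glance()` methods, and result
types have `autoplot()` methods.

## What it computes

| Quantity | Definition | Function |
|---|---|---|
| Co-recruitment fraction | fraction of new tracks colocalized (≤ 0.5 µm) with a partner channel in ≥ 1 of their first 3 frames | `co_recruitment_fraction()` |
| Chance colocalization | `1 − exp(−ρπr²)` for partner density ρ | `chance_colocalization()` |
| Landing rate | new tracks / (area × duration), s⁻¹µm⁻² | `landing_rate()` |
| Patterning index | `PI = ⟨I_in⟩ / ⟨I_out⟩` over a segmented lipid domain | `patterning_index()` |
| Diffusion coefficient | `MSD(kΔt) = 4Dk Δt + 4σ²`, D from the initial slope | `msd_curve()`, `fit_diffusion()` |
| Dwell kinetics | survival fraction `S(t)` and mono-exponential fits `y = C + A e^(−kt)`, `t½ = ln2/k` | `survival_curve()`, `fit_monoexp()` |
| Wound enrichment | radial kymograph peak / background ≥ 30 µm from the wound | `radial_kymograph()`, `wound_patterning_index()` |
| Binding equilibrium | root of `(A_t − x)(B_t − x) = K_D x`, solved stably | `equilibrium_free()` |

Supporting stages: LoG spot detection and greedy nearest-neighbour track
linking (`detect_spots()`, `link_tracks()`), TrackMate-dialect CSV I/O
(`read_spot_csv()`), top-left FOV cropping (`crop_fov()`), the
NLM → CLAHE → random-walker segmentation pipeline (`preprocess_stack()`,
`segment_stack()`), molecular footprints and surface coverage
(`footprint_diameter()`, `surface_coverage()`), and the generator family
(`simulate_tracks()`, `simulate_pattern_movie()`, `simulate_decay_trace()`,
`simulate_wound_movie()`, `render_movie()`).

## Worked example

Simulate dual-labeled GTPase:GDI complexes landing on a 50 × 50 µm
bilayer imaged at 22 ms for one minute — a 63% co-labeled population at
single-molecule density — then ask the analysis what it sees:

```r
library(rhopatterns)

cfg <- sim_config(fov_width = 50, fov_height = 50, frame_interval = 0.022,
                  n_frames = 2700, landing_rate = 0.0068,
                  dissociation_rate = 2, diffusion_coeff = 0.05,
                  colabel_fraction = 0.63, localization_sigma = 0.02,
                  seed = 1)
sim <- simulate_tracks(cfg)

sim$channel_a %>%
  co_recruitment_fraction(sim$channel_b, coloc_config(radius = 0.5, window = 3))
#> # A tibble: 1 × 4
#>   n_tracks n_corecruited fraction binomial_sd
#>      <int>         <int>    <dbl>       <dbl>
#> 1      988           618    0.626      0.0154

landing_rate(sim$channel_a)
#> [1] 0.006653199

sim$channel_a %>% msd_curve(max_lag = 4) %>% fit_diffusion() %>% glance()
#> # A tibble: 1 × 4
#>        D intercept r.squared n_points
#>    <dbl>     <dbl>     <dbl>    <int>
#> 1 0.0512   0.00151     1.000        4

equilibrium_free(600, 600, 0.09)
#> # A tibble: 1 × 3
#>   free_a free_b complex
#>    <dbl>  <dbl>   <dbl>
#> 1   7.30   7.30    593.
```

Reading the numbers: 618 of 988 new tracks (62.6 ± 1.5%) carried a
partner within 0.5 µm during their first three frames, recovering the
programmed 63% co-labeled fraction; the estimated landing rate matches
the configured 0.0068 s⁻¹µm⁻²; the MSD slope gives D = 0.051 µm²/s
(truth 0.05) with an intercept of 0.0015 µm² ≈ 4σ² for the 20 nm
localization noise; and a 600 nM 1:1 complex with K_D = 90 pM leaves
7.3 nM of each species free at equilibrium.

See `vignettes/rhopatterns-methods.Rmd` for the models, estimator
conventions, numerical choices and limitations.

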