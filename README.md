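# printability

Standardized analytics for extrusion-based bioprinting.

Extrusion bioprinting deposits a cell-laden or cell-free hydrogel
(e.g. alginate/GelMA biomaterial inks) through a pneumatic nozzle.
Comparing formulations fairly requires three things this package
provides to lab scientists and process engineers:

1. **Rheology-based pressure planning.** Shear-thinning inks follow the
   Ostwald–de Waele model η = K·γ̇ⁿ⁻¹ (flow-behavior exponent *n*,
   consistency index *K*). Coupling it with the Hagen–Poiseuille
   relation for a power-law fluid in a cylindrical nozzle,

   Q = v̄πR² = nπ/(3n+1) · R³ · (R·p / (2Kl))^(1/n),

   lets the pneumatic pressure *p* be computed so every ink extrudes at
   the same volumetric flow — printing parameters set from data rather
   than operator impressions.

2. **Image-based printing accuracy.** Photographs of printed
   single-layer line, circle and angle structures (52 px/mm) are
   binarized by local-mean thresholding, segmented, and reduced to
   normalized metrics against the CAD target: width w_n = w/d_nozzle,
   length l_n = l/l_model, radii-to-midline r_n = (r_i+r_o)/(2r_model)
   and angle-to-midline α_n = (α_i+α_o)/(2α_model). The midline
   formulation cancels the stroke width, so a perfectly placed
   structure scores exactly 1.

3. **Flow-cytometry viability.** Calcein-AM/propidium-iodide stained
   events are scatter-gated (debris/agglomerate exclusion), classified
   live/dead with a control-derived red threshold, and reduced to
   viability = live/(live+dead) with exact binomial intervals.

A synthetic-data generator renders ground-truthed structure images,
viscosity curves and cytometry event mixtures, so the whole measurement
chain is validated by recovery tests. Replicate aggregation ships with
first-order (Taylor) uncertainty propagation, Jarque–Bera normality
checks and one-way ANOVA.

## Worked example

```r
library(printability)

# --- plan the pressure for the stiffer ink (n = 0.32, K = 284.09) ----
curve <- simulate_viscosity(power_law(0.32, 284.09), c(1, 1000),
                            points = 25, noise_cv = 0, seed = 1)$curves[[1]]
ink   <- fit_power_law(curve)
plan  <- extrusion_plan(ink, nozzle_geometry(), mean_velocity = 10)
plan
#> Extrusion plan: p = 129.1 kPa, v = 10 mm/s, Q = 2.922 mm^3/s
#> Ostwald-de Waele model: n = 0.32, K = 284.09 Pa.s^n
#>   fitted over 1-1e+03 1/s (R^2 = 1.0000)
#> Nozzle: R = 0.305 mm, l = 12.7 mm

# --- measure a printed circle (synthetic, over-extruded stroke) ------
r   <- render_structure(render_spec(cad_target("circle"),
                                    stroke_width = 0.8, seed = 5))
seg <- segment_components(binarize(r$image, threshold_offset = 20))
analyze_circle(seg, cad_target("circle"))
#> Circle: r_i = 14.602, r_o = 15.399 mm (r_n = 1.0000), w_n = 1.304
#>   marker at -0.1 deg

# --- viability from gated cytometry events ---------------------------
sim  <- simulate_cytometry(10000, 0.963, debris_fraction = 0.1, seed = 7)
ctrl <- simulate_cytometry(3000, 0, seed = 8)          # all-dead control
thr  <- derive_dead_threshold(ctrl$events, 0.01)
viability(gate(sim$events,
               gating_config(c(1.3e4, 2.5e5), c(8e3, 1.8e5), thr, 1000)))
#> Viability: 96.4% (8665 live / 8987 cells; 95% CI 96.0-96.8%)
```

Reading the numbers: 129.1 kPa is the pneumatic pressure that pushes
this ink through a 0.61 mm × 12.7 mm nozzle at a mean velocity of
10 mm/s (Q = v̄πR² = 2.92 mm³/s). The circle was deliberately rendered
with a 0.8 mm stroke: the normalized width flags the over-extrusion
(w_n = 1.30), while r_n = 1.0000 shows the *placement* was perfect —
the midline metric is independent of stroke width. The viability
estimate (96.4%) recovers the simulation's ground truth within its
binomial interval, with the 10% debris excluded by the scatter gate.

Batch processing (`run_pipeline()`) takes image/curve/event manifests
and writes `metrics.csv`, `aggregate.csv`, `viability.csv` and
`report.json`; a thin command-line wrapper lives at
`inst/cli/printability.R` (subcommands `rheo-*`, `analyze`, `synth-*`,
`cyto-viability`).

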