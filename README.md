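# pomogram

Quantification pipeline for subcellular protein-cluster positioning in
rod-shaped bacteria and for ParA/MinD-family ATPase kinetics — with a
synthetic-data generator that makes every analysis stage verifiable by
parameter recovery.

## Who this is for

Groups studying spatial regulation of bacterial cell division (Pom/Min/Par
-type systems) quantify their microscopy in a recurring set of steps: cell
lengths from segmentation meshes, minicell and constriction calls,
background-corrected fluorescence profiles along the cell, cluster
detection and localization classes, length-sorted demographs, time-lapse
tracking of cluster fission at division, and — on the biochemistry side —
specific ATPase activities from NADH-coupled plate-reader traces.
`pomogram` packages that chain as tested, reusable R functions.

## The quantities at the core

* **Cell length** `L = Σᵢ ‖cᵢ₊₁ − cᵢ‖ · pixel_size` over the mesh
  centerline; population summaries in the 10/25/50/75/90-percentile
  boxplot convention; Mann–Whitney rank-sum comparisons.
* **Profiles and clusters**: per-segment mean intensity minus the median
  of a local background annulus; clusters called by seed-and-grow
  thresholding at `median + k·MAD` (extent `k = 2`, seed `k = 5`, ≥ 2
  segments); localization classes *midcell* (50 ± 5% of cell length),
  *off-center* (elsewhere on the nucleoid) and *subpolar* (DNA-free
  caps).
* **Demographs**: rows = cells sorted by length, oriented with the
  brightest segment rightwards, binned on absolute distance from midcell;
  the brightest 3% of pooled values are capped to the 97th percentile and
  scaled to 1.
* **Cluster fission**: divisions found by frame-to-frame overlap
  tracking; an event is *fission* when both daughters carry visible
  cluster signal (symmetric when the smaller share ≥ 0.3), *no fission*
  when only one does.
* **ATPase activity**: `rate = −slope(A340) / (ε·l)` with
  ε = 6220 M⁻¹cm⁻¹, l = 0.248 cm (one NADH oxidized per ADP), after
  pointwise subtraction of a no-enzyme control; specific activity =
  rate / [enzyme] in ATP · enzyme⁻¹ · hr⁻¹; hyperbolic dose-response
  fits with a 90%-of-plateau saturation dose.

The synthetic generator (`population_preset()`, `kinetic_preset()`,
`render_cell()`, `simulate_timelapse()`, `simulate_atpase_trace()`)
produces cell populations, rendered images + meshes, division series and
plate traces with known ground truth at the emulated study's measured
values (e.g. wild-type lengths 8.0 ± 1.8 µm, cluster prevalence 0.94,
~80% fission, specific activities 7–44 ATP hr⁻¹ at 4 µM enzyme).

## Worked example

```r
library(pomogram)

tr      <- sample_cell_population(population_preset("WT"), 100, seed = 1)
renders <- render_population(tr, seed = 1)

lens <- vapply(renders, function(r) cell_length(r$mesh), numeric(1))
summarize_lengths(lens)
#> Lengths (n = 100): 8.20 +/- 1.62 um; median 8.21 [7.11, 9.24],
#>   whiskers [6.11, 10.13], 20 outliers

profiles <- lapply(renders, function(r) extract_profile(r$image, r$mesh))
calls    <- lapply(profiles, detect_clusters)
cluster_fraction(calls)
#> [1] 0.9

all_calls <- do.call(rbind, calls)
table(classify_localization(all_calls$relative_position))
#>    midcell off_center   subpolar
#>         43         47          0

sim <- simulate_atpase_trace(kinetic_preset("pomx_wt"), seed = 1)
specific_activity(adp_rate(subtract_control(sim$sample, sim$control)))
#> ADP rate 175.93 uM/hr (slope -0.2714 /hr, R2 0.9992, 231 reads in [300, 7200] s)
#>   specific activity 43.98 ATP/enzyme/hr at 4 uM enzyme
```

The 100-cell sample recovers the preset length distribution (8.0 ± 1.8 µm)
and cluster prevalence (0.94 → 90/100 detected on this draw); the
simulated 15 µM-activator trace recovers its preset specific activity of
44 ATP hr⁻¹ from the fitted A340 slope of −0.27 hr⁻¹.

A demograph of the same population: `plot(build_demograph(profiles, lens))`.
A complete multi-stage run from a config file:
`run_pipeline(system.file("extdata", "demo_config.yaml", package = "pomogram"))`
(set `out_dir` first), or via the thin CLI wrapper `inst/exec/pomogram`.

## The methods vignette

`vignettes/pom-cluster-quantification.Rmd` documents the models and
procedures, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, numerical edge cases, and
known limitations.
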