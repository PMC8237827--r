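# meltprint

Species identification from ISSR-HRM melting fingerprints.

Inter-simple sequence repeat (ISSR) PCR amplifies many anonymous loci
with one microsatellite-anchored primer; high-resolution melting (HRM)
of the product mix yields a derivative melt curve, −dF/dT vs T, with one
peak per resolvable duplex population. The ordered peak set — the
**melting fingerprint** — is characteristic of the template species, and
matching a query fingerprint against an archived reference library
identifies stranded marine mammals (dolphins, whales, dugongs) whose
carcasses can no longer be identified morphologically.

`meltprint` implements the complete analysis:

* **Simulation** — 16-species × 8-primer ground-truth panels with the
  known reference Tm sets embedded exactly (bottlenose/striped dolphin
  UBC812, *Kogia* UBC826, the two dugong populations under UBC848),
  logistic melt-transition curves
  `F(T) = post + s·(T−T₀) + Σ aᵢ·σ((tmᵢ−T)/wᵢ) + ε`, replicate Tm jitter,
  population offsets and instrument noise — all pure functions of a seed.
* **Extraction** — pre/post-melt normalization, Savitzky–Golay −dF/dT,
  prominence-based peak calling with sub-grid Tm refinement.
* **Matching** — monotone dynamic-programming peak alignment under a Tm
  tolerance (default 0.3 °C); distance
  `d = (Σ|ΔTm|/τ + λ·u)/(|M| + u)` over matched pairs `M` and unmatched
  peaks `u`.
* **Classification** — nearest reference per primer with rejection
  (`UNCLASSIFIED`), mean-distance primer combinations, and
  primer-set discrimination matrices over all `C(8,2) = 28` pairs.
* **Evaluation** — one-vs-rest confusion counts and the four standard
  metrics (accuracy `(TP+TN)/n`, precision `TP/(TP+FP)`, sensitivity
  `TP/(TP+FN)`, specificity `TN/(TN+FP)`), aggregated per primer and per
  species, plus an end-to-end blind-trial harness.

## Worked example

```r
library(meltprint)

panel <- make_default_panel(seed = 1)
mc <- simulate_melt_curve(
  panel_cell(panel, "Indo-Pacific bottlenose dolphin", "UBC812"),
  panel$grid, baseline_post = 5, baseline_slope = -0.05)
fp <- extract_fingerprint(mc)
fp
#> <melt_fingerprint> curve [NA] 4 peak(s)
#>   Tm: 80.0, 81.9, 86.1, 88.0 degC

lib <- library_from_panel(panel)
classify_single_primer(fp, lib, "UBC812")
#> <classification> curve [UBC812] -> Indo-Pacific bottlenose dolphin (d=0.000, margin=0.250)
```

The four called peaks recover the reference pattern of this species to
grid precision, and the query is assigned at distance 0. The margin,
0.250, is the distance to the runner-up — the striped dolphin, whose
UBC812 fingerprint differs by only 0.1–0.2 °C in its first two peaks;
under realistic replicate jitter these two species form a genuinely
confusable cluster, which is why single-primer accuracy drops for them.

A small blind trial under realistic noise (Tm jitter SD 0.1 °C,
instrument noise 0.2 a.u.), classifying 20 unlabelled queries from four
species against a library rebuilt from 3 jittered replicates per cell:

```r
cfg <- trial_config(panel_seed = 1, tm_jitter_sd = 0.1, noise_sd = 0.2,
                    replicates_per_cell = 3,
                    counts = c("Spinner dolphin" = 5, "Striped dolphin" = 5,
                               "Indo-Pacific bottlenose dolphin" = 5,
                               "Dugong" = 5))
trial <- run_blind_trial(cfg)
trial
#> <blind_trial> 20 queries x 8 primers
#> Per-primer assignment accuracy (%):
#>   UBC812: 70.00
#>   UBC817: 95.00
#>   UBC818: 95.00
#>   UBC826: 80.00
#>   UBC827: 85.00
#>   UBC847: 90.00
#>   UBC848: 80.00
#>   UBC880: 80.00

format(trial$table)$per_species
#>                          species accuracy precision sensitivity specificity
#>                  Spinner dolphin    96.88    100.00        87.5      100.00
#>                  Striped dolphin    95.00     96.88        82.5       99.17
#>  Indo-Pacific bottlenose dolphin    96.88     95.83        92.5       98.33
#>                           Dugong    93.75    100.00        75.0      100.00
```

UBC812 — the primer whose bottlenose/striped patterns nearly coincide —
is the least accurate, exactly the qualitative behaviour seen on real
material. The per-species table is the one-vs-rest mean over all eight
primers (percent scale, half-up rounding at two decimals).

The same pipeline is scriptable from a shell via the launcher in
`inst/cli/` (`simulate-panel`, `simulate-curves`, `extract`, `classify`,
`discriminate`, `evaluate`, `report`); every run writes a
`*.manifest.json` with flags, config hash, seed and versions.

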