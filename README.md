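# limnoch4

Temperature sensitivity of lake-sediment methane ebullition, and the
geochemistry and microbiota underneath it.

Shallow post-glacial lakes lose methane mostly by ebullition — bubbles
rising straight from the sediment to the atmosphere — and that flux rises
steeply with sediment temperature. The steepness can differ between a
lake's shallow littoral **edge** and its deeper pelagic **middle**; since
the middles are the zones that will warm most in a longer ice-free season,
the difference matters for emission forecasts. `limnoch4` is an R package
for researchers analyzing that problem end to end:

* **Flux thermal analysis.** Bubble-trap records are binned in 1 °C
  intervals of surface-sediment temperature; binned means feed Arrhenius
  regressions `ln F = ln A + b / T` (apparent activation energy
  `E_a = -bR`), and pairwise homogeneity-of-slopes tests
  (`ln F ~ group × 1/T`) compare zones, with robustness subsets that trim
  unshared temperature ranges or extreme bins.
* **Isotope mass balance.** From porewater `δ13C-CH4`, `δ13C-DIC`, and
  bulk `δ13C-TOC`: the fractionation factor
  `α = (δ_sub + 1000)/(δ_CH4 + 1000)`, the fraction `f` of DIC generated by
  methanogenesis (two-endmember mixing with the methanogenic CO2 endmember
  at `2 δ_TOC − δ_CH4`), generated CH4 `= f·DIC`, and **fugitive CH4**
  `= generated − measured` at each core depth. `αC` classifies the dominant
  methanogenic pathway (hydrogenotrophic vs acetoclastic).
* **Community statistics.** Rarefaction, replicate averaging, square-root
  Bray–Curtis, PCoA, one-way PERMANOVA (with an exact exhaustive mode),
  Spearman Mantel tests, functional-guild relative abundances from an
  editable YAML clade map, qPCR absolute quantification, and an
  absolute-abundance guild proxy.
* **Prediction.** Self-contained NIPALS PLSR with VIP scores
  (`ΣVIP² = p`; predictors with VIP > 1 flagged) and MLR with adjusted r²,
  comparing abiotic-only against abiotic + microbial variable suites for
  predicting porewater CH4.
* **Synthetic study generator.** A seeded two-lake, edge/middle, 4–40 cm
  core design with zone-dependent Arrhenius slopes, a forward isotope
  model, guild-structured Dirichlet-multinomial OTU tables, and qPCR
  plates — so the entire pipeline is testable offline.

## Worked example

```r
library(limnoch4)
cfg <- synthetic_config(seed = 1)
rep <- run_pipeline(cfg, n_perm = 999)
print(rep)
#> <limnoch4 pipeline report>
#>   Arrhenius slopes (K):
#>     IH edge       -6072 (se 509, r2 0.90)
#>     MH edge       -4440 (se 852, r2 0.63)
#>     IH middle    -18601 (se 1100, r2 0.97)
#>     MH middle    -17022 (se 1300, r2 0.96)
#>   dominant methanogenic pathway: hydrogenotrophic
#>   PERMANOVA edge vs middle p = 0.057; lake p = 0.673
#>   PLSR abiotic         r2 = 0.582 (3 comps, 6 vars)
#>   PLSR abiotic_guilds  r2 = 0.643 (2 comps, 9 vars)
#>   PLSR full            r2 = 1.000 (10 comps, 136 vars)
```

The middle-zone slopes (≈ −18000 K) are ~3.4-fold steeper than the edge
slopes (≈ −5000 K): lake middles are the more temperature-sensitive
emitters, exactly the structure the generator encodes. The isotope module
classifies every core depth as hydrogenotrophic, and adding
functional-guild abundances to the six abiotic variables lifts the PLSR
calibration r² from 0.58 to 0.64 (the `full` suite's r² ≈ 1 is a
calibration artifact of 136 correlated predictors — compare `plsr_q2`).

A single depth through the isotope mass balance:

```r
fugitive_ch4(data.frame(depth_cm = 10, d13C_TOC = -28, d13C_CH4 = -80,
                        d13C_DIC = -2, CH4_uM = 300, DIC_uM = 2000))
#>      alpha   alphaC          pathway f_meth generated_CH4_uM fugitive_CH4_uM
#> 1 1.056522 1.084783 hydrogenotrophic    0.5             1000             700
```

Half the DIC is methanogenic, so 1000 µM CH4 was generated; with only
300 µM still in porewater, 700 µM already escaped as fugitive CH4.

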