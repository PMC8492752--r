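---
title: "Methods: from bubble-trap fluxes to sediment microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from bubble-trap fluxes to sediment microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limnoch4)
```

# The scientific problem

Post-glacial lakes at high latitude lose most of their methane by
ebullition: bubbles formed in the sediment rise straight to the atmosphere,
bypassing water-column oxidation. Ebullitive flux responds strongly to
sediment temperature, but that response can differ between the shallow
littoral "edge" of a lake and its deeper pelagic "middle" — and the deeper
zones are the ones that will warm most as ice-free seasons lengthen.
`limnoch4` implements a complete analysis chain linking that temperature
sensitivity to what lives and reacts in the sediment:

1. **Flux thermal analysis** — temperature binning of bubble-trap records,
   Arrhenius regression, and homogeneity-of-slopes tests between lake
   zones.
2. **Isotope mass balance** — partitioning porewater methane into the pool
   still present and the "fugitive" pool that already escaped, depth by
   depth, and classifying the dominant methanogenic pathway.
3. **Community statistics** — rarefaction, Bray–Curtis ordination,
   PERMANOVA, Mantel tests, functional-guild abundances, and qPCR-based
   absolute abundance.
4. **Predictive models** — PLSR (with VIP scores) and MLR predicting
   porewater CH4 from abiotic profiles and microbial abundances.

Every stage is exercised end-to-end on synthetic sediment cores whose
statistical structure mirrors a two-lake, edge-versus-middle field design,
so the whole chain is testable without any data download.

# Flux and temperature

Bubble-trap records carry a flux (mg CH4 m^-2 d^-1), a surface-sediment
temperature, and lake/zone labels. `bin_flux()` pools records into
half-open, integer-anchored 1 °C bins (`[k, k+1)`, center `k + 0.5`); the
anchoring convention is ours — any fixed anchor is defensible, and the bin
width is a parameter. Within-bin means carry Student-t 95% confidence
intervals computed from the within-bin flux values; single-record bins are
retained for regression but flagged as degenerate.

`fit_arrhenius()` regresses `ln(mean flux)` on inverse absolute temperature
per group, unweighted by default because each binned mean is treated as one
observation of the temperature response; a count-weighted variant sits
behind `weights = "n"`. The apparent activation energy is `-slope × R`.

`compare_slopes()` tests homogeneity of regression between group pairs with
the pooled interaction model `ln(flux) ~ group + 1/T + group:1/T`,
reporting the F-test p-value of the interaction. The "temperature interval"
regressor is continuous inverse temperature, consistent with the Arrhenius
framing. Three robustness subsets are built in for edge–middle pairs:
trimming edge bins warmer than the warmest middle bin, and dropping the
warmest or coldest middle bin. Both binned-means (default) and raw-record
modes are provided because the underlying choice is genuinely open; the
raw-record mode attains the exact nominal type-I level under lognormal
flux noise (the log records are Gaussian), while the binned-means mode is
slightly conservative in our null simulations (rejection ≈ 0.02–0.03 at a
0.05 level) because bins with unequal counts violate homoscedasticity.

`incubation_rate()` converts a headspace time series to a production rate:
OLS slope of headspace CH4 over time divided by sediment dry mass, with
negative slopes flagged rather than clipped.

# Isotope mass balance for fugitive CH4

The model rests on three assumptions, stated explicitly because every
downstream number inherits them: fermentation and respiration generate DIC
without fractionating carbon; methanogenesis generates CH4 and CO2 in 1:1
proportion and does fractionate; the system is at steady state, with DIC
staying dissolved while CH4 escapes. With the substrate pinned at the bulk
organic carbon ratio `d13C_TOC`:

* fractionation factor: `alpha = (d13C_TOC + 1000) / (d13C_CH4 + 1000)`;
* methanogenic CO2 endmember: `d13C_CO2meth = 2 d13C_TOC - d13C_CH4`;
* methanogenic fraction of DIC:
  `f = (d13C_DIC - d13C_TOC) / (d13C_CO2meth - d13C_TOC)`;
* generated CH4 = `f × DIC`; fugitive CH4 = generated − measured.

This is the minimal two-endmember formulation satisfying those
assumptions. A Rayleigh-distillation closure would change the endmember
equations only; they are isolated in one internal function
(`dic_endmembers()`) precisely so that variant can be substituted.
Acetate-pool fractionation is deliberately ignored: without a measured
acetate isotope ratio there is nothing to constrain it with.

Numerical policy: `f` is clipped to `[0, 1]` with a flag (field noise can
push it slightly out), negative fugitive CH4 is flagged but *not* clipped —
a steady-state violation is diagnostic information — and the degenerate
case `d13C_CH4 = d13C_TOC` (zero endmember separation) returns a flagged
missing result instead of dividing by zero.

The apparent fractionation `alphaC = (d13C_DIC + 1000)/(d13C_CH4 + 1000)`
classifies the dominant pathway: hydrogenotrophic at `>= 1.065`,
acetoclastic at `<= 1.055`, intermediate between. These are the classical
isotope-zonation conventions; the literature states no single pair, so both
thresholds are arguments.

# Community statistics

Rarefaction (`rarefy_counts()`) is a single seeded draw without
replacement, not a mean over draws, so one reproducible table feeds every
downstream statistic; samples below the depth are dropped with a warning.
Replicate pairs are averaged per OTU (`average_replicates()`); groups
larger than two are rejected because the supported design is paired.
Abundances are square-root transformed before Bray–Curtis dissimilarity
(computed by `vegan::vegdist()`).

`pcoa()` double-centers `-D^2/2` and eigendecomposes; coordinates are
eigenvectors scaled by the square root of positive eigenvalues, and
negative eigenvalues are reported without Lingoes/Cailliez correction so
the user sees the metric distortion rather than a silently adjusted
ordination. `permanova()` uses the classical one-way partition of squared
distances (total minus within-group) with label permutation, and offers an
exhaustive-enumeration mode for small designs where the permutation
distribution can be computed exactly. `mantel_test()` correlates condensed
distance vectors (Spearman by default) with row/column permutation. All
three are implemented here rather than delegated, because the exhaustive
modes and flags the pipeline needs are not exposed by the usual wrappers;
`vegan::adonis2`, `vegan::mantel`, and `stats::cmdscale` serve as
independent cross-checks in the test suite.

Functional guilds ship as an editable YAML map of case-insensitive
substring patterns over lineage strings. Order matters and the file says
so: ANME clades nest inside the methanogenic order Methanosarcinales, so
ANME patterns are matched first and each taxon is assigned to at most one
guild. Guild edge-versus-middle contrasts are reported both as a two-tailed
t-test and a one-way ANOVA, since both conventions are common and they
coincide (F = t²) for two groups with pooled variance.

qPCR quantification converts the standard stock to gene copies per µL from
the genome size (4,686,137 bp), 16S copy number (7), 20 ng/µL stock and a
650 g mol^-1 bp^-1 mean pair mass, regresses Ct on log10 copies, and
inverts sample Cts through the dilution and extraction normalization
(0.25 g into 100 µL by default). Out-of-range Cts are flagged as
extrapolated. The absolute-abundance proxy (relative abundance × total
copies per g) deliberately repeats the zone tests so the user can see how
the steep depth decay of total abundance attenuates a zone contrast that is
clear in relative terms.

# Predicting porewater CH4

`assemble_variables()` builds the design matrix in tagged blocks: six
abiotic variables (depth, TOC, d13C of TOC, DIC, S, TOC:TS — CH4-derived
measurements are excluded because they would circularly encode the
response), single OTUs above 1% relative abundance in any sample (strict
inequality), lineage sums at phylum level with a class-level override list,
functional-guild sums, and genome-bin (MAG) abundance proxies configured
either as a direct OTU link or a lineage pattern. Identical duplicate
columns are collapsed with a warning. Missing chemistry cells are expected
to be interpolated upstream; the assembly itself refuses unmatched sample
keys loudly.

PLSR is implemented as univariate NIPALS. Columns are centered and, by
default, autoscaled; centered-only fitting is a flag because the
appropriate scaling for mixed abiotic/compositional blocks is genuinely
debatable, and `headline_statistics()` evaluates both. The number of
latent components defaults to the leave-one-out minimum-PRESS choice, with
a fixed-`ncomp` override. The headline `r2` is the squared Pearson
correlation between fitted and measured response (a calibration quantity);
the cross-validated `q2` is reported alongside and is the number to watch
when suites of very different size are compared. VIP scores follow
`VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` with orthonormal
weights, so `sum(VIP^2) = p` identically; "significant" predictors use the
strict `VIP > 1` convention. At full rank the PLSR fit reproduces OLS,
which the tests exploit as an oracle, alongside an independent NIPALS
implementation (`mixOmics`).

`fit_mlr()` is ordinary least squares with the usual adjusted r2 and
overall F test, erroring on rank deficiency with the collinear columns
named. `compare_models()` evaluates named suites of blocks and flags which
biotic additions improve on the abiotic-only baseline.

# The synthetic study

The generator (`synthetic_config()` plus four `generate_*()` functions)
defines the study conditions; its defaults are fixed, not tuned:

* **Design**: two lakes × two zones, one core per lake-zone, depths 4–40 cm
  every 4 cm (10 depths, 40 core-depth samples), three bubble traps per
  zone with 200 records each over six June–September seasons.
* **Flux**: zone Arrhenius slopes −5000 K (edge) and −17500 K (middle) — a
  3.5-fold middle:edge contrast in the middle of the reported 3–5-fold
  field range — anchored by an expected flux at 10 °C of 25 (edge) and 5
  (middle) mg m^-2 d^-1, since edges currently emit more. Edge sediments
  sample 4–22 °C, middles 4–14 °C. Flux noise is lognormal (sdlog 1)
  because ebullition is strongly right-skewed.
* **Chemistry**: substrate d13C −28 permil, true fractionation factor
  1.060, methanogenic DIC fraction rising 0.2→0.7 over depth, a saturating
  DIC profile of 500–3000 µM, 30% of generated CH4 retained in porewater,
  0.5 permil Gaussian isotope noise, and mild lognormal concentration
  noise. With all noise at zero the forward model is exactly invertible,
  which the tests assert at 1e-10.
* **Community**: 150 OTUs, library 5000, rarefaction depth 3000.
  Background OTUs carry log-linear depth gradients (depth is the dominant
  compositional axis) and zone offsets; methanogens and Syntrophaceae are
  pinned near 0.5% (edge) versus 1.5% (middle) — inside the 0.3–2.3%
  field range — ANME an order of magnitude higher in edges, and aerobic
  methanotrophs confined to the shallowest stratum. Counts are
  Dirichlet-multinomial with weak overdispersion (theta 0.02) because no
  community noise model is dictated by the field design; for guilds this
  overdispersion makes single-seed rare-guild contrasts (notably the ANME
  direction) noisy even though they hold in expectation.
* **Coupling**: a shared latent per-sample "methanogenic activity"
  multiplier (lognormal, sdlog 0.4, drawn on its own RNG stream) scales
  both the methanogenic DIC fraction and the methanogen/syntroph abundance
  targets. This is what makes microbial abundance genuinely predictive of
  porewater CH4 beyond depth, mirroring the field observation the
  prediction module exists to test.
* **qPCR**: 10^9 copies g^-1 at the surface declining 0.04 log10 per cm,
  perfect amplification efficiency, 0.15-cycle Ct noise, standards at
  dilutions 1e-2..1e-6 of the 20 ng/µL stock.

Every artifact draws from its own RNG stream derived from the single seed,
so regenerating one artifact never perturbs another, and the within-zone
trap-to-trap variance — unspecified by any field source — is exposed as
the flux-noise parameter rather than asserted.

What the generator does **not** emulate: bubble physics and pressure
transients, raw sequencing reads (and hence OTU-picking artifacts),
phylogenetic correlation between OTUs, depth-matching error between
chemistry and isotope cores, and spatial autocorrelation among traps.
Passing tests therefore demonstrate that the statistical machinery is
correct and well calibrated under the assumed noise models — not that the
field effect sizes are recoverable from any particular real dataset.

# Problem sizes and numerical choices

The test suite runs the full synthetic design (40 samples, 150 OTUs, 2400
flux records) for pipeline checks and scaled-down twins for per-operation
checks; calibration properties use 500 null simulations (homogeneity and
PERMANOVA type-I error) and 50-seed replications (power and effect
directions), sizes at which the binomial error of an estimated rate is
well inside the asserted bands. Permutation p-values use the
add-one convention `(1 + #{>= observed}) / (1 + n_perm)`; exhaustive modes
count the identity relabeling in the numerator and denominator.
Eigenvalues below `max|eigenvalue| × 1e-10` are treated as zero in the
ordination; NIPALS stops when a weight or score norm falls below 1e-12.

# Known limitations

* The isotope model is the two-endmember steady-state formulation; no
  Rayleigh closure, no transport correction, no oxidation isotope effect.
* PCoA reports negative eigenvalues rather than correcting them.
* PLSR calibration r2 on large correlated variable suites approaches 1 by
  construction; use `q2` for honest suite comparisons.
* The guild map is a best-effort clade inventory and must be curated for
  any real study.
* MLR is only fit when `n > p + 1`; large suites report PLSR only.
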