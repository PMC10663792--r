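---
title: "Methods: from forest structure to carbon fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from forest structure to carbon fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`canopyflux` is a virtual experiment: a calibrated individual-based gap
model generates a tropical forest landscape whose "true" carbon fluxes
are known per tree, the landscape is re-observed as vertical biomass
profiles at chosen horizontal and vertical resolutions, and boosted
regression trees quantify how much of gross primary production (GPP),
net primary production (NPP) and carbon turnover time
(τ = AGB / GPP) those profiles contain. This vignette documents the
model equations, the parameters that matter, the calibration, the
discretization and machine-learning protocols, and the limits of what
the package's tests can show.

## The gap model

### State and geometry

The landscape is a set of independent replicate plots (default
200 × 200 m) tiled into 20 × 20 m patches, the classic gap-model
grain: one large falling tree can open a patch-sized canopy gap. Trees
have no within-patch coordinates. Each tree is a plant functional type
(PFT), a stem diameter `D` (m), and derived geometry:

* height `H = h0 * D^h1` (m),
* crown diameter `CD = c0 * D`, crown projection area `(pi/4) * CD^2`,
* leaf area `LA = la0 * D^2` (m²), with `la0` expressed as a crown
  leaf-area multiplier `cl` times `(pi/4) * c0²` so that `LA = cl` ×
  crown area,
* above-ground biomass `B = (pi/4) * D^2 * H * form * rho` (t organic
  dry matter, ODM), the geometric stem-volume allometry with form
  factor `form` and wood-density surrogate `rho`.

Because `B` is a pure power of `D`, growth inverts the allometry in
closed form; no iterative solver appears anywhere in the model.

### Light competition

Within a patch, leaf area is binned into 0.5-m vertical layers: a
crown occupies `[H(1 - f_crown), H]` with its leaf area uniform over
the covered layers. Relative light at height `z` follows Lambert–Beer
extinction through everything above,

`I(z) = exp(-k * LAI_above(z))`, `k = 0.6`,

and a tree assimilates at the light level of its own crown top
(self-shading within a crown is not modelled separately; the saturating
response absorbs it). The 0.5-m internal layering is fixed by
convention; halving it changes equilibrium GPP by well under 1 %.

### Carbon balance of a tree

Leaf-level production follows the saturating light response
`p(I) = alpha * I * pmax / (alpha * I + pmax)` (initial slope `alpha`,
asymptote `pmax`, both t ODM m⁻² yr⁻¹). Then, per year:

* `GPP = p(I) * LA`
* `NPP = (1 - r_growth) * (GPP - r_main * B)`, floored at zero for
  reporting; a tree whose raw balance is non-positive stops growing and
  accumulates stress.
* biomass increment `dB = f_stem * (1 - D/d_max) * NPP`: only the
  stem-allocated share of NPP becomes measurable above-ground biomass;
  leaves, fine roots and reproduction are produced and turned over
  within the year. The share declines linearly to zero at the PFT's
  maximum diameter, which makes large trees approach `d_max`
  asymptotically and eventually stall.

`r_growth` is the lumped fraction of assimilate lost to growth
respiration and to short-lived tissues; it is deliberately large
(0.7–0.93, largest for the pioneer) because observed tropical NPP/GPP
ratios near 0.2 demand that most assimilate never reaches the stem.
Splitting respiration between the multiplicative `r_growth` and the
biomass-proportional `r_main` is the key structural freedom: `r_main`
shapes *where* in a tree's life carbon balance binds (it sets the shade
compensation point and the respiratory size limit), while `r_growth`
scales everything without changing signs.

### Mortality

Four processes, combined as independent probabilities each year:

* **background** `m_b` per PFT (pioneers 0.025 yr⁻¹ down to 0.009 for
  the late-successional type);
* **stress**: two consecutive years with relative diameter increment
  below 0.3 % add 0.1 yr⁻¹ — this is what removes cohorts piling up at
  their `d_max` and the deep-shade losers;
* **crowding**: a tree competes for horizontal space with the crowns
  overlapping its own crown-top layer; when their summed projection
  area exceeds the patch area, mortality rises with the excess, capped
  at 0.03 yr⁻¹. The cap matters: an uncapped rule thins dense cohorts
  so fast that the canopy can never overshoot, and the understorey —
  the advance regeneration that must take over after pioneer die-off —
  is annihilated;
* **treefall**: a dying tree taller than 18 m falls with probability
  0.5 onto its own or a von-Neumann-neighbouring patch (toroidal
  grid), killing trees there with probability 0.8 × (faller crown area
  / patch area), capped at 1. This is the disturbance engine that keeps
  the equilibrium a shifting mosaic rather than a steady state.

Establishment adds Poisson-distributed seedlings (rate `i_seed` per ha
and year, per PFT) at `D = 1 cm` wherever forest-floor light exceeds
the PFT's `i_min`; the pioneer's `i_min = 0.25` confines it to gaps
and open ground.

### The four functional types

The set spans the classic succession trade-off. The pioneer is
balsa-like: very low wood density (`rho = 0.09`), high `pmax`, high
respiration, short-lived, gap-demanding, `d_max = 0.88 m`. Types 2–4
increase in wood density, maximum size and shade tolerance while
`pmax`, `alpha` and mortality decline. Two emergent consequences are
worth flagging. First, canopy closure is fast (the pioneer bank fills
gaps within ~25 years) but carries little biomass, because pioneer
wood is so light — so GPP saturates while AGB is still below a quarter
of its old-growth value. Second, the pioneer cohort keeps maturing for
decades after closure; its collective crown area, and hence landscape
GPP, peaks around simulation year 60–70 before stress mortality at
`d_max` removes the cohort and the lower-`pmax` late types take over.

### Calibration

The defaults in `default_pfts()` and `sim_config()` were fixed by a
coarse manual search against four emergent targets, in this order of
priority: equilibrium (years 160–320) landscape GPP inside the
field-measured 52–58.8 t ODM ha⁻¹ yr⁻¹; equilibrium NPP near 12 t ODM
ha⁻¹ yr⁻¹; a GPP trajectory that peaks in mid-succession and then
declines to the plateau; and an AGB plateau (~220 t ha⁻¹) with less
than 15 % drift across the equilibrium window. Fluxes are kept in
tonnes of organic dry matter, not carbon, matching the magnitude of
the tower-based reference range; no carbon conversion is applied
anywhere. The calibration is a property of the whole set; individual
parameters should be changed with the acceptance checks at hand.

## Vertical biomass profiles

The observation operator is deliberately crude, mimicking what a
tomographic radar product could plausibly deliver: each tree's biomass
is assumed uniform over `[0, H]` and binned into half-open layers
`[i·dh, (i+1)·dh)` up to a 100 m ceiling, so a 56 m tree puts equal
mass in 0–20 and 20–40 m and 16/56 of it in 40–60 m. Crown geometry is
intentionally ignored here even though the simulator knows it. The
per-tree decomposition is exactly conservative, which gives two
identities used heavily in the tests: layers sum to AGB to within
floating-point error, and fine layers aggregate exactly into nested
coarse layers. Cells (0.04, 1, 4 ha) are unions of whole patches;
cell densities are means over member patches.

## Flux aggregation and forest categories

Cell GPP/NPP are sums over trees alive during the year divided by
cell area; AGB is end-of-year standing stock. τ = AGB/GPP is computed
for every stand-year, including pre-equilibrium ones where the
steady-state interpretation does not strictly hold; records with
GPP = 0 are flagged `NA` and excluded from τ analyses. Stand-years
split into *disturbed* (age < 160) and *mature* (age ≥ 160); the
boundary year goes to mature, a documented convention (the source
intervals overlap at 160), and is configurable.

## Boosted regression trees

Features are the raw layer densities (for Δh = 100 the single feature
equals total AGB); no scaling, since trees are scale-invariant. The
protocol per target × resolution × category:

1. uniformly random 50 % training split, capped at 15 900 training
   points (binding only at 0.04 ha, where a full run has 800 000
   stand-years), validation = the rest; splits, like every stochastic
   step, derive from one root seed;
2. grid search over learning rate {0.05, 0.01, 0.005} × bag fraction
   {0.3, 0.5, 0.66} × tree complexity (3 for Δh ∈ {20, 100}, 5 for 10,
   {5, 7} for 2 m), absolute-error (Laplace) loss; the number of
   boosting stages is chosen by k-fold cross-validated early stopping
   on the training half (10 folds by default, configurable), then the
   winner is refit at that stage count;
3. ties in cross-validated loss break toward the smaller learning
   rate; category models train and validate strictly within category;
4. reported accuracy is the squared Pearson correlation between
   predicted and held-out reference values (matching scatter-plot R²),
   with RMSE and the alternative `1 - SSres/SStot` emitted alongside.

The boosting backend is `xgboost` with `reg:absoluteerror`,
`eta` = learning rate, `subsample` = bag fraction and `max_depth` =
tree complexity. One caveat travels with that choice: classical BRT
software defines tree complexity as the number of splits (interaction
depth), whereas `max_depth` bounds tree depth, so a "complexity 7"
tree here is somewhat richer than its namesake elsewhere. Since the
grid treats complexity as a tuned hyperparameter, the mapping affects
labels more than results. Fold assignment for stage selection pins
R's RNG from the fit seed and restores the caller's stream, so any
fit is a pure function of (data, configuration, seed).

## Synthetic fixtures

Two generators make the profile and regression stages testable without
the simulator. `make_stand()` draws standalone tree lists with uniform
or truncated log-normal heights and a power-law biomass–height
coupling. `make_regression_fixture()` draws independent uniform
features, applies a known generating function (linear, saturating, or
a two-layer sum), adds Gaussian or Laplace noise of known variance,
and returns the analytic ceiling `var(f) / (var(f) + var(noise))` that
any regressor can at best reach on held-out data — the recovery tests
require the BRT to land within ±0.05 of it. Laplace noise is included
precisely because the BRT loss is Laplace, exercising the matched-loss
case. What these fixtures do *not* emulate: spatial autocorrelation
between cells, the temporal autocorrelation of succession, and the
strongly non-uniform feature distributions of real profiles — so
passing recovery tests certify the estimator machinery, not
performance on real radar retrievals.

## Numerical choices and degenerate inputs

* Half-open layer intervals, boundary mass assigned downward; exact
  conservation is the tie-break criterion throughout.
* Internal light layering 0.5 m; profile ceiling 100 m (tallest
  simulated trees stay below 60 m).
* Empty patches and empty cells are valid (full light, zero profile);
  constant regression targets return a constant predictor with a
  warning; a constant predictor scores R² = 0 by convention; a
  constant relationship predictor (e.g. an upper layer that no tree
  reaches in a short run) reports `NA` rather than an error.
* RNG: one root seed; replicate `r` runs on stream
  `seed + 10000·r`; derived seeds stay far below 2³¹.
* CSV outputs carry 6 significant digits; in-memory objects keep full
  precision.

## Problem sizes used by the tests

The packaged checks run the study at reduced but faithful size, chosen
so the full suite completes comfortably on a single CPU: 5 replicate
plots (20 ha) over the full 320 years for the calibration,
relationship and BRT acceptance checks; the reduced BRT sweep uses two
learning rates {0.05, 0.01}, 3-fold stage selection and stage budgets
of 100 (4 ha / 1 ha) or 200 (0.04 ha) boosting stages. Unit tests use 40 × 40 m
landscapes. The full 25-replicate, three-learning-rate protocol is
available through `reproduce_study(quick = FALSE)`.

## Known limitations

* The upper canopy fills late: trees cross 40 m only after year ~200,
  so 40–60 m layer biomass is informative mainly for old-growth
  states. In the calibrated landscape the strongest single-layer
  correlate of total AGB is still the 40–60 m layer, but its absolute
  R² is modest.
* Equilibrium GPP varies little between 4-ha stands (a few per cent).
  Two consequences, both visible in the acceptance suite: τ = AGB/GPP
  is nearly an affine function of AGB over the pooled record, so its
  linear R² with biomass is very high rather than intermediate; and
  mature-forest fluxes remain quite predictable even at 4 ha, so the
  mature-forest accuracy gain from finer horizontal resolution is not
  reproduced (the disturbed-forest loss is). Both trace to the same
  model property — the absence of processes that decouple leaf area
  from standing biomass (leaf plasticity, rapid LAI recovery after
  gaps) — not to the estimation machinery.
* No climate forcing, soil carbon, explicit tree coordinates within
  patches, or measurement noise on the profiles; the "observation" is
  a perfect, conservatively binned biomass field.
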