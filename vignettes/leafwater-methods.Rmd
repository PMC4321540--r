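---
title: "Methods: from drying leaves to phylogenetic ordination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from drying leaves to phylogenetic ordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafwater)
```

`leafwater` chains two scientific layers: the derivation of leaf
water-relations traits from raw bench measurements, and the comparative
statistics that relate those traits to phylogeny, photosynthetic type and
habitat water availability. This vignette documents the models, their
assumptions, the tunable parameters, and the numerical and design decisions
behind the implementation. Every quantitative statement about the package's
accuracy is one the test suite or `scripts/acceptance.R` computes; nothing
here reports numbers beyond those checks.

## Pressure–volume analysis

A PV curve records total leaf water potential Ψ (MPa, ≤ 0) against relative
water content as a detached leaf dries. The analysis assumes the classical
two-compartment picture: once turgor is lost, Ψ equals the osmotic
potential Ψ_o, which in the linear-approximation regime declines with RWC;
above the turgor loss point, Ψ = Ψ_o + Ψ_p with Ψ_p ≥ 0 the turgor
(pressure) potential.

**Osmotic line.** Points are sorted from driest to wettest; the four driest
seed an ordinary least-squares line of Ψ on RWC, and wetter points are
appended one at a time while the incoming point's absolute residual stays
within `resid_factor` (default 2) times its prediction standard error. Two
details matter:

- the residual scale is floored at `resid_floor = 0.02` MPa, a typical
  pressure-chamber resolution, so that a handful of nearly collinear points
  cannot produce an unrealistically tight gate and freeze the selection at
  its 4-point seed;
- the gate uses the *prediction* SE at the incoming point — residual SD
  inflated by the leverage `1 + 1/k + (x − x̄)²/S_xx` — because each new
  point is an extrapolation one step beyond the fitted range, and judging
  it by the in-sample residual SD alone rejects valid points far too often.

An R² threshold (`r2_min`) is available but off by default: R² compares
residual variance to signal spread, so on the shallow osmotic segment it
conflates measurement noise with genuine nonlinearity and, at realistic
noise, stops the selection immediately regardless of how linear the segment
is. The residual gate measures lack of fit on the scale that matters (MPa
per point) and is the criterion we trust.

**Turgor curve.** Turgor is extracted as Ψ_p = Ψ − (osmotic line) and
fitted with the modified exponential Ψ_p(R) = a·(e^{b(R − R₀)} − 1), a > 0,
b > 0, which is exactly zero at its intercept R₀ (the RWC at turgor loss)
and degenerates to a straight line as b → 0. Points with Ψ_p above
`turgor_floor = 0.02` MPa (again the instrument scale) form the turgid set.
By default (`anchor_zero = TRUE`) the observations whose turgor is
indistinguishable from zero, |Ψ_p| ≤ `turgor_floor`, also enter the least
squares, compared against the physically floored prediction max(0, model):
turgor cannot be negative, so below the crossing the curve predicts exactly
zero. These points bracket R₀ from the dry side. Without them the crossing
is an extrapolation of a three-parameter curve that is weakly identified
when the turgor decline is near-linear (b → 0 makes R₀ trade off against
a·b), and its sampling variance under realistic noise is several times
larger. `anchor_zero = FALSE` recovers the bare fit, which reproduces
parameters exactly on data generated from the bare model.

The optimiser is a multi-start Nelder–Mead on (log a, log b, R₀) — the
anchored objective is piecewise in R₀, so derivative-free search is the
right tool; the bare fit goes through Levenberg–Marquardt first and falls
back to the same Nelder–Mead when the gradient is singular at the start.
Starts: a = max(Ψ_p)/2, b ∈ {0.5, 2, 8}, R₀ at the wettest zero-turgor
observation. The test suite verifies the fitted R₀ against an independent
grid search (10⁻³ resolution in R₀ with inner 2-parameter optimisation) to
2×10⁻³.

**Derived parameters.** Ψ_osat is the osmotic line at RWC = 1; TLP is the
osmotic line at R₀; ε = Ψ_p(1)/(1 − R₀) is the mean slope of turgor against
fractional RWC between saturation and turgor loss. Because the true
osmotic relation is a dilution curve (Ψ_o ∝ 1/R) while the fitted line is
its local-linear approximation over the measured dry range, TLP and Ψ_osat
carry a small systematic extrapolation bias even without noise; the
recovery tests quantify both this bias and the noise response. Two
conventions the literature leaves open are exposed as flags rather than
decided silently: ε is reported per unit fractional RWC by default
(`epsilon_per_percent = TRUE` divides by 100 for per-%RWC units), and the
osmotic fit uses Ψ itself (not 1/Ψ) against RWC, following the procedure's
literal description.

## Stomatal anatomy, fluxes and habitat

`g_max` uses the standard diffusion-limited pore model with water-vapour
diffusivity d = 2.49×10⁻⁵ m² s⁻¹ and molar air volume v = 2.45×10⁻² m³
mol⁻¹ at 25 °C (physical constants, exposed via `gas_constants()` rather
than hard-coded); pore area π(p/2)² from the measured pore length and pore
depth W/2 from the closed guard-cell pair width. Surfaces are computed
separately and summed, and species values are means of per-leaf values —
applying the formula to trait means differs by Jensen's inequality. SPI is
reported ×100 so grass values land on the conventional 5–15 scale; a flag
restores the bare product.

Cuticular conductance divides the hour-two mass-loss flux (one-sided leaf
area; a flag selects two-sided) by the cabinet's mole-fraction vapour
gradient Δw = e_sat(T)·(1 − RH)/P with e_sat from Tetens' formula. The
per-area flux before the Δw division is also returned, since published
tables sometimes report that quantity; dividing by Δw is what makes the
result a conductance in mmol m⁻² s⁻¹. The stomata-open/closed breakpoint
defaults to 60 min (configurable), matching the observation that most
leaves have curled and closed their stomata within the first hour.

Habitat classification is driven by an editable YAML lexicon
(`inst/extdata/habitat_lexicon.yaml`): wet-habitat keywords take precedence
over well-drained-soil keywords, everything else is intermediate, and
first-match precedence resolves multi-habitat floras. Water scores map
Hydrophyte/Helophyte/Mesophyte/Xerophyte to 5/4/3/1 (equal weighting of the
extremes) and summarise a species as the mean and range of its descriptor
values.

## Phylogenetic signal and ordination

`vcv_from_tree()` builds the Brownian covariance C (shared root-to-MRCA
path lengths) directly from the edge structure; the tests check it against
both a brute-force path enumeration and `ape::vcv`. Pagel's λ rescales the
off-diagonals of C; `fit_lambda()` profiles the GLS mean and rate in closed
form and maximises the remaining one-dimensional likelihood over λ ∈ [0, 1]
with a coarse-grid bracket plus golden-section refinement (tolerance 10⁻⁶).
λ is restricted to [0, 1] — the interpretable range from no to full
phylogenetic dependence — although slightly larger values can be
algebraically admissible on some trees. Boundary hypotheses are tested by
likelihood ratio with the 50:50 χ²₀/χ²₁ mixture appropriate at a boundary;
a flat likelihood (e.g. a star tree, where λ is unidentifiable) is reported
as λ = 0 with p(λ = 0) = 1. A numerically singular C(λ) receives a 10⁻¹⁰
ridge, with a message.

Phylogenetic PCA estimates the trait covariance by GLS: phylogenetic mean
a = (1ᵀC⁻¹1)⁻¹1ᵀC⁻¹X, S = (X − 1a)ᵀC⁻¹(X − 1a)/(n − 1), eigendecomposition
of S, scores (X − 1a)V. `mode = "lambda"` first estimates one multivariate
λ by ML. Eigenvector signs are fixed by making each component's
largest-magnitude loading positive so score plots reproduce across
platforms. On a star tree the GLS collapses to ordinary centring and the
result equals conventional PCA, which the tests assert to 10⁻⁸ — the
conventional route deliberately goes through `stats::prcomp` so the two
implementations stay independent. Traits are log-transformed first
(`log_transform_traits()`), using absolute values for negative-valued
traits such as TLP; species with missing traits are dropped complete-case
with a warning.

Non-ultrametric trees are accepted with a warning rather than rejected,
since empirical panels often graft taxa onto a backbone by closest
relatives.

## The comparison layer

Welch *t* tests default to species means — replicate leaves within a
species are pseudoreplicates for a between-species contrast — with
`level = "replicate"` available. The mixed model is
`trait ~ A × B + (1 | species)` by REML, F statistics from the type-III
table, and p-values on the between-species denominator df `n_species − p`
(29 for the default 33-species 2×2 design), matching the convention of
treating species as the experimental unit; Satterthwaite df are a switch.
With the species term removed (`random = FALSE`, the "species variance
forced to zero" route) the same table comes from a two-way fixed-effects
ANOVA, which the tests verify against hand-computed sums of squares.
Water-availability encodings (MAP, water score, habitat class) are compared
by AIC under ML fits, since REML likelihoods are not comparable across
fixed-effect structures.

## The synthetic panel: what it emulates and what it does not

The generator defines the study conditions under which everything above is
verified. One leaf's PV series follows the symplastic model
r_s = (RWC − af)/(1 − af), Ψ_o = π₀/r_s, Ψ_p linear from −π₀ at saturation
to zero at r_s = R₀ — chosen because it yields a closed-form TLP = π₀/R₀
(af = 0) for recovery tests. Defaults: 12 points from RWC 1.0 down to
R₀ − 0.15 at 15-min spacing, Gaussian noise 0.02 MPa on Ψ and 0.001 g on
mass (instrument-scale values; the apoplastic fraction defaults to 0 and
exists to stress-test robustness). Curling is piecewise linear with a
60-min breakpoint; width shrinks only during hour one, mass loses
stomatal + cuticular water in hour one and cuticular only in hour two.

The species panel reproduces an unbalanced two-subfamily ×
photosynthetic-type block of 33 species (7/5 PCK/non-PCK in one subfamily,
7/14 in the other) with 5 replicate leaves each, habitats cycled within
cells, habitat-linked MAP (centres 400/800/1200 mm ± uniform 150 mm for
arid/intermediate/wet) and water scores loosely tied to habitat. Each
trait follows `mean + subfamily + type + interaction + MAP-slope + species
intercept + residual`; raw measurement bundles are then constructed whose
derived trait equals the replicate's value exactly (the kleaf, g_max, WUEi
and curling chains invert exactly; the PV chain carries only the method's
small approximation bias), so measurement-level noise is carried once, by
the trait model's residual, rather than twice. The phylogeny is a
unit-depth Yule tree, independent of the trait factors.

Passing recovery tests on this panel therefore shows the *computational
chain* is correct and calibrated under known conditions. It does not show
that real leaves follow a linear turgor decline, that real residuals are
Gaussian or homoscedastic, that real traits are phylogenetically
independent of the design factors, or that real PV curves are sampled this
densely — on real data the same functions apply, but those assumptions are
the user's to check.

## Verification problem sizes

The acceptance layer runs at the following sizes, chosen to estimate each
property stably: 100 noisy leaves for PV recovery (medians of absolute
errors); 3 noiseless leaves for the turgor grid-search comparison; a
200-tip tree with 100 replicates at each λ ∈ {0, 0.5, 1} plus a 21-point
grid-dominance check on every replicate; 33 species × 6 traits for the
star-tree PPCA/PCA equivalence; 50 random 10-tip trees for the covariance
oracle; 1000 (hydraulic) and 200 (cuticular) random records for the flux
arithmetic; 500 null panels for type-I calibration of the subfamily test;
100 MAP-driven panels for the AIC comparison; and two full pipeline runs
for byte-level determinism.

## Known limitations

- TLP and Ψ_osat inherit the local-linear osmotic approximation's bias; on
  strongly curved osmotic relations (very negative π₀ over a wide dry
  range) a 1/Ψ-based analysis may be preferable and is not currently
  implemented as the default.
- The mixed model's between-species df convention is exact only when
  species is the sole grouping level; crossed measurement batches are not
  modelled.
- The λ likelihood assumes a single trait observation per species (species
  means); within-species measurement error is not propagated into the
  signal estimate.
- Capacitance and apoplastic-fraction estimation from PV data, Blomberg's
  K, and PGLS regression beyond λ and PPCA are out of scope.
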