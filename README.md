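# leafwater

Leaf water-relations traits and phylogenetic comparative analysis for
grasses (or any species panel measured the same way).

Comparative ecophysiology asks how lineages differ in drought tolerance, and
whether those differences track phylogeny, photosynthetic type, or habitat
water availability. Answering this from raw bench measurements takes a long
chain of derivations — pressure–volume (PV) curve fitting, stomatal anatomy
models, drying kinetics, hydraulic conductance — followed by comparative
statistics that respect both the replicate structure (leaves within species)
and the phylogeny (species are not independent). `leafwater` implements that
whole chain as composable, seed-reproducible functions, plus a synthetic
species-panel generator with known ground truth so every stage can be
verified by parameter recovery.

## What it computes

**Water-relations traits from raw measurements**

- *PV curves*: relative water content `RWC = (fresh − dry)/(sat − dry)`;
  a stepwise-selected osmotic line fitted through the driest observations,
  where total water potential Ψ tracks osmotic potential Ψ_o alone; turgor
  pressure `Ψ_p = Ψ − Ψ_o`; and a modified-exponential turgor curve
  `Ψ_p(R) = a·(e^{b(R − R₀)} − 1)` whose zero intercept R₀ is the RWC at the
  turgor loss point. Derived: saturated osmotic potential Ψ_osat (osmotic
  line at RWC = 1), turgor loss point TLP (osmotic line at R₀), and bulk
  elastic modulus `ε = Ψ_p(1)/(1 − R₀)`.
- *Stomatal anatomy*: stomatal pore index `SPI = SD·GL²` and the anatomical
  maximum stomatal conductance
  `g_max = (d/v)·D·a_max / (l + (π/2)·√(a_max/π))`, with pore area
  `a_max = π(p/2)²` and pore depth `l = W/2`, summed over both leaf
  surfaces.
- *Curling kinetics*: relative/absolute width- and weight-loss slopes from a
  two-hour bench record, and cuticular (minimum epidermal) conductance from
  the hour-two mass slope normalised by leaf area and the cabinet's
  mole-fraction vapour gradient.
- *Hydraulics and gas exchange*: `K_leaf = ΔW·t⁻¹·A⁻¹·ΔΨ⁻¹` from
  pressure-chamber sap expression, and `WUEi = A/g_s`.
- *Habitat*: flora-descriptor water scores (Hydrophyte = 5 … Xerophyte = 1),
  wet/arid/intermediate habitat classes with wet > arid precedence, and
  occurrence-based climate niche means (MAT, MAP).

**Comparative statistics**

- Welch *t* comparisons on species means and two-factor linear mixed models
  `trait ~ subfamily × type + (1 | species)` with between-species
  denominator degrees of freedom, plus AIC comparison of water-availability
  encodings (MAP vs water score vs habitat class).
- Pagel's λ by profiled maximum likelihood on the tree's Brownian
  covariance, with boundary-mixture likelihood-ratio tests against λ = 0
  and λ = 1.
- Conventional PCA and phylogenetic PCA (GLS against the λ- or BM-structured
  species covariance) on log-transformed trait tables.

All user-facing functions take data frames and return tibbles; fitted
objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(leafwater)

# one synthetic leaf: ground truth TLP = -1.2/0.88 = -1.364 MPa
pv  <- gen_pv_series(pi0 = -1.2, rwc_tlp = 0.88, seed = 101,
                     leaf_id = "demo_leaf")
fit <- derive_pv_result(pv)
fit
#> PV fit (demo_leaf): TLP -1.338 MPa | psi_osat -1.088 MPa | RWC at TLP 0.878 | epsilon 8.80 MPa
```

The fitted TLP (−1.338 MPa) recovers the generator's analytic value
(−1.364 MPa) to within the method's local-linear osmotic approximation; the
saturated osmotic potential (−1.088 MPa) likewise tracks π₀ = −1.2 MPa, and
ε ≈ 8.8 MPa says the leaf loses all turgor over a ~12 % drop in relative
water content.

```r
# a 33-species, 5-replicate panel and its comparison layer
panel <- gen_species_panel(panel_spec(), emit_raw = FALSE)
fit_two_factor_mixed(panel$traits, "tlp")
#> Two-factor mixed model for 'tlp' (33 species; species var 0.006011, residual 0.001738, AIC -455.4)
#>  term         f num_df den_df            p stars
#>     A 44.982600      1     29 2.337766e-07   ***
#>     B  4.194474      1     29 4.970603e-02     *
#>   A:B  1.141363      1     29 2.941773e-01    ns
```

The subfamily term (A) is strong — the default panel injects a −0.15 MPa
subfamily effect on TLP — the photosynthetic-type term (B, +0.10 MPa)
is detected at the margin, and no interaction was injected or found. The
denominator df of 29 is the between-species convention (33 species minus 4
fixed-effect parameters).

The full pipeline — simulate, derive every trait from the raw bundles,
compare, screen phylogenetic signal, ordinate — is one call writing a
self-contained run directory of CSVs:

```r
run_pipeline("runs/demo", seed = 7)
```

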