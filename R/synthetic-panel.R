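#' Specify one trait's generative model for the synthetic panel
#'
#' Each panel trait follows the replicate-level linear model
#' `trait = mean + subfamily_effect * I(Panicoideae) + type_effect * I(PCK) +
#' interaction * I(both) + map_effect * (MAP - mean MAP) + species intercept
#' + residual`, with the species intercept drawn `N(0, species_sd^2)` and
#' the residual `N(0, residual_sd^2)`.
#'
#' @param mean Grand mean, in the trait's units.
#' @param subfamily_effect,type_effect,interaction Fixed effects (trait units).
#' @param species_sd,residual_sd Variance components (trait units, >= 0).
#' @param map_effect Slope on centred MAP (trait units per mm), default 0.
#' @return A list describing the trait model.
#' @export
trait_model <- function(mean, subfamily_effect = 0, type_effect = 0,
                        interaction = 0, species_sd = 0, residual_sd = 0,
                        map_effect = 0) {
  if (species_sd < 0 || residual_sd < 0) {
    abort("variance components must be >= 0.")
  }
  list(
    mean = mean, subfamily_effect = subfamily_effect,
    type_effect = type_effect, interaction = interaction,
    species_sd = species_sd, residual_sd = residual_sd,
    map_effect = map_effect
  )
}

default_panel_traits <- function() {
  list(
    tlp = trait_model(-1.3, -0.15, 0.10, 0, species_sd = 0.08, residual_sd = 0.04),
    gmax = trait_model(0.8, 0.15, -0.05, 0, species_sd = 0.06, residual_sd = 0.03),
    kleaf = trait_model(8, 2, -0.5, 0, species_sd = 0.8, residual_sd = 0.4),
    gmin = trait_model(5, 1, 0.3, 0, species_sd = 0.5, residual_sd = 0.25),
    wuei = trait_model(120, -10, 5, 0, species_sd = 8, residual_sd = 5),
    relative_width_loss = trait_model(30, -12, 2, 0, species_sd = 3, residual_sd = 1.5)
  )
}

#' Specify a synthetic species panel
#'
#' Describes the factor structure, effect sizes and seeds of a simulated
#' glasshouse study. The default layout reproduces the real design the
#' package emulates: 33 species in a two-subfamily by two-photosynthetic-type
#' block (Chloridoideae 7 PCK + 5 non-PCK; Panicoideae 7 PCK + 14 non-PCK),
#' each measured on 5 replicate leaves, with habitats (arid, intermediate,
#' wet) cycled within cells.
#'
#' @param n_species_per_cell Either `NULL` (the 7/5/7/14 layout above) or a
#'   single integer giving a balanced count for every subfamily x type cell.
#' @param n_replicates Replicate leaves per species (default 5).
#' @param traits Named list of [trait_model()] specifications.
#' @param tree_seed,trait_seed Integer seeds for the phylogeny and the trait
#'   draws.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(n_species_per_cell = NULL, n_replicates = 5,
                       traits = default_panel_traits(), tree_seed = 1L,
                       trait_seed = 2L) {
  cells <- tibble::tibble(
    subfamily = rep(c("Chloridoideae", "Panicoideae"), each = 2),
    ptype = rep(c("PCK", "non-PCK"), 2),
    n = if (is.null(n_species_per_cell)) {
      c(7L, 5L, 7L, 14L)
    } else {
      rep(as.integer(n_species_per_cell), 4)
    }
  )
  has_interaction <- any(vapply(traits, function(tr) tr$interaction != 0, logical(1)))
  if (any(cells$n == 0) && has_interaction) {
    abort("cells with zero species cannot support interaction effects.")
  }
  structure(
    list(
      cells = cells, n_replicates = as.integer(n_replicates),
      traits = traits, tree_seed = as.integer(tree_seed),
      trait_seed = as.integer(trait_seed)
    ),
    class = "panel_spec"
  )
}

habitat_map_centre <- c(wet = 1200, intermediate = 800, arid = 400)
habitat_keywords_for <- c(
  wet = "swamps and riverbanks",
  intermediate = "open grassland",
  arid = "well-drained sandy soils"
)

#' Generate a synthetic species panel
#'
#' Draws the full simulated study defined by a [panel_spec()]: a species
#' table (subfamily, photosynthetic type, habitat, realized climate niche,
#' water score), a replicate-level trait table following each trait's linear
#' model, a unit-depth Yule phylogeny over the species, and (optionally) the
#' raw measurement bundles — pressure-volume drying series, curling series,
#' stomatal micrograph samples, hydraulic-conductance records and gas
#' exchange — constructed so that each replicate's derived trait equals its
#' trait-table value (all measurement-level noise is carried by the trait
#' model's residual term).
#'
#' @param spec A [panel_spec()].
#' @param emit_raw Also emit the raw measurement bundles (default TRUE);
#'   turn off for fast statistical calibration runs that only need traits.
#' @return A list with elements `species`, `traits`, `tree`, `effects`
#'   (the injected ground truth), and if `emit_raw` the tibbles `pv`,
#'   `curling`, `stomata`, `kleaf_records`, `gas_exchange`.
#' @examples
#' panel <- gen_species_panel(panel_spec(), emit_raw = FALSE)
#' dplyr::count(panel$species, subfamily, ptype)
#' @export
gen_species_panel <- function(spec, emit_raw = TRUE) {
  stopifnot(inherits(spec, "panel_spec"))
  cells <- spec$cells
  n_species <- sum(cells$n)
  species <- tibble::tibble(
    species = sprintf("s%02d", seq_len(n_species)),
    subfamily = rep(cells$subfamily, cells$n),
    ptype = rep(cells$ptype, cells$n)
  )
  # habitats cycle within each cell so both subfamilies span the gradient
  species$habitat_class <- unlist(lapply(cells$n, function(k) {
    rep(c("arid", "intermediate", "wet"), length.out = k)
  }))

  withr::with_seed(spec$trait_seed, {
    species$map <- unname(habitat_map_centre[species$habitat_class]) +
      runif(n_species, -150, 150)
    species$mat <- 20 + runif(n_species, -5, 5)
    species$water_score <- dplyr::case_when(
      species$habitat_class == "wet" ~ 4 + runif(n_species, 0, 1),
      species$habitat_class == "intermediate" ~ 2.5 + runif(n_species, 0, 1),
      .default = 1 + runif(n_species, 0, 0.8)
    )
    species$habitat_keywords <- unname(habitat_keywords_for[species$habitat_class])

    map_c <- species$map - mean(species$map)
    reps <- tidyr::expand_grid(
      species = species$species,
      replicate = seq_len(spec$n_replicates)
    )
    traits <- dplyr::left_join(reps, species, by = "species")
    for (tn in names(spec$traits)) {
      tm <- spec$traits[[tn]]
      sp_mean <- tm$mean +
        tm$subfamily_effect * (species$subfamily == "Panicoideae") +
        tm$type_effect * (species$ptype == "PCK") +
        tm$interaction * (species$subfamily == "Panicoideae" &
                            species$ptype == "PCK") +
        tm$map_effect * map_c +
        rnorm(n_species, sd = tm$species_sd)
      idx <- match(traits$species, species$species)
      traits[[tn]] <- sp_mean[idx] +
        rnorm(nrow(traits), sd = tm$residual_sd)
    }
  })
  traits$leaf_id <- paste0(traits$species, "_r", traits$replicate)

  tree <- gen_tree(n_species, seed = spec$tree_seed)
  out <- list(
    species = species, traits = traits, tree = tree,
    effects = spec$traits
  )
  if (emit_raw) out <- c(out, emit_raw_bundles(traits, spec))
  out
}

# Build raw measurement tables whose derived traits reproduce the replicate
# trait values (noise lives in the trait model, not the instruments).
emit_raw_bundles <- function(traits, spec) {
  const <- gas_constants()
  rwc_tlp <- 0.9

  pv <- purrr::map_dfr(seq_len(nrow(traits)), function(i) {
    ser <- gen_pv_series(
      pi0 = traits$tlp[i] * rwc_tlp, rwc_tlp = rwc_tlp,
      noise_sd_psi = 0, noise_sd_mass = 0,
      seed = spec$trait_seed + i, leaf_id = traits$leaf_id[i]
    )
    ser$species <- traits$species[i]
    ser
  })

  # invert the cuticular-conductance chain to a g h^-1 hour-2 mass slope
  area_cm2 <- 10
  temp_c <- 23.5
  rh <- 0.6
  p_kpa <- 101.325
  dw <- esat_tetens(temp_c) * (1 - rh) / p_kpa
  curling <- purrr::map_dfr(seq_len(nrow(traits)), function(i) {
    cut_rate <- traits$gmin[i] / 1000 * dw * (area_cm2 * 1e-4) *
      .lw_const$m_water * 3600
    ser <- gen_curling_series(
      w0 = 10, curl_rate = min(0.9, traits$relative_width_loss[i] / 100),
      mass0 = 0.4, dry_mass = 0.1,
      stomatal_loss_rate = 5 * cut_rate, cuticular_loss_rate = cut_rate,
      area_cm2 = area_cm2, temp_c = temp_c, rh = rh, pressure_kpa = p_kpa,
      seed = spec$trait_seed + i, leaf_id = traits$leaf_id[i]
    )
    ser$species <- traits$species[i]
    ser
  })

  # two identical surfaces each carrying half the target g_max
  pore_um <- 12
  width_um <- 14
  gl_um <- 22
  per_density <- function(g_half) {
    unit <- gmax_one_surface(1, pore_um, width_um, const)
    g_half / unit
  }
  stomata <- purrr::map_dfr(seq_len(nrow(traits)), function(i) {
    D <- per_density(traits$gmax[i] / 2)
    tibble::tibble(
      leaf_id = traits$leaf_id[i], species = traits$species[i],
      surface = c("abaxial", "adaxial"),
      gl_um = gl_um, width_um = width_um, pore_um = pore_um,
      density_per_mm2 = D
    )
  })

  duration_s <- 10
  karea_m2 <- 5e-4
  dpsi <- 0.5
  kleaf_records <- tibble::tibble(
    leaf_id = traits$leaf_id, species = traits$species,
    delta_w_g = traits$kleaf / 1000 * .lw_const$m_water *
      duration_s * karea_m2 * dpsi,
    duration_s = duration_s, area_m2 = karea_m2, delta_psi_mpa = dpsi
  )

  gs <- 0.25
  gas_exchange <- tibble::tibble(
    leaf_id = traits$leaf_id, species = traits$species,
    a_umol = traits$wuei * gs, gs_mol = gs,
    ci_umol_mol = 150, e_mmol = 4
  )

  list(
    pv = pv, curling = curling, stomata = stomata,
    kleaf_records = kleaf_records, gas_exchange = gas_exchange
  )
}
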