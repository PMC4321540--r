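default_panel_traits_for_test <- function() {
  list(
    tlp = trait_model(-1.3, -0.1, 0, 0, species_sd = 0.05, residual_sd = 0.02),
    gmax = trait_model(0.8, 0.1, 0, 0, species_sd = 0.05, residual_sd = 0.02),
    kleaf = trait_model(8, 1, 0, 0, species_sd = 0.5, residual_sd = 0.2),
    gmin = trait_model(5, 1, 0, 0, species_sd = 0.3, residual_sd = 0.1),
    wuei = trait_model(120, -5, 0, 0, species_sd = 5, residual_sd = 2),
    relative_width_loss = trait_model(30, -8, 0, 0, species_sd = 2, residual_sd = 1)
  )
}

test_that("null panel with all variance off is perfectly uniform", {
  spec <- panel_spec(traits = list(y = trait_model(7)), trait_seed = 1)
  panel <- gen_species_panel(spec, emit_raw = FALSE)
  expect_true(all(panel$traits$y == 7))
  expect_equal(nrow(panel$traits), 33 * 5)
})

test_that("injected subfamily effect is recovered at large n", {
  spec <- panel_spec(
    n_species_per_cell = 50,
    traits = list(y = trait_model(
      0, subfamily_effect = 2, species_sd = 0.5, residual_sd = 0.5
    )),
    trait_seed = 8
  )
  panel <- gen_species_panel(spec, emit_raw = FALSE)
  means <- tapply(panel$traits$y, panel$traits$subfamily, mean)
  expect_equal(
    unname(means["Panicoideae"] - means["Chloridoideae"]), 2, tolerance = 0.15
  )
})

test_that("panel generation is byte-deterministic and validates cells", {
  a <- gen_species_panel(panel_spec(trait_seed = 5), emit_raw = TRUE)
  b <- gen_species_panel(panel_spec(trait_seed = 5), emit_raw = TRUE)
  expect_identical(a$traits, b$traits)
  expect_identical(a$pv, b$pv)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_error(
    panel_spec(
      n_species_per_cell = 0,
      traits = list(y = trait_model(1, interaction = 2))
    ),
    "zero species"
  )
})

test_that("species metadata is internally consistent", {
  panel <- gen_species_panel(panel_spec(), emit_raw = FALSE)
  sp <- panel$species
  expect_equal(nrow(sp), 33)
  expect_equal(length(unique(sp$species)), 33)
  # habitat keywords classify back to the assigned habitat class
  reclass <- vapply(sp$habitat_keywords, classify_habitat, character(1))
  expect_equal(unname(reclass), sp$habitat_class)
  # MAP centres track the habitat gradient
  agg <- tapply(sp$map, sp$habitat_class, mean)
  expect_true(agg["wet"] > agg["intermediate"])
  expect_true(agg["intermediate"] > agg["arid"])
  expect_true(all(sp$water_score >= 1 & sp$water_score <= 5))
  # tree tips match species labels
  expect_setequal(panel$tree$tip.label, sp$species)
})

test_that("raw bundles reproduce the trait table when re-derived", {
  spec <- panel_spec(
    n_species_per_cell = 2, n_replicates = 2,
    traits = default_panel_traits_for_test(), trait_seed = 4
  )
  panel <- gen_species_panel(spec, emit_raw = TRUE)
  tr <- panel$traits

  # K_leaf and WUEi invert exactly
  k <- kleaf(
    panel$kleaf_records$delta_w_g, panel$kleaf_records$duration_s,
    panel$kleaf_records$area_m2, panel$kleaf_records$delta_psi_mpa
  )
  expect_equal(k, tr$kleaf[match(panel$kleaf_records$leaf_id, tr$leaf_id)],
               tolerance = 1e-10)
  w <- wue_instantaneous(panel$gas_exchange$a_umol, panel$gas_exchange$gs_mol)
  expect_equal(w, tr$wuei[match(panel$gas_exchange$leaf_id, tr$leaf_id)],
               tolerance = 1e-10)

  # stomatal anatomy inverts g_max
  st <- stomatal_traits(panel$stomata[names(panel$stomata) != "species"])
  expect_equal(
    st$gmax_total, tr$gmax[match(st$leaf_id, tr$leaf_id)], tolerance = 1e-10
  )

  # curling series invert the cuticular conductance and width-loss rate
  one <- panel$curling[panel$curling$leaf_id == tr$leaf_id[1], ]
  expect_equal(
    cuticular_conductance(one)$gmin_mmol, tr$gmin[1], tolerance = 1e-8
  )
  expect_equal(
    curling_rates(one)$relative_width_loss, tr$relative_width_loss[1],
    tolerance = 1e-8
  )

  # PV series carry the TLP with only the method's small local-linear bias
  pv1 <- panel$pv[panel$pv$leaf_id == tr$leaf_id[1], ]
  fit <- derive_pv_result(pv1)
  expect_equal(fit$tlp, tr$tlp[1], tolerance = 0.05)
})

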