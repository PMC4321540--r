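test_that("compute_rwc applies its definition and flags oversaturation", {
  d <- tibble::tibble(
    fresh_mass_g = c(0.50, 0.10, 0.42, 0.52),
    sat_mass_g = 0.50, dry_mass_g = 0.10
  )
  out <- compute_rwc(d)
  expect_equal(out$rwc, c(1, 0, 0.8, 1.05))
  expect_equal(out$oversaturated, c(FALSE, FALSE, FALSE, TRUE))
  expect_error(
    compute_rwc(tibble::tibble(
      fresh_mass_g = 1, sat_mass_g = 0.2, dry_mass_g = 0.2
    )),
    "denominator"
  )
})

test_that("osmotic line recovers an exactly linear curve in full", {
  rwc <- seq(0.7, 1, length.out = 10)
  d <- tibble::tibble(rwc = rwc, psi_mpa = -2 + 1 * rwc)
  line <- fit_osmotic_line(d)
  expect_equal(line$n_points, 10)
  expect_equal(line$slope, 1, tolerance = 1e-10)
  expect_equal(line$intercept, -2, tolerance = 1e-10)
  expect_true(all(line$used))
})

test_that("osmotic line base case returns the exact 4-point OLS fit", {
  rwc <- c(0.70, 0.75, 0.80, 0.85)
  psi <- c(-1.45, -1.30, -1.28, -1.15)
  line <- fit_osmotic_line(tibble::tibble(rwc = rwc, psi_mpa = psi))
  ref <- lm(psi ~ rwc)
  expect_equal(line$n_points, 4)
  expect_equal(line$slope, unname(coef(ref)[2]))
  expect_equal(line$intercept, unname(coef(ref)[1]))
})

test_that("stepwise selection stays in the turgor-free region of a noiseless curve", {
  pv <- gen_pv_series(
    pi0 = -1, rwc_tlp = 0.9, noise_sd_psi = 0, noise_sd_mass = 0, seed = 1
  )
  d <- compute_rwc(pv)
  line <- fit_osmotic_line(d)
  expect_true(all(d$rwc[line$used] <= 0.9 + 1e-9))
  # local-linear approximation of psi_o = pi0 / RWC at the turgor loss point
  expect_equal(
    line$intercept + line$slope * 0.9, -1 / 0.9, tolerance = 0.02
  )
})

test_that("pressure potential is the gap to the osmotic line", {
  d <- tibble::tibble(rwc = seq(0.7, 1, length.out = 8),
                      psi_mpa = -2 + 1 * seq(0.7, 1, length.out = 8))
  line <- fit_osmotic_line(d)
  out <- pressure_potential(d, line)
  expect_equal(out$psi_p, rep(0, 8), tolerance = 1e-10)
  # a point 0.8 MPa above a line value of -1.0
  d2 <- tibble::tibble(rwc = 1, psi_mpa = -0.2)
  expect_equal(pressure_potential(d2, line)$psi_p, 0.8, tolerance = 1e-10)
  # noiseless generator at saturation: psi_p approximates -pi0
  pv <- compute_rwc(gen_pv_series(
    pi0 = -1, rwc_tlp = 0.9, noise_sd_psi = 0, noise_sd_mass = 0, seed = 1
  ))
  pp <- pressure_potential(pv, fit_osmotic_line(pv))
  expect_equal(pp$psi_p[pv$rwc == 1], 1, tolerance = 0.05)
})

test_that("turgor fitter is self-consistent on model-generated data", {
  rwc <- seq(0.85, 1, length.out = 10)
  psi_p <- 0.6 * (exp(3 * (rwc - 0.88)) - 1)
  fit <- fit_turgor_curve(tibble::tibble(rwc = rwc, psi_p = psi_p),
                          anchor_zero = FALSE)
  expect_equal(fit$a, 0.6, tolerance = 1e-6)
  expect_equal(fit$b, 3, tolerance = 1e-6)
  expect_equal(fit$rwc_tlp, 0.88, tolerance = 1e-6)
})

test_that("turgor fitter rejects a turgorless series", {
  d <- tibble::tibble(rwc = seq(0.7, 1, length.out = 8), psi_p = 0.01)
  expect_error(fit_turgor_curve(d), "no turgor phase")
})

test_that("full PV analysis recovers noiseless generator truth", {
  pv <- gen_pv_series(
    pi0 = -1, rwc_tlp = 0.9, noise_sd_psi = 0, noise_sd_mass = 0, seed = 1
  )
  fit <- derive_pv_result(pv)
  expect_equal(fit$tlp, -1 / 0.9, tolerance = 0.05)
  expect_equal(fit$psi_osat, -1, tolerance = 0.05)
  expect_equal(fit$rwc_tlp, 0.9, tolerance = 0.02)
  expect_true(fit$tlp <= fit$psi_osat)
  expect_true(fit$epsilon > 0)
  # determinism: identical leaves give identical results
  fit2 <- derive_pv_result(gen_pv_series(
    pi0 = -1, rwc_tlp = 0.9, noise_sd_psi = 0, noise_sd_mass = 0, seed = 1
  ))
  expect_identical(generics::tidy(fit), generics::tidy(fit2))
})

test_that("elastic modulus diverges as turgor loss approaches saturation", {
  f_soft <- derive_pv_result(gen_pv_series(
    pi0 = -1, rwc_tlp = 0.9, noise_sd_psi = 0, noise_sd_mass = 0, seed = 1
  ))
  # near-saturation turgor loss needs dense sampling of the narrow turgid phase
  f_rigid <- derive_pv_result(gen_pv_series(
    pi0 = -1, rwc_tlp = 0.99, noise_sd_psi = 0, noise_sd_mass = 0,
    n_points = 30, rwc_min = 0.935, seed = 1
  ))
  expect_gte(f_rigid$epsilon, 10 * f_soft$epsilon)
  expect_equal(f_soft$epsilon / 100,
    derive_pv_result(gen_pv_series(
      pi0 = -1, rwc_tlp = 0.9, noise_sd_psi = 0, noise_sd_mass = 0, seed = 1
    ), epsilon_per_percent = TRUE)$epsilon
  )
})

test_that("dropping the wettest point never changes the selected osmotic set", {
  for (seed in 1:20) {
    pv <- compute_rwc(gen_pv_series(
      pi0 = -1.2, rwc_tlp = 0.88, noise_sd_psi = 0.02, seed = seed
    ))
    full <- fit_osmotic_line(pv)
    trimmed <- fit_osmotic_line(pv[pv$rwc < max(pv$rwc), ])
    expect_gte(full$n_points, trimmed$n_points)
    expect_equal(trimmed$n_points, min(full$n_points, nrow(pv) - 1))
  }
})

test_that("TLP never exceeds the saturated osmotic potential across noisy fits", {
  for (seed in 1:25) {
    fit <- derive_pv_result(gen_pv_series(
      pi0 = -1, rwc_tlp = 0.9, noise_sd_psi = 0.02, noise_sd_mass = 0.001,
      seed = seed
    ))
    expect_lte(fit$tlp, fit$psi_osat)
    expect_gt(fit$rwc_tlp, 0)
    expect_lt(fit$rwc_tlp, 1)
  }
})

test_that("per-leaf mapper drops failing leaves with a warning", {
  good <- gen_pv_series(pi0 = -1, rwc_tlp = 0.9, seed = 1, leaf_id = "ok")
  bad <- good
  bad$leaf_id <- "flat"
  bad$psi_mpa <- -1 # constant: no turgor phase
  expect_warning(out <- fit_pv_curves(dplyr::bind_rows(good, bad)), "flat")
  expect_equal(out$leaf_id, "ok")
})
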