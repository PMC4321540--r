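make_groups <- function(n_per = 20, delta = 0, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    species = sprintf("sp%03d", seq_len(2 * n_per)),
    grp = rep(c("g1", "g2"), each = n_per),
    y = rnorm(2 * n_per) + rep(c(0, delta), each = n_per)
  ))
}

test_that("Welch test behaves symmetrically and detects separation", {
  d <- make_groups(delta = 0, seed = 1)
  same <- d
  same$y <- rep(d$y[seq_len(20)], 2)
  out <- welch_test(same, "y", "grp")
  expect_equal(out$t, 0, tolerance = 1e-12)
  expect_equal(out$p, 1, tolerance = 1e-12)
  expect_equal(out$stars, "ns")
  # label swap negates t, keeps p
  d2 <- d
  d2$grp <- ifelse(d$grp == "g1", "g2", "g1")
  a <- welch_test(d, "y", "grp")
  b <- welch_test(d2, "y", "grp")
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  # strong separation is detected essentially always
  hits <- vapply(1:50, function(s) {
    welch_test(make_groups(delta = 5, seed = s), "y", "grp")$p < 0.001
  }, logical(1))
  expect_gte(sum(hits), 49)
})

test_that("Welch test collapses replicates to species means by default", {
  d <- tibble::tibble(
    species = rep(c("a", "b", "c", "d"), each = 3),
    grp = rep(c("g1", "g2"), each = 6),
    y = c(1, 2, 3, 4, 5, 6, 11, 12, 13, 14, 15, 16)
  )
  out <- welch_test(d, "y", "grp")
  ref <- t.test(c(2, 5), c(12, 15), var.equal = FALSE)
  expect_equal(out$t, unname(ref$statistic))
  expect_equal(out$df, unname(ref$parameter))
})

test_that("noiseless panel mixed model returns the injected effects exactly", {
  spec <- panel_spec(
    traits = list(y = trait_model(
      10, subfamily_effect = 2, type_effect = -1, interaction = 0.5
    )),
    trait_seed = 3
  )
  panel <- gen_species_panel(spec, emit_raw = FALSE)
  fit <- fit_two_factor_mixed(panel$traits, "y")
  cells <- expand.grid(
    A = c("Chloridoideae", "Panicoideae"), B = c("PCK", "non-PCK"),
    stringsAsFactors = FALSE
  )
  pred <- predict(fit$fit, newdata = cells, re.form = NA)
  truth <- 10 + 2 * (cells$A == "Panicoideae") - 1 * (cells$B == "PCK") +
    0.5 * (cells$A == "Panicoideae" & cells$B == "PCK")
  expect_equal(unname(pred), truth, tolerance = 1e-8)
  expect_equal(unname(fit$varcomp["residual"]), 0, tolerance = 1e-10)
})

test_that("with species variance forced off, F equals the balanced ANOVA oracle", {
  spec <- panel_spec(
    n_species_per_cell = 4,
    traits = list(y = trait_model(
      5, subfamily_effect = 1, type_effect = 0.5, interaction = 0.2,
      species_sd = 0, residual_sd = 1
    )),
    trait_seed = 11
  )
  panel <- gen_species_panel(spec, emit_raw = FALSE)
  fit <- fit_two_factor_mixed(panel$traits, "y", random = FALSE)
  oracle <- balanced_twoway_anova(
    panel$traits$y, panel$traits$subfamily, panel$traits$ptype
  )
  expect_equal(fit$table$f, oracle$f, tolerance = 1e-6)
  expect_equal(fit$table$den_df, rep(oracle$df_err[1], 3))
})

test_that("mixed model uses the between-species denominator df by default", {
  panel <- gen_species_panel(panel_spec(), emit_raw = FALSE)
  fit <- fit_two_factor_mixed(panel$traits, "tlp")
  expect_equal(fit$table$den_df, rep(29, 3)) # 33 species - 4 parameters
  expect_equal(fit$table$num_df, rep(1, 3))
  sat <- fit_two_factor_mixed(panel$traits, "tlp", ddf = "satterthwaite")
  expect_false(all(sat$table$den_df == 29))
})

test_that("a dominant species variance component is recovered", {
  hits <- vapply(1:20, function(s) {
    spec <- panel_spec(
      traits = list(y = trait_model(0, species_sd = 2, residual_sd = 0.2)),
      trait_seed = s
    )
    panel <- gen_species_panel(spec, emit_raw = FALSE)
    fit <- fit_two_factor_mixed(panel$traits, "y")
    fit$varcomp["species"] > fit$varcomp["residual"]
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("MAP encoding wins the AIC comparison when MAP drives the trait", {
  wins <- vapply(1:20, function(s) {
    spec <- panel_spec(
      traits = list(y = trait_model(
        5, species_sd = 0.3, residual_sd = 0.3, map_effect = 0.004
      )),
      trait_seed = s
    )
    panel <- gen_species_panel(spec, emit_raw = FALSE)
    d <- dplyr::left_join(
      panel$traits[c("species", "subfamily", "replicate", "y")],
      panel$species[c("species", "map", "water_score", "habitat_class")],
      by = "species"
    )
    cmp <- compare_water_encodings(d, "y")
    cmp$encoding[cmp$best]
  }, character(1))
  expect_gte(sum(wins == "map"), 18)
})

test_that("mixed model rejects non-varying factors", {
  panel <- gen_species_panel(panel_spec(), emit_raw = FALSE)
  d <- panel$traits
  d$ptype <- "PCK"
  expect_error(fit_two_factor_mixed(d, "tlp"), "does not vary")
})
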