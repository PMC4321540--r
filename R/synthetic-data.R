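#' Simulate one leaf's pressure-volume drying series
#'
#' Generates the (water potential, fresh mass) observations a pressure-chamber
#' drying experiment would record, from a ground-truth osmotic/turgor model
#' with closed-form parameters, so that downstream curve fitting can be tested
#' by parameter recovery.
#'
#' The noiseless model works on the symplastic relative water content
#' `r_s = (RWC - af) / (1 - af)`:
#' \itemize{
#'   \item osmotic potential `psi_o = pi0 / r_s` (van't Hoff dilution),
#'   \item turgor pressure `psi_p = -pi0 * (r_s - rwc_tlp) / (1 - rwc_tlp)`
#'         while `r_s >= rwc_tlp`, else 0 (linear turgor decline),
#'   \item total `psi = psi_o + psi_p`.
#' }
#' At full hydration this gives `psi = 0` exactly, and turgor is lost at
#' `r_s = rwc_tlp` where `psi = pi0 / rwc_tlp` — the analytic turgor loss
#' point stored in the returned ground truth. Gaussian noise is then added to
#' the water potentials and fresh masses.
#'
#' @param pi0 Osmotic potential at full turgor (MPa, negative).
#' @param rwc_tlp Symplastic relative water content at turgor loss, in (0, 1).
#' @param apoplastic_fraction Fraction of leaf water held in cell walls,
#'   in `[0, 1)`. Defaults to 0 (all water osmotically active).
#' @param n_points Number of drying observations (>= 8).
#' @param noise_sd_psi Gaussian noise SD on water potential (MPa).
#' @param noise_sd_mass Gaussian noise SD on fresh mass (g).
#' @param sat_mass,dry_mass Saturated and oven-dry leaf mass (g).
#' @param rwc_min Lowest total RWC reached while drying; must lie below the
#'   turgor loss point so the osmotic line is identifiable.
#' @param seed Integer seed; every call is fully deterministic.
#' @param leaf_id Label carried through to the output.
#' @return A tibble with one row per observation: `leaf_id`, `time_min`,
#'   `psi_mpa`, `fresh_mass_g`, `sat_mass_g`, `dry_mass_g`, plus the noiseless
#'   `rwc_true` and `psi_true`. The generating parameters (including the
#'   analytic `tlp`) are attached as the `"truth"` attribute.
#' @examples
#' pv <- gen_pv_series(pi0 = -1.0, rwc_tlp = 0.9, seed = 1)
#' attr(pv, "truth")$tlp # -1.0 / 0.9
#' @export
gen_pv_series <- function(pi0, rwc_tlp, apoplastic_fraction = 0,
                          n_points = 12, noise_sd_psi = 0.02,
                          noise_sd_mass = 0.001, sat_mass = 0.5,
                          dry_mass = 0.1, rwc_min = NULL, seed = 1L,
                          leaf_id = "leaf_1") {
  af <- apoplastic_fraction
  if (!is.numeric(pi0) || pi0 >= 0) abort("`pi0` must be negative (MPa).")
  if (rwc_tlp <= 0 || rwc_tlp >= 1) abort("`rwc_tlp` must lie in (0, 1).")
  if (af < 0 || af >= 1) abort("`apoplastic_fraction` must lie in [0, 1).")
  if (n_points < 8) abort("`n_points` must be >= 8 for the stepwise linear fit.")
  if (rwc_tlp <= af) abort("`rwc_tlp` must exceed the apoplastic fraction.")
  if (sat_mass <= dry_mass || dry_mass <= 0) {
    abort("need `sat_mass` > `dry_mass` > 0.")
  }
  # turgor loss expressed on the total-RWC scale
  rwc_at_tlp_total <- af + rwc_tlp * (1 - af)
  if (is.null(rwc_min)) rwc_min <- rwc_at_tlp_total - 0.15
  if (rwc_min >= rwc_at_tlp_total - 0.05) {
    abort("`rwc_min` must be at least 0.05 below the total RWC at turgor loss.")
  }
  if (rwc_min <= af) abort("`rwc_min` must exceed the apoplastic fraction.")

  rwc <- seq(1, rwc_min, length.out = n_points)
  psi <- pv_model_psi(rwc, pi0, rwc_tlp, af)

  withr::with_seed(as.integer(seed), {
    psi_obs <- pmin(psi + rnorm(n_points, sd = noise_sd_psi), 0)
    mass <- dry_mass + rwc * (sat_mass - dry_mass) +
      rnorm(n_points, sd = noise_sd_mass)
  })

  out <- tibble::tibble(
    leaf_id = leaf_id,
    time_min = 15 * (seq_len(n_points) - 1),
    psi_mpa = psi_obs,
    fresh_mass_g = mass,
    sat_mass_g = sat_mass,
    dry_mass_g = dry_mass,
    rwc_true = rwc,
    psi_true = psi
  )
  attr(out, "truth") <- list(
    pi0 = pi0, rwc_tlp = rwc_tlp, apoplastic_fraction = af,
    tlp = pi0 / rwc_tlp, rwc_at_tlp_total = rwc_at_tlp_total,
    noise_sd_psi = noise_sd_psi, noise_sd_mass = noise_sd_mass,
    sat_mass = sat_mass, dry_mass = dry_mass, seed = as.integer(seed)
  )
  out
}

# Noiseless total water potential at a given total RWC.
pv_model_psi <- function(rwc, pi0, rwc_tlp, af = 0) {
  rs <- (rwc - af) / (1 - af)
  if (any(rs <= 0)) abort("RWC at or below the apoplastic fraction.")
  psi_o <- pi0 / rs
  psi_p <- ifelse(rs >= rwc_tlp, -pi0 * (rs - rwc_tlp) / (1 - rwc_tlp), 0)
  psi_o + psi_p
}

#' Simulate a leaf-curling time series
#'
#' Emulates the bench protocol in which a detached leaf's width and mass are
#' recorded at 15-minute intervals for two hours in a constant-environment
#' cabinet. Width shrinks linearly during the first hour (active curling) and
#' is constant afterwards; mass falls at the combined stomatal + cuticular
#' rate during hour 1 and at the cuticular rate alone during hour 2, once
#' curled leaves are assumed to have closed their stomata.
#'
#' @param w0 Initial leaf width (mm).
#' @param curl_rate Fractional width loss per hour during hour 1
#'   (e.g. 0.5 halves the width by t = 1 h).
#' @param mass0 Initial fresh mass (g).
#' @param dry_mass Oven-dry mass (g); the series must stay above it.
#' @param stomatal_loss_rate,cuticular_loss_rate Water loss rates (g h^-1);
#'   the cuticular rate must be the smaller.
#' @param area_cm2 One-sided leaf area (cm^2), used later to normalise fluxes.
#' @param interval_min Sampling interval (minutes).
#' @param duration_hr Record length (hours, >= 2).
#' @param noise_sd_width,noise_sd_mass Gaussian noise SDs (mm, g).
#' @param temp_c,rh,pressure_kpa Cabinet conditions stored with the series.
#' @param seed Integer seed.
#' @param leaf_id Label carried through to the output.
#' @return A tibble with columns `leaf_id`, `t_min`, `width_mm`, `mass_g`,
#'   `area_cm2`, `dry_mass_g`, `temp_c`, `rh`, `pressure_kpa`, with the
#'   generating rates in the `"truth"` attribute.
#' @examples
#' cs <- gen_curling_series(w0 = 10, curl_rate = 0.5, seed = 1)
#' cs$width_mm[cs$t_min == 60] # 5 mm
#' @export
gen_curling_series <- function(w0 = 10, curl_rate = 0.4, mass0 = 0.4,
                               dry_mass = 0.1, stomatal_loss_rate = 0.02,
                               cuticular_loss_rate = 0.004, area_cm2 = 10,
                               interval_min = 15, duration_hr = 2,
                               noise_sd_width = 0, noise_sd_mass = 0,
                               temp_c = 23.5, rh = 0.6,
                               pressure_kpa = 101.325, seed = 1L,
                               leaf_id = "leaf_1") {
  if (w0 <= 0) abort("`w0` must be positive.")
  if (mass0 <= dry_mass) abort("`mass0` must exceed `dry_mass`.")
  if (cuticular_loss_rate >= stomatal_loss_rate) {
    abort("`cuticular_loss_rate` must be below `stomatal_loss_rate`.")
  }
  if (duration_hr < 2) abort("`duration_hr` must be at least 2.")
  if (curl_rate < 0 || curl_rate >= 1) abort("`curl_rate` must lie in [0, 1).")

  t_min <- seq(0, duration_hr * 60, by = interval_min)
  t_hr <- t_min / 60
  width <- w0 * (1 - curl_rate * pmin(t_hr, 1))
  total_rate <- stomatal_loss_rate + cuticular_loss_rate
  mass <- ifelse(
    t_hr <= 1,
    mass0 - total_rate * t_hr,
    mass0 - total_rate - cuticular_loss_rate * (t_hr - 1)
  )
  if (any(mass <= dry_mass)) {
    abort("loss rates dry the leaf below `dry_mass` within the record.")
  }

  withr::with_seed(as.integer(seed), {
    width <- width + rnorm(length(width), sd = noise_sd_width)
    mass <- mass + rnorm(length(mass), sd = noise_sd_mass)
  })

  out <- tibble::tibble(
    leaf_id = leaf_id, t_min = t_min, width_mm = width, mass_g = mass,
    area_cm2 = area_cm2, dry_mass_g = dry_mass,
    temp_c = temp_c, rh = rh, pressure_kpa = pressure_kpa
  )
  attr(out, "truth") <- list(
    w0 = w0, curl_rate = curl_rate, mass0 = mass0,
    stomatal_loss_rate = stomatal_loss_rate,
    cuticular_loss_rate = cuticular_loss_rate,
    seed = as.integer(seed)
  )
  out
}
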