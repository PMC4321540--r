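#' Leaf curling and water-loss rates from a bench time series
#'
#' Summarises a two-hour width/mass record into the four curling kinetics
#' reported for grass leaves. Width-based rates are fitted over the first
#' hour only (the active curling phase, before the leaf settles); the
#' weight-based rates use the full record. Each rate is the negated ordinary
#' least-squares slope against time in hours:
#' \describe{
#'   \item{relative_width_loss}{slope of `100 * width / width(0)` (% h^-1).}
#'   \item{absolute_width_loss}{slope of width (mm h^-1).}
#'   \item{relative_weight_loss}{slope of `100 * mass / mass(0)` (% h^-1).}
#'   \item{width_weight_ratio_loss}{slope of the width/mass ratio relative
#'     to its initial value (% h^-1).}
#' }
#'
#' @param data Data frame with columns `t_min`, `width_mm`, `mass_g`
#'   (15-minute spacing over at least 2 h; at least 5 points in hour 1).
#' @param breakpoint_min End of the active curling phase (default 60 min).
#' @return A one-row tibble with the four rates.
#' @examples
#' curling_rates(gen_curling_series(seed = 1))
#' @export
curling_rates <- function(data, breakpoint_min = 60) {
  need <- c("t_min", "width_mm", "mass_g")
  if (!all(need %in% names(data))) {
    abort(paste("`data` needs columns:", paste(need, collapse = ", ")))
  }
  t_hr <- (data$t_min - data$t_min[1]) / 60
  if (data$width_mm[1] <= 0 || data$mass_g[1] <= 0) {
    abort("zero initial width or mass.")
  }
  hour1 <- data$t_min - data$t_min[1] <= breakpoint_min
  if (sum(hour1) < 5) abort("fewer than 5 points in the curling window.")
  slope <- function(y, sel = TRUE) {
    unname(coef(lm(y[sel] ~ t_hr[sel]))[2])
  }
  rel_w <- 100 * data$width_mm / data$width_mm[1]
  rel_m <- 100 * data$mass_g / data$mass_g[1]
  ratio <- (data$width_mm / data$mass_g) /
    (data$width_mm[1] / data$mass_g[1]) * 100
  tibble::tibble(
    relative_width_loss = -slope(rel_w, hour1),
    absolute_width_loss = -slope(data$width_mm, hour1),
    relative_weight_loss = -slope(rel_m),
    width_weight_ratio_loss = -slope(ratio)
  )
}

#' Cuticular conductance from the second hour of a curling record
#'
#' Once leaves have curled and closed their stomata (assumed complete after
#' the first hour), residual water loss is cuticular. The mass-loss slope
#' over the second hour is converted to a molar flux per unit leaf area and
#' divided by the mole-fraction vapour gradient of the cabinet,
#' `dw = e_sat(T) * (1 - RH) / P` with `e_sat` from Tetens' formula, to give
#' a conductance. The raw per-area flux is returned alongside, since the
#' slope-per-area quantity is sometimes reported without the gradient
#' normalisation.
#'
#' @param data Curling record with columns `t_min`, `mass_g`, `area_cm2`,
#'   `temp_c`, `rh`, `pressure_kpa` (cabinet metadata constant per leaf).
#' @param breakpoint_min Start of the stomata-closed window (default 60 min).
#' @param two_sided Normalise by two-sided leaf area instead of one-sided.
#' @return A one-row tibble: `gmin_mmol` (mmol m^-2 s^-1; `NA` if the leaf
#'   gained mass), `flux_mol_m2_s` (mol m^-2 s^-1), `mass_slope_g_hr`.
#' @examples
#' cuticular_conductance(gen_curling_series(seed = 1))
#' @export
cuticular_conductance <- function(data, breakpoint_min = 60,
                                  two_sided = FALSE) {
  need <- c("t_min", "mass_g", "area_cm2", "temp_c", "rh", "pressure_kpa")
  if (!all(need %in% names(data))) {
    abort(paste("`data` needs columns:", paste(need, collapse = ", ")))
  }
  t0 <- data$t_min[1]
  sel <- data$t_min - t0 >= breakpoint_min
  if (sum(sel) < 4) abort("fewer than 4 points in the stomata-closed window.")
  t_hr <- (data$t_min - t0) / 60
  slope_g_hr <- unname(coef(lm(data$mass_g[sel] ~ t_hr[sel]))[2])

  area_m2 <- data$area_cm2[1] * 1e-4 * (1 + two_sided)
  flux <- -slope_g_hr / 3600 / .lw_const$m_water / area_m2 # mol m^-2 s^-1
  dw <- esat_tetens(data$temp_c[1]) * (1 - data$rh[1]) / data$pressure_kpa[1]

  gmin <- if (slope_g_hr >= 0) {
    warn("non-negative hour-2 mass slope; cuticular conductance set missing.")
    NA_real_
  } else {
    1000 * flux / dw
  }
  tibble::tibble(
    gmin_mmol = gmin, flux_mol_m2_s = flux, mass_slope_g_hr = slope_g_hr
  )
}

#' Leaf hydraulic conductance from a pressure-chamber record
#'
#' `K_leaf = dW * time^-1 * area^-1 * dPsi^-1`: the mass of sap expressed
#' (`delta_w_g`, converted to mmol of water) per second, per unit leaf area,
#' per unit of the applied water-potential step.
#'
#' @param delta_w_g Expressed sap mass (g).
#' @param duration_s Collection time (s).
#' @param area_m2 Leaf area (m^2).
#' @param delta_psi_mpa Water-potential step (MPa, > 0).
#' @return K_leaf in mmol m^-2 s^-1 MPa^-1, vectorised.
#' @examples
#' kleaf(0.018015, duration_s = 10, area_m2 = 0.001, delta_psi_mpa = 0.5)
#' @export
kleaf <- function(delta_w_g, duration_s, area_m2, delta_psi_mpa) {
  if (any(delta_psi_mpa <= 0)) abort("`delta_psi_mpa` must be positive.")
  if (any(duration_s <= 0) || any(area_m2 <= 0)) {
    abort("duration and area must be positive.")
  }
  if (any(delta_w_g < 0)) abort("`delta_w_g` must be non-negative.")
  mmol <- delta_w_g / .lw_const$m_water * 1000
  mmol / duration_s / area_m2 / delta_psi_mpa
}

#' Instantaneous water use efficiency from gas exchange
#'
#' `WUEi = A / gs`: net CO2 assimilation per unit stomatal conductance to
#' water vapour (micromol CO2 per mol H2O).
#'
#' @param a_umol Net assimilation rate A (micromol CO2 m^-2 s^-1).
#' @param gs_mol Stomatal conductance g_s (mol H2O m^-2 s^-1, > 0).
#' @return WUEi (micromol mol^-1), vectorised.
#' @examples
#' wue_instantaneous(a_umol = 30, gs_mol = 0.25)
#' @export
wue_instantaneous <- function(a_umol, gs_mol) {
  if (any(gs_mol <= 0)) abort("`gs_mol` must be positive to compute WUEi.")
  a_umol / gs_mol
}
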