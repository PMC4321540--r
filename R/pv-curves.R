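#' Relative water content of pressure-volume observations
#'
#' Adds the relative water content `rwc = (fresh - dry) / (sat - dry)` to a
#' drying series. Values above 1.02 indicate oversaturation (surface water at
#' the start of the bench-dry) and are flagged, not altered.
#'
#' @param data Data frame with columns `fresh_mass_g`, `sat_mass_g`,
#'   `dry_mass_g`.
#' @return `data` with columns `rwc` and logical `oversaturated` appended.
#' @examples
#' compute_rwc(tibble::tibble(
#'   fresh_mass_g = 0.42, sat_mass_g = 0.50, dry_mass_g = 0.10
#' ))
#' @export
compute_rwc <- function(data) {
  need <- c("fresh_mass_g", "sat_mass_g", "dry_mass_g")
  if (!all(need %in% names(data))) {
    abort(paste("`data` needs columns:", paste(need, collapse = ", ")))
  }
  denom <- data$sat_mass_g - data$dry_mass_g
  if (any(denom == 0)) abort("sat_mass equals dry_mass: zero RWC denominator.")
  data$rwc <- (data$fresh_mass_g - data$dry_mass_g) / denom
  data$oversaturated <- data$rwc > 1.02
  data
}

#' Stepwise fit of the osmotic line at low RWC
#'
#' Identifies the linear portion of the pressure-volume curve, where turgor
#' is lost and total water potential tracks osmotic potential alone. Starting
#' from the four driest observations, progressively wetter points are added
#' while the incoming point's absolute residual from the current fit does not
#' exceed `resid_factor` times the current residual SD (floored at
#' `resid_floor`, the assumed pressure-chamber precision, so a handful of
#' noiseless points cannot lock the line prematurely). An optional R-squared
#' gate (`r2_min > 0`) additionally stops extension when the candidate fit's
#' R-squared falls below the threshold; it is off by default because
#' R-squared confounds measurement noise with genuine nonlinearity on the
#' shallow osmotic segment. The accepted line estimates the response of
#' osmotic potential to RWC across the whole curve.
#'
#' @param data Data frame with columns `rwc` and `psi_mpa`.
#' @param resid_factor Residual gate in multiples of the current residual SD.
#' @param resid_floor Floor on the residual SD used by the gate (MPa);
#'   default 0.02, of the order of pressure-chamber resolution.
#' @param r2_min Optional minimum R-squared to keep extending the line;
#'   0 (default) disables the gate.
#' @return A list of class `osmotic_line`: `slope`, `intercept` (MPa),
#'   `n_points`, `r2`, `resid_sd`, and `used` (logical, in the order of
#'   `data`).
#' @export
fit_osmotic_line <- function(data, resid_factor = 2, resid_floor = 0.02,
                             r2_min = 0) {
  if (!all(c("rwc", "psi_mpa") %in% names(data))) {
    abort("`data` needs columns `rwc` and `psi_mpa`.")
  }
  ord <- order(data$rwc)
  rwc <- data$rwc[ord]
  psi <- data$psi_mpa[ord]
  n <- length(rwc)
  if (n < 4) abort("no linear region: fewer than 4 usable points.")

  k <- 4L
  fit <- lm(psi[1:k] ~ rwc[1:k])
  while (k < n) {
    cur_sd <- max(summary(fit)$sigma, resid_floor)
    # prediction SE of the incoming point: residual scale inflated by the
    # leverage of extrapolating one step beyond the current fit
    x <- rwc[1:k]
    lev <- 1 + 1 / k + (rwc[k + 1] - mean(x))^2 / sum((x - mean(x))^2)
    new_resid <- abs(psi[k + 1] - unname(coef(fit)[1] + coef(fit)[2] * rwc[k + 1]))
    if (new_resid > resid_factor * cur_sd * sqrt(lev)) break
    cand <- lm(psi[1:(k + 1)] ~ rwc[1:(k + 1)])
    if (r2_min > 0 && summary(cand)$r.squared < r2_min) break
    k <- k + 1L
    fit <- cand
  }
  used <- logical(n)
  used[1:k] <- TRUE
  structure(
    list(
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      n_points = k, r2 = summary(fit)$r.squared,
      resid_sd = summary(fit)$sigma,
      used = used[match(seq_len(n), ord)]
    ),
    class = "osmotic_line"
  )
}

#' Pressure (turgor) potential from the fitted osmotic line
#'
#' Extrapolates the osmotic line across all RWC values and subtracts it from
#' the total water potential: `psi_p = psi - (intercept + slope * rwc)`.
#' Values below -0.05 MPa are flagged (they indicate an osmotic line fitted
#' too high) but kept for diagnostics.
#'
#' @param data Data frame with columns `rwc` and `psi_mpa`.
#' @param line An `osmotic_line` from [fit_osmotic_line()].
#' @return `data` with columns `psi_p` and logical `psi_p_suspect` appended.
#' @export
pressure_potential <- function(data, line) {
  stopifnot(inherits(line, "osmotic_line"))
  data$psi_p <- data$psi_mpa - (line$intercept + line$slope * data$rwc)
  data$psi_p_suspect <- data$psi_p < -0.05
  data
}

#' Fit the modified-exponential turgor curve
#'
#' Fits `psi_p(RWC) = a * (exp(b * (RWC - rwc_tlp)) - 1)` with `a, b > 0` to
#' the turgid part of the curve by nonlinear least squares
#' (Levenberg-Marquardt). The form is zero exactly at its intercept
#' `rwc_tlp`, which is therefore the estimated relative water content at the
#' turgor loss point, and it degenerates to a straight line as `b -> 0`.
#' Only points with `psi_p` above `turgor_floor` enter the fit.
#'
#' Starting values: `a = max(psi_p) / 2`, `b = 2`, and `rwc_tlp` at the
#' largest RWC whose observed `psi_p` is at or below `turgor_floor`.
#'
#' With `anchor_zero = TRUE` (the default), observations whose turgor is
#' indistinguishable from zero (`|psi_p| <= turgor_floor`) also enter the
#' objective, compared against the physically floored prediction
#' `max(0, model)`: turgor cannot be negative, so below the crossing the
#' curve predicts exactly zero. These points bracket the zero crossing from
#' the dry side and stabilise it considerably under measurement noise.
#' Distinctly negative `psi_p` (below `-turgor_floor`) indicates an osmotic
#' line fitted too low and is excluded as diagnostic. Set
#' `anchor_zero = FALSE` to fit the bare exponential to the turgid points
#' alone.
#'
#' @param data Data frame with columns `rwc` and `psi_p`.
#' @param turgor_floor Turgor threshold (MPa) separating the turgid phase
#'   from measurement noise around zero; default 0.02.
#' @param max_iter Iteration cap for the optimiser.
#' @param anchor_zero Use the zero-turgor observations to anchor the
#'   crossing (default TRUE).
#' @return A list of class `turgor_curve`: `a`, `b`, `rwc_tlp`, `n_points`,
#'   `resid_sd`, `convergence`.
#' @export
fit_turgor_curve <- function(data, turgor_floor = 0.02, max_iter = 500,
                             anchor_zero = TRUE) {
  if (!all(c("rwc", "psi_p") %in% names(data))) {
    abort("`data` needs columns `rwc` and `psi_p` (see pressure_potential()).")
  }
  turgid <- data$psi_p > turgor_floor
  if (!any(turgid)) abort("no turgor phase: all psi_p at or below the floor.")
  if (sum(turgid) < 4) abort("fewer than 4 points in the turgor phase.")
  rwc <- data$rwc[turgid]
  psi_p <- data$psi_p[turgid]
  zero_sel <- !turgid & abs(data$psi_p) <= turgor_floor
  rwc_z <- data$rwc[zero_sel]
  psi_z <- data$psi_p[zero_sel]

  below <- data$rwc[data$psi_p <= turgor_floor]
  r0_init <- if (length(below)) max(below) else min(rwc) - 0.02
  start <- list(a = max(psi_p) / 2, b = 2, r0 = min(r0_init, min(rwc) - 1e-4))

  if (anchor_zero && length(rwc_z)) {
    fit <- turgor_fit_anchored(rwc, psi_p, rwc_z, psi_z, start, max_iter)
  } else {
    fit <- turgor_fit_plain(rwc, psi_p, start, max_iter)
  }
  structure(
    list(
      a = fit$a, b = fit$b, rwc_tlp = fit$r0,
      n_points = sum(turgid),
      resid_sd = sqrt(fit$sse / max(1, sum(turgid) - 3)),
      convergence = fit$conv
    ),
    class = "turgor_curve"
  )
}

# Bare exponential least squares on the turgid points: Levenberg-Marquardt,
# with a derivative-free multi-start fallback for singular-gradient starts.
turgor_fit_plain <- function(rwc, psi_p, start, max_iter) {
  fit <- tryCatch(
    minpack.lm::nlsLM(
      psi_p ~ a * (exp(b * (rwc - r0)) - 1),
      start = start,
      lower = c(a = 1e-9, b = 1e-9, r0 = 0),
      upper = c(a = Inf, b = Inf, r0 = 1),
      control = minpack.lm::nls.lm.control(maxiter = max_iter)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    cf <- coef(fit)
    return(list(
      a = unname(cf["a"]), b = unname(cf["b"]), r0 = unname(cf["r0"]),
      sse = sum(stats::residuals(fit)^2), conv = fit$convInfo$isConv
    ))
  }
  obj <- function(th) {
    r0 <- min(max(th[3], 0), 1)
    sum((psi_p - exp(th[1]) * (exp(exp(th[2]) * (rwc - r0)) - 1))^2)
  }
  nm_multistart(obj, start, max_iter)
}

# Anchored least squares: turgid points follow the exponential, zero-phase
# points follow its non-negative floor. Piecewise in r0, so derivative-free.
turgor_fit_anchored <- function(rwc, psi_p, rwc_z, psi_z, start, max_iter) {
  obj <- function(th) {
    a <- exp(th[1])
    b <- exp(th[2])
    r0 <- min(max(th[3], 0), 1)
    pred_t <- a * (exp(b * (rwc - r0)) - 1)
    pred_z <- pmax(0, a * (exp(b * (rwc_z - r0)) - 1))
    sum((psi_p - pred_t)^2) + sum((psi_z - pred_z)^2)
  }
  nm_multistart(obj, start, max_iter)
}

nm_multistart <- function(obj, start, max_iter) {
  starts <- expand.grid(
    b0 = c(0.5, 2, 8),
    r0 = unique(c(start$r0, max(0, start$r0 - 0.02)))
  )
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    optim(
      c(log(start$a), log(starts$b0[i]), starts$r0[i]), obj,
      method = "Nelder-Mead",
      control = list(maxit = max_iter * 4, reltol = 1e-13)
    )
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  if (!is.finite(best$value)) {
    abort("turgor curve did not converge from any start point.")
  }
  list(
    a = exp(best$par[1]), b = exp(best$par[2]),
    r0 = min(max(best$par[3], 0), 1), sse = best$value,
    conv = best$convergence == 0
  )
}

#' Full pressure-volume analysis of one leaf
#'
#' Composes the whole PV procedure: RWC computation, stepwise osmotic-line
#' fit, turgor-pressure extraction, and the modified-exponential turgor
#' curve. From these it derives the classical water-relations parameters:
#' \describe{
#'   \item{psi_osat}{osmotic potential at full hydration — the osmotic line
#'     evaluated at RWC = 1 (MPa).}
#'   \item{tlp}{turgor loss point — the osmotic line evaluated at the turgor
#'     curve's zero crossing (MPa).}
#'   \item{rwc_tlp}{relative water content at turgor loss.}
#'   \item{epsilon}{bulk elastic modulus — turgor at saturation divided by
#'     the fractional RWC drop to the turgor loss point,
#'     `psi_p(1) / (1 - rwc_tlp)` (MPa per unit fractional RWC). Set
#'     `epsilon_per_percent = TRUE` to report MPa per % RWC instead.}
#' }
#'
#' @param data One leaf's drying series: columns `psi_mpa`, `fresh_mass_g`,
#'   `sat_mass_g`, `dry_mass_g` (at least 8 rows, all `psi_mpa <= 0`).
#' @param epsilon_per_percent Report epsilon per % RWC (divides by 100).
#' @inheritParams fit_osmotic_line
#' @inheritParams fit_turgor_curve
#' @return An object of class `pv_fit`; [generics::tidy()] returns its
#'   one-row parameter tibble and [ggplot2::autoplot()] draws the fitted
#'   curve diagnostics.
#' @examples
#' pv <- gen_pv_series(pi0 = -1, rwc_tlp = 0.9, noise_sd_psi = 0, seed = 1)
#' derive_pv_result(pv)
#' @export
derive_pv_result <- function(data, epsilon_per_percent = FALSE,
                             resid_factor = 2, resid_floor = 0.02,
                             r2_min = 0, turgor_floor = 0.02, max_iter = 500,
                             anchor_zero = TRUE) {
  if (nrow(data) < 8) abort("pv_curves: need at least 8 observations.")
  if (any(data$psi_mpa > 0)) abort("pv_curves: water potentials must be <= 0.")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }
  data <- stage("rwc", compute_rwc(data))
  line <- stage(
    "osmotic_line",
    fit_osmotic_line(data, resid_factor, resid_floor, r2_min)
  )
  data <- stage("pressure_potential", pressure_potential(data, line))
  turgor <- stage(
    "turgor_curve",
    fit_turgor_curve(data, turgor_floor, max_iter, anchor_zero)
  )

  psi_osat <- line$intercept + line$slope * 1
  tlp <- line$intercept + line$slope * turgor$rwc_tlp
  psi_p_sat <- turgor$a * (exp(turgor$b * (1 - turgor$rwc_tlp)) - 1)
  epsilon <- psi_p_sat / (1 - turgor$rwc_tlp)
  if (epsilon_per_percent) epsilon <- epsilon / 100

  structure(
    list(
      leaf_id = if ("leaf_id" %in% names(data)) data$leaf_id[1] else NA_character_,
      psi_osat = psi_osat, tlp = tlp, rwc_tlp = turgor$rwc_tlp,
      epsilon = epsilon, psi_p_sat = psi_p_sat,
      osmotic_slope = line$slope, osmotic_intercept = line$intercept,
      n_osmotic_points = line$n_points, osmotic_r2 = line$r2,
      turgor_a = turgor$a, turgor_b = turgor$b,
      turgor_resid_sd = turgor$resid_sd,
      data = data, line = line, turgor = turgor,
      epsilon_per_percent = epsilon_per_percent
    ),
    class = "pv_fit"
  )
}

#' @export
print.pv_fit <- function(x, ...) {
  cat(sprintf(
    "PV fit%s: TLP %.3f MPa | psi_osat %.3f MPa | RWC at TLP %.3f | epsilon %.2f MPa%s\n",
    if (is.na(x$leaf_id)) "" else paste0(" (", x$leaf_id, ")"),
    x$tlp, x$psi_osat, x$rwc_tlp, x$epsilon,
    if (x$epsilon_per_percent) " per %RWC" else ""
  ))
  invisible(x)
}

#' Pressure-volume analysis for a table of leaves
#'
#' Maps [derive_pv_result()] over every `leaf_id` in a long drying table and
#' returns the per-leaf parameters as one tidy row each. Leaves whose fit
#' fails are dropped with a warning naming the leaf and the failing stage.
#'
#' @param data Long drying table with a `leaf_id` column plus the columns of
#'   [derive_pv_result()]. An optional `species` column is carried through.
#' @param ... Passed to [derive_pv_result()].
#' @return A tibble with one row per leaf: the PV parameters and diagnostics.
#' @export
fit_pv_curves <- function(data, ...) {
  if (!"leaf_id" %in% names(data)) abort("`data` needs a `leaf_id` column.")
  purrr::map_dfr(split(data, data$leaf_id), function(d) {
    res <- tryCatch(derive_pv_result(d, ...), error = function(e) {
      warn(sprintf("leaf '%s' dropped: %s", d$leaf_id[1], conditionMessage(e)))
      NULL
    })
    if (is.null(res)) return(NULL)
    out <- generics::tidy(res)
    if ("species" %in% names(d)) out$species <- d$species[1]
    out
  })
}
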