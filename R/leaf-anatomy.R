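#' Stomatal pore index
#'
#' The dimensionless index of stomatal pore area per lamina area,
#' `SPI = SD * GL^2`, computed with density in mm^-2 and guard-cell length
#' converted to mm. By default the bare product (which is of order 0.1 for
#' grass leaves) is multiplied by 100 so values land on the conventional
#' reporting scale of roughly 5-15; set `scale100 = FALSE` for the bare
#' product.
#'
#' @param density_per_mm2 Stomatal density (mm^-2).
#' @param gl_um Guard cell length (micrometres).
#' @param scale100 Multiply by 100 (default TRUE).
#' @return Dimensionless SPI, vectorised over its inputs.
#' @examples
#' spi(density_per_mm2 = 200, gl_um = 20) # 8
#' @export
spi <- function(density_per_mm2, gl_um, scale100 = TRUE) {
  if (any(density_per_mm2 < 0) || any(gl_um < 0)) {
    abort("density and guard-cell length must be non-negative.")
  }
  out <- density_per_mm2 * (gl_um / 1000)^2
  if (scale100) out <- out * 100
  out
}

#' Anatomical maximum stomatal conductance of one leaf surface
#'
#' Estimates the maximum diffusive conductance to water vapour from stomatal
#' anatomy alone:
#' `g_max = (d / v) * D * a_max / (l + (pi / 2) * sqrt(a_max / pi))`,
#' where `a_max = pi * (p / 2)^2` is the fully open pore area from the
#' measured pore length `p`, and the pore depth `l` is approximated by half
#' the width of the closed guard-cell pair, `W / 2`. Since
#' `sqrt(a_max / pi) = p / 2`, the denominator is `W / 2 + (pi / 4) * p`.
#' Inputs are given in field units (micrometres, mm^-2) and converted to SI
#' internally.
#'
#' @param density_per_mm2 Stomatal density (mm^-2); 0 for a surface without
#'   stomata.
#' @param pore_um Stomatal pore length `p` (micrometres).
#' @param width_um Width of the closed guard-cell pair `W` (micrometres).
#' @param const Gas constants from [gas_constants()].
#' @return Maximum stomatal conductance (mol m^-2 s^-1), vectorised.
#' @examples
#' gmax_one_surface(100, pore_um = 10, width_um = 14) # ~0.537
#' @export
gmax_one_surface <- function(density_per_mm2, pore_um, width_um,
                             const = gas_constants()) {
  if (any(density_per_mm2 < 0)) abort("stomatal density must be >= 0.")
  if (any(pore_um <= 0) || any(width_um <= 0)) {
    abort("pore length and guard-pair width must be positive.")
  }
  D <- density_per_mm2 * 1e6 # mm^-2 -> m^-2
  p <- pore_um * 1e-6
  w <- width_um * 1e-6
  a_max <- pi * (p / 2)^2
  l <- w / 2
  (const$d / const$v) * D * a_max / (l + (pi / 2) * sqrt(a_max / pi))
}

#' Whole-leaf anatomical maximum stomatal conductance
#'
#' Computes [gmax_one_surface()] for the abaxial and adaxial surfaces and
#' sums them. A missing surface (`NULL`) is treated as stomate-free.
#'
#' @param abaxial,adaxial Lists or one-row data frames with elements
#'   `density_per_mm2`, `pore_um`, `width_um`.
#' @param const Gas constants from [gas_constants()].
#' @return Total g_max (mol m^-2 s^-1).
#' @export
gmax_total <- function(abaxial = NULL, adaxial = NULL,
                       const = gas_constants()) {
  one <- function(s) {
    if (is.null(s) || s$density_per_mm2 == 0) return(0)
    gmax_one_surface(s$density_per_mm2, s$pore_um, s$width_um, const)
  }
  one(abaxial) + one(adaxial)
}

#' Leaf structural traits from morphometrics
#'
#' Derives the classical structural traits from one leaf's area, masses and
#' volume:
#' \describe{
#'   \item{sla}{specific leaf area, area (m^2) per dry mass (kg), m^2 kg^-1.}
#'   \item{ldmc}{leaf dry matter content, `100 * dry / saturated` (%).}
#'   \item{density}{dry mass per volume (g cm^-3).}
#'   \item{thickness}{volume per area, reported in mm.}
#' }
#'
#' @param area_cm2 One-sided leaf area (cm^2).
#' @param sat_mass_g,dry_mass_g Saturated and oven-dry mass (g).
#' @param volume_cm3 Leaf volume (cm^3).
#' @return A tibble with the four derived traits plus the inputs, vectorised
#'   over its arguments.
#' @examples
#' leaf_structure(25, sat_mass_g = 0.3125, dry_mass_g = 0.0625,
#'                volume_cm3 = 0.5)
#' @export
leaf_structure <- function(area_cm2, sat_mass_g, dry_mass_g, volume_cm3) {
  if (any(area_cm2 <= 0) || any(volume_cm3 <= 0)) {
    abort("leaf area and volume must be positive.")
  }
  if (any(dry_mass_g <= 0) || any(dry_mass_g > sat_mass_g)) {
    abort("need 0 < dry_mass_g <= sat_mass_g.")
  }
  tibble::tibble(
    area_cm2 = area_cm2, sat_mass_g = sat_mass_g,
    dry_mass_g = dry_mass_g, volume_cm3 = volume_cm3,
    sla = (area_cm2 * 1e-4) / (dry_mass_g * 1e-3),
    ldmc = 100 * dry_mass_g / sat_mass_g,
    density = dry_mass_g / volume_cm3,
    thickness = volume_cm3 / area_cm2 * 10
  )
}

#' Per-leaf stomatal traits from a micrograph measurement table
#'
#' Aggregates a long table of per-surface stomatal measurements into
#' per-leaf SPI and g_max. Species values should be computed as means of
#' per-leaf values (not by plugging trait means into the formulas, which
#' differs by Jensen's inequality).
#'
#' @param data Long table with columns `leaf_id`, `surface`
#'   (`"abaxial"`/`"adaxial"`), `gl_um`, `width_um`, `pore_um`,
#'   `density_per_mm2`; several micrograph rows per surface are averaged.
#' @param const Gas constants from [gas_constants()].
#' @param scale100 Passed to [spi()].
#' @return A tibble with one row per leaf: per-surface SPI and g_max plus
#'   their totals.
#' @export
stomatal_traits <- function(data, const = gas_constants(), scale100 = TRUE) {
  need <- c("leaf_id", "surface", "gl_um", "width_um", "pore_um", "density_per_mm2")
  if (!all(need %in% names(data))) {
    abort(paste("`data` needs columns:", paste(need, collapse = ", ")))
  }
  if (!all(data$surface %in% c("abaxial", "adaxial"))) {
    abort("`surface` must be 'abaxial' or 'adaxial'.")
  }
  if (any(data$pore_um > data$gl_um)) {
    abort("pore length cannot exceed guard cell length.")
  }
  data |>
    dplyr::group_by(.data$leaf_id, .data$surface) |>
    dplyr::summarise(
      spi = mean(spi(.data$density_per_mm2, .data$gl_um, scale100)),
      gmax = mean(gmax_one_surface(
        .data$density_per_mm2, .data$pore_um, .data$width_um, const
      )),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(
      names_from = "surface", values_from = c("spi", "gmax"),
      values_fill = 0
    ) |>
    dplyr::mutate(
      spi_total = rowSums(dplyr::pick(dplyr::starts_with("spi_"))),
      gmax_total = rowSums(dplyr::pick(dplyr::starts_with("gmax_")))
    )
}
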