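#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pressure-volume fit
#'
#' @param x A `pv_fit` from [derive_pv_result()].
#' @param ... Unused.
#' @return One row per leaf with the fitted water-relations parameters.
#' @method tidy pv_fit
#' @export
tidy.pv_fit <- function(x, ...) {
  tibble::tibble(
    leaf_id = x$leaf_id, tlp = x$tlp, psi_osat = x$psi_osat,
    rwc_tlp = x$rwc_tlp, epsilon = x$epsilon,
    osmotic_slope = x$osmotic_slope,
    osmotic_intercept = x$osmotic_intercept,
    n_osmotic_points = x$n_osmotic_points,
    turgor_a = x$turgor_a, turgor_b = x$turgor_b
  )
}

#' @rdname tidy.pv_fit
#' @method glance pv_fit
#' @export
glance.pv_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = nrow(x$data), n_osmotic_points = x$n_osmotic_points,
    osmotic_r2 = x$osmotic_r2, turgor_resid_sd = x$turgor_resid_sd,
    converged = x$turgor$convergence
  )
}

#' Tidy a phylogenetic signal fit
#'
#' @param x A `phylo_signal` from [fit_lambda()].
#' @param ... Unused.
#' @return A one-row tibble with lambda and its boundary tests.
#' @method tidy phylo_signal
#' @export
tidy.phylo_signal <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, sigma2 = x$sigma2, mu = x$mu,
    p_lambda0 = x$p_lambda0, p_lambda1 = x$p_lambda1
  )
}

#' @rdname tidy.phylo_signal
#' @method glance phylo_signal
#' @export
glance.phylo_signal <- function(x, ...) {
  tibble::tibble(
    n = x$n, logLik = x$logLik, logLik0 = x$logLik0, logLik1 = x$logLik1
  )
}

#' Tidy an ordination
#'
#' @param x An `lw_pca` from [phyl_pca()] or [ordinary_pca()].
#' @param ... Unused.
#' @return Long tibble of loadings (one row per trait x component).
#' @method tidy lw_pca
#' @export
tidy.lw_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "trait") |>
    tidyr::pivot_longer(-"trait", names_to = "component",
                        values_to = "loading")
}

#' @rdname tidy.lw_pca
#' @method glance lw_pca
#' @export
glance.lw_pca <- function(x, ...) {
  tibble::tibble(
    component = colnames(x$loadings),
    eigenvalue = x$eigenvalues,
    explained = x$explained
  )
}

#' Tidy a two-factor mixed-model fit
#'
#' @param x A `trait_mixed` from [fit_two_factor_mixed()].
#' @param ... Unused.
#' @return The per-term F-test table.
#' @method tidy trait_mixed
#' @export
tidy.trait_mixed <- function(x, ...) x$table

#' @rdname tidy.trait_mixed
#' @method glance trait_mixed
#' @export
glance.trait_mixed <- function(x, ...) {
  tibble::tibble(
    trait = x$trait, n_species = x$n_species,
    species_var = unname(x$varcomp["species"]),
    residual_var = unname(x$varcomp["residual"]),
    aic = x$aic, ddf = x$ddf
  )
}
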