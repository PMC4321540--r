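#' Maximum-likelihood Pagel's lambda for one trait
#'
#' Measures phylogenetic signal by fitting the multivariate-normal model
#' `y ~ N(mu * 1, sigma2 * C(lambda))`, where `C(lambda)` is the tree's
#' Brownian covariance with off-diagonals scaled by lambda. The mean and rate
#' are profiled out by their GLS closed forms; lambda is maximised over
#' `[0, 1]` by a grid-bracketed golden-section search (tolerance 1e-6).
#' `lambda = 1` implies trait covariance proportional to shared ancestry
#' (full Brownian signal); `lambda = 0` implies no phylogenetic dependence.
#'
#' Likelihood-ratio tests against the boundary hypotheses `lambda = 0` and
#' `lambda = 1` use the 50:50 chi-square(0)/chi-square(1) boundary mixture,
#' so a deviance of exactly zero gives p = 1.
#'
#' @param trait Named numeric vector of species trait values; names must
#'   match the tree's tip labels.
#' @param tree An [ape::phylo] tree.
#' @return A `phylo_signal` object: list with `lambda`, `sigma2`, `mu`,
#'   `logLik`, `logLik0`, `logLik1`, `p_lambda0`, `p_lambda1`, `n`.
#'   [generics::tidy()] turns it into a one-row tibble.
#' @examples
#' tr <- gen_tree(20, seed = 1)
#' y <- gen_bm_traits(tr, sigma2 = 1, lambda_true = 1, seed = 2)
#' fit_lambda(y, tr)$lambda
#' @export
fit_lambda <- function(trait, tree) {
  if (is.null(names(trait))) abort("`trait` must be named by species.")
  if (!all(tree$tip.label %in% names(trait))) {
    abort("trait names do not cover the tree's tip labels.")
  }
  y <- trait[tree$tip.label]
  n <- length(y)
  if (n < 4) abort("need at least 4 species.")
  if (var(y) == 0) abort("trait has zero variance.")
  C <- vcv_from_tree(tree)

  ll <- function(lambda) lambda_profile_loglik(lambda, y, C)$logLik

  # coarse scan brackets the optimum; golden-section refines it
  grid <- seq(0, 1, by = 0.1)
  gl <- vapply(grid, ll, numeric(1))
  k <- which.max(gl)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(length(grid), k + 1)]
  opt <- optimize(ll, lower = lo, upper = hi, maximum = TRUE, tol = 1e-6)

  cand <- c(0, opt$maximum, 1)
  cand_ll <- c(gl[1], opt$objective, gl[length(gl)])
  # prefer the smaller lambda when the likelihood surface is flat (star tree)
  best <- which(cand_ll >= max(cand_ll) - 1e-8)[1]
  lambda_hat <- cand[best]
  fit <- lambda_profile_loglik(lambda_hat, y, C)

  d0 <- 2 * (fit$logLik - gl[1])
  d1 <- 2 * (fit$logLik - gl[length(gl)])
  structure(
    list(
      lambda = lambda_hat, sigma2 = fit$sigma2, mu = fit$mu,
      logLik = fit$logLik, logLik0 = gl[1], logLik1 = gl[length(gl)],
      p_lambda0 = boundary_lrt_p(d0), p_lambda1 = boundary_lrt_p(d1),
      n = n
    ),
    class = "phylo_signal"
  )
}

# Profile log-likelihood at a fixed lambda: GLS closed forms for mu and the
# ML rate sigma2. Adds a 1e-10 ridge if the covariance is numerically singular.
lambda_profile_loglik <- function(lambda, y, C) {
  Cl <- lambda_transform(C, lambda)
  ch <- tryCatch(chol(Cl), error = function(e) {
    inform("singular C(lambda); adding 1e-10 ridge.")
    chol(Cl + diag(1e-10, nrow(Cl)))
  })
  n <- length(y)
  logdet <- 2 * sum(log(diag(ch)))
  z_y <- backsolve(ch, y, transpose = TRUE)
  z_1 <- backsolve(ch, rep(1, n), transpose = TRUE)
  mu <- sum(z_1 * z_y) / sum(z_1 * z_1)
  q <- sum((z_y - mu * z_1)^2)
  sigma2 <- q / n
  logLik <- -n / 2 * log(2 * pi * sigma2) - logdet / 2 - n / 2
  list(logLik = logLik, mu = mu, sigma2 = sigma2)
}

# One-sided LRT p-value at a parameter boundary: 0.5 chi2_0 + 0.5 chi2_1.
boundary_lrt_p <- function(dev) {
  if (dev <= 1e-12) return(1)
  0.5 * pchisq(dev, df = 1, lower.tail = FALSE)
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat(sprintf(
    "Pagel's lambda: %.3f (sigma2 = %.4g, n = %d)\n  logLik %.3f | p(lambda=0) = %.3g | p(lambda=1) = %.3g\n",
    x$lambda, x$sigma2, x$n, x$logLik, x$p_lambda0, x$p_lambda1
  ))
  invisible(x)
}

#' Phylogenetic signal screen across a trait table
#'
#' Runs [fit_lambda()] on every requested trait column of a species-level
#' table, returning one row per trait in the layout of a published
#' signal-screening table (lambda with p-values against both boundaries).
#'
#' @param data Data frame with a `species` column and numeric trait columns.
#' @param tree An [ape::phylo] tree whose tips match `data$species`.
#' @param traits Character vector of trait column names; defaults to all
#'   numeric columns.
#' @return A tibble with columns `trait`, `n`, `lambda`, `p_lambda0`,
#'   `p_lambda1`, `logLik`.
#' @export
phylo_signal_table <- function(data, tree, traits = NULL) {
  if (!"species" %in% names(data)) abort("`data` needs a `species` column.")
  if (is.null(traits)) {
    traits <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  purrr::map_dfr(traits, function(tr) {
    y <- setNames(data[[tr]], data$species)
    y <- y[!is.na(y)]
    fit <- fit_lambda(y, ape::keep.tip(tree, names(y)))
    tibble::tibble(
      trait = tr, n = fit$n, lambda = fit$lambda,
      p_lambda0 = fit$p_lambda0, p_lambda1 = fit$p_lambda1,
      logLik = fit$logLik
    )
  })
}
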