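#' Phylogenetic principal component analysis (GLS)
#'
#' Ordinates a species-by-trait matrix while accounting for the non-independence
#' of related species. The trait covariance is estimated by generalised least
#' squares against the tree's Brownian covariance `C`:
#' `a = (1' C^-1 1)^-1 1' C^-1 X` (phylogenetic mean) and
#' `S = (X - 1a)' C^-1 (X - 1a) / (n - 1)`, followed by an eigendecomposition
#' of `S`. Scores are the mean-centred data projected on the eigenvectors.
#' With `mode = "lambda"`, a single multivariate Pagel's lambda is first
#' estimated by maximum likelihood and used to transform `C`.
#'
#' Eigenvector signs are fixed by making each component's largest-magnitude
#' loading positive, so score plots are reproducible across platforms.
#'
#' @param data Data frame with a `species` column and numeric trait columns
#'   (log-transform skewed traits first, see [log_transform_traits()]).
#' @param tree An [ape::phylo] tree covering the species.
#' @param mode `"BM"` (use `C` as is) or `"lambda"` (lambda-transform `C`).
#' @return An object of class `lw_pca` with elements `loadings`, `scores`,
#'   `eigenvalues`, `explained` (fractions), `mode`, `lambda`, `mean`.
#' @examples
#' tr <- gen_tree(10, seed = 1)
#' X <- tibble::tibble(
#'   species = tr$tip.label,
#'   a = gen_bm_traits(tr, seed = 2), b = gen_bm_traits(tr, seed = 3)
#' )
#' phyl_pca(X, tr)
#' @export
phyl_pca <- function(data, tree, mode = c("BM", "lambda")) {
  mode <- match.arg(mode)
  X <- trait_matrix(data)
  keep <- complete.cases(X)
  if (!all(keep)) {
    warn(sprintf("dropping %d species with missing traits.", sum(!keep)))
    X <- X[keep, , drop = FALSE]
  }
  if (!all(rownames(X) %in% tree$tip.label)) {
    abort("species in `data` missing from the tree.")
  }
  tree <- ape::keep.tip(tree, rownames(X))
  C <- vcv_from_tree(tree)[rownames(X), rownames(X)]
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) warn("fewer species than traits; covariance is rank-deficient.")

  lambda <- NA_real_
  if (mode == "lambda") {
    ll <- function(l) mv_lambda_loglik(l, X, C)
    grid <- seq(0, 1, by = 0.1)
    gl <- vapply(grid, ll, numeric(1))
    k <- which.max(gl)
    opt <- optimize(ll,
      lower = grid[max(1, k - 1)], upper = grid[min(length(grid), k + 1)],
      maximum = TRUE, tol = 1e-6
    )
    cand <- c(0, opt$maximum, 1)
    cand_ll <- c(gl[1], opt$objective, gl[length(gl)])
    lambda <- cand[which(cand_ll >= max(cand_ll) - 1e-8)[1]]
    C <- lambda_transform(C, lambda)
  }

  Ci <- solve(C)
  one <- rep(1, n)
  a <- drop(crossprod(one, Ci %*% X)) / drop(crossprod(one, Ci %*% one))
  Xc <- sweep(X, 2, a)
  S <- crossprod(Xc, Ci %*% Xc) / (n - 1)
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  V <- fix_eigen_signs(eig$vectors)
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(p)))
  scores <- Xc %*% V
  new_lw_pca(
    loadings = V, scores = scores, eigenvalues = eig$values,
    explained = eig$values / sum(eig$values),
    mode = paste0("phylogenetic (", mode, ")"), lambda = lambda, mean = a
  )
}

# Multivariate profile log-likelihood of lambda: mean and cross-trait
# covariance profiled out (ML divisor n).
mv_lambda_loglik <- function(lambda, X, C) {
  Cl <- lambda_transform(C, lambda)
  ch <- chol(Cl)
  n <- nrow(X)
  p <- ncol(X)
  logdetC <- 2 * sum(log(diag(ch)))
  Z <- backsolve(ch, X, transpose = TRUE)
  z1 <- backsolve(ch, rep(1, n), transpose = TRUE)
  a <- drop(crossprod(z1, Z)) / sum(z1^2)
  Zc <- Z - tcrossprod(z1, a)
  R <- crossprod(Zc) / n
  ldR <- determinant(R, logarithm = TRUE)$modulus
  -n * p / 2 * log(2 * pi) - n / 2 * ldR - p / 2 * logdetC - n * p / 2
}

#' Conventional principal component analysis of a trait table
#'
#' Covariance-matrix PCA on (typically log-transformed) species trait values,
#' the non-phylogenetic counterpart of [phyl_pca()]. Constant columns are
#' dropped with a warning. The same eigenvector sign convention as
#' [phyl_pca()] is applied.
#'
#' @param data Data frame with a `species` column and numeric trait columns.
#' @return An `lw_pca` object (see [phyl_pca()]).
#' @export
ordinary_pca <- function(data) {
  X <- trait_matrix(data)
  keep <- complete.cases(X)
  if (!all(keep)) {
    warn(sprintf("dropping %d species with missing traits.", sum(!keep)))
    X <- X[keep, , drop = FALSE]
  }
  const <- apply(X, 2, function(v) var(v) == 0)
  if (any(const)) {
    warn(paste("dropping constant columns:", paste(colnames(X)[const], collapse = ", ")))
    X <- X[, !const, drop = FALSE]
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  V <- fix_eigen_signs(pc$rotation)
  scores <- sweep(X, 2, pc$center) %*% V
  new_lw_pca(
    loadings = V, scores = scores, eigenvalues = pc$sdev^2,
    explained = pc$sdev^2 / sum(pc$sdev^2),
    mode = "conventional", lambda = NA_real_, mean = pc$center
  )
}

#' Log-transform trait columns, using absolute values for negative traits
#'
#' Prepares a trait table for ordination: each numeric column is
#' log-transformed; columns containing negative values (such as the turgor
#' loss point, which is a negative water potential) are transformed on their
#' absolute values so the ordination operates on magnitudes.
#'
#' @param data Data frame with a `species` column and numeric trait columns.
#' @param traits Columns to transform; defaults to all numeric columns.
#' @return `data` with the selected columns replaced by their logs.
#' @export
log_transform_traits <- function(data, traits = NULL) {
  if (is.null(traits)) {
    traits <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  for (tr in traits) {
    v <- data[[tr]]
    if (any(v < 0, na.rm = TRUE)) v <- abs(v)
    if (any(v <= 0, na.rm = TRUE)) {
      abort(sprintf("trait '%s' has zero magnitudes; cannot log-transform.", tr))
    }
    data[[tr]] <- log(v)
  }
  data
}

trait_matrix <- function(data) {
  if (!"species" %in% names(data)) abort("`data` needs a `species` column.")
  num <- vapply(data, is.numeric, logical(1))
  X <- as.matrix(data[num])
  rownames(X) <- data$species
  X
}

fix_eigen_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  V
}

new_lw_pca <- function(...) structure(list(...), class = "lw_pca")

#' @export
print.lw_pca <- function(x, ...) {
  k <- min(4, length(x$explained))
  cat(sprintf(
    "%s PCA: %d components; variance explained: %s\n",
    x$mode, length(x$eigenvalues),
    paste(sprintf("PC%d %.0f%%", seq_len(k), 100 * x$explained[seq_len(k)]),
      collapse = ", "
    )
  ))
  invisible(x)
}
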