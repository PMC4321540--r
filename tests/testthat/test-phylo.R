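test_that("phylogenetic covariance matches definitions on simple trees", {
  st <- star_tree(5)
  expect_equal(vcv_from_tree(st), diag(5) * 1,
               ignore_attr = TRUE, tolerance = 1e-12)
  # two tips splitting at depth 0.4 of a unit-depth tree
  two <- ape::read.tree(text = "((a:0.6,b:0.6):0.4,c:1);")
  C <- vcv_from_tree(two)
  expect_equal(C["a", "b"], 0.4)
  expect_equal(C["a", "a"], 1)
  expect_equal(C["a", "c"], 0)
})

test_that("phylogenetic covariance agrees with brute-force path enumeration and ape", {
  for (seed in 1:10) {
    tr <- gen_tree(10, seed = seed)
    C <- vcv_from_tree(tr)
    expect_equal(C, vcv_brute_force(tr), tolerance = 1e-14)
    expect_equal(C, ape::vcv(tr), tolerance = 1e-12)
  }
  bad <- gen_tree(5, seed = 1)
  bad$edge.length[1] <- -0.1
  expect_error(vcv_from_tree(bad), "negative")
})

test_that("lambda transform scales only the off-diagonal", {
  C <- vcv_from_tree(gen_tree(6, seed = 2))
  Cl <- lambda_transform(C, 0.5)
  expect_equal(diag(Cl), diag(C))
  expect_equal(Cl[1, 2], 0.5 * C[1, 2])
  expect_equal(lambda_transform(C, 1), C)
  expect_error(lambda_transform(C, 1.2), "lambda")
})

test_that("lambda is unidentifiable on a star tree and reported at zero", {
  st <- star_tree(20)
  y <- withr::with_seed(1, setNames(rnorm(20), st$tip.label))
  fit <- fit_lambda(y, st)
  expect_equal(fit$lambda, 0)
  expect_equal(fit$p_lambda0, 1)
  expect_equal(fit$logLik, fit$logLik1, tolerance = 1e-8)
})

test_that("lambda ML agrees with phytools and beats a grid oracle", {
  skip_if_not_installed("phytools")
  tr <- gen_tree(50, seed = 7)
  y <- gen_bm_traits(tr, sigma2 = 1, lambda_true = 0.7, seed = 3)
  fit <- fit_lambda(y, tr)
  ps <- phytools::phylosig(tr, y, method = "lambda")
  expect_equal(fit$lambda, ps$lambda, tolerance = 1e-3)
  expect_equal(fit$logLik, ps$logL, tolerance = 1e-4)
  # optimiser result dominates a dense lambda grid
  for (seed in 1:10) {
    y <- gen_bm_traits(tr, sigma2 = 1, lambda_true = runif(1), seed = seed)
    fit <- fit_lambda(y, tr)
    expect_gte(fit$logLik, max(lambda_grid_loglik(y, tr)) - 1e-6)
  }
})

test_that("lambda estimates track simulated signal strength", {
  tr <- gen_tree(100, seed = 5)
  lam1 <- vapply(1:15, function(s) {
    fit_lambda(gen_bm_traits(tr, 1, lambda_true = 1, seed = s), tr)$lambda
  }, numeric(1))
  lam0 <- vapply(1:15, function(s) {
    fit_lambda(gen_bm_traits(tr, 1, lambda_true = 0, seed = s), tr)$lambda
  }, numeric(1))
  expect_gt(mean(lam1), 0.85)
  expect_lt(mean(lam0), 0.15)
  # permuting tip values destroys the signal
  y <- gen_bm_traits(tr, 1, lambda_true = 1, seed = 99)
  hits <- vapply(1:20, function(s) {
    perm <- withr::with_seed(s, setNames(sample(y), names(y)))
    fit_lambda(perm, tr)$lambda < 0.1
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("phylogenetic PCA reduces to ordinary PCA on a star tree", {
  st <- star_tree(12)
  X <- withr::with_seed(4, tibble::tibble(
    species = st$tip.label,
    t1 = rnorm(12), t2 = rnorm(12), t3 = rnorm(12), t4 = rnorm(12)
  ))
  pp <- phyl_pca(X, st)
  op <- ordinary_pca(X)
  expect_equal(pp$loadings, op$loadings, tolerance = 1e-8)
  expect_equal(pp$eigenvalues, op$eigenvalues, tolerance = 1e-8)
  expect_equal(pp$scores, op$scores, tolerance = 1e-8)
})

test_that("phylogenetic PCA matches a dense GLS oracle and phytools", {
  tr <- gen_tree(10, seed = 9)
  X <- tibble::tibble(
    species = tr$tip.label,
    a = gen_bm_traits(tr, 1, seed = 1), b = gen_bm_traits(tr, 1, seed = 2),
    c = gen_bm_traits(tr, 1, seed = 3), d = gen_bm_traits(tr, 1, seed = 4)
  )
  pp <- phyl_pca(X, tr)
  # explicit-inverse GLS covariance oracle
  M <- as.matrix(X[-1])
  rownames(M) <- X$species
  C <- ape::vcv(tr)[X$species, X$species]
  Ci <- solve(C)
  one <- rep(1, 10)
  a <- drop(solve(t(one) %*% Ci %*% one) %*% t(one) %*% Ci %*% M)
  S <- t(M - one %*% t(a)) %*% Ci %*% (M - one %*% t(a)) / 9
  expect_equal(sort(pp$eigenvalues), sort(eigen(S)$values), tolerance = 1e-10)
  # eigenvalue sum conserves the trace of S
  expect_equal(sum(pp$eigenvalues), sum(diag(S)), tolerance = 1e-10)

  skip_if_not_installed("phytools")
  ref <- phytools::phyl.pca(tr, M, method = "BM", mode = "cov")
  expect_equal(abs(unclass(pp$loadings)), abs(unclass(ref$Evec)),
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(unname(pp$eigenvalues), unname(diag(ref$Eval)),
               tolerance = 1e-6)
})

test_that("rank deficiency and degenerate inputs are handled", {
  tr <- gen_tree(8, seed = 3)
  X <- tibble::tibble(
    species = tr$tip.label,
    a = gen_bm_traits(tr, 1, seed = 1), b = gen_bm_traits(tr, 1, seed = 2)
  )
  X$dup <- X$a
  pp <- phyl_pca(X, tr)
  expect_equal(min(abs(pp$eigenvalues)), 0, tolerance = 1e-10)
  # ordinary PCA drops a constant column with a warning
  X2 <- X
  X2$dup <- 1
  expect_warning(op <- ordinary_pca(X2), "constant")
  expect_equal(nrow(op$loadings), 2)
})

test_that("ordinary PCA explains correlated data on one axis and centres internally", {
  d <- withr::with_seed(2, {
    x <- rnorm(40)
    tibble::tibble(species = sprintf("s%02d", 1:40), a = x, b = 2 * x)
  })
  op <- ordinary_pca(d)
  expect_equal(op$explained[1], 1, tolerance = 1e-12)
  shifted <- d
  shifted$a <- shifted$a + 100
  expect_equal(ordinary_pca(shifted)$loadings, op$loadings, tolerance = 1e-9)
})

test_that("log transform uses magnitudes for negative-valued traits", {
  d <- tibble::tibble(species = c("a", "b"), tlp = c(-1.2, -1.5), sla = c(30, 40))
  out <- log_transform_traits(d)
  expect_equal(out$tlp, log(c(1.2, 1.5)))
  expect_equal(out$sla, log(c(30, 40)))
  expect_error(
    log_transform_traits(tibble::tibble(species = "a", x = 0)), "zero"
  )
})
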