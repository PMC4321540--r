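# Independent oracles used to cross-check the package's implementations.
# Each deliberately takes a different computational route from the code it
# verifies.

# Star phylogeny with unit-length pendant edges.
star_tree <- function(n) {
  tree <- ape::stree(n, type = "star")
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree$tip.label <- sprintf("s%02d", seq_len(n))
  tree
}

# Brute-force phylogenetic covariance: enumerate each tip's root-to-tip edge
# list and sum the branch lengths shared by every pair, accumulating from the
# root outwards.
vcv_brute_force <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent <- integer(max(tree$edge))
  edge_len <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_len[tree$edge[, 2]] <- tree$edge.length
  # edges from root to each tip, in root-first order
  edges_to <- lapply(seq_len(n), function(tip) {
    path <- integer(0)
    while (tip != root) {
      path <- c(tip, path)
      tip <- parent[tip]
    }
    path
  })
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in i:n) {
      a <- edges_to[[i]]
      b <- edges_to[[j]]
      k <- min(length(a), length(b))
      same <- a[seq_len(k)] == b[seq_len(k)]
      shared <- a[seq_len(k)][cumprod(same) == 1]
      s <- 0
      for (e in shared) s <- s + edge_len[e]
      C[i, j] <- C[j, i] <- s
    }
  }
  C
}

# Grid-search oracle for the modified-exponential turgor curve: sweep the
# zero crossing at 1e-3 resolution, solving (a, b) at each candidate by
# general-purpose optimisation on the log scale. Mirrors the package's
# fitted objective: turgid points follow the exponential, zero-phase points
# its non-negative floor.
turgor_grid_search <- function(rwc, psi_p, rwc_z = numeric(0),
                               psi_z = numeric(0),
                               r0_grid = seq(0.5, 0.999, by = 1e-3)) {
  sse_at <- function(r0) {
    obj <- function(th) {
      a <- exp(th[1])
      b <- exp(th[2])
      sum((psi_p - a * (exp(b * (rwc - r0)) - 1))^2) +
        sum((psi_z - pmax(0, a * (exp(b * (rwc_z - r0)) - 1)))^2)
    }
    op <- optim(c(log(max(psi_p) / 2), log(2)), obj, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-12))
    op$value
  }
  sse <- vapply(r0_grid, sse_at, numeric(1))
  r0_grid[which.min(sse)]
}

# 21-point grid oracle for Pagel's lambda (profile likelihood reused from the
# package's likelihood kernel would not be independent; recompute densely).
lambda_grid_loglik <- function(y, tree, grid = seq(0, 1, length.out = 21)) {
  C <- ape::vcv(tree)[names(y), names(y)]
  vapply(grid, function(l) {
    Cl <- l * C
    diag(Cl) <- diag(C)
    n <- length(y)
    Ci <- solve(Cl)
    one <- rep(1, n)
    mu <- drop(one %*% Ci %*% y) / drop(one %*% Ci %*% one)
    q <- drop(t(y - mu) %*% Ci %*% (y - mu))
    s2 <- q / n
    -n / 2 * log(2 * pi * s2) - determinant(Cl)$modulus / 2 - n / 2
  }, numeric(1))
}

# Hand-computed sums of squares for a balanced two-way ANOVA.
balanced_twoway_anova <- function(y, A, B) {
  A <- factor(A)
  B <- factor(B)
  n <- length(y)
  cell <- interaction(A, B)
  gm <- mean(y)
  ssa <- sum(tapply(y, A, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(y, B, function(v) length(v) * (mean(v) - gm)^2))
  sscell <- sum(tapply(y, cell, function(v) length(v) * (mean(v) - gm)^2))
  ssab <- sscell - ssa - ssb
  sse <- sum((y - ave(y, cell))^2)
  dfa <- nlevels(A) - 1
  dfb <- nlevels(B) - 1
  dfab <- dfa * dfb
  dfe <- n - nlevels(A) * nlevels(B)
  mse <- sse / dfe
  data.frame(
    term = c("A", "B", "A:B"),
    f = c(ssa / dfa, ssb / dfb, ssab / dfab) / mse,
    df = c(dfa, dfb, dfab), df_err = dfe
  )
}

# Unit-tracking recomputation of K_leaf: grams -> mol -> mmol, step by step.
kleaf_unit_oracle <- function(delta_w_g, duration_s, area_m2, delta_psi_mpa) {
  mol_water <- delta_w_g / 18.015
  mmol_water <- mol_water * 1000
  flux_mmol_s <- mmol_water / duration_s
  flux_mmol_s_m2 <- flux_mmol_s / area_m2
  flux_mmol_s_m2 / delta_psi_mpa
}

# Unit-tracking recomputation of cuticular conductance from an hour-2 slope.
gmin_unit_oracle <- function(slope_g_hr, area_cm2, temp_c, rh, pressure_kpa) {
  g_per_s <- -slope_g_hr / 3600
  mol_per_s <- g_per_s / 18.015
  mol_m2_s <- mol_per_s / (area_cm2 / 1e4)
  esat <- 0.61078 * exp(17.27 * temp_c / (temp_c + 237.3))
  dw <- esat * (1 - rh) / pressure_kpa
  1000 * mol_m2_s / dw
}
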