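#' Simulate a Yule species tree
#'
#' Draws a pure-birth (Yule) phylogeny with the requested number of tips and
#' rescales it to unit root-to-tip depth. The result is rooted, binary and
#' ultrametric, with tip labels `s01, s02, ...` matching the species labels
#' used by the panel generator.
#'
#' @param n_tips Number of species (>= 3).
#' @param seed Integer seed; the same seed yields an identical tree.
#' @return An [ape::phylo] object of unit depth.
#' @examples
#' tr <- gen_tree(5, seed = 1)
#' max(ape::node.depth.edgelength(tr)) # 1
#' @export
gen_tree <- function(n_tips, seed = 1L) {
  if (n_tips < 3) abort("`n_tips` must be at least 3.")
  tree <- withr::with_seed(as.integer(seed), {
    ape::rphylo(n = n_tips, birth = 1, death = 0)
  })
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("s%02d", seq_len(n_tips))
  tree
}

#' Simulate species trait values under Brownian motion with Pagel's lambda
#'
#' Draws one trait vector from the multivariate normal
#' `N(mu * 1, sigma2 * V(lambda))`, where `V` is the phylogenetic
#' variance-covariance matrix of the tree and the lambda transform multiplies
#' its off-diagonal (shared-history) entries by `lambda_true`. `lambda_true = 1`
#' is plain Brownian motion; `lambda_true = 0` removes all phylogenetic
#' covariance and tips are independent.
#'
#' @param tree An [ape::phylo] tree (ideally ultrametric).
#' @param sigma2 Brownian rate (trait^2 per unit depth, > 0).
#' @param lambda_true Signal strength in `[0, 1]`.
#' @param mu Trait grand mean.
#' @param seed Integer seed.
#' @return A named numeric vector, one value per tip.
#' @examples
#' tr <- gen_tree(5, seed = 1)
#' gen_bm_traits(tr, sigma2 = 1, lambda_true = 1, seed = 2)
#' @export
gen_bm_traits <- function(tree, sigma2 = 1, lambda_true = 1, mu = 0,
                          seed = 1L) {
  if (sigma2 <= 0) abort("`sigma2` must be positive.")
  if (lambda_true < 0 || lambda_true > 1) {
    abort("`lambda_true` must lie in [0, 1].")
  }
  C <- lambda_transform(vcv_from_tree(tree), lambda_true)
  x <- withr::with_seed(as.integer(seed), {
    MASS::mvrnorm(1, mu = rep(mu, nrow(C)), Sigma = sigma2 * C)
  })
  setNames(as.numeric(x), rownames(C))
}
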