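#' Phylogenetic variance-covariance matrix of a tree
#'
#' Builds the Brownian-motion covariance matrix among species implied by a
#' rooted tree with branch lengths: entry (i, j) is the root-to-MRCA path
#' length shared by tips i and j, and the diagonal holds the root-to-tip
#' depths. Under Brownian motion this matrix, times the rate, is the expected
#' covariance of trait values across species.
#'
#' @param tree An [ape::phylo] object; branch lengths must be non-negative.
#' @return A symmetric numeric matrix with tip labels as dimnames.
#' @examples
#' tr <- gen_tree(4, seed = 1)
#' vcv_from_tree(tr)
#' @export
vcv_from_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape 'phylo' object.")
  if (is.null(tree$edge.length)) abort("`tree` has no branch lengths.")
  if (any(tree$edge.length < 0)) abort("negative branch length in tree.")
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  root <- n + 1L
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]

  # root-to-tip node paths, used to locate each pair's MRCA
  paths <- lapply(seq_len(n), function(tip) {
    p <- tip
    while (tip != root) {
      tip <- parent[tip]
      p <- c(tip, p)
    }
    p
  })

  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    C[i, i] <- depth[i]
    for (j in seq_len(n)[-seq_len(i)]) {
      pi <- paths[[i]]
      pj <- paths[[j]]
      k <- min(length(pi), length(pj))
      shared <- which(pi[seq_len(k)] != pj[seq_len(k)])
      mrca <- if (length(shared)) pi[shared[1] - 1L] else pi[k]
      C[i, j] <- C[j, i] <- depth[mrca]
    }
  }
  C
}

#' Apply Pagel's lambda transform to a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries by `lambda` while leaving the diagonal
#' untouched. `lambda = 1` returns the matrix unchanged; `lambda = 0` removes
#' all shared-history covariance (a star phylogeny).
#'
#' @param C A phylogenetic covariance matrix from [vcv_from_tree()].
#' @param lambda Signal multiplier in `[0, 1]`.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (lambda < 0 || lambda > 1) abort("`lambda` must lie in [0, 1].")
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Cl
}
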