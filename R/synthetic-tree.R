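#' Simulate a tree and traits with controlled phylogenetic signal
#'
#' Grows a pure-birth tree and draws traits from the multivariate normal
#' model implied by Brownian motion on the lambda-transformed tree: the trait
#' covariance is `sigma2 * (lambda * C_offdiag + diag(C))`, optionally plus
#' per-species observation error. `lambda_true = 1` is plain Brownian motion,
#' `lambda_true = 0` makes tip values independent.
#'
#' @param n_tips number of tips (>= 4).
#' @param lambda_true signal strength in `[0, 1]`.
#' @param sigma2 Brownian rate.
#' @param n_traits number of independent traits to draw.
#' @param se per-species observation standard error (scalar or vector).
#' @param seed RNG seed.
#' @return list: `tree` (ape phylo), `newick` (string), `traits` (data.frame
#'   with `species` first), `se`.
#' @export
simulate_tree_and_traits <- function(n_tips, lambda_true = 1, sigma2 = 1,
                                     n_traits = 1, se = 0, seed = 1L) {
  stopifnot(n_tips >= 4, lambda_true >= 0, lambda_true <= 1, sigma2 > 0)
  with_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = 1, death = 0)
    C <- ape::vcv(tree)
    Cl <- lambda_vcv(C, lambda_true)
    L <- chol(sigma2 * Cl)
    X <- t(L) %*% matrix(rnorm(n_tips * n_traits), n_tips, n_traits)
    se <- rep(se, length.out = n_tips)
    if (any(se > 0))
      X <- X + matrix(rnorm(n_tips * n_traits, 0, rep(se, n_traits)),
                      n_tips, n_traits)
    colnames(X) <- paste0("trait", seq_len(n_traits))
    traits <- data.frame(species = rownames(C), X, stringsAsFactors = FALSE)
    list(tree = tree, newick = ape::write.tree(tree), traits = traits, se = se)
  })
}

# Pagel lambda transform of a phylogenetic covariance matrix
lambda_vcv <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}
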