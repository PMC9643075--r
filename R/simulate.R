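#' Derive a reproducible stage seed from a master seed
#'
#' Replicates and pipeline stages draw their seeds from one master seed via
#' a fixed linear-congruential map, `(master * 48271 + index * 104729) mod
#' (2^31 - 1)`, so independent streams are reproducible without sharing
#' state.
#'
#' @param master Integer master seed.
#' @param index Stage or replicate index (vectorised).
#' @return Integer seed(s) in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647
  s <- ((as.numeric(master) %% m) * 48271 + as.numeric(index) * 104729) %% m
  as.integer(ifelse(s == 0, 1, s))
}

#' Simulate an ultrametric pure-birth phylogeny
#'
#' Constant-rate Yule process conditioned on the number of tips, rescaled to
#' unit root-to-tip depth (only relative shared branch lengths enter the
#' phylogenetic covariance, so the absolute depth is a nuisance scale).
#'
#' @param n_tips Number of tips (>= 3).
#' @param birth_rate Per-lineage speciation rate (default 1).
#' @param seed Integer seed; fixed seed gives an identical tree.
#' @return A rooted, ultrametric, fully bifurcating `phylo` object with tips
#'   `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (!is.numeric(n_tips) || n_tips < 3) stop("`n_tips` must be >= 3")
  if (birth_rate <= 0) stop("`birth_rate` must be positive")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n = as.integer(n_tips), birth = birth_rate, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree
}

#' Simulate a trait under lambda-transformed Brownian motion
#'
#' One draw from `MVN(mu * 1, sigma2 * C_lambda)` where `C_lambda` is the
#' lambda-transformed Brownian covariance of the tree — the generative model
#' assumed by the Pagel's-lambda estimator.
#'
#' @param tree Rooted `phylo` object.
#' @param lambda_true Signal strength in `[0, 1]`.
#' @param sigma2 Brownian rate (>= 0); 0 gives the constant vector `mu`.
#' @param mu Trait grand mean (default 0).
#' @param seed Integer seed.
#' @return Named numeric vector keyed by tip label.
#' @export
simulate_lambda_trait <- function(tree, lambda_true, sigma2 = 1, mu = 0,
                                  seed = NULL) {
  if (sigma2 < 0) stop("`sigma2` must be >= 0")
  C <- phylo_covariance(tree)
  if (lambda_true < 1 && max(abs(diag(C) - max(diag(C)))) > 1e-8 * max(diag(C)))
    warning("tree is not ultrametric; lambda transform is still defined")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(C)
  if (sigma2 == 0) return(setNames(rep(mu, n), rownames(C)))
  Cl <- lambda_transform(C, lambda_true)
  L <- chol(Cl + diag(1e-12 * max(diag(Cl)), n))
  y <- mu + sqrt(sigma2) * as.vector(crossprod(L, rnorm(n)))
  setNames(y, rownames(C))
}

#' Simulate a trait under the phylogenetic mixed model
#'
#' Draws `y = mu + a + e` with heritable values `a ~ MVN(0, sigma2_a * G)`
#' (G the depth-normalised phylogenetic correlation matrix) and independent
#' residuals `e ~ N(0, sigma2_e)`; returns the true additive values so
#' decomposition accuracy can be scored.
#'
#' @param tree Rooted `phylo` object.
#' @param sigma2_a Phylogenetic variance (>= 0).
#' @param sigma2_e Residual variance (>= 0).
#' @param mu Grand mean (default 0).
#' @param seed Integer seed.
#' @return List with `y` (named trait vector), `a` (true additive values),
#'   and `flag` (`"degenerate"` when both variances are zero).
#' @export
simulate_lynch_trait <- function(tree, sigma2_a, sigma2_e, mu = 0,
                                 seed = NULL) {
  if (sigma2_a < 0 || sigma2_e < 0) stop("variances must be >= 0")
  C <- phylo_covariance(tree)
  G <- C / max(diag(C))
  n <- nrow(G)
  if (!is.null(seed)) set.seed(seed)
  flag <- "ok"
  if (sigma2_a == 0) {
    a <- rep(0, n)
  } else {
    L <- chol(G + diag(1e-12, n))
    a <- sqrt(sigma2_a) * as.vector(crossprod(L, rnorm(n)))
  }
  e <- if (sigma2_e == 0) rep(0, n) else rnorm(n, sd = sqrt(sigma2_e))
  if (sigma2_a == 0 && sigma2_e == 0) flag <- "degenerate"
  list(y = setNames(mu + a + e, rownames(G)),
       a = setNames(a, rownames(G)), flag = flag)
}

#' Simulate ordinal responses from a proportional-odds model
#'
#' Each response is drawn with `P(Y <= k | x) = logistic(zeta_k - x'beta)`
#' by comparing one uniform deviate per observation against the cumulative
#' category probabilities, so all K categories are representable.
#'
#' @param X Predictor matrix (n x p) or data frame.
#' @param beta Coefficient vector, length p.
#' @param zeta Strictly increasing threshold vector, length K - 1.
#' @param seed Integer seed.
#' @return Integer vector in `0..K-1`, length n.
#' @export
simulate_ordinal_response <- function(X, beta, zeta, seed = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.unsorted(zeta, strictly = TRUE))
    stop("`zeta` must be strictly increasing")
  if (ncol(X) != length(beta)) stop("length(beta) must equal ncol(X)")
  if (!is.null(seed)) set.seed(seed)
  eta <- as.vector(X %*% beta)
  u <- runif(length(eta))
  cum <- plogis(outer(eta, zeta, function(e, z) z - e))  # n x (K-1)
  as.integer(rowSums(u > cum))
}
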