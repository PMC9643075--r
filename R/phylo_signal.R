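#' Brownian-motion covariance matrix of a phylogeny
#'
#' Under Brownian motion on a rooted tree, the covariance of the trait values
#' of two tips is proportional to the shared path length from the root to
#' their most recent common ancestor; the variance of a tip is its
#' root-to-tip distance.
#'
#' @param tree A rooted `phylo` object with branch lengths and unique tip
#'   labels.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames; `C[i, j]` is the root-to-MRCA path length of tips i and j.
#' @export
phylo_covariance <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a `phylo` object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  # a star phylogeny (single basal polytomy) counts as rooted at its center
  if (!ape::is.rooted(tree) && tree$Nnode != 1L) stop("tree must be rooted")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transformation of a phylogenetic covariance matrix
#'
#' Multiplies all off-diagonal covariances by `lambda`, leaving variances
#' untouched. `lambda = 1` returns the Brownian covariance unchanged;
#' `lambda = 0` removes all phylogenetic covariance (star phylogeny).
#'
#' @param C Phylogenetic covariance matrix, e.g. from [phylo_covariance()].
#' @param lambda Signal strength in `[0, 1]`.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("`lambda` must be a single value in [0, 1]")
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

# Eigen-based GLS preparation for covariances of the form
# V(theta) = D^{1/2} (theta * Cstar + (1 - theta) * I) D^{1/2},
# where D = diag(C) and Cstar = D^{-1/2} C D^{-1/2} (unit diagonal).
# This family contains both the lambda transform (theta = lambda) and the
# mixed-model correlation h2*G + (1-h2)*I when diag(G) = 1. One
# eigendecomposition makes each profile evaluation O(n).
.gls_prep <- function(C) {
  d <- diag(C)
  if (any(d <= 0)) stop("covariance matrix has non-positive diagonal")
  sdD <- sqrt(d)
  Cstar <- C / tcrossprod(sdD)
  eig <- eigen(Cstar, symmetric = TRUE)
  list(values = eig$values, vectors = eig$vectors,
       sdD = sdD, logdetD = sum(log(d)), n = length(d))
}

# Profile ML of mu and sigma2 given mixing weight theta in [0, 1].
# ytil/otil are the rotated data/intercept: Q' D^{-1/2} y and Q' D^{-1/2} 1.
.gls_profile <- function(theta, prep, ytil, otil) {
  w <- theta * prep$values + (1 - theta)
  if (any(w <= 0)) return(list(loglik = -Inf, mu = NA_real_, sigma2 = NA_real_))
  n <- prep$n
  mu <- sum(otil * ytil / w) / sum(otil^2 / w)
  rss <- sum((ytil - mu * otil)^2 / w)
  sigma2 <- rss / n
  if (sigma2 <= 0)
    return(list(loglik = -Inf, mu = mu, sigma2 = 0))
  ll <- -0.5 * (n * log(2 * pi * sigma2) + prep$logdetD + sum(log(w)) + n)
  list(loglik = ll, mu = mu, sigma2 = sigma2)
}

.rotate <- function(prep, y) as.vector(crossprod(prep$vectors, y / prep$sdD))

#' Profile log-likelihood of a trait under a lambda-transformed covariance
#'
#' For `V = lambda_transform(C, lambda)` the mean and rate are profiled out
#' analytically: `mu_hat = (1'V^-1 y)/(1'V^-1 1)`,
#' `sigma2_hat = (y - mu_hat)' V^-1 (y - mu_hat) / n`, and the maximised
#' log-likelihood is `-[n log(2 pi sigma2_hat) + log|V| + n] / 2`.
#'
#' @param y Numeric trait vector, aligned to the rows of `C`. If named, the
#'   names must match `rownames(C)`.
#' @param C Phylogenetic covariance matrix.
#' @param lambda Signal strength in `[0, 1]`.
#' @return A list with `loglik`, `mu_hat`, `sigma2_hat`. A degenerate
#'   (constant) trait yields `sigma2_hat = 0` and `loglik = -Inf`.
#' @export
loglik_lambda <- function(y, C, lambda) {
  y <- .align_trait(y, C)
  prep <- .gls_prep(lambda_transform(C, lambda))
  # theta = 1 evaluates the already-transformed matrix exactly
  p <- .gls_profile(1, prep, .rotate(prep, y), .rotate(prep, rep(1, length(y))))
  list(loglik = p$loglik, mu_hat = p$mu, sigma2_hat = p$sigma2)
}

.align_trait <- function(y, C) {
  if (!is.null(names(y))) {
    miss <- setdiff(rownames(C), names(y))
    extra <- setdiff(names(y), rownames(C))
    if (length(miss) || length(extra))
      stop("trait/tree name mismatch; missing from trait: ",
           paste(head(miss, 5), collapse = ", "),
           "; absent from tree: ", paste(head(extra, 5), collapse = ", "))
    y <- y[rownames(C)]
  } else if (length(y) != nrow(C)) {
    stop("trait length ", length(y), " does not match ", nrow(C), " tips")
  }
  if (anyNA(y)) stop("trait contains missing values")
  as.numeric(y)
}

#' Maximum-likelihood estimate of Pagel's lambda with a likelihood-ratio test
#'
#' Profiles the likelihood over lambda in `[0, 1]` (coarse grid of 101 points
#' followed by bounded refinement to tolerance 1e-6) and tests the estimate
#' against `lambda = 0` (no signal) with a likelihood-ratio statistic
#' referred to chi-square with 1 df. At the boundary `lambda = 0` this
#' reference is conservative.
#'
#' @param y Named numeric trait vector (names = tip labels), or unnamed in
#'   tree tip order.
#' @param tree Rooted `phylo` object.
#' @param log_transform Apply a natural-log transformation to `y` first
#'   (requires positive values). Default `FALSE`.
#' @return An object of class `phylo_signal`: a list with `lambda_hat`,
#'   `sigma2_hat`, `mu_hat`, `loglik_at_hat`, `loglik_at_zero`, `p_value`,
#'   `n`, and `flag` (`"ok"` or `"non-identifiable"` when the profile is
#'   flat, e.g. on a star tree).
#' @export
estimate_lambda <- function(y, tree, log_transform = FALSE) {
  C <- phylo_covariance(tree)
  y <- .align_trait(y, C)
  if (log_transform) {
    if (any(y <= 0)) stop("log transform requires positive trait values")
    y <- log(y)
  }
  if (sd(y) == 0) stop("trait is constant; lambda is undefined")
  prep <- .gls_prep(C)
  ytil <- .rotate(prep, y)
  otil <- .rotate(prep, rep(1, length(y)))
  ll <- function(th) .gls_profile(th, prep, ytil, otil)$loglik
  grid <- seq(0, 1, length.out = 101)
  llg <- vapply(grid, ll, numeric(1))
  flag <- if (max(llg) - min(llg) < 1e-8) "non-identifiable" else "ok"
  i <- which.max(llg)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-6)
  cand <- rbind(c(opt$maximum, opt$objective), c(grid[i], llg[i]))
  best <- cand[which.max(cand[, 2]), ]
  fit <- .gls_profile(best[1], prep, ytil, otil)
  ll0 <- llg[1]
  lr <- max(0, 2 * (fit$loglik - ll0))
  structure(list(
    lambda_hat = best[1], sigma2_hat = fit$sigma2, mu_hat = fit$mu,
    loglik_at_hat = fit$loglik, loglik_at_zero = ll0,
    p_value = pchisq(lr, df = 1, lower.tail = FALSE),
    n = length(y), flag = flag
  ), class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat(sprintf(
    "Pagel's lambda: %.4f (n = %d)\n  logLik = %.4f, logLik(lambda=0) = %.4f, LR p = %.3g%s\n",
    x$lambda_hat, x$n, x$loglik_at_hat, x$loglik_at_zero, x$p_value,
    if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Phylogenetic-signal table for several traits
#'
#' Runs [estimate_lambda()] on each trait column and assembles the result
#' in one row per trait (trait, lambda, loglik, loglik0, p_value, flag).
#'
#' @param traits Data frame of numeric trait columns with species as
#'   row names, or with a `species` column.
#' @param tree Rooted `phylo` object.
#' @param trait_cols Character vector of trait columns; default all numeric
#'   columns.
#' @inheritParams estimate_lambda
#' @return A data frame, one row per trait.
#' @export
signal_table <- function(traits, tree, trait_cols = NULL, log_transform = FALSE) {
  traits <- .species_rownames(traits)
  if (is.null(trait_cols))
    trait_cols <- names(traits)[vapply(traits, is.numeric, logical(1))]
  rows <- lapply(trait_cols, function(tc) {
    f <- estimate_lambda(setNames(traits[[tc]], rownames(traits)), tree,
                         log_transform = log_transform)
    data.frame(trait = tc, lambda = f$lambda_hat, loglik = f$loglik_at_hat,
               loglik0 = f$loglik_at_zero, p_value = f$p_value,
               flag = f$flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.species_rownames <- function(df) {
  if ("species" %in% names(df)) {
    rownames(df) <- df$species
    df$species <- NULL
  }
  df
}
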