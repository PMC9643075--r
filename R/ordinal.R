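#' Encode IUCN red-list categories on the ordinal extinction-risk scale
#'
#' Maps LC -> 0, NT -> 1, VU -> 2, EN -> 3, CR -> 4 (case-insensitive).
#' Categories outside this scale (DD, NE, RE, EX, ...) are not orderable as
#' extinction risk and raise an error; such species must be excluded before
#' modelling.
#'
#' @param category Character vector of category codes.
#' @return Integer vector in `0..4`.
#' @export
encode_status <- function(category) {
  map <- c(LC = 0L, NT = 1L, VU = 2L, EN = 3L, CR = 4L)
  key <- toupper(trimws(as.character(category)))
  bad <- unique(key[!key %in% names(map)])
  if (length(bad))
    stop("unsupported red-list categories (not on the LC..CR ordinal scale): ",
         paste(bad, collapse = ", "))
  unname(map[key])
}

# Negative log-likelihood and gradient of the proportional-odds model in the
# latent parameterisation P(Y <= k) = logistic(zeta_k - x'beta). theta packs
# (beta_1..p, zeta_1..K-1). y is 0-based, already using all K categories.
.po_nll <- function(theta, X, y, K) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  zeta <- theta[p + seq_len(K - 1)]
  if (is.unsorted(zeta, strictly = FALSE)) return(1e10)
  eta <- as.vector(X %*% beta)
  up <- ifelse(y == K - 1, 1, plogis(zeta[pmin(y + 1, K - 1)] - eta))
  lo <- ifelse(y == 0, 0, plogis(zeta[pmax(y, 1)] - eta))
  -sum(log(pmax(up - lo, 1e-300)))
}

.po_grad <- function(theta, X, y, K) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  zeta <- theta[p + seq_len(K - 1)]
  eta <- as.vector(X %*% beta)
  dl <- function(x) {
    q <- plogis(x)
    q * (1 - q)
  }
  upx <- zeta[pmin(y + 1, K - 1)] - eta
  lox <- zeta[pmax(y, 1)] - eta
  Fu <- ifelse(y == K - 1, 1, plogis(upx))
  Fl <- ifelse(y == 0, 0, plogis(lox))
  fu <- ifelse(y == K - 1, 0, dl(upx))
  fl <- ifelse(y == 0, 0, dl(lox))
  pr <- pmax(Fu - Fl, 1e-300)
  # d nll / d eta_i = (fu - fl) / pr
  geta <- (fu - fl) / pr
  gbeta <- as.vector(crossprod(X, geta))
  gzeta <- numeric(K - 1)
  for (k in seq_len(K - 1)) {
    gzeta[k] <- -sum(fu[y == k - 1] / pr[y == k - 1]) +
      sum(fl[y == k] / pr[y == k])
  }
  c(gbeta, gzeta)
}

#' Fit a proportional-odds (ordered logistic) regression
#'
#' Maximises the cumulative-logit likelihood
#' `P(Y <= k | x) = logistic(zeta_k - x'beta)` so that a positive
#' coefficient shifts probability mass toward higher (more threatened)
#' categories. Optimisation is quasi-Newton from the closed-form
#' intercept-only start (thresholds at the logits of the cumulative category
#' frequencies, `beta = 0`), followed by Newton polishing until the gradient
#' infinity-norm is below 1e-8. Standard errors come from the inverse
#' observed information at the optimum; p-values are two-sided Wald normal.
#'
#' @param X Numeric design matrix (n x p, no intercept column) or data frame
#'   of numeric predictors.
#' @param y Ordinal response: integer codes `0..K-1`, an ordered factor, or
#'   red-list category strings (passed through [encode_status()]).
#' @return An object of class `ordinal_fit`: list with `coefficients` (data
#'   frame: predictor, estimate, std_error, z_value, p_value), `zeta`
#'   (thresholds), `zeta_se`, `loglik`, `loglik_null` (intercept-only),
#'   `n`, `K`, `converged`, `gradient_norm`, `collapsed` (dropped empty
#'   categories, if any).
#' @export
fit_proportional_odds <- function(X, y) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!is.numeric(X)) stop("predictors must be numeric")
  if (anyNA(X) || anyNA(y)) stop("missing values in predictors or response")
  if (is.character(y)) y <- encode_status(y)
  if (is.ordered(y) || is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (nrow(X) != length(y)) stop("X rows and response length differ")
  lev <- sort(unique(y))
  collapsed <- integer(0)
  if (length(lev) < 2L) stop("response uses fewer than 2 categories")
  full <- seq(min(lev), max(lev))
  if (!all(full %in% lev)) {
    collapsed <- setdiff(full, lev)
    warning("collapsing empty response categories: ",
            paste(collapsed, collapse = ", "))
  }
  y <- match(y, lev) - 1L
  K <- length(lev)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + K - 1)
    stop("too few observations (n = ", n, ") for ", p, " predictors and ",
         K - 1, " thresholds")
  # singular design screen, naming the offender
  cs <- apply(X, 2, sd)
  if (any(cs == 0))
    stop("singular design: constant predictor(s) ",
         paste(colnames(X)[cs == 0], collapse = ", "))
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1)
    stop("singular design: linearly dependent predictor set {",
         paste(colnames(X), collapse = ", "), "}")

  # optimise on standardised predictors (well-conditioned, scale-free
  # convergence test), then map the optimum and its covariance back exactly
  mX <- colMeans(X)
  Xs <- sweep(sweep(X, 2, mX), 2, cs, "/")
  cum <- cumsum(tabulate(y + 1L, nbins = K))[seq_len(K - 1)] / n
  theta0 <- c(rep(0, p), qlogis(cum))
  opt <- optim(theta0, .po_nll, .po_grad, X = Xs, y = y, K = K,
               method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  theta <- opt$par
  # Newton polish on the analytic gradient
  for (it in 1:50) {
    g <- .po_grad(theta, Xs, y, K)
    if (max(abs(g)) < 1e-9) break
    H <- optimHess(theta, .po_nll, .po_grad, X = Xs, y = y, K = K)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    damp <- 1
    nll0 <- .po_nll(theta, Xs, y, K)
    while (.po_nll(theta - damp * step, Xs, y, K) > nll0 + 1e-12 &&
           damp > 1e-6)
      damp <- damp / 2
    if (.po_nll(theta - damp * step, Xs, y, K) > nll0 + 1e-12) break
    theta <- theta - damp * step
  }
  g <- .po_grad(theta, Xs, y, K)
  gnorm <- max(abs(g))
  bstd <- theta[seq_len(p)]
  if (gnorm > 1e-6 || max(abs(bstd)) > 30) {
    worst <- colnames(X)[which.max(abs(bstd))]
    stop(sprintf(paste0(
      "proportional-odds fit did not converge (gradient inf-norm %.3g); ",
      "possible separation on predictor '%s' (|beta| x sd = %.3g)"),
      gnorm, worst, max(abs(bstd))))
  }
  H <- optimHess(theta, .po_nll, .po_grad, X = Xs, y = y, K = K)
  Vstd <- tryCatch(solve(H), error = function(e)
    stop("singular information matrix at the optimum"))
  # Jacobian of (beta, zeta) w.r.t. the standardised parameters
  J <- diag(p + K - 1)
  diag(J)[seq_len(p)] <- 1 / cs
  for (k in seq_len(K - 1)) J[p + k, seq_len(p)] <- mX / cs
  theta <- as.vector(J %*% theta)
  Vc <- J %*% Vstd %*% t(J)
  beta <- theta[seq_len(p)]
  se <- sqrt(pmax(diag(Vc), 0))
  zeta <- theta[p + seq_len(K - 1)]
  if (is.unsorted(zeta, strictly = TRUE))
    stop("estimated thresholds are not strictly increasing")
  est <- beta
  zse <- se[seq_len(p)]
  z <- est / zse
  coefs <- data.frame(
    predictor = colnames(X), estimate = est, std_error = zse,
    z_value = z, p_value = 2 * pnorm(-abs(z)),
    stringsAsFactors = FALSE, row.names = NULL)
  ll_null <- -.po_nll(c(rep(0, p), qlogis(cum)), matrix(0, n, p), y, K)
  structure(list(
    coefficients = coefs, zeta = zeta, zeta_se = se[p + seq_len(K - 1)],
    loglik = -opt$value, loglik_null = ll_null,
    n = n, K = K, converged = gnorm < 1e-6, gradient_norm = gnorm,
    collapsed = collapsed
  ), class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("Proportional-odds fit (n = %d, K = %d), logLik = %.4f\n",
              x$n, x$K, x$loglik))
  print(format(x$coefficients, digits = 4), row.names = FALSE)
  cat("thresholds:", sprintf("%.4f", x$zeta), "\n")
  invisible(x)
}

#' Fit one red-list regression block (S-, P- or raw-trait predictors)
#'
#' A single joint proportional-odds model of ordinal red-list status on the
#' four traits of one component block (body volume, wing area, color
#' lightness, range size), so each coefficient is the effect of that trait
#' controlled for the other three — in particular for range size. A
#' per-trait mode fits four separate univariate models instead.
#'
#' @param traits Matrix or data frame of the block's predictor columns,
#'   species-aligned with `status`.
#' @param status Ordinal response (see [fit_proportional_odds()]).
#' @param joint Fit one joint model (default) or one model per trait.
#' @return For `joint = TRUE` an `ordinal_fit`; otherwise a named list of
#'   per-trait `ordinal_fit` objects.
#' @export
fit_table2_block <- function(traits, status, joint = TRUE) {
  if (is.data.frame(traits)) traits <- as.matrix(traits)
  if (joint) return(fit_proportional_odds(traits, status))
  fits <- lapply(colnames(traits), function(tc)
    fit_proportional_odds(traits[, tc, drop = FALSE], status))
  setNames(fits, colnames(traits))
}

#' Tidy coefficient table of an ordinal fit
#'
#' @param fit An `ordinal_fit` object.
#' @return Data frame with predictor, estimate, std_error, z_value, p_value.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "ordinal_fit"))
  fit$coefficients
}
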