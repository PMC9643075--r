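# Independent oracles used across the suite. Each re-derives its quantity
# from first principles (brute force, enumeration, closed form) without
# touching the package's computational path.

# Shoelace polygon area, written out longhand.
oracle_shoelace <- function(v) {
  n <- nrow(v)
  a <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    a <- a + v[i, 1] * v[j, 2] - v[j, 1] * v[i, 2]
  }
  abs(a) / 2
}

# Brownian covariance by explicit root-path enumeration: C[i, j] is the
# summed branch length shared by the root-to-tip paths of i and j.
oracle_vcv <- function(tree) {
  n <- length(tree$tip.label)
  nmax <- max(tree$edge)
  parent <- integer(nmax)
  elen <- numeric(nmax)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  path_up <- function(i) {
    p <- integer(0)
    while (i != root) {
      p <- c(p, i)
      i <- parent[i]
    }
    p
  }
  paths <- lapply(seq_len(n), path_up)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in i:n) {
      shared <- intersect(paths[[i]], paths[[j]])
      C[i, j] <- C[j, i] <- sum(elen[shared])
    }
  }
  C
}

# ML of an MVN(mu * 1, sigma2 * V) by nested grid refinement over
# (mu, sigma2); returns the maximised log-likelihood.
oracle_mvn_ml <- function(y, V) {
  n <- length(y)
  Vi <- solve(V)
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  ll <- function(mu, s2) {
    r <- y - mu
    -0.5 * (n * log(2 * pi * s2) + ld +
              as.numeric(t(r) %*% Vi %*% r) / s2)
  }
  mlo <- mean(y) - 4 * sd(y); mhi <- mean(y) + 4 * sd(y)
  slo <- var(y) / 100; shi <- var(y) * 100
  best <- -Inf
  for (round in 1:14) {
    mus <- seq(mlo, mhi, length.out = 21)
    s2s <- exp(seq(log(slo), log(shi), length.out = 21))
    g <- outer(mus, s2s, Vectorize(ll))
    ij <- which(g == max(g), arr.ind = TRUE)[1, ]
    best <- max(best, g[ij[1], ij[2]])
    dm <- mus[2] - mus[1]
    mlo <- mus[ij[1]] - dm; mhi <- mus[ij[1]] + dm
    fs <- s2s[2] / s2s[1]
    slo <- s2s[ij[2]] / fs; shi <- s2s[ij[2]] * fs
  }
  best
}

# ML of the Lynch model by brute-force 2-D grid refinement over
# (sigma2_a, sigma2_e), profiling mu by GLS at each grid point.
oracle_lynch_ml <- function(y, G) {
  n <- length(y)
  ll <- function(sa, se) {
    V <- sa * G + se * diag(n)
    Vi <- tryCatch(solve(V), error = function(e) NULL)
    if (is.null(Vi)) return(-Inf)
    mu <- sum(Vi %*% y) / sum(Vi)
    r <- y - mu
    -0.5 * (n * log(2 * pi) +
              as.numeric(determinant(V, logarithm = TRUE)$modulus) +
              as.numeric(t(r) %*% Vi %*% r))
  }
  v0 <- var(y)
  alo <- v0 * 1e-4; ahi <- v0 * 10
  elo <- v0 * 1e-4; ehi <- v0 * 10
  best <- -Inf
  for (round in 1:12) {
    sas <- exp(seq(log(alo), log(ahi), length.out = 21))
    ses <- exp(seq(log(elo), log(ehi), length.out = 21))
    g <- outer(sas, ses, Vectorize(ll))
    ij <- which(g == max(g), arr.ind = TRUE)[1, ]
    best <- max(best, g[ij[1], ij[2]])
    fa <- sas[2] / sas[1]; fe <- ses[2] / ses[1]
    alo <- sas[ij[1]] / fa; ahi <- sas[ij[1]] * fa
    elo <- ses[ij[2]] / fe; ehi <- ses[ij[2]] * fe
  }
  best
}

# Binary logistic regression MLE (intercept + slopes) by Newton-Raphson.
oracle_binary_logit <- function(X, y01) {
  A <- cbind(1, X)
  b <- rep(0, ncol(A))
  for (it in 1:100) {
    p <- 1 / (1 + exp(-as.vector(A %*% b)))
    g <- crossprod(A, y01 - p)
    W <- p * (1 - p)
    H <- crossprod(A * W, A)
    step <- solve(H, g)
    b <- b + step
    if (max(abs(g)) < 1e-12) break
  }
  p <- 1 / (1 + exp(-as.vector(A %*% b)))
  H <- crossprod(A * (p * (1 - p)), A)
  list(coef = as.vector(b), se = sqrt(diag(solve(H))))
}

# OLS residuals of log(area) on log(volume) via the normal equations.
oracle_log_residuals <- function(areas, volumes) {
  A <- cbind(1, log(volumes))
  b <- solve(t(A) %*% A, t(A) %*% log(areas))
  as.vector(log(areas) - A %*% b)
}

# Nearest-to-body wing fraction by exhaustive pixel-pair distances.
oracle_proximal <- function(wing_mask, body_mask, fraction) {
  bp <- which(body_mask, arr.ind = TRUE)
  lab <- oracle_components(wing_mask)
  out <- wing_mask & FALSE
  for (k in seq_len(max(lab))) {
    wp <- which(lab == k, arr.ind = TRUE)
    wp <- wp[order(wp[, 1], wp[, 2]), , drop = FALSE]
    d <- apply(wp, 1, function(p)
      sqrt(min((p[1] - bp[, 1])^2 + (p[2] - bp[, 2])^2)))
    keep <- ceiling(fraction * nrow(wp))
    sel <- wp[order(d)[seq_len(keep)], , drop = FALSE]
    out[sel] <- TRUE
  }
  out
}

# Flood-fill connected components (4-connectivity, the package's stated
# convention) on a logical matrix.
oracle_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nextlab <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      rc <- arrayInd(cur, dim(mask))
      for (k in 1:4) {
        dr <- c(-1L, 1L, 0L, 0L)[k]; dc <- c(0L, 0L, -1L, 1L)[k]
        r <- rc[1] + dr; cc <- rc[2] + dc
        if (r >= 1 && r <= nrow(mask) && cc >= 1 && cc <= ncol(mask)) {
          i <- (cc - 1L) * nrow(mask) + r
          if (mask[i] && lab[i] == 0L) {
            lab[i] <- nextlab
            queue <- c(queue, i)
          }
        }
      }
    }
  }
  lab
}

# Occupied cells of a rectangular range over a rectangular grid, by
# closed-form rectangle-rectangle overlap.
oracle_rect_cells <- function(rx1, ry1, rx2, ry2, grid) {
  ow <- pmax(0, pmin(rx2, grid$xmax) - pmax(rx1, grid$xmin))
  oh <- pmax(0, pmin(ry2, grid$ymax) - pmax(ry1, grid$ymin))
  grid$cell[ow * oh > 0]
}

# Independent greedy correlation/VIF elimination using matrix algebra for
# the R^2 (inverse-correlation diagonal) instead of per-variable lm fits.
oracle_vif_retained <- function(X, threshold) {
  keep <- seq_len(ncol(X))
  repeat {
    if (length(keep) < 2) break
    R <- abs(cor(X[, keep, drop = FALSE]))
    diag(R) <- 0
    m <- which(R == max(R), arr.ind = TRUE)[1, ]
    if (R[m[1], m[2]] < threshold) break
    vifs <- diag(solve(cor(X[, keep, drop = FALSE])))
    pair <- sort(m)
    drop_local <- if (abs(vifs[pair[1]] - vifs[pair[2]]) < 1e-10) pair[2]
    else pair[which.max(vifs[pair])]
    keep <- keep[-drop_local]
  }
  colnames(X)[keep]
}

# One small deterministic tree reused by several files.
fixture_tree <- function(n = 20, seed = 42) simulate_tree(n, seed = seed)
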