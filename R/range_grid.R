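# Sutherland-Hodgman clipping of a simple polygon to an axis-aligned
# rectangle; returns the clipped vertex matrix (possibly with degenerate
# edges, which do not affect the shoelace area).
.clip_to_rect <- function(poly, xmin, ymin, xmax, ymax) {
  clip_half <- function(v, inside, intersect) {
    if (nrow(v) == 0) return(v)
    out <- matrix(numeric(0), 0, 2)
    n <- nrow(v)
    for (i in seq_len(n)) {
      cur <- v[i, ]; prev <- v[if (i == 1) n else i - 1, ]
      ci <- inside(cur); pi_ <- inside(prev)
      if (ci) {
        if (!pi_) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pi_) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, axis, val) {
    t <- (val - p[axis]) / (q[axis] - p[axis])
    p + t * (q - p)
  }
  v <- as.matrix(poly)
  v <- clip_half(v, function(p) p[1] >= xmin, function(p, q) ix(p, q, 1, xmin))
  v <- clip_half(v, function(p) p[1] <= xmax, function(p, q) ix(p, q, 1, xmax))
  v <- clip_half(v, function(p) p[2] >= ymin, function(p, q) ix(p, q, 2, ymin))
  v <- clip_half(v, function(p) p[2] <= ymax, function(p, q) ix(p, q, 2, ymax))
  v
}

#' Build an axis-aligned rectangular grid
#'
#' @param xmin,ymin,xmax,ymax Grid extent.
#' @param nx,ny Number of cells along x and y.
#' @return Data frame of cells: `cell`, `xmin`, `ymin`, `xmax`, `ymax`.
#' @export
make_grid <- function(xmin, ymin, xmax, ymax, nx, ny) {
  xb <- seq(xmin, xmax, length.out = nx + 1)
  yb <- seq(ymin, ymax, length.out = ny + 1)
  g <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  data.frame(cell = paste0("c", g$i, "_", g$j),
             xmin = xb[g$i], ymin = yb[g$j],
             xmax = xb[g$i + 1], ymax = yb[g$j + 1],
             stringsAsFactors = FALSE)
}

#' Intersect a species range with an equal-area grid
#'
#' A grid cell counts as occupied when its intersection with the range has
#' positive area (any overlap, not cell-center containment); an optional
#' center-containment mode is available for sensitivity checks.
#'
#' @param polygons One two-column (x, y) vertex matrix or a list of them
#'   (simple polygons, in grid coordinates).
#' @param grid Data frame of rectangular cells as from [make_grid()]
#'   (columns `cell`, `xmin`, `ymin`, `xmax`, `ymax`).
#' @param mode `"area"` (default) or `"center"`.
#' @return Character vector of occupied cell ids.
#' @export
rasterize_range <- function(polygons, grid, mode = c("area", "center")) {
  mode <- match.arg(mode)
  if (is.matrix(polygons) || is.data.frame(polygons))
    polygons <- list(as.matrix(polygons))
  if (!length(polygons)) stop("invalid range: no polygons")
  for (p in polygons) {
    p <- as.matrix(p)
    if (ncol(p) != 2 || nrow(p) < 3 || any(!is.finite(p)))
      stop("invalid polygon: need >= 3 finite (x, y) vertices")
    if (polygon_area(p) == 0) stop("invalid polygon: zero area")
  }
  occ <- logical(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    cellarea <- (grid$xmax[k] - grid$xmin[k]) * (grid$ymax[k] - grid$ymin[k])
    for (p in polygons) {
      p <- as.matrix(p)
      if (mode == "center") {
        cx <- (grid$xmin[k] + grid$xmax[k]) / 2
        cy <- (grid$ymin[k] + grid$ymax[k]) / 2
        hit <- .points_in_polygon(matrix(cx), matrix(cy), p)[1]
      } else {
        cv <- .clip_to_rect(p, grid$xmin[k], grid$ymin[k],
                            grid$xmax[k], grid$ymax[k])
        hit <- nrow(cv) >= 3 && polygon_area(cv) > 1e-12 * cellarea
      }
      if (hit) { occ[k] <- TRUE; break }
    }
  }
  grid$cell[occ]
}

#' Range occupancy
#'
#' Fraction of the study region's grid cells occupied by a species.
#'
#' @param occupied Number of occupied cells (> 0; a species with no range
#'   cannot be analysed).
#' @param total_cells Total number of grid cells covering the region.
#' @return Occupancy in `(0, 1]`.
#' @export
range_occupancy <- function(occupied, total_cells) {
  if (any(total_cells <= 0)) stop("`total_cells` must be positive")
  if (any(occupied <= 0))
    stop("species with zero occupied cells cannot be analysed")
  if (any(occupied > total_cells)) stop("occupied exceeds total cells")
  occupied / total_cells
}

#' Iterative pairwise-correlation / VIF screen for multicollinearity
#'
#' Repeatedly finds the predictor pair with the largest absolute Pearson
#' correlation; while it reaches `threshold`, the member with the larger
#' variance-inflation factor (VIF_j = 1 / (1 - R^2) from regressing j on all
#' other retained predictors) is dropped. Ties drop the higher column index,
#' so the lowest-index variable is dropped last.
#'
#' @param X Numeric matrix or data frame of candidate predictors (>= 2
#'   columns, more rows than columns).
#' @param threshold Absolute correlation threshold (default 0.9, the
#'   conventional screening value).
#' @return List with `retained` (column names), and `excluded` (data frame:
#'   variable, abs_correlation, vif, partner at the time of exclusion).
#' @export
vif_screen <- function(X, threshold = 0.9) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 predictors")
  if (nrow(X) <= ncol(X)) stop("need more observations than predictors")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  csd <- apply(X, 2, sd)
  if (any(csd == 0))
    stop("singular predictor matrix: constant column(s) ",
         paste(colnames(X)[csd == 0], collapse = ", "))
  retained <- colnames(X)
  excl <- list()
  vif_of <- function(j, vars) {
    others <- setdiff(vars, j)
    # exact duplicates give a perfect fit on purpose; the warning is noise
    r2 <- suppressWarnings(
      summary(lm(X[, j] ~ X[, others, drop = FALSE]))$r.squared)
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }
  repeat {
    if (length(retained) < 2) break
    R <- abs(cor(X[, retained, drop = FALSE]))
    diag(R) <- 0
    top <- which(R == max(R), arr.ind = TRUE)[1, ]
    if (R[top[1], top[2]] < threshold) break
    pair <- retained[sort(top)]
    v <- vapply(pair, vif_of, numeric(1), vars = retained)
    drop_var <- if (abs(v[1] - v[2]) < 1e-10 || (is.infinite(v[1]) && is.infinite(v[2])))
      pair[2] else pair[which.max(v)]
    excl[[drop_var]] <- data.frame(
      variable = drop_var, abs_correlation = R[top[1], top[2]],
      vif = unname(v[drop_var]), partner = setdiff(pair, drop_var),
      stringsAsFactors = FALSE)
    retained <- setdiff(retained, drop_var)
  }
  list(retained = retained,
       excluded = if (length(excl)) do.call(rbind, c(excl, list(make.row.names = FALSE)))
       else data.frame(variable = character(0), abs_correlation = numeric(0),
                       vif = numeric(0), partner = character(0)))
}

#' Occupancy table from a presence matrix
#'
#' @param presence Species x cell 0/1 matrix (row names = species).
#' @return Data frame: `species`, `occupied_cells`, `total_cells`,
#'   `occupancy`.
#' @export
occupancy_table <- function(presence) {
  presence <- as.matrix(presence)
  occ <- rowSums(presence > 0)
  data.frame(species = rownames(presence), occupied_cells = occ,
             total_cells = ncol(presence),
             occupancy = range_occupancy(occ, ncol(presence)),
             row.names = NULL, stringsAsFactors = FALSE)
}
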