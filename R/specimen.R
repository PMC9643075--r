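#' Exact area of a simple polygon (shoelace formula)
#'
#' @param vertices Two-column matrix of (x, y) vertices in order.
#' @return Absolute enclosed area.
#' @export
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3) stop("a polygon needs at least 3 vertices")
  x <- v[, 1]; y <- v[, 2]
  j <- c(2:nrow(v), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

.segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

.check_simple_polygon <- function(v) {
  n <- nrow(v)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1 || (i == 1 && j == n)) next
      if (.segments_intersect(v[i, ], v[i %% n + 1, ], v[j, ], v[j %% n + 1, ]))
        stop("self-intersecting polygon")
    }
  }
  invisible(TRUE)
}

#' Specification of a synthetic specimen drawing
#'
#' Describes a dorsal specimen image: a vertically oriented cylindrical body
#' (rendered as a rectangle of its projected outline) plus flat polygonal
#' wings, each region at a constant 8-bit gray level on a pure-white
#' background. Coordinates are in cm, with the body centered at the origin
#' and the body axis along y.
#'
#' @param body_length_cm,body_width_cm Body dimensions (> 0).
#' @param wing_polygons List of two-column (x, y) vertex matrices in cm;
#'   may be empty for body-only (odonate-style) images.
#' @param body_gray Body gray level in `[0, 255]`.
#' @param wing_gray_profile Gray level per wing polygon (recycled).
#' @param dpi Raster resolution in pixels per inch.
#' @return A `specimen_spec` list.
#' @export
specimen_spec <- function(body_length_cm, body_width_cm,
                          wing_polygons = list(), body_gray = 100,
                          wing_gray_profile = 180, dpi = 1200) {
  if (body_length_cm <= 0 || body_width_cm <= 0)
    stop("body dimensions must be positive")
  if (dpi <= 0) stop("`dpi` must be positive")
  grays <- c(body_gray, wing_gray_profile)
  if (any(grays < 0 | grays > 255)) stop("gray levels must be in [0, 255]")
  wing_polygons <- lapply(wing_polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2 || nrow(p) < 3) stop("wing polygons need >= 3 (x, y) vertices")
    .check_simple_polygon(p)
    p
  })
  structure(list(body_length_cm = body_length_cm,
                 body_width_cm = body_width_cm,
                 wing_polygons = wing_polygons, body_gray = body_gray,
                 wing_gray_profile = rep_len(wing_gray_profile,
                                             max(1L, length(wing_polygons))),
                 dpi = dpi),
            class = "specimen_spec")
}

#' Render a synthetic specimen image with analytic ground truth
#'
#' Rasterises a [specimen_spec()] at its stated dpi: the body becomes an
#' exact pixel rectangle of `round(width/s) x round(length/s)` pixels
#' (s = pixel edge in cm), wings are filled by even-odd pixel-center tests,
#' and the background is pure white (255, 255, 255). Returns the analytic
#' ground truth alongside: cylinder volume `pi (w/2)^2 l` and exact
#' shoelace wing areas.
#'
#' @param spec A `specimen_spec`.
#' @return List with `image` (H x W x 3 array of 0-255 values), `body_mask`
#'   and `wing_mask` (logical H x W matrices, disjoint), `dpi`, and `truth`
#'   (list: `body_volume_cm3`, `wing_areas_cm2`, `wing_area_cm2`,
#'   `body_width_px`, `body_length_px`).
#' @export
render_specimen_image <- function(spec) {
  stopifnot(inherits(spec, "specimen_spec"))
  s <- pixel_edge_cm(spec$dpi)
  nw <- round(spec$body_width_cm / s)
  nl <- round(spec$body_length_cm / s)
  if (nw < 1 || nl < 1)
    stop("body dimensions smaller than one pixel at ", spec$dpi, " dpi")
  w2 <- spec$body_width_cm / 2
  l2 <- spec$body_length_cm / 2
  xs <- c(-w2, w2, unlist(lapply(spec$wing_polygons, function(p) p[, 1])))
  ys <- c(-l2, l2, unlist(lapply(spec$wing_polygons, function(p) p[, 2])))
  pad <- 2 * s
  x0 <- min(xs) - pad
  y1 <- max(ys) + pad
  W <- ceiling((max(xs) + pad - x0) / s)
  H <- ceiling((y1 - (min(ys) - pad)) / s)
  # body as an exact pixel block, centered on the origin
  c0 <- round((-w2 - x0) / s)
  r0 <- round((y1 - l2) / s)
  body <- matrix(FALSE, H, W)
  body[r0 + seq_len(nl), c0 + seq_len(nw)] <- TRUE
  # pixel-center coordinates
  px <- x0 + (seq_len(W) - 0.5) * s
  py <- y1 - (seq_len(H) - 0.5) * s
  X <- matrix(px, H, W, byrow = TRUE)
  Y <- matrix(py, H, W)
  wing <- matrix(FALSE, H, W)
  wing_id <- matrix(0L, H, W)
  for (k in seq_along(spec$wing_polygons)) {
    inside <- .points_in_polygon(X, Y, spec$wing_polygons[[k]])
    wing_id[inside & !wing] <- k
    wing <- wing | inside
  }
  wing <- wing & !body
  wing_id[body | !wing] <- 0L
  img <- array(255, dim = c(H, W, 3))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[body] <- spec$body_gray
    for (k in seq_along(spec$wing_polygons))
      plane[wing_id == k] <- spec$wing_gray_profile[k]
    img[, , ch] <- plane
  }
  areas <- vapply(spec$wing_polygons, polygon_area, numeric(1))
  list(image = img, body_mask = body, wing_mask = wing, dpi = spec$dpi,
       truth = list(
         body_volume_cm3 = pi * (spec$body_width_cm / 2)^2 * spec$body_length_cm,
         wing_areas_cm2 = areas,
         wing_area_cm2 = sum(areas),
         body_width_px = nw, body_length_px = nl))
}

# Even-odd (crossing-number) point-in-polygon test, vectorised over a grid.
.points_in_polygon <- function(X, Y, poly) {
  inside <- matrix(FALSE, nrow(X), ncol(X))
  n <- nrow(poly)
  xv <- poly[, 1]; yv <- poly[, 2]
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    crosses <- ((yv[i] > Y) != (yv[j] > Y)) &
      (X < (xv[j] - xv[i]) * (Y - yv[i]) / (yv[j] - yv[i]) + xv[i])
    inside <- xor(inside, crosses)
  }
  inside
}

#' Write a rendered specimen to disk (image, masks, ground-truth sidecar)
#'
#' Writes `<species>.png` (24-bit sRGB), `<species>_body.png` and
#' `<species>_wings.png` (binary masks), and `<species>.json` with the dpi
#' and analytic ground truth.
#'
#' @param rendered Result of [render_specimen_image()].
#' @param dir Output directory (created if needed).
#' @param species Species identifier used as the file stem.
#' @return Invisibly, the sidecar path.
#' @export
write_specimen <- function(rendered, dir, species) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  png::writePNG(rendered$image / 255, file.path(dir, paste0(species, ".png")))
  png::writePNG(rendered$body_mask * 1, file.path(dir, paste0(species, "_body.png")))
  png::writePNG(rendered$wing_mask * 1, file.path(dir, paste0(species, "_wings.png")))
  sidecar <- file.path(dir, paste0(species, ".json"))
  jsonlite::write_json(c(list(dpi = rendered$dpi), rendered$truth),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a specimen image and its masks back from disk
#'
#' @param dir Directory written by [write_specimen()].
#' @param species Species identifier (file stem).
#' @return List with `image` (0-255 array), `body_mask`, `wing_mask`,
#'   `dpi`, and `truth` (from the sidecar, if present).
#' @export
read_specimen <- function(dir, species) {
  img <- png::readPNG(file.path(dir, paste0(species, ".png"))) * 255
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  body <- png::readPNG(file.path(dir, paste0(species, "_body.png"))) > 0.5
  wings_path <- file.path(dir, paste0(species, "_wings.png"))
  wing <- if (file.exists(wings_path)) png::readPNG(wings_path) > 0.5
          else matrix(FALSE, nrow(body), ncol(body))
  sidecar <- file.path(dir, paste0(species, ".json"))
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
          else list(dpi = 1200)
  list(image = img, body_mask = body[, , drop = TRUE], wing_mask = wing[, , drop = TRUE],
       dpi = meta$dpi, truth = meta[setdiff(names(meta), "dpi")])
}
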