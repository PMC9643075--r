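#' Physical edge length of one pixel
#'
#' @param dpi Resolution in pixels per inch.
#' @return Pixel edge length in cm, `2.54 / dpi`.
#' @export
pixel_edge_cm <- function(dpi) {
  if (!is.numeric(dpi) || length(dpi) != 1L || is.na(dpi) || dpi <= 0)
    stop("`dpi` must be a single positive number")
  2.54 / dpi
}

#' Body volume from a dorsal body mask
#'
#' Treats the body as a stack of cylindrical discs, one per pixel row: each
#' row of the mask contributes `pi * (n_r * s / 2)^2 * s`, where `n_r` is
#' the number of body pixels in that row (the local body width) and `s` the
#' pixel edge in cm. The body axis must run perpendicular to pixel rows
#' (vertical in the image).
#'
#' @param body_mask Logical matrix, `TRUE` on body pixels.
#' @param dpi Resolution in pixels per inch.
#' @return Body volume in cm^3.
#' @export
body_volume <- function(body_mask, dpi) {
  s <- pixel_edge_cm(dpi)
  m <- .as_mask(body_mask)
  if (!any(m)) stop("empty body mask")
  n_r <- rowSums(m)
  sum(pi * (n_r * s / 2)^2 * s)
}

.as_mask <- function(m) {
  if (is.logical(m)) return(m)
  if (is.numeric(m)) return(m > 0.5)
  stop("mask must be a logical or numeric matrix")
}

#' Mean color lightness over body (and proximal wings)
#'
#' Mean over the scored pixels of the per-pixel channel average
#' `(R + G + B) / 3`, on the 8-bit gray scale (0 = black, 255 = white).
#' For butterflies (`include_wings = TRUE`) the scored region is the body
#' plus the fraction of each wing closest to the body (default the nearest
#' third, the part most relevant for thermoregulation); in odonate mode
#' (`include_wings = FALSE`) only the body is scored.
#'
#' @param image H x W x 3 array of 0-255 channel values (a plain H x W
#'   matrix is treated as grayscale).
#' @param body_mask Logical body mask.
#' @param wing_mask Logical wing mask (disjoint from the body), or `NULL`.
#' @param proximal_fraction Fraction of each wing scored, in `(0, 1]`.
#' @param include_wings Score proximal wing pixels in addition to the body.
#' @return Mean gray value in `[0, 255]`.
#' @export
color_lightness <- function(image, body_mask, wing_mask = NULL,
                            proximal_fraction = 1 / 3, include_wings = TRUE) {
  body_mask <- .as_mask(body_mask)
  if (!any(body_mask)) stop("empty body mask")
  gray <- if (length(dim(image)) == 3)
    (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  else image
  sel <- body_mask
  if (include_wings && !is.null(wing_mask) && any(.as_mask(wing_mask))) {
    wing_mask <- .as_mask(wing_mask)
    if (any(wing_mask & body_mask)) stop("body and wing masks overlap")
    sel <- sel | proximal_wing_region(wing_mask, body_mask, proximal_fraction)
  }
  if (!any(sel)) stop("empty pixel selection")
  mean(gray[sel])
}

#' Proximal part of each wing, by distance to the body
#'
#' For each connected wing component (4-connectivity), retains the
#' `ceiling(fraction * size)` pixels with the smallest Euclidean distance to
#' the body mask (ties broken by distance, then row-major pixel order), and
#' unions the result across components. This realises "the fraction of the
#' wing area closest to the body" by pixel count, robust to wing shape.
#'
#' @param wing_mask Logical wing mask; an empty mask returns an empty mask.
#' @param body_mask Logical body mask, disjoint from the wings.
#' @param fraction Fraction in `(0, 1]` of each wing to retain.
#' @return Logical mask of the retained wing pixels.
#' @export
proximal_wing_region <- function(wing_mask, body_mask, fraction = 1 / 3) {
  wing_mask <- .as_mask(wing_mask)
  body_mask <- .as_mask(body_mask)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]")
  if (any(wing_mask & body_mask)) stop("body and wing masks overlap")
  out <- wing_mask & FALSE
  if (!any(wing_mask)) return(out)
  if (fraction == 1) return(wing_mask)
  if (!any(body_mask)) stop("empty body mask")
  # Euclidean distance of every pixel to the nearest body pixel
  dist_to_body <- EBImage::distmap(1 - body_mask, metric = "euclidean")
  labels <- EBImage::bwlabel(EBImage::Image(wing_mask * 1))
  labels <- matrix(as.integer(labels), nrow(wing_mask), ncol(wing_mask))
  for (k in seq_len(max(labels))) {
    idx <- which(labels == k)           # row-major within-column order? which() is column-major
    # row-major tie order: sort indices by (row, col)
    rc <- arrayInd(idx, dim(wing_mask))
    ord_rm <- order(rc[, 1], rc[, 2])
    idx <- idx[ord_rm]
    d <- dist_to_body[idx]
    keep <- ceiling(fraction * length(idx))
    sel <- idx[order(d)[seq_len(keep)]]  # stable sort: ties fall back to row-major
    out[sel] <- TRUE
  }
  out
}

#' Total wing area from a wing mask
#'
#' Number of wing pixels times the pixel area in cm^2.
#'
#' @param wing_mask Logical wing mask (empty mask gives 0).
#' @param dpi Resolution in pixels per inch.
#' @return Wing area in cm^2.
#' @export
wing_area <- function(wing_mask, dpi) {
  s <- pixel_edge_cm(dpi)
  sum(.as_mask(wing_mask)) * s^2
}

#' Size-corrected wing area (dispersal-ability proxy)
#'
#' Residuals of the ordinary least-squares regression of `ln(wing area)` on
#' `ln(body volume)` with intercept: the variation in wing area not
#' explained by body size.
#'
#' @param wing_areas Positive wing areas (cm^2), length >= 3.
#' @param body_volumes Positive body volumes (cm^3), same length.
#' @return Residual vector (sums to zero to numerical precision).
#' @export
residual_wing_area <- function(wing_areas, body_volumes) {
  if (length(wing_areas) != length(body_volumes))
    stop("input lengths differ")
  if (length(wing_areas) < 3)
    stop("need at least 3 species for the size-correction regression")
  if (any(!is.finite(wing_areas)) || any(!is.finite(body_volumes)) ||
      any(wing_areas <= 0) || any(body_volumes <= 0))
    stop("wing areas and body volumes must be positive and finite")
  lv <- log(body_volumes)
  if (sd(lv) == 0) stop("singular design: log body volume is constant")
  out <- unname(resid(lm(log(wing_areas) ~ lv)))
  names(out) <- names(wing_areas)
  out
}

#' Morphometric record for one specimen image
#'
#' Convenience wrapper computing body volume, color lightness and wing area
#' from one image + mask set. Residual wing area is a cross-species
#' regression and is added later by [residual_wing_area()].
#'
#' @param image 0-255 RGB array (or grayscale matrix).
#' @param body_mask,wing_mask Logical masks (disjoint).
#' @param dpi Resolution in pixels per inch.
#' @param include_wings Score proximal wings in the lightness (butterfly
#'   mode); `FALSE` for odonate (body-only) mode.
#' @param proximal_fraction Proximal wing fraction for the lightness.
#' @return One-row data frame: `body_volume_cm3`, `color_lightness`,
#'   `wing_area_cm2`.
#' @export
measure_specimen <- function(image, body_mask, wing_mask, dpi,
                             include_wings = TRUE, proximal_fraction = 1 / 3) {
  data.frame(
    body_volume_cm3 = body_volume(body_mask, dpi),
    color_lightness = color_lightness(image, body_mask, wing_mask,
                                      proximal_fraction, include_wings),
    wing_area_cm2 = wing_area(wing_mask, dpi))
}

#' Morphometric table for a directory of specimen images
#'
#' Reads every `<species>.png` / `<species>_body.png` / `<species>_wings.png`
#' triplet (plus optional JSON sidecar with the dpi) in `dir`, measures each
#' specimen, and appends the cross-species residual wing area.
#'
#' @param dir Directory of images written by [write_specimen()] (or
#'   following the same naming convention).
#' @param dpi Fallback resolution when a sidecar is absent (default 1200).
#' @inheritParams measure_specimen
#' @return Data frame with columns `species`, `body_volume_cm3`,
#'   `color_lightness`, `wing_area_cm2`, `residual_wing_area`.
#' @export
measure_specimen_dir <- function(dir, dpi = 1200, include_wings = TRUE,
                                 proximal_fraction = 1 / 3) {
  pngs <- list.files(dir, pattern = "\\.png$")
  species <- sort(setdiff(sub("\\.png$", "", pngs),
                          grep("_(body|wings)$", sub("\\.png$", "", pngs),
                               value = TRUE)))
  if (!length(species)) stop("no specimen images found in ", dir)
  rows <- lapply(species, function(sp) {
    spm <- read_specimen(dir, sp)
    cbind(species = sp,
          measure_specimen(spm$image, spm$body_mask, spm$wing_mask, spm$dpi,
                           include_wings, proximal_fraction))
  })
  out <- do.call(rbind, rows)
  out$residual_wing_area <- residual_wing_area(out$wing_area_cm2,
                                               out$body_volume_cm3)
  out
}
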