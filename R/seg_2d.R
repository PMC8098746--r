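# Per-plane segmentation operations: adaptive threshold, 2D object
# measurement under the rectangle fiber model, the two filter masks, shrink,
# and keep-marked-objects.

#' Adaptive (local mean + offset) threshold of one plane
#'
#' A pixel is foreground iff its intensity exceeds the mean over the
#' surrounding `(2r+1) x (2r+1)` window by more than `offset`. Borders are
#' handled by reflective padding. A constant plane yields an empty mask.
#'
#' @param plane 2D intensity matrix.
#' @param radius_px window radius in pixels (>= 2).
#' @param offset threshold offset in counts.
#' @return Logical matrix of the same shape.
#' @export
adaptive_threshold <- function(plane, radius_px, offset) {
  stopifnot(is.matrix(plane), radius_px >= 2)
  r <- min(as.integer(radius_px), nrow(plane) - 1L, ncol(plane) - 1L)
  plane > box_mean(plane, r) + offset
}

#' Measure 2D connected components
#'
#' Components are 8-connected. Area is pixel count times the squared pixel
#' size; perimeter is the exposed-pixel-edge count times the pixel size.
#' Fiber length and breadth come from the rectangle model solving
#' `A = L * B`, `P = 2 (L + B)`: `L = (P + sqrt(max(P^2 - 16 A, 0))) / 4`,
#' `B = A / L` (exact for ideal rectangles). The elliptical form factor is
#' the major/minor axis ratio of the second-central-moment ellipse (with the
#' 1/12 per-pixel variance term, so one-pixel-wide objects stay finite), and
#' `intensity_sd` the sample SD of the raw intensities over member pixels.
#'
#' @param mask logical/integer matrix (binary mask) or an integer label
#'   matrix.
#' @param plane raw intensity matrix of the same shape.
#' @param pixel_size_um pixel size.
#' @return A data.frame with one row per object: `label, n_px, area_um2,
#'   perimeter_um, fiber_length_um, fiber_breadth_um, eff, intensity_sd,
#'   centroid_x_um, centroid_y_um`.
#' @export
measure_objects_2d <- function(mask, plane, pixel_size_um) {
  stopifnot(all(dim(mask) == dim(plane)))
  lab <- if (is.logical(mask) || all(mask %in% c(0, 1)))
    label8(mask) else matrix(as.integer(mask), nrow(mask), ncol(mask))
  n <- max(lab)
  empty <- data.frame(label = integer(0), n_px = integer(0),
                      area_um2 = numeric(0), perimeter_um = numeric(0),
                      fiber_length_um = numeric(0),
                      fiber_breadth_um = numeric(0), eff = numeric(0),
                      intensity_sd = numeric(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0))
  if (n == 0L) return(structure(empty, labels = lab))
  px <- pixel_size_um
  idx <- which(lab > 0L)
  l <- lab[idx]
  npx <- tabulate(l, n)
  # exposed edges: for each 4-neighbour direction, member pixels whose
  # neighbour is background or off the image edge
  ny <- nrow(lab); nx <- ncol(lab)
  exposed <- integer(n)
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nb <- matrix(0L, ny, nx)
    ys <- seq_len(ny) - d[1L]; xs <- seq_len(nx) - d[2L]
    ok_y <- ys >= 1L & ys <= ny; ok_x <- xs >= 1L & xs <= nx
    nb[ok_y, ok_x] <- lab[ys[ok_y], xs[ok_x]]
    ex <- lab > 0L & nb == 0L
    exposed <- exposed + tabulate(lab[ex], n)
  }
  # second central moments per label (0-based pixel centres)
  ai <- arrayInd(idx, dim(lab))
  yy <- ai[, 1L] - 1; xx <- ai[, 2L] - 1
  sx <- rowsum_vec(xx, l, n); sy <- rowsum_vec(yy, l, n)
  sxx <- rowsum_vec(xx^2, l, n); syy <- rowsum_vec(yy^2, l, n)
  sxy <- rowsum_vec(xx * yy, l, n)
  mx <- sx / npx; my <- sy / npx
  vxx <- sxx / npx - mx^2 + 1 / 12
  vyy <- syy / npx - my^2 + 1 / 12
  vxy <- sxy / npx - mx * my
  tr <- vxx + vyy
  det <- vxx * vyy - vxy^2
  disc <- sqrt(pmax(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- pmax(tr / 2 - disc, 1e-12)
  eff <- sqrt(l1 / l2)
  # intensity SD (sample SD; single-pixel objects get 0)
  iv <- plane[idx]
  s1 <- rowsum_vec(iv, l, n); s2 <- rowsum_vec(iv^2, l, n)
  varr <- ifelse(npx > 1, (s2 - s1^2 / npx) / (npx - 1), 0)
  isd <- sqrt(pmax(varr, 0))

  A <- npx * px^2
  P <- exposed * px
  L <- (P + sqrt(pmax(P^2 - 16 * A, 0))) / 4
  B <- A / L
  out <- data.frame(
    label = seq_len(n), n_px = npx, area_um2 = A, perimeter_um = P,
    fiber_length_um = L, fiber_breadth_um = B, eff = eff,
    intensity_sd = isd,
    centroid_x_um = (mx + 0.5) * px, centroid_y_um = (my + 0.5) * px)
  out <- out[out$n_px > 0L, , drop = FALSE]
  structure(out, labels = lab)
}

rowsum_vec <- function(v, g, n) {
  out <- numeric(n)
  rs <- rowsum(v, g)
  out[as.integer(rownames(rs))] <- rs[, 1L]
  out
}

#' Apply a removal rule set to measured objects and return the retained mask.
#' The returned mask carries the surviving label matrix and retained-object
#' count as attributes so later stages need not relabel.
#' @noRd
apply_filter <- function(measures, remove_flags, logic) {
  lab <- attr(measures, "labels")
  if (nrow(measures) == 0L)
    return(structure(lab > 0L, labels = lab, n_retained = 0L))
  fire <- do.call(cbind, remove_flags)
  remove <- if (logic == "or") rowSums(fire) > 0 else rowSums(fire) ==
    ncol(fire)
  keep_labels <- measures$label[!remove]
  keep_lab <- lab
  keep_lab[!(keep_lab %in% keep_labels)] <- 0L
  structure(keep_lab > 0L, labels = keep_lab,
            n_retained = length(keep_labels))
}

#' Filter Mask 1: reject wide, short, or small objects
#'
#' Removes an object when (disjunctive default) its fiber breadth exceeds
#' `f1_max_breadth_um`, its fiber length is below `f1_min_length_um`, or its
#' area is below `f1_min_area_um2`. All comparisons strict; boundary equality
#' retains the object.
#'
#' @param measures output of [measure_objects_2d()].
#' @param params a [seg_params()] object.
#' @return Logical retained mask (same shape as the measured mask).
#' @export
filter_mask_1 <- function(measures, params = seg_params()) {
  apply_filter(measures, list(
    measures$fiber_breadth_um > params$f1_max_breadth_um,
    measures$fiber_length_um < params$f1_min_length_um,
    measures$area_um2 < params$f1_min_area_um2), params$filter_logic)
}

#' Filter Mask 2: reject round, wide, or internally uniform shrunk objects
#'
#' Applied to the measures of the shrunk objects against the raw intensity
#' plane. Removes an object when its elliptical form factor is below
#' `f2_min_eff`, its fiber breadth exceeds `f2_max_breadth_um`, or its
#' intensity SD is below `f2_min_intensity_sd` (counts at 16 bit, rescaled
#' for other depths). This is the step that rejects cell bodies and debris.
#'
#' @inheritParams filter_mask_1
#' @param bit_depth camera bit depth of the measured plane.
#' @export
filter_mask_2 <- function(measures, params = seg_params(), bit_depth = 16L) {
  sd_thr <- scale_counts(params$f2_min_intensity_sd, bit_depth)
  apply_filter(measures, list(
    measures$eff < params$f2_min_eff,
    measures$fiber_breadth_um > params$f2_max_breadth_um,
    measures$intensity_sd < sd_thr), params$filter_logic)
}

#' Shrink objects by morphological erosion with a disc
#'
#' Objects eroded to nothing disappear; radius 0 is the identity.
#'
#' @param mask logical matrix.
#' @param radius_px erosion radius in pixels.
#' @return Logical matrix.
#' @export
shrink_objects <- function(mask, radius_px = 4L) {
  stopifnot(radius_px >= 0)
  if (radius_px == 0L) return(mask != 0)
  EBImage::erode(mask != 0, disc_brush(radius_px)) > 0
}

#' Retain mask1 objects that overlap mask2
#'
#' An object of `mask1` is retained, at its full extent, iff at least one of
#' its pixels overlaps a foreground pixel of `mask2`.
#'
#' @param mask1,mask2 logical matrices of the same shape.
#' @return Logical matrix.
#' @export
keep_marked_objects <- function(mask1, mask2) {
  stopifnot(all(dim(mask1) == dim(mask2)))
  lab <- attr(mask1, "labels")
  if (is.null(lab)) lab <- label8(mask1 != 0)
  if (max(lab) == 0L)
    return(structure(lab > 0L, labels = lab, n_retained = 0L))
  marked <- unique(lab[lab > 0L & (mask2 != 0)])
  keep_lab <- lab
  keep_lab[!(keep_lab %in% marked)] <- 0L
  structure(keep_lab > 0L, labels = keep_lab,
            n_retained = length(marked))
}
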