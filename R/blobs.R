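# Multi-scale blob detection and subtraction. Round non-myelin structures
# (cell bodies, debris) are detected as scale-space maxima of the
# scale-normalized Laplacian of Gaussian, rendered as discs, enlarged, and
# set-subtracted from the retained myelin mask.

#' Detect round blobs in a plane by multi-scale Laplacian of Gaussian
#'
#' Scales are `sigma = d / (2 sqrt(2))` for `blob_n_scales` log-spaced widths
#' `d` across `width_range_um`. Detections are interior local maxima of the
#' scale-normalized LoG response in (x, y, scale); the scale list is padded by
#' one step on each side so that structures whose characteristic width falls
#' outside the requested range do not surface at a range edge. The response
#' threshold is `blob_rel_threshold` times the plane's intensity range.
#' Candidates whose local Hessian is strongly anisotropic (principal-axis
#' ratio above `blob_max_axis_ratio`) are rejected: elongated structures such
#' as sheath cross-sections produce LoG ridges, not blobs. Overlapping
#' detections are pruned greedily by response. For efficiency the plane is
#' processed at a block-mean-reduced resolution chosen so the smallest scale
#' stays >= 2 px; centres are refined to sub-pixel by parabolic interpolation.
#'
#' @param plane 2D intensity matrix.
#' @param width_range_um blob width (diameter) range, micrometres.
#' @param pixel_size_um pixel size.
#' @param params a [seg_params()] (supplies the detection settings).
#' @return An object of class `blob_set`: list with `mask` (logical matrix,
#'   detections rendered as discs of their detected diameter) and
#'   `detections` (data.frame `y_px, x_px, diameter_um, response`, pixel
#'   coordinates 0-based voxel-centre).
#' @export
find_blobs <- function(plane, width_range_um, pixel_size_um,
                       params = seg_params()) {
  stopifnot(length(width_range_um) == 2L, width_range_um[1] > 0,
            diff(width_range_um) > 0)
  ny <- nrow(plane); nx <- ncol(plane)
  empty <- structure(list(
    mask = matrix(FALSE, ny, nx),
    detections = data.frame(y_px = numeric(0), x_px = numeric(0),
                            diameter_um = numeric(0), response = numeric(0))),
    class = "blob_set")
  irange <- diff(range(plane))
  if (irange == 0) return(empty)

  n_sc <- params$blob_n_scales
  d_um <- exp(seq(log(width_range_um[1]), log(width_range_um[2]),
                  length.out = n_sc))
  step <- d_um[2] / d_um[1]
  d_pad <- c(d_um[1] / step, d_um, d_um[n_sc] * step)
  sig_px <- d_pad / (2 * sqrt(2)) / pixel_size_um

  ds <- max(1L, as.integer(floor(sig_px[2L] / 2)))
  W <- block_mean(plane, ds)
  sig_w <- sig_px / ds
  nyw <- nrow(W); nxw <- ncol(W)
  if (min(nyw, nxw) < 5L) return(empty)

  K <- length(sig_w)
  resp <- array(0, dim = c(nyw, nxw, K))
  smooth <- gauss_bank(W, sig_w)
  for (k in seq_len(K)) {
    S <- smooth[[k]]
    lap <- matrix(0, nyw, nxw)
    lap[2:(nyw - 1), 2:(nxw - 1)] <-
      S[1:(nyw - 2), 2:(nxw - 1)] + S[3:nyw, 2:(nxw - 1)] +
      S[2:(nyw - 1), 1:(nxw - 2)] + S[2:(nyw - 1), 3:nxw] -
      4 * S[2:(nyw - 1), 2:(nxw - 1)]
    resp[, , k] <- -sig_w[k]^2 * lap   # positive for bright blobs
  }

  thr <- params$blob_rel_threshold * irange
  r_ax <- params$blob_max_axis_ratio
  edge_bound <- (r_ax + 1)^2 / r_ax

  # vectorized 3x3 spatial max per scale, so the expensive per-candidate work
  # only runs on true scale-space peaks
  spat_max <- array(0, dim = dim(resp))
  for (k in seq_len(K)) spat_max[, , k] <- max3x3(resp[, , k])

  dets <- list()
  for (k in 2:(K - 1)) {          # interior scales = the requested range
    R <- resp[, , k]
    nbmax <- pmax(spat_max[, , k - 1], spat_max[, , k], spat_max[, , k + 1])
    cand <- which(R >= thr & R >= nbmax)
    if (!length(cand)) next
    ai <- arrayInd(cand, c(nyw, nxw))
    keep <- ai[, 1L] > 1L & ai[, 1L] < nyw & ai[, 2L] > 1L & ai[, 2L] < nxw
    ai <- ai[keep, , drop = FALSE]
    if (!nrow(ai)) next
    for (m in seq_len(nrow(ai))) {
      i <- ai[m, 1L]; j <- ai[m, 2L]
      v <- R[i, j]
      nb <- resp[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)]
      if (sum(nb == v) > 1L && !first_of_plateau(resp, i, j, k, v)) next
      # Hessian ridge rejection on the smoothed image at this scale
      S <- smooth[[k]]
      dxx <- S[i, j + 1] - 2 * S[i, j] + S[i, j - 1]
      dyy <- S[i + 1, j] - 2 * S[i, j] + S[i - 1, j]
      dxy <- (S[i + 1, j + 1] - S[i + 1, j - 1] -
                S[i - 1, j + 1] + S[i - 1, j - 1]) / 4
      trH <- dxx + dyy
      detH <- dxx * dyy - dxy^2
      if (detH <= 0 || trH^2 / detH > edge_bound) next
      oy <- parab_offset(R[i - 1, j], v, R[i + 1, j])
      ox <- parab_offset(R[i, j - 1], v, R[i, j + 1])
      dets[[length(dets) + 1L]] <- c(
        y = ((i - 0.5 + oy) * ds) - 0.5, x = ((j - 0.5 + ox) * ds) - 0.5,
        d = d_pad[k], resp = v)
    }
  }
  if (!length(dets)) return(empty)
  dd <- do.call(rbind, dets)
  dd <- dd[order(-dd[, "resp"]), , drop = FALSE]

  # greedy overlap pruning (overlap fraction relative to the smaller disc)
  kept <- logical(nrow(dd))
  for (m in seq_len(nrow(dd))) {
    ok <- TRUE
    if (any(kept)) {
      prev <- dd[kept, , drop = FALSE]
      for (q in seq_len(nrow(prev))) {
        r1 <- dd[m, "d"] / 2 / pixel_size_um
        r2 <- prev[q, "d"] / 2 / pixel_size_um
        ctr_d <- sqrt((dd[m, "y"] - prev[q, "y"])^2 +
                        (dd[m, "x"] - prev[q, "x"])^2)
        if (circle_overlap_frac(r1, r2, ctr_d) > params$blob_overlap) {
          ok <- FALSE; break
        }
      }
    }
    kept[m] <- ok
  }
  dd <- dd[kept, , drop = FALSE]

  mask <- matrix(FALSE, ny, nx)
  xs <- seq_len(nx) - 1; ys <- seq_len(ny) - 1
  for (m in seq_len(nrow(dd))) {
    r_px <- dd[m, "d"] / 2 / pixel_size_um
    jr <- which(abs(xs - dd[m, "x"]) <= r_px)
    ir <- which(abs(ys - dd[m, "y"]) <= r_px)
    if (!length(jr) || !length(ir)) next
    sub <- outer((ys[ir] - dd[m, "y"])^2, (xs[jr] - dd[m, "x"])^2, "+") <=
      r_px^2
    mask[ir, jr] <- mask[ir, jr] | sub
  }
  structure(list(
    mask = mask,
    detections = data.frame(y_px = dd[, "y"], x_px = dd[, "x"],
                            diameter_um = dd[, "d"],
                            response = dd[, "resp"])),
    class = "blob_set")
}

max3x3 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  out <- m
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
                 c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))) {
    sh <- matrix(-Inf, ny, nx)
    ys <- seq_len(ny) - d[1L]; xs <- seq_len(nx) - d[2L]
    ok_y <- ys >= 1L & ys <= ny; ok_x <- xs >= 1L & xs <= nx
    sh[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
    out <- pmax(out, sh)
  }
  out
}

# plateau tie-break: accept only the lexicographically first grid point of an
# exactly-tied neighbourhood, so a flat maximum yields one detection
first_of_plateau <- function(resp, i, j, k, v) {
  nb <- which(resp[(i - 1):(i + 1), (j - 1):(j + 1), (k - 1):(k + 1)] == v,
              arr.ind = TRUE)
  ord <- order(nb[, 3L], nb[, 2L], nb[, 1L])
  all(nb[ord[1L], ] == c(2L, 2L, 2L))
}

parab_offset <- function(lo, mid, hi) {
  den <- lo - 2 * mid + hi
  if (den >= 0) return(0)
  off <- 0.5 * (lo - hi) / den
  max(min(off, 0.5), -0.5)
}

circle_overlap_frac <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  rs <- min(r1, r2); rl <- max(r1, r2)
  if (d <= rl - rs) return(1)
  a1 <- rs^2 * acos(pmin(pmax((d^2 + rs^2 - rl^2) / (2 * d * rs), -1), 1))
  a2 <- rl^2 * acos(pmin(pmax((d^2 + rl^2 - rs^2) / (2 * d * rl), -1), 1))
  tri <- 0.5 * sqrt(pmax((-d + rs + rl) * (d + rs - rl) * (d - rs + rl) *
                           (d + rs + rl), 0))
  (a1 + a2 - tri) / (pi * rs^2)
}

#' Subtract (enlarged) blobs from a myelin mask
#'
#' The blob mask is dilated by a disc of `enlarge_px` pixels and
#' set-subtracted from the myelin mask. Pixels of retained objects that do
#' not overlap the enlarged blobs persist.
#'
#' @param mask logical myelin mask.
#' @param blobs a `blob_set` from [find_blobs()] or a logical matrix.
#' @param enlarge_px dilation radius in pixels.
#' @return Logical matrix.
#' @export
subtract_blobs <- function(mask, blobs, enlarge_px = 5L) {
  bm <- if (inherits(blobs, "blob_set")) blobs$mask else blobs != 0
  stopifnot(all(dim(mask) == dim(bm)), enlarge_px >= 0)
  if (!any(bm)) return(mask != 0)
  if (enlarge_px > 0)
    bm <- EBImage::dilate(bm, disc_brush(enlarge_px)) > 0
  (mask != 0) & !bm
}
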