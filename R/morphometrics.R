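# Single-cell and population morphometrics: sheath statistics from trace
# tables, nearest-neighbor oligodendrocyte density, and Sholl analysis.

#' Per-cell sheath summaries from a trace table
#'
#' Sheath length is the polyline arc length in micrometres. Cells appear once
#' with their sheath count, mean length and the individual lengths; the
#' pooled length vector (for frequency distributions) is attached as
#' attribute `pooled_lengths`.
#'
#' @param traces a `trace_table` (see [read_trace_table()]).
#' @return data.frame `myelinoid_id, cell_id, sheath_count,
#'   mean_length_um` with list-column `lengths_um`; attribute
#'   `pooled_lengths`.
#' @export
sheath_summaries <- function(traces) {
  stopifnot(inherits(traces, "data.frame"))
  if (!"z_um" %in% names(traces)) traces$z_um <- 0
  key <- interaction(traces$myelinoid_id, traces$cell_id, traces$sheath_id,
                     drop = TRUE)
  per_sheath <- do.call(rbind, lapply(split(traces, key), function(s) {
    s <- s[order(s$point_index), ]
    data.frame(myelinoid_id = s$myelinoid_id[1L], cell_id = s$cell_id[1L],
               sheath_id = s$sheath_id[1L],
               length_um = sum(sqrt(diff(s$x_um)^2 + diff(s$y_um)^2 +
                                      diff(s$z_um)^2)))
  }))
  per_sheath <- per_sheath[per_sheath$length_um > 0, , drop = FALSE]
  cells <- split(per_sheath,
                 interaction(per_sheath$myelinoid_id, per_sheath$cell_id,
                             drop = TRUE))
  out <- do.call(rbind, lapply(cells, function(cc) {
    data.frame(myelinoid_id = cc$myelinoid_id[1L], cell_id = cc$cell_id[1L],
               sheath_count = nrow(cc), mean_length_um = mean(cc$length_um))
  }))
  rownames(out) <- NULL
  out$lengths_um <- lapply(cells, function(cc) cc$length_um)
  attr(out, "pooled_lengths") <- per_sheath$length_um
  out
}

#' Percentage frequency distribution of sheath lengths
#'
#' Left-closed right-open bins starting at 0; percentages sum to 100.
#'
#' @param lengths numeric vector of lengths (um), non-empty.
#' @param bin_width_um bin width (default 10 um).
#' @return data.frame `bin_low_um, bin_high_um, count, percent`.
#' @export
length_histogram <- function(lengths, bin_width_um = 10) {
  stopifnot(length(lengths) > 0, bin_width_um > 0, all(lengths >= 0))
  bin <- floor(lengths / bin_width_um)
  n_bins <- max(bin) + 1L
  cnt <- tabulate(bin + 1L, n_bins)
  data.frame(bin_low_um = (seq_len(n_bins) - 1L) * bin_width_um,
             bin_high_um = seq_len(n_bins) * bin_width_um,
             count = cnt, percent = 100 * cnt / sum(cnt))
}

#' Nearest-neighbor oligodendrocyte density
#'
#' For each index cell, the number of OTHER myelinating-oligodendrocyte
#' centroids within `radius_um` (Euclidean distance, boundary inclusive:
#' a cell exactly at the radius counts). The index cell itself is excluded.
#' By default every cell is an index cell; restrict with `index`.
#'
#' @param centroids a `centroid_table` (columns `myelinoid_id, cell_id, x_um,
#'   y_um, is_myelinating`).
#' @param radius_um counting radius (default 100 um).
#' @param index logical vector choosing index cells (default all).
#' @return data.frame `myelinoid_id, cell_id, n_neighbors`.
#' @export
nearest_neighbor_density <- function(centroids, radius_um = 100,
                                     index = NULL) {
  stopifnot(nrow(centroids) >= 1, radius_um > 0)
  if (is.null(index)) index <- rep(TRUE, nrow(centroids))
  out <- lapply(split(seq_len(nrow(centroids)), centroids$myelinoid_id),
                function(rows) {
    cc <- centroids[rows, ]
    idx <- index[rows]
    dm <- as.matrix(stats::dist(cbind(cc$x_um, cc$y_um)))
    counts <- vapply(seq_len(nrow(cc)), function(i) {
      sum(dm[i, ] <= radius_um & cc$is_myelinating & seq_len(nrow(cc)) != i)
    }, integer(1))
    data.frame(myelinoid_id = cc$myelinoid_id, cell_id = cc$cell_id,
               n_neighbors = counts)[idx, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Sholl analysis of a binary cell mask
#'
#' For each radius, the digitized circle of that radius around the centre is
#' traversed and the number of connected runs of foreground pixels along it
#' is counted (a process crossing the circle produces one run). Total
#' outgrowth is the skeleton length of the mask (sum of inter-pixel steps
#' along the morphological skeleton) times the pixel size.
#'
#' @param mask logical/0-1 matrix.
#' @param center `c(y_px, x_px)` centre in 0-based pixel coordinates.
#' @param pixel_size_um pixel size.
#' @param step_um radius step.
#' @param max_radius_um largest radius.
#' @return A list of class `sholl_result`: `radii_um`, `intersections`,
#'   `total_outgrowth_um`.
#' @export
sholl <- function(mask, center, pixel_size_um = 1, step_um = 10,
                  max_radius_um = NULL) {
  stopifnot(is.matrix(mask), length(center) == 2)
  ny <- nrow(mask); nx <- ncol(mask)
  if (center[1] < 0 || center[1] > ny - 1 || center[2] < 0 ||
      center[2] > nx - 1)
    stop("center outside mask bounds")
  if (is.null(max_radius_um))
    max_radius_um <- max(ny, nx) * pixel_size_um / 2
  radii <- seq(step_um, max_radius_um, by = step_um)
  inter <- vapply(radii, function(r)
    circle_runs(mask != 0, center, r / pixel_size_um), integer(1))
  structure(list(radii_um = radii, intersections = inter,
                 total_outgrowth_um =
                   skeleton_length_px(mask != 0) * pixel_size_um),
            class = "sholl_result")
}

#' @export
print.sholl_result <- function(x, ...) {
  cat("sholl_result: total outgrowth", round(x$total_outgrowth_um, 1),
      "um\n")
  print(stats::setNames(x$intersections, paste0(x$radii_um, "um")))
  invisible(x)
}

# number of connected foreground runs along the digitized circle of radius
# r_px (pixels) around center (0-based y, x)
circle_runs <- function(mask, center, r_px) {
  ny <- nrow(mask); nx <- ncol(mask)
  n_theta <- max(16L, ceiling(2 * pi * r_px * 2))
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  iy <- round(center[1] + r_px * sin(th)) + 1L
  ix <- round(center[2] + r_px * cos(th)) + 1L
  keep <- iy >= 1L & iy <= ny & ix >= 1L & ix <= nx
  if (!any(keep)) return(0L)
  # de-duplicate consecutive identical pixels while preserving circular order
  pix <- cbind(iy, ix)[keep, , drop = FALSE]
  dup <- c(FALSE, pix[-1L, 1L] == pix[-nrow(pix), 1L] &
             pix[-1L, 2L] == pix[-nrow(pix), 2L])
  pix <- pix[!dup, , drop = FALSE]
  v <- mask[cbind(pix[, 1L], pix[, 2L])]
  if (!any(v)) return(0L)
  if (all(v)) return(1L)
  runs <- sum(v & !c(v[length(v)], v[-length(v)]))
  as.integer(runs)
}

#' Morphological skeleton length in pixel units
#'
#' Zhang-Suen thinning to a one-pixel skeleton, then length as the sum over
#' skeleton adjacencies: 1 per orthogonal neighbour pair, sqrt(2) per
#' diagonal pair (each pair counted once).
#' @noRd
skeleton_length_px <- function(mask) {
  sk <- zhang_suen(mask)
  if (!any(sk)) return(0)
  orth <- count_adjacencies(sk, list(c(0L, 1L), c(1L, 0L)))
  diag <- count_adjacencies(sk, list(c(1L, 1L), c(1L, -1L)))
  # do not double-count the diagonal of a 2x2 elbow already linked orthogonally
  orth + sqrt(2) * diag
}

count_adjacencies <- function(m, dirs) {
  total <- 0L
  ny <- nrow(m); nx <- ncol(m)
  for (d in dirs) {
    sh <- matrix(FALSE, ny, nx)
    ys <- seq_len(ny) - d[1L]; xs <- seq_len(nx) - d[2L]
    ok_y <- ys >= 1L & ys <= ny; ok_x <- xs >= 1L & xs <= nx
    sh[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
    total <- total + sum(m & sh)
  }
  total
}

zhang_suen <- function(mask) {
  m <- mask
  pad <- function(x) rbind(FALSE, cbind(FALSE, x, FALSE), FALSE)
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      mp <- pad(m)
      ny <- nrow(m); nx <- ncol(m)
      ctr <- mp[2:(ny + 1), 2:(nx + 1)]
      p2 <- mp[1:ny, 2:(nx + 1)]       # north
      p3 <- mp[1:ny, 3:(nx + 2)]
      p4 <- mp[2:(ny + 1), 3:(nx + 2)] # east
      p5 <- mp[3:(ny + 2), 3:(nx + 2)]
      p6 <- mp[3:(ny + 2), 2:(nx + 1)] # south
      p7 <- mp[3:(ny + 2), 1:nx]
      p8 <- mp[2:(ny + 1), 1:nx]       # west
      p9 <- mp[1:ny, 1:nx]
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      cond <- ctr & B >= 2 & B <= 6 & A == 1
      if (phase == 1) {
        cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}
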