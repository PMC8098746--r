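# Seeded generators for tabular datasets with known ground truth: grouped
# normalized-volume measurements (lognormal hierarchy), centroid fields,
# g-ratio diameter tables, and binary process-tree masks for Sholl analysis.

#' Parameters for grouped measurement simulation
#'
#' Emulates the two-group myelinoid experiments: per-image normalized myelin
#' volumes drawn from a lognormal hierarchy, `log value = group mean + batch
#' effect + myelinoid effect + residual`, with the paper-scale design of 13
#' vs 13 myelinoids across 3 batch-conversions and two images per myelinoid.
#' Variance components are on the natural-log scale.
#'
#' @param n_myelinoids integer vector, myelinoids per group.
#' @param group_labels labels for the groups (first is the control).
#' @param n_batches number of batch-conversions (myelinoids are spread over
#'   batches round-robin; both groups appear in every batch).
#' @param images_per_myelinoid images (acquisition sites) per myelinoid.
#' @param fold_change true multiplicative effect of each non-control group
#'   relative to control (scalar or one value per extra group).
#' @param base_value control-group geometric mean of the measurement.
#' @param sd_batch,sd_myelinoid,sd_residual log-scale SDs of the batch,
#'   myelinoid, and image-level components.
#' @param seed RNG seed.
#' @return A list of class `group_sim_params`.
#' @export
group_sim_params <- function(n_myelinoids = c(13L, 13L),
                             group_labels = c("Ctrl", "Treated"),
                             n_batches = 3L,
                             images_per_myelinoid = 2L,
                             fold_change = 2,
                             base_value = 1e-4,
                             sd_batch = 0.3, sd_myelinoid = 0.4,
                             sd_residual = 0.2,
                             seed = 1L) {
  p <- as.list(environment())
  stopifnot(length(p$n_myelinoids) == length(p$group_labels),
            length(p$n_myelinoids) >= 2,
            all(p$fold_change > 0),
            length(p$fold_change) %in% c(1L, length(p$group_labels) - 1L),
            p$sd_batch >= 0, p$sd_myelinoid >= 0, p$sd_residual >= 0,
            p$n_batches >= 1, p$images_per_myelinoid >= 1)
  class(p) <- "group_sim_params"
  p
}

#' Generate a grouped measurement table from the lognormal hierarchy
#'
#' @param params a [group_sim_params()].
#' @return data.frame `value, unit, myelinoid_id, batch, group, image_id`
#'   with attribute `true_fold_change`.
#' @export
generate_group_data <- function(params = group_sim_params()) {
  stopifnot(inherits(params, "group_sim_params"))
  p <- params
  with_seed(p$seed, {
    fold <- rep_len(c(1, p$fold_change), length(p$group_labels))
    batch_eff <- stats::rnorm(p$n_batches, 0, p$sd_batch)
    rows <- list()
    mid <- 0L
    for (gi in seq_along(p$group_labels)) {
      for (mi in seq_len(p$n_myelinoids[gi])) {
        mid <- mid + 1L
        batch <- ((mi - 1L) %% p$n_batches) + 1L
        m_eff <- stats::rnorm(1, 0, p$sd_myelinoid)
        lv <- log(p$base_value) + log(fold[gi]) + batch_eff[batch] + m_eff +
          stats::rnorm(p$images_per_myelinoid, 0, p$sd_residual)
        rows[[mid]] <- data.frame(
          value = exp(lv), unit = "um3_per_count",
          myelinoid_id = sprintf("m%03d", mid),
          batch = sprintf("b%d", batch),
          group = p$group_labels[gi],
          image_id = seq_len(p$images_per_myelinoid))
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "true_fold_change") <- fold[-1L]
    out
  })
}

#' Generate a homogeneous-Poisson (optionally clustered) centroid field
#'
#' @param n expected number of cells.
#' @param field_um square field side length (um).
#' @param p_myelinating probability a cell is a myelinating oligodendrocyte.
#' @param cluster_sd if > 0, cells are scattered around `n_parents` parent
#'   points with this SD (Thomas-process-like clustering); 0 = homogeneous.
#' @param n_parents number of cluster parents when `cluster_sd > 0`.
#' @param seed RNG seed.
#' @return A `centroid_table` data.frame.
#' @export
generate_centroids <- function(n, field_um = 500, p_myelinating = 1,
                               cluster_sd = 0, n_parents = 5L, seed = 1L) {
  stopifnot(n >= 1, field_um > 0)
  with_seed(seed, {
    if (cluster_sd > 0) {
      par_x <- stats::runif(n_parents, 0, field_um)
      par_y <- stats::runif(n_parents, 0, field_um)
      pick <- sample.int(n_parents, n, replace = TRUE)
      x <- (par_x[pick] + stats::rnorm(n, 0, cluster_sd)) %% field_um
      y <- (par_y[pick] + stats::rnorm(n, 0, cluster_sd)) %% field_um
    } else {
      x <- stats::runif(n, 0, field_um)
      y <- stats::runif(n, 0, field_um)
    }
    validate_centroids(data.frame(
      myelinoid_id = "m1", cell_id = seq_len(n), x_um = x, y_um = y,
      is_myelinating = stats::runif(n) <= p_myelinating))
  })
}

#' Generate a g-ratio diameter table from the logarithmic model
#'
#' Simulates `g = a + b ln(axon diameter) + noise`, truncated to (0, 1), and
#' derives fiber diameter as axon diameter divided by g. Defaults mirror a
#' TEM dataset of 124 myelinated axons with mean g-ratio about 0.75.
#'
#' @param a,b model intercept and slope (natural log).
#' @param noise_sd residual SD of g.
#' @param n number of axons.
#' @param diameter_meanlog,diameter_sdlog lognormal axon-diameter prior (um).
#' @param seed RNG seed.
#' @return data.frame `axon_diameter_um, fiber_diameter_um, g` with
#'   attributes `true_a`, `true_b`. Warns when more than half the draws had
#'   to be truncated.
#' @export
generate_gratio_table <- function(a = 0.72, b = 0.055, noise_sd = 0.05,
                                  n = 124L, diameter_meanlog = 0.5,
                                  diameter_sdlog = 0.45, seed = 1L) {
  stopifnot(n >= 1, noise_sd >= 0)
  with_seed(seed, {
    d <- stats::rlnorm(n, diameter_meanlog, diameter_sdlog)
    g <- a + b * log(d) + stats::rnorm(n, 0, noise_sd)
    n_trunc <- sum(g <= 0 | g >= 1)
    g <- pmin(pmax(g, 1e-3), 1 - 1e-3)
    if (n_trunc > n / 2)
      warning("more than half of simulated g values truncated; ",
              "model poorly specified", call. = FALSE)
    out <- data.frame(axon_diameter_um = d, fiber_diameter_um = d / g, g = g)
    attr(out, "true_a") <- a
    attr(out, "true_b") <- b
    out
  })
}

#' Render a branching process tree as a binary mask for Sholl analysis
#'
#' Branches are straight segments of given length and absolute angle,
#' attached to the end of their parent (`parent = 0` starts at the centre).
#' Lines are drawn with the given thickness.
#'
#' @param branches data.frame with columns `parent` (0 for root branches),
#'   `angle_deg`, `length_um`.
#' @param pixel_size_um pixel size of the rendered mask.
#' @param thickness_px line thickness.
#' @param margin_um empty margin around the tree.
#' @return A list: `mask` (logical matrix), `center` (`c(y_px, x_px)`,
#'   0-based), `pixel_size_um`, `total_length_um` (true summed branch
#'   length).
#' @export
generate_sholl_tree <- function(branches, pixel_size_um = 1,
                                thickness_px = 3L, margin_um = 10) {
  stopifnot(all(c("parent", "angle_deg", "length_um") %in% names(branches)),
            all(branches$length_um > 0),
            all(branches$parent < seq_len(nrow(branches))))
  # build endpoints in um, centre at origin
  start <- matrix(0, nrow(branches), 2)
  end <- matrix(0, nrow(branches), 2)
  for (i in seq_len(nrow(branches))) {
    s <- if (branches$parent[i] == 0) c(0, 0) else end[branches$parent[i], ]
    th <- branches$angle_deg[i] * pi / 180
    start[i, ] <- s
    end[i, ] <- s + branches$length_um[i] * c(cos(th), sin(th))
  }
  allx <- c(start[, 1], end[, 1]); ally <- c(start[, 2], end[, 2])
  lo <- c(min(allx), min(ally)) - margin_um
  hi <- c(max(allx), max(ally)) + margin_um
  nx <- ceiling((hi[1] - lo[1]) / pixel_size_um)
  ny <- ceiling((hi[2] - lo[2]) / pixel_size_um)
  mask <- matrix(FALSE, ny, nx)
  half <- (thickness_px - 1) / 2 * pixel_size_um
  xs <- (seq_len(nx) - 0.5) * pixel_size_um + lo[1]
  ys <- (seq_len(ny) - 0.5) * pixel_size_um + lo[2]
  for (i in seq_len(nrow(branches))) {
    p0 <- start[i, ]; p1 <- end[i, ]
    d <- p1 - p0; L2 <- sum(d^2)
    bx <- range(p0[1], p1[1]) + c(-1, 1) * (half + pixel_size_um)
    by <- range(p0[2], p1[2]) + c(-1, 1) * (half + pixel_size_um)
    jx <- which(xs >= bx[1] & xs <= bx[2])
    jy <- which(ys >= by[1] & ys <= by[2])
    if (!length(jx) || !length(jy)) next
    X <- outer(rep(1, length(jy)), xs[jx])
    Y <- outer(ys[jy], rep(1, length(jx)))
    t <- pmin(pmax(((X - p0[1]) * d[1] + (Y - p0[2]) * d[2]) / L2, 0), 1)
    dist2 <- (X - p0[1] - t * d[1])^2 + (Y - p0[2] - t * d[2])^2
    sub <- dist2 <= max(half, pixel_size_um / 2)^2
    mask[jy, jx] <- mask[jy, jx] | sub
  }
  center_px <- c((0 - lo[2]) / pixel_size_um - 0.5,
                 (0 - lo[1]) / pixel_size_um - 0.5)
  list(mask = mask, center = center_px, pixel_size_um = pixel_size_um,
       total_length_um = sum(branches$length_um))
}
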