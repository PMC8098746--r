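# Seeded synthetic-stack generator with voxel-level ground truth.
#
# The generator emulates the statistical structure of a 20X myelinoid
# acquisition: a shallow stack (12 planes at 1 um), elongated capsule-shaped
# myelin sheath bundles lying mostly in-plane, round somata and small debris
# as distractors in the myelin channel, a dense thin-tube NF-H axon channel
# partially co-located with the sheaths, and additive-plus-shot camera noise.
# Ground truth (class labels and per-object records) is captured before noise.

#' Parameters for the synthetic stack generator
#'
#' Defaults reproduce the acquisition geometry the pipeline targets: 12 um
#' stacks at 1 um z-step, sheath bundles with lengths centred on the mature
#' per-cell mean (87 um) and in-plane breadth ~5 um, somata 8-20 um and
#' debris 4-6 um wide as distractors. All lengths are micrometres, all
#' intensities camera counts at `bit_depth`.
#'
#' @param shape integer `c(z, y, x)` stack shape in voxels.
#' @param pixel_size_um,z_step_um calibration.
#' @param bit_depth camera bit depth.
#' @param n_sheaths number of sheaths.
#' @param sheath_length_mean,sheath_length_sd,sheath_length_range normal
#'   length prior (um), truncated to the range.
#' @param sheath_radius_um tube radius (half in-plane breadth).
#' @param sheath_tilt_max_deg maximum out-of-plane tilt.
#' @param sheath_amplitude,sheath_jitter_sd intensity above background and
#'   per-voxel intensity jitter inside sheaths.
#' @param n_somata,soma_diameter_range,soma_amplitude,soma_jitter_sd soma
#'   distractors: count, diameter range, intensity, internal jitter (low, so
#'   the intensity-SD filter criterion is exercised).
#' @param n_debris,debris_diameter_range,debris_amplitude,debris_jitter_sd
#'   debris distractors (moderate internal jitter).
#' @param n_axons,axon_radius_um,axon_amplitude,axon_sheath_fraction NF-H
#'   channel: thin tubes, a fraction of which run along sheath axes so axonal
#'   density correlates with sheath placement.
#' @param background background level (counts).
#' @param read_noise_sd additive zero-mean read noise SD.
#' @param shot_noise_factor signal-proportional variance term: noise variance
#'   at a voxel is `read_noise_sd^2 + shot_noise_factor * signal`.
#' @param min_gap_um minimum clearance enforced between rendered objects in
#'   the myelin channel (placement by rejection; failures are dropped and
#'   logged).
#' @param max_place_attempts placement attempts per object before dropping.
#' @param seed RNG seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(shape = c(12L, 512L, 512L),
                       pixel_size_um = 0.25, z_step_um = 1,
                       bit_depth = 16L,
                       n_sheaths = 12L,
                       sheath_length_mean = 87, sheath_length_sd = 28,
                       sheath_length_range = c(55, 115),
                       sheath_radius_um = 2.5,
                       sheath_tilt_max_deg = 2,
                       sheath_amplitude = 5000, sheath_jitter_sd = 1400,
                       n_somata = 5L, soma_diameter_range = c(8, 20),
                       soma_amplitude = 4000, soma_jitter_sd = 200,
                       n_debris = 10L, debris_diameter_range = c(4, 6),
                       debris_amplitude = 4500, debris_jitter_sd = 600,
                       n_axons = 40L, axon_radius_um = 0.4,
                       axon_amplitude = 3000, axon_sheath_fraction = 0.5,
                       background = 200,
                       read_noise_sd = 50, shot_noise_factor = 0.5,
                       min_gap_um = 2, max_place_attempts = 500L,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(length(p$shape) == 3L, all(p$shape >= 1L),
            p$pixel_size_um > 0, p$z_step_um > 0,
            p$n_sheaths >= 0, p$n_somata >= 0, p$n_debris >= 0,
            p$n_axons >= 0,
            diff(p$sheath_length_range) >= 0, p$sheath_length_range[1] > 0,
            diff(p$soma_diameter_range) >= 0, p$soma_diameter_range[1] > 0,
            diff(p$debris_diameter_range) >= 0,
            p$debris_diameter_range[1] > 0,
            p$sheath_radius_um > 0, p$axon_radius_um > 0,
            p$background >= 0, p$read_noise_sd >= 0, p$shot_noise_factor >= 0)
  class(p) <- "sim_params"
  p
}

# class codes in the ground-truth label grid; overlap priority is the order
# sheath > soma > debris > axon (lower code wins where classes collide)
GT_CLASSES <- c(sheath = 1L, soma = 2L, debris = 3L, axon = 4L)

#' Generate a synthetic myelinoid stack with ground truth
#'
#' Sheaths are capsules (cylinders with hemispherical caps), somata and debris
#' spheres, axons long thin tubes in the NF-H channel. Object intensities are
#' rendered noise-free first (ground truth is recorded at this point), then
#' read + shot noise is applied and intensities are clipped to the camera
#' range and rounded.
#'
#' @param params a [sim_params()] object.
#' @return A list with elements `stack` (an [image_stack()] with channels
#'   `MBP` and `NFH`) and `truth` (class `ground_truth`: `labels` array
#'   `y x x x z` with codes 0=background, 1=sheath, 2=soma, 3=debris, 4=axon;
#'   `object_ids` array of per-object integer ids; `objects` per-object
#'   data.frame; `class_volumes_um3`; `sheath_volume_um3`;
#'   `nfh_integrated_intensity`; `n_dropped` placement failures).
#' @export
generate_stack <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, generate_stack_impl(params))
}

generate_stack_impl <- function(p) {
  nz <- p$shape[1L]; ny <- p$shape[2L]; nx <- p$shape[3L]
  px <- p$pixel_size_um; zs <- p$z_step_um
  field_y <- ny * px; field_x <- nx * px; field_z <- nz * zs
  myelin <- array(p$background, dim = c(ny, nx, nz))
  nfh <- array(p$background, dim = c(ny, nx, nz))
  labels <- array(0L, dim = c(ny, nx, nz))
  object_ids <- array(0L, dim = c(ny, nx, nz))
  next_id <- 0L

  placed <- list()   # segments: p0, p1 (um, xyz), radius
  objects <- list()
  dropped <- 0L

  # somata up to 20 um wide cannot fit a 12 um-deep stack; spheres are allowed
  # to protrude through the top/bottom plane (clip_z), as they do in real
  # acquisitions, while sheaths must lie fully inside the imaged volume
  place_segment <- function(len, radius, tilt_max_deg, gap, clip_z = FALSE) {
    for (attempt in seq_len(p$max_place_attempts)) {
      theta <- stats::runif(1, 0, pi)
      phi <- stats::runif(1, -1, 1) * tilt_max_deg * pi / 180
      u <- c(cos(theta) * cos(phi), sin(theta) * cos(phi), sin(phi))
      margin <- radius + 0.5
      zlo <- if (clip_z) field_z / 2 - 2 else max(margin, field_z / 2 - 2)
      zhi <- if (clip_z) field_z / 2 + 2 else
        min(field_z - margin, field_z / 2 + 2)
      if (zhi < zlo) { zlo <- field_z / 2; zhi <- field_z / 2 }
      cz <- stats::runif(1, zlo, zhi)
      cx <- stats::runif(1, margin, field_x - margin)
      cy <- stats::runif(1, margin, field_y - margin)
      ctr <- c(cx, cy, cz)
      p0 <- ctr - u * len / 2; p1 <- ctr + u * len / 2
      inside <- all(p0[1:2] > margin) && all(p1[1:2] > margin) &&
        p0[1] < field_x - margin && p1[1] < field_x - margin &&
        p0[2] < field_y - margin && p1[2] < field_y - margin &&
        (clip_z || (p0[3] > margin && p1[3] > margin &&
                    p0[3] < field_z - margin && p1[3] < field_z - margin))
      if (!inside) next
      ok <- TRUE
      for (q in placed) {
        if (seg_seg_dist(p0, p1, q$p0, q$p1) < radius + q$radius + gap) {
          ok <- FALSE; break
        }
      }
      if (ok) return(list(p0 = p0, p1 = p1, radius = radius))
    }
    NULL
  }

  # voxel-center coordinate vectors (0-based indices; centre of voxel i is
  # (i + 0.5) * spacing)
  xs <- (seq_len(nx) - 0.5) * px
  ys <- (seq_len(ny) - 0.5) * px
  zc <- (seq_len(nz) - 0.5) * zs

  render_capsule <- function(seg) {
    # returns integer voxel indices (in the flat y,x,z array) inside the capsule
    r <- seg$radius
    lo <- pmin(seg$p0, seg$p1) - r; hi <- pmax(seg$p0, seg$p1) + r
    jx <- which(xs >= lo[1] & xs <= hi[1])
    jy <- which(ys >= lo[2] & ys <= hi[2])
    jz <- which(zc >= lo[3] & zc <= hi[3])
    if (!length(jx) || !length(jy) || !length(jz)) return(integer(0))
    gx <- xs[jx]; gy <- ys[jy]; gz <- zc[jz]
    d <- seg$p1 - seg$p0
    L2 <- sum(d^2)
    # distance from each grid point to the segment, fully vectorised
    nyb <- length(jy); nxb <- length(jx); nzb <- length(jz)
    X <- array(rep(gx, each = nyb), c(nyb, nxb, nzb))
    Y <- array(gy, c(nyb, nxb, nzb))
    Z <- array(rep(gz, each = nyb * nxb), c(nyb, nxb, nzb))
    wx <- X - seg$p0[1]; wy <- Y - seg$p0[2]; wz <- Z - seg$p0[3]
    t <- if (L2 > 0) pmin(pmax((wx * d[1] + wy * d[2] + wz * d[3]) / L2, 0), 1)
         else 0
    dx <- wx - t * d[1]; dy <- wy - t * d[2]; dz <- wz - t * d[3]
    inside <- dx * dx + dy * dy + dz * dz <= r * r
    idx <- which(inside)
    if (!length(idx)) return(integer(0))
    ai <- arrayInd(idx, c(nyb, nxb, nzb))
    (jz[ai[, 3]] - 1L) * (ny * nx) + (jx[ai[, 2]] - 1L) * ny + jy[ai[, 1]]
  }

  add_object <- function(cls, seg, amplitude, jitter_sd) {
    vox <- render_capsule(seg)
    if (!length(vox)) return(NULL)
    next_id <<- next_id + 1L
    val <- amplitude +
      if (jitter_sd > 0) stats::rnorm(length(vox), 0, jitter_sd) else 0
    if (cls == "axon") {
      nfh[vox] <<- pmax(nfh[vox], p$background + val)
      sel <- labels[vox] == 0L
      labels[vox[sel]] <<- GT_CLASSES[[cls]]
    } else {
      myelin[vox] <<- pmax(myelin[vox], p$background + val)
      sel <- labels[vox] == 0L | labels[vox] > GT_CLASSES[[cls]]
      labels[vox[sel]] <<- GT_CLASSES[[cls]]
    }
    object_ids[vox[sel]] <<- next_id
    ctr <- (seg$p0 + seg$p1) / 2
    data.frame(
      object_id = next_id,
      class = cls, x_um = ctr[1], y_um = ctr[2], z_um = ctr[3],
      length_um = sqrt(sum((seg$p1 - seg$p0)^2)) + 2 * seg$radius,
      radius_um = seg$radius,
      volume_um3 = length(vox) * px^2 * zs)
  }

  # sheaths first (they own the overlap priority), then somata, debris, axons
  sheath_segs <- list()
  for (i in seq_len(p$n_sheaths)) {
    len <- rtrunc_norm(p$sheath_length_mean, p$sheath_length_sd,
                       p$sheath_length_range)
    seg <- place_segment(len, p$sheath_radius_um, p$sheath_tilt_max_deg,
                         p$min_gap_um)
    if (is.null(seg)) { dropped <- dropped + 1L; next }
    placed[[length(placed) + 1L]] <- seg
    sheath_segs[[length(sheath_segs) + 1L]] <- seg
    objects[[length(objects) + 1L]] <-
      add_object("sheath", seg, p$sheath_amplitude, p$sheath_jitter_sd)
  }
  for (i in seq_len(p$n_somata)) {
    d <- stats::runif(1, p$soma_diameter_range[1], p$soma_diameter_range[2])
    seg <- place_segment(0, d / 2, 0, p$min_gap_um, clip_z = TRUE)
    if (is.null(seg)) { dropped <- dropped + 1L; next }
    placed[[length(placed) + 1L]] <- seg
    objects[[length(objects) + 1L]] <-
      add_object("soma", seg, p$soma_amplitude, p$soma_jitter_sd)
  }
  for (i in seq_len(p$n_debris)) {
    d <- stats::runif(1, p$debris_diameter_range[1],
                      p$debris_diameter_range[2])
    seg <- place_segment(0, d / 2, 0, p$min_gap_um, clip_z = TRUE)
    if (is.null(seg)) { dropped <- dropped + 1L; next }
    placed[[length(placed) + 1L]] <- seg
    objects[[length(objects) + 1L]] <-
      add_object("debris", seg, p$debris_amplitude, p$debris_jitter_sd)
  }
  # axons: a fraction run along sheath axes (extended to cross the field),
  # the rest are independent long tubes; axons may overlap anything
  n_along <- min(length(sheath_segs),
                 round(p$n_axons * p$axon_sheath_fraction))
  if (n_along > 0) {
    for (seg in sheath_segs[seq_len(n_along)]) {
      a <- list(p0 = seg$p0, p1 = seg$p1, radius = p$axon_radius_um)
      objects[[length(objects) + 1L]] <-
        add_object("axon", a, p$axon_amplitude, p$axon_amplitude * 0.1)
    }
  }
  for (i in seq_len(max(0L, p$n_axons - n_along))) {
    theta <- stats::runif(1, 0, pi)
    u <- c(cos(theta), sin(theta), 0)
    ctr <- c(stats::runif(1, 0, field_x), stats::runif(1, 0, field_y),
             stats::runif(1, 1, field_z - 1))
    fmin <- 0.9 * min(field_x, field_y)
    len <- stats::runif(1, min(40, fmin / 2), fmin)
    a <- list(p0 = clamp_point(ctr - u * len / 2, field_x, field_y, field_z),
              p1 = clamp_point(ctr + u * len / 2, field_x, field_y, field_z),
              radius = p$axon_radius_um)
    objects[[length(objects) + 1L]] <-
      add_object("axon", a, p$axon_amplitude, p$axon_amplitude * 0.1)
  }
  if (dropped > 0)
    mq_log("generate_stack: dropped %d object(s) after %d placement attempts",
           dropped, p$max_place_attempts)

  objects <- if (length(objects)) do.call(rbind, objects) else
    data.frame(object_id = integer(0), class = character(0),
               x_um = numeric(0), y_um = numeric(0),
               z_um = numeric(0), length_um = numeric(0),
               radius_um = numeric(0), volume_um3 = numeric(0))
  voxvol <- px^2 * zs
  class_volumes <- vapply(names(GT_CLASSES), function(cl)
    sum(labels == GT_CLASSES[[cl]]) * voxvol, numeric(1))
  nfh_true <- sum(nfh[labels == GT_CLASSES[["axon"]]])

  truth <- structure(list(
    labels = labels, object_ids = object_ids, objects = objects,
    class_volumes_um3 = class_volumes,
    sheath_volume_um3 = unname(class_volumes["sheath"]),
    nfh_integrated_intensity = nfh_true,
    n_dropped = dropped), class = "ground_truth")

  vmax <- 2^p$bit_depth - 1
  noisy <- function(v) {
    if (p$read_noise_sd == 0 && p$shot_noise_factor == 0) return(round(v))
    sd <- sqrt(p$read_noise_sd^2 + p$shot_noise_factor * v)
    n <- v + stats::rnorm(length(v), 0, 1) * sd
    round(pmin(pmax(n, 0), vmax))
  }
  vox <- array(0, dim = c(ny, nx, nz, 2L))
  vox[, , , 1L] <- noisy(myelin)
  vox[, , , 2L] <- noisy(nfh)
  stack <- image_stack(vox, px, zs, c("MBP", "NFH"), p$bit_depth)
  list(stack = stack, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", nrow(x$objects), "objects;",
      sprintf("sheath volume %.1f um^3", x$sheath_volume_um3), "\n")
  print(table(x$objects$class))
  invisible(x)
}

rtrunc_norm <- function(mean, sd, range) {
  for (i in 1:1000) {
    v <- stats::rnorm(1, mean, sd)
    if (v >= range[1] && v <= range[2]) return(v)
  }
  stats::runif(1, range[1], range[2])
}

clamp_point <- function(pt, fx, fy, fz) {
  c(min(max(pt[1], 0.5), fx - 0.5), min(max(pt[2], 0.5), fy - 0.5),
    min(max(pt[3], 0.5), fz - 0.5))
}

#' Minimum distance between two 3D segments
#' @noRd
seg_seg_dist <- function(a0, a1, b0, b1) {
  u <- a1 - a0; v <- b1 - b0; w <- a0 - b0
  a <- sum(u * u); b <- sum(u * v); cc <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  D <- a * cc - b * b
  sc <- sN <- sD <- D
  tc <- tN <- tD <- D
  eps <- 1e-12
  if (D < eps) {
    sN <- 0; sD <- 1; tN <- e; tD <- cc
    if (cc < eps) { tN <- 0; tD <- 1 }  # both segments degenerate to points
  }
  else {
    sN <- b * e - cc * d; tN <- a * e - b * d
    if (sN < 0) { sN <- 0; tN <- e; tD <- cc }
    else if (sN > sD) { sN <- sD; tN <- e + b; tD <- cc }
  }
  if (tN < 0) {
    tN <- 0
    if (-d < 0) sN <- 0 else if (-d > a) sN <- sD else { sN <- -d; sD <- a }
  } else if (tN > tD) {
    tN <- tD
    if ((-d + b) < 0) sN <- 0 else if ((-d + b) > a) sN <- sD
    else { sN <- -d + b; sD <- a }
  }
  sc <- if (abs(sN) < eps) 0 else sN / sD
  tc <- if (abs(tN) < eps) 0 else tN / tD
  dP <- w + sc * u - tc * v
  sqrt(sum(dP * dP))
}
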