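# Shared fixture builders. Everything is generated in code; silence the
# package logger during tests.
mq_log_file(tempfile(fileext = ".log"))

# rectangular bar mask (h x w px) inside a zero plane
bar_mask <- function(ny, nx, y0, x0, h, w) {
  m <- matrix(FALSE, ny, nx)
  m[y0:(y0 + h - 1L), x0:(x0 + w - 1L)] <- TRUE
  m
}

# isotropic Gaussian spot image: amplitude * exp(-r^2 / (2 sigma_um^2))
gaussian_spot <- function(n_px, pixel_size_um, center_um, width_um,
                          amplitude = 4000) {
  xs <- (seq_len(n_px) - 0.5) * pixel_size_um
  sig <- width_um / (2 * sqrt(2))
  amplitude * exp(-outer((xs - center_um[1])^2, (xs - center_um[2])^2,
                         "+") / (2 * sig^2))
}

# filled disc mask
disc_mask <- function(ny, nx, cy, cx, r_px) {
  outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, "+") <= r_px^2
}

# long-form trace table from a list of polylines (each a 2-col matrix, um)
traces_from_polylines <- function(polys, myelinoid_id = "m1",
                                  cell_id = "c1") {
  do.call(rbind, lapply(seq_along(polys), function(i) {
    p <- polys[[i]]
    data.frame(myelinoid_id = myelinoid_id, cell_id = cell_id,
               sheath_id = i, point_index = seq_len(nrow(p)),
               x_um = p[, 1], y_um = p[, 2])
  }))
}

# straight-line polyline of a given length along x
straight_polyline <- function(length_um) {
  cbind(c(0, length_um), c(0, 0))
}

# small easy-regime simulation parameters (fast unit-test scale);
# `...` overrides the fixture defaults
small_sim_params <- function(seed, ...) {
  args <- list(shape = c(12L, 384L, 384L), n_sheaths = 8L,
               sheath_length_range = c(55, 90), n_somata = 3L,
               n_debris = 6L, n_axons = 20L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_params, args)
}

# brute-force 26-connected 3D labeling (flood fill); oracle for
# connect_touching_3d
brute_label_3d <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  cur <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      a <- arrayInd(v, dims)
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        y <- a[1L] + dy; x <- a[2L] + dx; z <- a[3L] + dz
        if (y < 1 || y > dims[1L] || x < 1 || x > dims[2L] ||
            z < 1 || z > dims[3L]) next
        w <- (z - 1L) * dims[1L] * dims[2L] + (x - 1L) * dims[1L] + y
        if (mask[w] && lab[w] == 0L) { lab[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  lab
}

# brute-force neighbor counts within radius (inclusive), self excluded
brute_neighbor_counts <- function(x, y, myel, radius) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    s <- 0L
    for (j in seq_len(n)) {
      if (j == i || !myel[j]) next
      if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= radius) s <- s + 1L
    }
    s
  }, integer(1))
}
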