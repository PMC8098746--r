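# Internal helpers: seeded RNG scopes, hashing, logging, and the small image
# primitives (box means, separable Gaussian smoothing, union-find labeling)
# shared by the segmentation and simulation code.

#' Evaluate an expression under a fixed RNG seed, restoring the caller's state
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Stable md5 hash of an R object (used to stamp parameter sets into outputs)
#' @noRd
param_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

#' Minimal timestamped logger. `mq_log_file(path)` redirects messages to a file
#' for the rest of the session (or until called with NULL).
#' @param path File to append log lines to, or `NULL` to log to the console.
#' @return Invisibly, the previously configured path.
#' @export
mq_log_file <- function(path = NULL) {
  old <- .mq_state$log_file
  .mq_state$log_file <- path
  invisible(old)
}

.mq_state <- new.env(parent = emptyenv())
.mq_state$log_file <- NULL

mq_log <- function(fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(fmt, ...))
  if (!is.null(.mq_state$log_file)) {
    cat(line, "\n", file = .mq_state$log_file, append = TRUE, sep = "")
  } else {
    message(line)
  }
  invisible(line)
}

# ---- image primitives -------------------------------------------------------

#' Local mean over a (2r+1)x(2r+1) box with reflective padding, via summed-area
#' tables. Exact (no approximation at the borders).
#' @noRd
box_mean <- function(m, radius) {
  r <- as.integer(radius)
  stopifnot(r >= 0)
  if (r == 0L) return(m)
  mp <- pad_reflect(m, r)
  # summed-area table with a zero first row/col
  s <- rbind(0, cbind(0, mp))
  s <- apply(s, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  n <- (2L * r + 1L)
  ny <- nrow(m); nx <- ncol(m)
  i1 <- 1:ny; i2 <- i1 + 2L * r
  j1 <- 1:nx; j2 <- j1 + 2L * r
  (s[i2 + 1L, j2 + 1L, drop = FALSE] - s[i1, j2 + 1L, drop = FALSE] -
     s[i2 + 1L, j1, drop = FALSE] + s[i1, j1, drop = FALSE]) / (n * n)
}

#' Reflective padding of a matrix by r rows/cols on each side. Mirror-101
#' boundary, applied periodically so r may exceed the image extent.
#' @noRd
pad_reflect <- function(m, r) {
  iy <- reflect_idx(seq(1L - r, nrow(m) + r), nrow(m))
  ix <- reflect_idx(seq(1L - r, ncol(m) + r), ncol(m))
  m[iy, ix, drop = FALSE]
}

reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  j <- ifelse(j >= n, period - j, j)
  j + 1L
}

#' Separable Gaussian smoothing (reflective borders), kernel truncated at 3 sigma
#' @noRd
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  mp <- pad_reflect(m, r)
  # filter along rows then columns; stats::filter works column-wise
  sm <- stats::filter(mp, k, sides = 2)
  sm <- t(stats::filter(t(sm), k, sides = 2))
  sm[(r + 1L):(r + nrow(m)), (r + 1L):(r + ncol(m)), drop = FALSE]
}

#' Bank of Gaussian-smoothed copies of a matrix, computed in the frequency
#' domain: the image is reflect-padded once (to a 2-3-5-smooth size), Fourier
#' transformed once, and multiplied by the analytic Gaussian transfer
#' function per scale. Equivalent to separable spatial convolution with
#' reflective borders up to wrap-around at > 3 sigma.
#' @param m matrix
#' @param sigmas vector of Gaussian SDs in pixels
#' @return list of smoothed matrices, one per sigma
#' @noRd
gauss_bank <- function(m, sigmas) {
  ny <- nrow(m); nx <- ncol(m)
  r <- as.integer(ceiling(3 * max(sigmas)))
  tn_y <- stats::nextn(ny + 2L * r, c(2L, 3L, 5L))
  tn_x <- stats::nextn(nx + 2L * r, c(2L, 3L, 5L))
  ry0 <- (tn_y - ny) %/% 2L; ry1 <- tn_y - ny - ry0
  rx0 <- (tn_x - nx) %/% 2L; rx1 <- tn_x - nx - rx0
  iy <- reflect_idx(seq(1L - ry0, ny + ry1), ny)
  ix <- reflect_idx(seq(1L - rx0, nx + rx1), nx)
  P <- m[iy, ix, drop = FALSE]
  FP <- stats::fft(P)
  fy <- seq_len(tn_y) - 1L; fy <- ifelse(fy > tn_y / 2, fy - tn_y, fy) / tn_y
  fx <- seq_len(tn_x) - 1L; fx <- ifelse(fx > tn_x / 2, fx - tn_x, fx) / tn_x
  f2 <- outer(fy^2, fx^2, "+")
  lapply(sigmas, function(s) {
    S <- Re(stats::fft(FP * exp(-2 * pi^2 * s^2 * f2), inverse = TRUE)) /
      (tn_y * tn_x)
    S[ry0 + seq_len(ny), rx0 + seq_len(nx), drop = FALSE]
  })
}

#' Block-mean downsampling by integer factor (trailing partial blocks dropped)
#' @noRd
block_mean <- function(m, f) {
  f <- as.integer(f)
  if (f <= 1L) return(m)
  ny <- (nrow(m) %/% f) * f
  nx <- (ncol(m) %/% f) * f
  m <- m[seq_len(ny), seq_len(nx), drop = FALSE]
  a <- array(m, dim = c(f, ny %/% f, f, nx %/% f))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}

# ---- union-find -------------------------------------------------------------

#' Resolve a set of equivalence pairs over labels 1..n into a relabeling that
#' maps each label to the smallest label of its class, then compacts to 1..k.
#' @param n number of labels
#' @param pairs 2-column integer matrix of equivalent label pairs (may be empty)
#' @return integer vector `map` of length n with compact class ids
#' @noRd
uf_resolve <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, sort(unique(roots)))
}

#' Unique label-adjacency pairs between two equally sized label matrices under
#' a set of integer (dy, dx) offsets. Used for 8-connectivity completion and
#' cross-plane overlap connection.
#' @noRd
label_pairs <- function(a, b, offsets) {
  ny <- nrow(a); nx <- ncol(a)
  out <- vector("list", nrow(offsets))
  for (k in seq_len(nrow(offsets))) {
    dy <- offsets[k, 1L]; dx <- offsets[k, 2L]
    ia <- seq_len(ny - abs(dy)); ja <- seq_len(nx - abs(dx))
    if (dy > 0) ia <- ia + dy
    if (dx > 0) ja <- ja + dx
    ib <- ia - dy; jb <- ja - dx
    va <- a[ia, ja]; vb <- b[ib, jb]
    sel <- va > 0L & vb > 0L
    if (any(sel)) out[[k]] <- cbind(va[sel], vb[sel])
  }
  prs <- do.call(rbind, out)
  if (is.null(prs)) return(matrix(integer(0), 0, 2))
  # de-duplicate through scalar keys (unique() on a matrix is slow)
  key <- unique(prs[, 1L] * 2^26 + prs[, 2L])
  cbind(as.integer(key %/% 2^26), as.integer(key %% 2^26))
}

#' 8-connected labeling of a binary matrix. EBImage::bwlabel gives 4-connected
#' components; diagonal adjacencies are merged on top with a union-find.
#' @noRd
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask != 0)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n == 0L) return(lab)
  prs <- label_pairs(lab, lab, rbind(c(1L, 1L), c(1L, -1L)))
  prs <- prs[prs[, 1L] != prs[, 2L], , drop = FALSE]
  if (nrow(prs) == 0L) return(lab)
  map <- uf_resolve(n, prs)
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  out
}

#' Exact Otsu threshold on non-negative integer-valued data. Returns the
#' threshold t maximizing between-class variance for the split x <= t vs x > t.
#' @noRd
otsu_threshold <- function(x) {
  x <- as.integer(round(x))
  lev <- sort(unique(x))
  if (length(lev) < 2L) return(if (length(lev)) lev[1L] else 0L)
  cnt <- tabulate(match(x, lev))
  p <- cnt / sum(cnt)
  w <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[length(mu)]
  bc <- (mu_t * w - mu)^2 / (w * (1 - w))
  bc[!is.finite(bc)] <- -Inf
  lev[which.max(bc)]
}

#' Convert a micrometre length to integer pixels, rounding half up
#' @noRd
um_to_px <- function(um, pixel_size_um) {
  as.integer(floor(um / pixel_size_um + 0.5))
}

#' Disc structuring element of a given integer pixel radius
#' @noRd
disc_brush <- function(radius_px) {
  EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
}
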