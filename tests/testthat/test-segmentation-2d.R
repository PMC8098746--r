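test_that("adaptive threshold matches a brute-force local-mean oracle", {
  set.seed(4)
  plane <- matrix(round(runif(28 * 24, 0, 2000)), 28, 24)
  r <- 3L; off <- 150
  got <- adaptive_threshold(plane, r, off)
  # brute force with reflective (mirror-101) borders
  ref <- function(i, n) { # 1-based mirror
    j <- (i - 1) %% (2 * (n - 1)); ifelse(j >= n, 2 * (n - 1) - j, j) + 1 }
  want <- matrix(FALSE, 28, 24)
  for (i in 1:28) for (j in 1:24) {
    vals <- plane[cbind(rep(ref(seq(i - r, i + r), 28), each = 2 * r + 1),
                        rep(ref(seq(j - r, j + r), 24), times = 2 * r + 1))]
    want[i, j] <- plane[i, j] > mean(vals) + off
  }
  expect_identical(got, want)
})

test_that("adaptive threshold degenerate planes give empty masks", {
  expect_false(any(adaptive_threshold(matrix(0, 16, 16), 3, 10)))
  expect_false(any(adaptive_threshold(matrix(500, 16, 16), 3, 1)))
  # bright bar on zero background is fully foreground
  plane <- matrix(0, 20, 20); plane[10:11, 5:14] <- 1000
  m <- adaptive_threshold(plane, 5, 50)
  expect_true(all(m[plane > 0]))
})

test_that("fiber model is exact on ideal rectangles and squares", {
  # 10x2 px bar at 1 um/px: A=20, P=24, L=10, B=2
  m <- bar_mask(20, 20, 5, 4, 2, 10)
  plane <- matrix(0, 20, 20); plane[m] <- 777
  meas <- measure_objects_2d(m, plane, 1)
  expect_equal(meas$area_um2, 20)
  expect_equal(meas$perimeter_um, 24)
  expect_equal(meas$fiber_length_um, 10)
  expect_equal(meas$fiber_breadth_um, 2)
  expect_equal(meas$intensity_sd, 0)   # constant intensity

  # 5x5 square: L = B = 5, EFF = 1
  sq <- bar_mask(12, 12, 4, 4, 5, 5)
  ms <- measure_objects_2d(sq, sq * 1.0, 1)
  expect_equal(ms$fiber_length_um, 5)
  expect_equal(ms$fiber_breadth_um, 5)
  expect_equal(ms$eff, 1)
})

test_that("rectangle measures follow closed forms for random sizes/scales", {
  set.seed(9)
  for (i in 1:10) {
    h <- sample(1:6, 1); w <- sample(h:20, 1); px <- sample(c(0.25, 0.5, 1), 1)
    m <- bar_mask(30, 30, 3, 3, h, w)
    meas <- measure_objects_2d(m, m * 1.0, px)
    expect_equal(meas$area_um2, h * w * px^2)
    expect_equal(meas$perimeter_um, 2 * (h + w) * px)
    expect_equal(meas$fiber_length_um, max(h, w) * px)
    expect_equal(meas$fiber_breadth_um, min(h, w) * px)
  }
})

test_that("areas scale as s^2 when pixel size scales by s", {
  m <- bar_mask(20, 20, 5, 4, 3, 9)
  a1 <- measure_objects_2d(m, m * 1.0, 0.5)$area_um2
  a2 <- measure_objects_2d(m, m * 1.0, 1.0)$area_um2
  expect_equal(a2 / a1, 4)
})

test_that("filter mask 1 removes wide, short, or small objects (strictly)", {
  px <- 1
  plane <- matrix(0, 64, 130)
  keep <- bar_mask(64, 130, 2, 2, 3, 30)      # L=30 B=3 A=90: retained
  short <- bar_mask(64, 130, 10, 2, 6, 8)     # L=8 < 10: removed
  wide <- bar_mask(64, 130, 20, 2, 17, 40)    # B=17 > 16: removed
  small <- bar_mask(64, 130, 45, 2, 2, 22)    # A=44 < 45: removed
  at45 <- bar_mask(64, 130, 52, 2, 3, 15)     # A=45 exactly: retained
  m <- keep | short | wide | small | at45
  meas <- measure_objects_2d(m, plane, px)
  out <- filter_mask_1(meas, seg_params())
  expect_true(all(out[keep]) && all(out[at45]))
  expect_false(any(out[short]) || any(out[wide]) || any(out[small]))
})

test_that("shrink is erosion by a disc, removing over-eroded objects", {
  m3 <- bar_mask(12, 12, 5, 5, 3, 3)
  expect_false(any(shrink_objects(m3, 4)))
  m20 <- bar_mask(40, 40, 11, 11, 20, 20)
  s <- shrink_objects(m20, 4)
  expect_equal(sum(s), 144)                       # 12 x 12
  expect_equal(range(which(rowSums(s) > 0)), c(15, 26))
  expect_identical(shrink_objects(m20, 0), m20)
})

test_that("filter mask 2 removes round, wide, or uniform objects", {
  px <- 0.5
  set.seed(7)
  plane <- matrix(0, 80, 80)
  elong <- bar_mask(80, 80, 4, 4, 2, 40)       # B=1um, EFF~10
  plane[elong] <- 20000 + rnorm(sum(elong), 0, 3000)
  disc <- disc_mask(80, 80, 40, 20, 8)         # round: EFF ~ 1
  plane[disc] <- 20000 + rnorm(sum(disc), 0, 3000)
  flat <- bar_mask(80, 80, 60, 4, 2, 40)       # sd = 0
  plane[flat] <- 20000
  plane <- pmin(plane, 65535)
  m <- elong | disc | flat
  meas <- measure_objects_2d(m, plane, px)
  out <- filter_mask_2(meas, seg_params(), bit_depth = 16L)
  expect_true(all(out[elong]))
  expect_false(any(out[disc]))
  expect_false(any(out[flat]))
})

test_that("intensity SD threshold rescales with bit depth", {
  px <- 0.5
  set.seed(12)
  plane <- matrix(0, 40, 90)
  elong <- bar_mask(40, 90, 4, 4, 2, 80)
  # sd ~ 12 at 8 bit corresponds to ~ 3084 at 16 bit: retained at 8 bit
  plane[elong] <- pmin(pmax(128 + rnorm(sum(elong), 0, 12), 0), 255)
  meas <- measure_objects_2d(elong, plane, px)
  expect_true(any(filter_mask_2(meas, seg_params(), bit_depth = 8L)))
  expect_false(any(filter_mask_2(meas, seg_params(), bit_depth = 16L)))
})

test_that("keep marked objects retains full mask1 extent on any overlap", {
  o1 <- bar_mask(30, 30, 2, 2, 3, 20)
  o2 <- bar_mask(30, 30, 10, 2, 3, 20)
  m1 <- o1 | o2
  m2 <- bar_mask(30, 30, 3, 5, 1, 4)     # overlaps only o1, partially
  out <- keep_marked_objects(m1, m2)
  expect_identical(unname(as.vector(out)), as.vector(o1))
  expect_false(any(keep_marked_objects(m1, matrix(FALSE, 30, 30))))
  expect_identical(unname(as.vector(keep_marked_objects(m1, m1))),
                   as.vector(m1))
})

test_that("conjunctive filter logic is available as the configured switch", {
  plane <- matrix(0, 64, 130)
  short_small <- bar_mask(64, 130, 10, 2, 6, 8)   # L=8, A=48: or-removed
  meas <- measure_objects_2d(short_small, plane, 1)
  expect_false(any(filter_mask_1(meas, seg_params())))
  # under AND logic the object survives: not all criteria fire
  expect_true(any(filter_mask_1(meas, seg_params(filter_logic = "and"))))
})

test_that("blob detection finds isolated round blobs at the right scale", {
  img <- gaussian_spot(200, 0.5, c(50, 50), 10)
  b <- find_blobs(img, c(8, 100), 0.5, seg_params())
  expect_equal(nrow(b$detections), 1L)
  # truth centre: 50 um -> 0-based pixel 99.5
  expect_lt(max(abs(c(b$detections$y_px, b$detections$x_px) - 99.5)), 1)
  expect_lt(abs(b$detections$diameter_um - 10) / 10, 0.25)

  # a 2 um blob lies outside the 8-100 um search range
  img2 <- gaussian_spot(200, 0.5, c(50, 50), 2)
  expect_equal(nrow(find_blobs(img2, c(8, 100), 0.5,
                               seg_params())$detections), 0L)
  # blank plane
  expect_false(any(find_blobs(matrix(0, 64, 64), c(8, 100), 0.5,
                              seg_params())$mask))
})

test_that("elongated ridges are not reported as blobs", {
  set.seed(5)
  plane <- matrix(0, 200, 200)
  tube <- bar_mask(200, 200, 95, 10, 10, 180)  # 5 um x 90 um at 0.5 um/px
  plane[tube] <- 4000
  plane <- plane + matrix(rnorm(200 * 200, 0, 60), 200)
  expect_equal(nrow(find_blobs(plane, c(4, 6), 0.5,
                               seg_params())$detections), 0L)
  expect_equal(nrow(find_blobs(plane, c(8, 100), 0.5,
                               seg_params())$detections), 0L)
})

test_that("blob subtraction removes only the enlarged blob footprint", {
  mask <- bar_mask(60, 60, 28, 5, 4, 50)
  blob <- disc_mask(60, 60, 30, 45, 6)
  # enlarge 0: exact set subtraction
  out0 <- subtract_blobs(mask, blob, 0)
  expect_identical(out0, mask & !blob)
  # enlargement by 5 px: pixels within Euclidean distance 4.9 of the blob
  # are removed, pixels beyond 6.5 persist
  out5 <- subtract_blobs(mask, blob, 5)
  dist_to_blob <- function(i, j) {
    bidx <- which(blob, arr.ind = TRUE)
    min(sqrt((bidx[, 1] - i)^2 + (bidx[, 2] - j)^2))
  }
  idx <- which(mask, arr.ind = TRUE)
  d <- vapply(seq_len(nrow(idx)),
              function(k) dist_to_blob(idx[k, 1], idx[k, 2]), numeric(1))
  expect_false(any(out5[idx[d <= 4.9, , drop = FALSE]]))
  expect_true(all(out5[idx[d > 6.5, , drop = FALSE]]))
  # blob disjoint from the mask leaves it unchanged
  far <- disc_mask(60, 60, 10, 10, 3)
  expect_identical(subtract_blobs(mask, far & !mask, 5), mask)
  # blob covering the entire object removes it
  expect_false(any(subtract_blobs(disc_mask(60, 60, 30, 30, 5),
                                  disc_mask(60, 60, 30, 30, 8), 5)))
})
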