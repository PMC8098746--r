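test_that("sheath summaries compute per-cell counts and arc lengths", {
  tr <- traces_from_polylines(list(straight_polyline(40),
                                   straight_polyline(60)))
  s <- sheath_summaries(tr)
  expect_equal(s$sheath_count, 2L)
  expect_equal(s$mean_length_um, 50)

  # 3-4-5 triangle polyline
  tr2 <- traces_from_polylines(list(cbind(c(0, 3), c(0, 4))))
  expect_equal(sheath_summaries(tr2)$mean_length_um, 5)
})

test_that("summaries reproduce the reported central tendencies of mature cells", {
  # three cells with 5, 13 and 21 sheaths (mean 13) whose per-cell mean
  # lengths are 80, 87 and 94 um (mean 87)
  mk_cell <- function(cell, n, mean_len) {
    lens <- seq(mean_len - 10, mean_len + 10, length.out = n)
    do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(myelinoid_id = "m1", cell_id = cell, sheath_id = i,
                 point_index = 1:2, x_um = c(0, lens[i]), y_um = 0)))
  }
  tr <- rbind(mk_cell("c1", 5, 80), mk_cell("c2", 13, 87),
              mk_cell("c3", 21, 94))
  s <- sheath_summaries(tr)
  expect_equal(mean(s$sheath_count), 13)
  expect_equal(mean(s$mean_length_um), 87)
})

test_that("length histogram uses left-closed bins and sums to 100", {
  h <- length_histogram(c(5, 15, 15, 25), 10)
  expect_equal(h$percent, c(25, 50, 25))
  expect_equal(h$bin_low_um, c(0, 10, 20))
  h1 <- length_histogram(42, 10)
  expect_equal(sum(h1$percent), 100)
  set.seed(2)
  for (i in 1:5) {
    lens <- runif(sample(5:50, 1), 0, 150)
    expect_equal(sum(length_histogram(lens, sample(c(5, 10, 25), 1))$percent),
                 100)
  }
})

test_that("neighbor counts match brute force, excluding self, inclusive edge", {
  ct <- validate_centroids(data.frame(
    myelinoid_id = "m1", cell_id = 1:3, x_um = c(0, 50, 120), y_um = 0,
    is_myelinating = TRUE))
  expect_equal(nearest_neighbor_density(ct, 100)$n_neighbors, c(1L, 2L, 1L))

  single <- validate_centroids(data.frame(
    myelinoid_id = "m1", cell_id = 1, x_um = 0, y_um = 0,
    is_myelinating = TRUE))
  expect_equal(nearest_neighbor_density(single, 100)$n_neighbors, 0L)

  # boundary: a cell exactly at distance 100 is counted
  edge <- validate_centroids(data.frame(
    myelinoid_id = "m1", cell_id = 1:2, x_um = c(0, 100), y_um = 0,
    is_myelinating = TRUE))
  expect_equal(nearest_neighbor_density(edge, 100)$n_neighbors, c(1L, 1L))

  # non-myelinating cells are never counted as neighbours
  mixed <- validate_centroids(data.frame(
    myelinoid_id = "m1", cell_id = 1:3, x_um = c(0, 10, 20), y_um = 0,
    is_myelinating = c(TRUE, FALSE, TRUE)))
  expect_equal(nearest_neighbor_density(mixed, 100)$n_neighbors,
               c(1L, 2L, 1L))

  set.seed(14)
  for (i in 1:10) {
    n <- sample(2:40, 1)
    x <- runif(n, 0, 400); y <- runif(n, 0, 400)
    myel <- runif(n) < 0.7
    ct <- validate_centroids(data.frame(
      myelinoid_id = "m1", cell_id = seq_len(n), x_um = x, y_um = y,
      is_myelinating = myel))
    expect_equal(nearest_neighbor_density(ct, 100)$n_neighbors,
                 brute_neighbor_counts(x, y, myel, 100))
  }
})

test_that("sholl counts one intersection per crossing process", {
  # straight process of 100 um from the centre
  tree <- generate_sholl_tree(
    data.frame(parent = 0L, angle_deg = 0, length_um = 100))
  sh <- sholl(tree$mask, tree$center, tree$pixel_size_um, 10, 90)
  expect_equal(sh$intersections, rep(1L, 9))

  # Y: stem of 50 um branching into two arms
  ytree <- generate_sholl_tree(
    data.frame(parent = c(0L, 1L, 1L), angle_deg = c(90, 60, 120),
               length_um = c(50, 60, 60)))
  shy <- sholl(ytree$mask, ytree$center, ytree$pixel_size_um, 10, 100)
  expect_true(all(shy$intersections[shy$radii_um < 45] == 1L))
  expect_true(all(shy$intersections[shy$radii_um > 55 &
                                      shy$radii_um < 95] == 2L))
  expect_equal(round(ytree$total_length_um), 170)

  # empty mask: all zeros, no outgrowth
  sh0 <- sholl(matrix(FALSE, 50, 50), c(25, 25), 1, 10, 40)
  expect_true(all(sh0$intersections == 0L))
  expect_equal(sh0$total_outgrowth_um, 0)
})

test_that("sholl intersections are invariant to translation and rotation", {
  ytree <- generate_sholl_tree(
    data.frame(parent = c(0L, 1L, 1L), angle_deg = c(90, 60, 120),
               length_um = c(40, 50, 50)), margin_um = 30)
  base <- sholl(ytree$mask, ytree$center, 1, 10, 80)$intersections
  # translate by padding
  pad <- rbind(matrix(FALSE, 7, ncol(ytree$mask)), ytree$mask)
  pad <- cbind(matrix(FALSE, nrow(pad), 5), pad)
  tr <- sholl(pad, ytree$center + c(7, 5), 1, 10, 80)$intersections
  expect_equal(tr, base)
  # rotate 90 degrees: transpose + reverse rows
  rot <- t(ytree$mask)[rev(seq_len(ncol(ytree$mask))), ]
  ctr_rot <- c(ncol(ytree$mask) - 1 - ytree$center[2], ytree$center[1])
  ro <- sholl(rot, ctr_rot, 1, 10, 80)$intersections
  expect_equal(ro, base)
})

test_that("g-ratio regression recovers exact and degenerate coefficients", {
  tab <- generate_gratio_table(a = 0.6, b = 0.05, noise_sd = 0, n = 30L,
                               seed = 6L)
  fit <- gratio_fit(tab)
  expect_equal(unname(coef(fit)), c(0.6, 0.05), tolerance = 1e-10)
  expect_lt(fit$residual_sd, 1e-10)

  flat <- data.frame(axon_diameter_um = c(1, 2, 3, 4), g = 0.7)
  ffit <- gratio_fit(flat)
  expect_equal(unname(coef(ffit)["b"]), 0, tolerance = 1e-12)

  # g always in (0, 1) when axon < fiber; residuals mean-zero
  rec <- gratio_records(c(1, 2, 3), c(2, 3, 5))
  expect_true(all(rec$g > 0 & rec$g < 1))
  noisy <- generate_gratio_table(seed = 2L)
  nf <- gratio_fit(noisy)
  expect_lt(abs(mean(residuals(nf$lm))), 1e-12)
  expect_error(gratio_records(c(-1, 2), c(2, 3)), "positive")
  expect_error(gratio_fit(data.frame(axon_diameter_um = 1:2, g = c(.5, .6))),
               "nrow")
})
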