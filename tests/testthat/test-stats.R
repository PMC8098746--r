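mk_table <- function(values, groups, myelinoids, batches,
                     images = seq_along(values)) {
  data.frame(value = values, unit = "norm", myelinoid_id = myelinoids,
             batch = batches, group = groups, image_id = images)
}

test_that("aggregation to myelinoid level averages images", {
  tab <- mk_table(c(10, 20, 30, 50), c("A", "A", "A", "A"),
                  c("m1", "m1", "m2", "m2"), "b1", c(1, 2, 1, 2))
  agg <- aggregate_measurements(tab, "myelinoid")
  expect_equal(sort(agg$value), c(15, 40))
  # idempotent at the same level
  agg2 <- aggregate_measurements(transform(agg, image_id = 1), "myelinoid")
  expect_equal(sort(agg2$value), c(15, 40))
  # grand mean equals raw mean with equal per-unit counts
  expect_equal(mean(agg$value), mean(tab$value))
  expect_error(aggregate_measurements(transform(tab, unit = c(
    "a", "a", "b", "b"))), "mixed units")
})

test_that("batch-control normalization maps control means to 1", {
  tab <- mk_table(c(2, 4, 6), c("Ctrl", "Ctrl", "Treated"),
                  c("m1", "m2", "m3"), "b1")
  norm <- normalize_to_batch_control(tab, "Ctrl")
  expect_equal(norm$value[norm$group == "Ctrl"], c(2 / 3, 4 / 3))
  expect_equal(norm$value[norm$group == "Treated"], 2)

  # all-control table: every batch mean is exactly 1
  tab2 <- mk_table(c(3, 5, 7, 9), "Ctrl", paste0("m", 1:4),
                   c("b1", "b1", "b2", "b2"))
  norm2 <- normalize_to_batch_control(tab2, "Ctrl")
  expect_equal(as.numeric(tapply(norm2$value, norm2$batch, mean)),
               c(1, 1))

  # scale invariance within batch
  tab3 <- transform(tab, value = value * 17)
  expect_equal(normalize_to_batch_control(tab3, "Ctrl")$value, norm$value)

  expect_error(normalize_to_batch_control(
    mk_table(1, "Treated", "m1", "b9"), "Ctrl"), "b9")
})

test_that("fold change is exact in degenerate designs", {
  tab <- mk_table(rep(c(1, 2), each = 4), rep(c("Ctrl", "Treated"), each = 4),
                  paste0("m", rep(1:4, each = 2)),
                  "b1", rep(1:2, 4))
  fc <- fold_change_bootstrap(tab, reps = 200L, seed = 1L)
  expect_equal(fc$ratio, 2)
  expect_equal(fc$ci, c(2, 2))

  same <- mk_table(rep(c(1, 1.3, 0.8, 1.1), 2),
                   rep(c("Ctrl", "Treated"), each = 4),
                   paste0("m", 1:8), rep(c("b1", "b2"), 4), rep(1, 8))
  fc1 <- fold_change_bootstrap(same, reps = 500L, seed = 2L)
  expect_lt(fc1$ci[1], 1)
  expect_gt(fc1$ci[2], 1)
  expect_true(fc1$ci[1] <= fc1$ratio && fc1$ratio <= fc1$ci[2])
})

test_that("bootstrap estimate and CI are equivariant under scaling group B", {
  set.seed(3)
  tab <- generate_group_data(group_sim_params(fold_change = 1.5, seed = 9L))
  f1 <- fold_change_bootstrap(tab, reps = 400L, seed = 5L)
  tab2 <- tab
  tab2$value[tab2$group == "Treated"] <- 3 * tab2$value[tab2$group ==
                                                          "Treated"]
  f2 <- fold_change_bootstrap(tab2, reps = 400L, seed = 5L)
  expect_equal(f2$ratio, 3 * f1$ratio, tolerance = 1e-12)
  expect_equal(f2$ci, 3 * f1$ci, tolerance = 1e-12)
})

test_that("non-positive values fall back to arithmetic-mean ratio", {
  tab <- mk_table(c(0, 2, 4, 8), rep(c("Ctrl", "Treated"), each = 2),
                  paste0("m", 1:4), "b1", rep(1, 4))
  expect_warning(fc <- fold_change_bootstrap(tab, reps = 100L, seed = 1L),
                 "arithmetic")
  expect_equal(fc$ratio, 6)
})

test_that("bootstrap agrees with a lognormal mixed model on balanced data", {
  skip_if_not_installed("glmmTMB")
  tab <- generate_group_data(group_sim_params(fold_change = 2, seed = 11L))
  fc <- fold_change_bootstrap(tab, reps = 500L, seed = 4L)
  df <- glmm_export(aggregate_measurements(tab, "myelinoid"))
  fit <- glmmTMB::glmmTMB(log_value ~ group + (1 | batch), data = df)
  beta <- glmmTMB::fixef(fit)$cond[["groupTreated"]]
  expect_equal(log(fc$ratio), beta, tolerance = 0.02)
})

test_that("Tukey box summary follows the type-7 quartile convention", {
  b <- tukey_box_summary(1:9)
  expect_equal(b$median, 5)
  expect_equal(b$q1, 3)
  expect_equal(b$q3, 7)
  expect_equal(b$whisker_low, 1)
  expect_equal(b$whisker_high, 9)
  expect_equal(length(b$outliers), 0L)

  cb <- tukey_box_summary(rep(4.2, 5))
  expect_equal(unlist(cb[c("median", "q1", "q3", "whisker_low",
                           "whisker_high")]),
               setNames(rep(4.2, 5), c("median", "q1", "q3", "whisker_low",
                                       "whisker_high")))

  set.seed(8)
  for (i in 1:5) {
    # uniform base data cannot produce 1.5-IQR outliers of its own
    v <- runif(sample(8:40, 1))
    out <- tukey_box_summary(c(v, 1e6))
    expect_equal(length(out$outliers), 1L)
    expect_true(out$q1 <= out$median && out$median <= out$q3)
    expect_true(out$whisker_low <= out$q1 && out$q3 <= out$whisker_high)
  }
})
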