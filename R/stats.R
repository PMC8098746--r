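# Aggregation, batch-control normalization, cluster-aware fold-change
# estimation, and boxplot summary conventions.

#' Aggregate a measurement table to a coarser level of the hierarchy
#'
#' Rows are averaged (arithmetic mean) within each unit of the target level:
#' `"myelinoid"` averages images within myelinoid, `"batch"` averages
#' myelinoids within batch (the table must already be at myelinoid level for
#' the latter). Metadata constant within a unit is carried through.
#' Aggregating a table already at the target level is the identity.
#'
#' @param table data.frame with columns `value`, `unit`, `myelinoid_id`,
#'   `batch`, `group`, and optionally `image_id`.
#' @param level `"myelinoid"` or `"batch"`.
#' @return Aggregated data.frame.
#' @export
aggregate_measurements <- function(table, level = c("myelinoid", "batch")) {
  level <- match.arg(level)
  check_measurement_table(table)
  if (length(unique(table$unit)) > 1L)
    stop("mixed units: ", paste(unique(table$unit), collapse = ", "))
  key <- if (level == "myelinoid") table$myelinoid_id else table$batch
  pieces <- split(table, key)
  out <- do.call(rbind, lapply(pieces, function(s) {
    meta <- s[1L, setdiff(names(s), c("value", "image_id")), drop = FALSE]
    if (level == "batch") meta$myelinoid_id <- NULL
    if (length(unique(s$group)) > 1L)
      stop("aggregation unit spans multiple groups")
    cbind(value = mean(s$value), meta)
  }))
  rownames(out) <- NULL
  out
}

check_measurement_table <- function(table) {
  need <- c("value", "unit", "myelinoid_id", "batch", "group")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("measurement table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(table$value))) stop("values must be finite")
  invisible(table)
}

#' Normalize measurements to the batch control
#'
#' Each value is divided by the mean value of the control-group units in its
#' batch, so the control-group batch mean maps to 1. Normalization is applied
#' after aggregation to myelinoid level in the standard workflow.
#'
#' @param table measurement table (see [aggregate_measurements()]).
#' @param control control-group label.
#' @return The table with normalized `value` and `unit = "fold of batch
#'   control"`.
#' @export
normalize_to_batch_control <- function(table, control = "Ctrl") {
  check_measurement_table(table)
  out <- lapply(split(table, table$batch), function(s) {
    ctrl <- s$value[s$group == control]
    if (!length(ctrl))
      stop("batch '", s$batch[1L], "' has no '", control, "' units")
    s$value <- s$value / mean(ctrl)
    s
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$unit <- "fold of batch control"
  out
}

#' Fold change between two groups with a stratified cluster bootstrap
#'
#' The point estimate is the ratio of geometric means (group B over group A)
#' of myelinoid-level values; rows at image level are first averaged per
#' myelinoid. Uncertainty comes from a nonparametric bootstrap that resamples
#' whole myelinoids with replacement, stratified by batch and group (the
#' myelinoid is the random-effect unit of the designs this emulates), with a
#' percentile confidence interval. With any non-positive value the estimator
#' falls back to the ratio of arithmetic means, with a warning.
#'
#' @param table measurement table.
#' @param group_a,group_b labels of the reference and comparison groups.
#' @param reps bootstrap replicates (default 2000).
#' @param seed RNG seed for resampling.
#' @param conf confidence level.
#' @return An object of class `fold_change_estimate`: `ratio`, `ci`
#'   (length 2), `reps`, `seed`, `conf`, `clustering` and the bootstrap
#'   replicate vector `boot_ratios`.
#' @export
fold_change_bootstrap <- function(table, group_a = "Ctrl",
                                  group_b = "Treated", reps = 2000L,
                                  seed = 1L, conf = 0.95) {
  check_measurement_table(table)
  if ("image_id" %in% names(table))
    table <- aggregate_measurements(table, "myelinoid")
  a <- table[table$group == group_a, ]
  b <- table[table$group == group_b, ]
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("both groups must be non-empty after aggregation")
  geometric <- all(a$value > 0) && all(b$value > 0)
  if (!geometric)
    warning("non-positive values; falling back to arithmetic-mean ratio",
            call. = FALSE)
  est <- function(av, bv) {
    if (geometric) exp(mean(log(bv)) - mean(log(av)))
    else mean(bv) / mean(av)
  }
  ratio <- est(a$value, b$value)
  strata_a <- split(a$value, a$batch)
  strata_b <- split(b$value, b$batch)
  boot <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      av <- unlist(lapply(strata_a, function(v)
        v[sample.int(length(v), replace = TRUE)]), use.names = FALSE)
      bv <- unlist(lapply(strata_b, function(v)
        v[sample.int(length(v), replace = TRUE)]), use.names = FALSE)
      est(av, bv)
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  # a degenerate bootstrap distribution still brackets the point estimate
  ci <- c(min(ci[1L], ratio), max(ci[2L], ratio))
  structure(list(ratio = ratio, ci = ci, reps = reps, seed = seed,
                 conf = conf,
                 clustering = "myelinoid, stratified by batch and group",
                 n_a = nrow(a), n_b = nrow(b),
                 estimator = if (geometric) "geometric" else "arithmetic",
                 boot_ratios = boot), class = "fold_change_estimate")
}

#' @export
print.fold_change_estimate <- function(x, ...) {
  cat(sprintf(
    "fold change (%s-mean ratio): %.3f (%.0f%% CI %.3f to %.3f)\n",
    x$estimator, x$ratio, 100 * x$conf, x$ci[1L], x$ci[2L]))
  cat(sprintf("  %d vs %d myelinoids; %d bootstrap reps (seed %d), %s\n",
              x$n_a, x$n_b, x$reps, x$seed, x$clustering))
  invisible(x)
}

#' Export a model-ready table for external mixed-model fitting
#'
#' Convenience hook: returns the measurement table with factor columns
#' suitable for a lognormal mixed model (`log(value) ~ group + (1 | batch) +
#' (1 | myelinoid_id)`) fitted in an external package.
#'
#' @param table measurement table.
#' @return data.frame with `log_value` and factor `group`, `batch`,
#'   `myelinoid_id`.
#' @export
glmm_export <- function(table) {
  check_measurement_table(table)
  if (any(table$value <= 0)) stop("log link requires positive values")
  data.frame(log_value = log(table$value),
             group = factor(table$group),
             batch = factor(table$batch),
             myelinoid_id = factor(table$myelinoid_id))
}

#' Five-number boxplot summary with Tukey-style whiskers
#'
#' Quartiles by linear interpolation (R quantile type 7); whiskers extend to
#' the most extreme data points within 1.5 interquartile ranges of the
#' quartiles; points beyond are listed as outliers.
#'
#' @param values numeric vector, length >= 1.
#' @return A list: `median, q1, q3, whisker_low, whisker_high, outliers`.
#' @export
tukey_box_summary <- function(values) {
  stopifnot(length(values) >= 1, all(is.finite(values)))
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3L] - q[1L]
  lo_fence <- q[1L] - 1.5 * iqr
  hi_fence <- q[3L] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = sort(values[!inside]))
}
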