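# g-ratio computation and the logarithmic regression of g on axon diameter.

#' Build g-ratio records from axon and fiber diameters
#'
#' The g-ratio is axon diameter divided by myelinated-fiber diameter
#' (lower = thicker myelin); with `0 < axon < fiber` it lies in (0, 1).
#'
#' @param axon_diameter_um,fiber_diameter_um numeric vectors (um).
#' @return data.frame `axon_diameter_um, fiber_diameter_um, g`.
#' @export
gratio_records <- function(axon_diameter_um, fiber_diameter_um) {
  stopifnot(length(axon_diameter_um) == length(fiber_diameter_um))
  if (any(axon_diameter_um <= 0) || any(fiber_diameter_um <= 0))
    stop("diameters must be positive")
  if (any(axon_diameter_um >= fiber_diameter_um))
    stop("axon diameter must be smaller than fiber diameter")
  data.frame(axon_diameter_um = axon_diameter_um,
             fiber_diameter_um = fiber_diameter_um,
             g = axon_diameter_um / fiber_diameter_um)
}

#' Fit the logarithmic g-ratio regression g = a + b ln(axon diameter)
#'
#' Ordinary least squares of g on the natural log of axon diameter, the
#' standard parameterization for g-ratio vs axon-calibre scatter plots. A
#' `log10` parameterization is available via `base`.
#'
#' @param records data.frame from [gratio_records()] (or with columns
#'   `axon_diameter_um` and `g`); at least 3 rows.
#' @param base logarithm base: `"ln"` (default) or `"log10"`.
#' @return An object of class `gratio_fit` with `coef` (a, b), the underlying
#'   `lm` fit, `residual_sd`, and the observed diameter range. Methods:
#'   `print`, `coef`, `predict`, `plot`.
#' @export
gratio_fit <- function(records, base = c("ln", "log10")) {
  base <- match.arg(base)
  stopifnot(is.data.frame(records), nrow(records) >= 3)
  if (any(records$axon_diameter_um <= 0))
    stop("axon diameters must be positive")
  ld <- if (base == "ln") log(records$axon_diameter_um)
        else log10(records$axon_diameter_um)
  fit <- stats::lm(records$g ~ ld)
  structure(list(
    coef = stats::setNames(unname(stats::coef(fit)), c("a", "b")),
    base = base,
    lm = fit,
    residual_sd = stats::sigma(fit),
    diameter_range_um = range(records$axon_diameter_um),
    n = nrow(records),
    mean_g = mean(records$g)), class = "gratio_fit")
}

#' @export
print.gratio_fit <- function(x, ...) {
  op <- if (x$base == "ln") "ln" else "log10"
  cat(sprintf("g-ratio regression: g = %.4f + %.4f %s(axon diameter)\n",
              x$coef["a"], x$coef["b"], op))
  cat(sprintf("  n = %d, mean g = %.3f, residual SD = %.4f\n",
              x$n, x$mean_g, x$residual_sd))
  invisible(x)
}

#' @export
coef.gratio_fit <- function(object, ...) object$coef

#' @export
#' @param newdata optional data.frame with `axon_diameter_um`; defaults to a
#'   grid over the observed diameter range.
#' @rdname gratio_fit
#' @param object a `gratio_fit`.
#' @param ... passed on.
predict.gratio_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata))
    seq(object$diameter_range_um[1], object$diameter_range_um[2],
        length.out = 100)
  else newdata$axon_diameter_um
  ld <- if (object$base == "ln") log(d) else log10(d)
  data.frame(axon_diameter_um = d,
             g = object$coef["a"] + object$coef["b"] * ld)
}

#' @export
plot.gratio_fit <- function(x, ...) {
  md <- stats::model.frame(x$lm)
  d <- if (x$base == "ln") exp(md$ld) else 10^md$ld
  graphics::plot(d, md[[1L]], xlab = "axon diameter (um)", ylab = "g-ratio",
                 pch = 16, col = grDevices::adjustcolor("steelblue", 0.6),
                 ...)
  pr <- predict.gratio_fit(x)
  graphics::lines(pr$axon_diameter_um, pr$g, lwd = 2, col = "firebrick")
  invisible(x)
}
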