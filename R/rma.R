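#' Reduced major axis regression
#'
#' Symmetric line fit appropriate when both variables carry error, as when
#' relating country mean heights to estimated nutrient intakes. The slope
#' is `sign(r) * sd(y) / sd(x)`, the intercept passes the line through the
#' centroid, and the reported `r_squared` is the squared Pearson
#' correlation (identical to the OLS coefficient of determination).
#'
#' @param x predictor values (e.g. intake, kg per person per year).
#' @param y response values (e.g. height, cm).
#' @return An object of class `"rma_fit"` with components `slope`,
#'   `intercept`, `r_squared`, `r`, `n`, and the centroid means. Supports
#'   [coef()], [predict()], [residuals()], `print()`, `summary()` and
#'   `plot()`.
#' @examples
#' fit <- rma_fit(c(1, 2, 3, 4), c(2, 1, 4, 3))
#' coef(fit)
#' @export
rma_fit <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    np_error("x and y must be numeric vectors of equal length", "domain_error")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3)
    np_error("reduced major axis fit needs at least 3 complete pairs",
             "degenerate_input_error")
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0)
    np_error("zero variance in x or y: reduced major axis slope is undefined",
             "degenerate_input_error")
  r <- cor(x, y)
  slope <- (if (r < 0) -1 else 1) * sy / sx
  intercept <- mean(y) - slope * mean(x)
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r^2, r = r, n = n,
                 mean_x = mean(x), mean_y = mean(y),
                 x = x, y = y, call = match.call()),
            class = "rma_fit")
}

#' @export
coef.rma_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.rma_fit <- function(object, newdata = NULL, ...) {
  x <- newdata %||% object$x
  if (is.data.frame(x)) x <- x[[1]]
  object$intercept + object$slope * x
}

#' @export
residuals.rma_fit <- function(object, ...) {
  object$y - predict(object)
}

#' @export
print.rma_fit <- function(x, ...) {
  cat("Reduced major axis fit (n =", x$n, ")\n")
  cat(sprintf("  slope: %.6g   intercept: %.6g   r^2: %.4f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
summary.rma_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  r: %.4f   centroid: (%.6g, %.6g)\n",
              object$r, object$mean_x, object$mean_y))
  invisible(object)
}

#' @export
plot.rma_fit <- function(x, xlab = "x", ylab = "y", ...) {
  plot(x$x, x$y, xlab = xlab, ylab = ylab, ...)
  abline(a = x$intercept, b = x$slope, col = "red3")
  invisible(x)
}
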