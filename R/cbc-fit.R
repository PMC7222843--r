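#' Select the fit window of a titration record
#'
#' Restricts the record to the pH window the determination model is fitted
#' on: acidification uses pH 7.0 down to 3.0; direct alkalization uses pH
#' 7.8 to 11.5, except that a record starting above pH 7.8 starts at the
#' step whose pH is nearest 7.8 (in practice its first step); alkalization
#' after acidification uses pH 7.0 to 11.5.
#'
#' @param record a [titration_record()].
#' @return data.frame with columns `amount` (mol kg-1 slurry), `pH`,
#'   `temperature`, ordered by amount, with attributes `fit_window` and
#'   `direction`.
#' @export
select_fit_range <- function(record) {
  amount <- normalize_amount(record)
  pH <- record$steps$pH
  win <- switch(record$direction,
    acidify = c(3.0, 7.0),
    alkalize = c(7.8, 11.5),
    alkalize_after_acid = c(7.0, 11.5))
  keep <- pH >= win[1] & pH <= win[2]
  if (record$direction == "alkalize" && pH[1] > win[1]) {
    # record starts in the alkaline range: start at the step nearest pH 7.8
    start <- which.min(abs(pH - win[1]))
    keep <- seq_along(pH) >= start & pH <= win[2]
  }
  pts <- data.frame(amount = amount[keep], pH = pH[keep],
                    temperature = record$steps$temperature[keep])
  pts <- pts[order(pts$amount), , drop = FALSE]
  rownames(pts) <- NULL
  if (nrow(pts) < 10L)
    stop_slurrycbc("insufficient_data",
      "only %d titration points inside the fit window [%.1f, %.1f]",
      nrow(pts), win[1], win[2])
  structure(pts, fit_window = win, direction = record$direction)
}

#' Fit the titration-curve polynomial
#'
#' Least-squares polynomial of pH on titrant amount — the titration curve of
#' the determination model. The amount axis is centred and scaled to [-1, 1]
#' internally for numerical conditioning; coefficients are stored in that
#' basis together with the transform. Monotonicity of the fitted curve is
#' checked on a 512-point grid and recorded in `monotone` (a non-monotone
#' fit is retained but flagged, and its near-zero-slope grid points are
#' dropped later by [compute_cbc()]).
#'
#' @param points data.frame with columns `amount` and `pH`, e.g. from
#'   [select_fit_range()].
#' @param degree polynomial degree; the reference model uses 6 and changing
#'   it emits a warning.
#' @return an object of class `cbc_fit`.
#' @export
fit_titration_curve <- function(points, degree = 6) {
  if (degree != 6)
    warn_slurrycbc("degree",
      "polynomial degree %d differs from the reference model's degree 6", degree)
  x <- points$amount; y <- points$pH
  if (length(x) < degree + 4)
    stop_slurrycbc("insufficient_data",
      "need at least degree + 4 = %d points, got %d", degree + 4, length(x))
  if (diff(range(x)) == 0)
    stop_slurrycbc("parameter", "titrant amounts are all equal; nothing to fit")
  centre <- mean(range(x)); half <- diff(range(x)) / 2
  z <- (x - centre) / half
  X <- outer(z, 0:degree, `^`)
  qr_X <- qr(X)
  if (qr_X$rank < degree + 1L)
    stop_slurrycbc("fit",
      "rank-deficient design (rank %d < %d); reduce the polynomial degree",
      qr_X$rank, degree + 1L)
  coefs <- qr.coef(qr_X, y)
  resid <- y - drop(X %*% coefs)

  direction <- attr(points, "direction") %||%
    if (stats::cor(x, y) < 0) "acidify" else "alkalize"
  fit_window <- attr(points, "fit_window") %||% range(y)

  fit <- structure(list(
    coefficients = coefs, degree = degree, centre = centre, half_width = half,
    amount_window = range(x), fit_window = fit_window, direction = direction,
    n_points = length(x), rmse_pH = sqrt(mean(resid^2)),
    points = points[, c("amount", "pH")], residuals = resid
  ), class = "cbc_fit")

  g <- seq(fit$amount_window[1], fit$amount_window[2], length.out = 512)
  sl <- slope_curve(fit)(g)
  fit$monotone <- if (direction == "acidify") all(sl < 0) else all(sl > 0)
  fit
}

#' Fit the determination model to a titration record
#'
#' Front door of the determination model: selects the direction's fit window
#' with [select_fit_range()] and fits the degree-6 titration-curve polynomial
#' with [fit_titration_curve()]. Follow with [compute_cbc()] and
#' [find_peak()], or use the `plot` method to see the full pipeline.
#'
#' @param record a [titration_record()].
#' @param degree polynomial degree (reference: 6).
#' @return a `cbc_fit`.
#' @examples
#' mix <- preset_mixture("fattening_pig")
#' rec <- simulate_titration(mix, titration_protocol("HCl"))
#' fit <- cbc_fit(rec)
#' fit
#' @export
cbc_fit <- function(record, degree = 6) {
  pts <- select_fit_range(record)
  fit <- fit_titration_curve(pts, degree = degree)
  fit$record <- record
  fit
}

# evaluate the fitted polynomial and its exact derivative in amount units
.poly_eval <- function(fit, amount) {
  z <- (amount - fit$centre) / fit$half_width
  drop(outer(z, 0:fit$degree, `^`) %*% fit$coefficients)
}

#' Analytic slope of the fitted titration curve
#'
#' Returns the exact derivative of the fitted polynomial (degree d - 1; no
#' finite differences) as a function of titrant amount, in pH per mol kg-1
#' slurry. Its reciprocal absolute value is the CBC.
#'
#' @param fit a `cbc_fit`.
#' @return function(amount) -> dpH/damount.
#' @export
slope_curve <- function(fit) {
  d <- fit$degree
  dcoef <- fit$coefficients[-1] * seq_len(d)
  centre <- fit$centre; half <- fit$half_width
  function(amount) {
    z <- (amount - centre) / half
    drop(outer(z, 0:(d - 1), `^`) %*% dcoef) / half
  }
}

#' @export
print.cbc_fit <- function(x, ...) {
  cat(sprintf("<cbc_fit> degree %d on %d points, pH window [%.1f, %.1f] (%s)\n",
              x$degree, x$n_points, x$fit_window[1], x$fit_window[2], x$direction))
  cat(sprintf("  amount %.4g..%.4g mol/kg slurry, rmse %.4g pH, monotone: %s\n",
              x$amount_window[1], x$amount_window[2], x$rmse_pH,
              ifelse(x$monotone, "yes", "NO (flagged)")))
  invisible(x)
}

#' @export
summary.cbc_fit <- function(object, ...) {
  cbc <- tryCatch(compute_cbc(object), slurrycbc_error = function(e) NULL)
  out <- list(fit = object, cbc = cbc,
              peaks = if (!is.null(cbc)) {
                wins <- buffer_windows()
                lapply(names(wins), function(nm)
                  tryCatch(find_peak(cbc, wins[[nm]], buffer = nm),
                           slurrycbc_error = function(e) NULL))
              })
  class(out) <- "summary.cbc_fit"
  out
}

#' @export
print.summary.cbc_fit <- function(x, ...) {
  print(x$fit)
  if (is.null(x$cbc)) {
    cat("  CBC curve degenerate for this fit\n")
    return(invisible(x))
  }
  cat(sprintf("  CBC over %d grid points, %.1f%% dropped near zero slope\n",
              nrow(x$cbc), 100 * attr(x$cbc, "dropped_fraction")))
  for (p in Filter(Negate(is.null), x$peaks))
    cat(sprintf("  %-5s [%4.1f,%4.1f]: %s pH %.2f, CBC %.3g mol/kg/pH\n",
                p$buffer, p$window[1], p$window[2],
                ifelse(p$is_local_max, "peak at", "no local max; supremum at"),
                p$peak_pH, p$max_cbc))
  invisible(x)
}

#' @export
coef.cbc_fit <- function(object, ...) {
  structure(object$coefficients,
            names = paste0("z^", 0:object$degree),
            centre = object$centre, half_width = object$half_width)
}

#' @export
residuals.cbc_fit <- function(object, ...) object$residuals

#' Predict pH from titrant amount
#'
#' @param object a `cbc_fit`.
#' @param amount titrant amounts (mol kg-1 slurry); defaults to the fitted
#'   points' amounts.
#' @param ... unused.
#' @return predicted pH values.
#' @export
predict.cbc_fit <- function(object, amount = NULL, ...) {
  if (is.null(amount)) amount <- object$points$amount
  .poly_eval(object, amount)
}

#' Plot the determination-model pipeline
#'
#' Four panels: titration data with the polynomial fit, the analytic slope,
#' the reciprocal slope versus amount, and the CBC curve versus pH.
#'
#' @param x a `cbc_fit`.
#' @param ... passed to the CBC panel's `plot`.
#' @export
plot.cbc_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  g <- seq(x$amount_window[1], x$amount_window[2], length.out = 256)
  graphics::plot(x$points$amount, x$points$pH, pch = 16, cex = 0.5,
                 xlab = "amount (mol/kg slurry)", ylab = "pH",
                 main = "titration curve + fit")
  graphics::lines(g, .poly_eval(x, g), col = 2)
  sl <- slope_curve(x)(g)
  graphics::plot(g, sl, type = "l", col = 2,
                 xlab = "amount (mol/kg slurry)", ylab = "dpH/damount",
                 main = "slope")
  graphics::plot(g, abs(1 / sl), type = "l", col = 4,
                 xlab = "amount (mol/kg slurry)", ylab = "CBC",
                 main = "reciprocal slope")
  cbc <- tryCatch(compute_cbc(x), slurrycbc_error = function(e) NULL)
  if (!is.null(cbc))
    graphics::plot(cbc$pH, cbc$cbc, type = "l", col = 4,
                   xlab = "pH", ylab = "CBC (mol/kg slurry/pH)",
                   main = "buffer capacity curve", ...)
  invisible(x)
}
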