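#' Default per-buffer pH windows
#'
#' Windows in which each buffer system's peak is sought: VFA 4.0-4.5 and
#' bicarbonate 6.0-6.5 (where slurry peaks are observed during
#' acidification), carbonate 9.5-11.5, and ammonia 8.5-10.0 centred on the
#' NH4+/NH3 pKs of 9.25. All user-configurable.
#'
#' @param VFA,HCO3,NH3,CO3 two-element numeric windows (pH).
#' @return named list of windows.
#' @export
buffer_windows <- function(VFA = c(4.0, 4.5), HCO3 = c(6.0, 6.5),
                           NH3 = c(8.5, 10.0), CO3 = c(9.5, 11.5)) {
  w <- list(VFA = VFA, HCO3 = HCO3, NH3 = NH3, CO3 = CO3)
  for (nm in names(w))
    if (length(w[[nm]]) != 2L || diff(w[[nm]]) <= 0)
      stop_slurrycbc("parameter", "window %s must be (low, high) with low < high", nm)
  w
}

#' Current buffer capacity curve from a titration-curve fit
#'
#' Samples the fitted polynomial on a uniform amount grid and forms
#' CBC = |1 / slope| at each grid point, pairing it with the fitted pH. Grid
#' points whose absolute slope falls below `eps_slope` (reciprocal blows up
#' where a non-monotone fit wiggles through zero slope) are dropped and
#' counted; more than `max_dropped` of the grid dropped aborts with a
#' degenerate-fit error.
#'
#' @param fit a [cbc_fit()] / [fit_titration_curve()] result.
#' @param n_grid number of grid points over the fitted amount range.
#' @param eps_slope smallest usable |slope|, pH kg mol-1.
#' @param max_dropped largest tolerated dropped-grid fraction.
#' @return a `cbc_curve`: data.frame with columns `amount`, `pH`, `cbc`
#'   (mol kg-1 slurry pH-1), attributes `direction`, `fit`,
#'   `dropped_fraction`.
#' @export
compute_cbc <- function(fit, n_grid = 512, eps_slope = 1e-3, max_dropped = 0.1) {
  g <- seq(fit$amount_window[1], fit$amount_window[2], length.out = n_grid)
  sl <- slope_curve(fit)(g)
  keep <- abs(sl) >= eps_slope
  dropped <- 1 - mean(keep)
  if (dropped > max_dropped)
    stop_slurrycbc("degenerate_fit",
      "%.0f%% of the CBC grid has |slope| < %g; the fit is too steep or non-monotone for a buffer-capacity curve",
      100 * dropped, eps_slope)
  if (dropped > 0)
    warn_slurrycbc("dropped_grid",
      "%d of %d CBC grid points dropped near zero slope", sum(!keep), n_grid)
  curve <- data.frame(amount = g[keep], pH = .poly_eval(fit, g[keep]),
                      cbc = abs(1 / sl[keep]))
  structure(curve, class = c("cbc_curve", "data.frame"),
            direction = fit$direction, fit = fit, dropped_fraction = dropped)
}

#' @export
plot.cbc_curve <- function(x, ...) {
  graphics::plot(x$pH, x$cbc, type = "l", xlab = "pH",
                 ylab = "CBC (mol/kg slurry/pH)", ...)
  invisible(x)
}

#' Locate a buffer peak on a CBC curve
#'
#' Finds the interior local maximum of CBC(pH) inside a buffer window from
#' sign changes of the first difference on the grid, refines it by quadratic
#' interpolation of the three bracketing grid points, and reports the
#' largest such maximum (equal candidates resolve toward the window
#' midpoint). When no interior local maximum exists the window's boundary
#' supremum is reported with `is_local_max = FALSE` — the peak is then not
#' quantifiable, only bounded.
#'
#' @param cbc a [compute_cbc()] curve.
#' @param window two-element pH window, or a name from [buffer_windows()].
#' @param buffer label stored in the result; defaults to the window name if
#'   one was given.
#' @return a `buffer_peak` list: `buffer`, `window`, `peak_pH`, `max_cbc`,
#'   `is_local_max`.
#' @export
find_peak <- function(cbc, window, buffer = NULL) {
  if (is.character(window)) {
    buffer <- buffer %||% window
    window <- buffer_windows()[[window]]
    if (is.null(window)) stop_slurrycbc("parameter", "unknown buffer window name")
  }
  buffer <- buffer %||% "custom"
  o <- order(cbc$pH)
  pH <- cbc$pH[o]; v <- cbc$cbc[o]
  inside <- which(pH >= window[1] & pH <= window[2])
  if (length(inside) == 0L)
    stop_slurrycbc("coverage",
      "CBC curve (pH %.2f..%.2f) does not cover the window [%.2f, %.2f]",
      min(pH), max(pH), window[1], window[2])

  # interior local maxima: grid points at least as high as both neighbours
  cand <- inside[inside > 1L & inside < length(pH)]
  is_max <- vapply(cand, function(i) v[i] >= v[i - 1] && v[i] >= v[i + 1], logical(1))
  cand <- cand[is_max]
  if (length(cand) > 0L) {
    best <- max(v[cand])
    top <- cand[v[cand] >= best * (1 - 1e-12)]
    mid <- mean(window)
    i <- top[which.min(abs(pH[top] - mid))]
    # quadratic refinement through the three bracketing points
    x3 <- pH[(i - 1):(i + 1)]; y3 <- v[(i - 1):(i + 1)]
    denom <- (x3[1] - x3[2]) * (x3[1] - x3[3]) * (x3[2] - x3[3])
    a <- (x3[3] * (y3[2] - y3[1]) + x3[2] * (y3[1] - y3[3]) + x3[1] * (y3[3] - y3[2])) / denom
    peak_pH <- if (a < 0) {
      b <- (x3[3]^2 * (y3[1] - y3[2]) + x3[2]^2 * (y3[3] - y3[1]) + x3[1]^2 * (y3[2] - y3[3])) / denom
      -b / (2 * a)
    } else pH[i]
    peak_pH <- min(max(peak_pH, window[1]), window[2])
    max_cbc <- if (a < 0) {
      b <- (x3[3]^2 * (y3[1] - y3[2]) + x3[2]^2 * (y3[3] - y3[1]) + x3[1]^2 * (y3[2] - y3[3])) / denom
      cc <- y3[1] - a * x3[1]^2 - b * x3[1]
      a * peak_pH^2 + b * peak_pH + cc
    } else v[i]
    local_max <- TRUE
  } else {
    i <- inside[which.max(v[inside])]
    peak_pH <- pH[i]; max_cbc <- v[i]; local_max <- FALSE
  }
  structure(list(buffer = buffer, window = window, peak_pH = peak_pH,
                 max_cbc = max_cbc, is_local_max = local_max),
            class = "buffer_peak")
}

#' @export
print.buffer_peak <- function(x, ...) {
  cat(sprintf("<buffer_peak> %s [%.1f, %.1f]: %s pH %.3f, CBC %.4g mol/kg slurry/pH\n",
              x$buffer, x$window[1], x$window[2],
              ifelse(x$is_local_max, "local max at", "NOT quantifiable (supremum at)"),
              x$peak_pH, x$max_cbc))
  invisible(x)
}

#' Integrate a CBC curve between two pH values
#'
#' Trapezoidal integral of CBC over pH. Because CBC is the absolute inverse
#' slope of the titration curve, this integral recovers the titrant amount
#' (mol kg-1 slurry) the model attributes to that pH interval — the
#' conservation property tying the fitted curve to [amount_between()].
#'
#' @param cbc a [compute_cbc()] curve.
#' @param pH_low,pH_high integration bounds, `pH_low < pH_high`.
#' @return integral value, mol kg-1 slurry.
#' @export
integrate_cbc <- function(cbc, pH_low, pH_high) {
  if (pH_low >= pH_high) stop_slurrycbc("parameter", "need pH_low < pH_high")
  o <- order(cbc$pH)
  pH <- cbc$pH[o]; v <- cbc$cbc[o]
  if (pH_low < min(pH) - 1e-9 || pH_high > max(pH) + 1e-9)
    stop_slurrycbc("coverage",
      "integration bounds [%.2f, %.2f] exceed curve coverage (%.2f..%.2f)",
      pH_low, pH_high, min(pH), max(pH))
  vb <- stats::approx(pH, v, xout = c(pH_low, pH_high), ties = "ordered")$y
  inner <- pH > pH_low & pH < pH_high
  xs <- c(pH_low, pH[inner], pH_high)
  ys <- c(vb[1], v[inner], vb[2])
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}
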