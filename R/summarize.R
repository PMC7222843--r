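#' Pearson correlation with a two-sided t-test
#'
#' Sample Pearson r with the two-sided p-value from the t-transform on n - 2
#' degrees of freedom (via [stats::cor.test()]).
#'
#' @param xs,ys numeric vectors of equal length, n >= 3, finite.
#' @return list with `r`, `p`, `n`.
#' @export
pearson <- function(xs, ys) {
  ok <- is.finite(xs) & is.finite(ys)
  xs <- xs[ok]; ys <- ys[ok]
  if (length(xs) < 3) stop_slurrycbc("insufficient_data", "need at least 3 complete pairs")
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop_slurrycbc("undefined_correlation", "zero variance; correlation undefined")
  ct <- stats::cor.test(xs, ys, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(xs))
}

#' Model-verification correlations for a batch
#'
#' The four pairings used to verify the determination model: peak pH vs
#' temperature, and maximum CBC vs TIC, TAN, and the acid amount of the
#' matching pH segment. Rows named in `exclude_ids` are dropped openly (an
#' audit trail for outliers such as urea-rich fresh sow slurry); pairings
#' with fewer than 3 complete pairs are skipped with a message.
#'
#' @param samples data.frame with one row per record. Columns used (any may
#'   be missing): `sample_id`, `temperature`, `peak_pH`, `max_cbc`, `tic`,
#'   `tan`, `acid_amount`.
#' @param exclude_ids sample_id values to exclude from every pairing.
#' @return data.frame with `pairing`, `n`, `pearson_r`, `p_value`, `slope`,
#'   `intercept`; skipped pairings appear with NA statistics.
#' @export
verification_suite <- function(samples, exclude_ids = character(0)) {
  if (length(exclude_ids) && "sample_id" %in% names(samples)) {
    message("excluding ", sum(samples$sample_id %in% exclude_ids),
            " sample(s): ", paste(exclude_ids, collapse = ", "))
    samples <- samples[!samples$sample_id %in% exclude_ids, , drop = FALSE]
  }
  pairings <- list(
    peakpH_vs_temperature = c("temperature", "peak_pH"),
    maxCBC_vs_TIC = c("tic", "max_cbc"),
    maxCBC_vs_TAN = c("tan", "max_cbc"),
    maxCBC_vs_acid_amount = c("acid_amount", "max_cbc")
  )
  rows <- lapply(names(pairings), function(nm) {
    cols <- pairings[[nm]]
    out <- data.frame(pairing = nm, n = NA_integer_, pearson_r = NA_real_,
                      p_value = NA_real_, slope = NA_real_, intercept = NA_real_,
                      stringsAsFactors = FALSE)
    if (!all(cols %in% names(samples))) {
      message("pairing ", nm, " skipped: missing column(s)")
      return(out)
    }
    x <- samples[[cols[1]]]; y <- samples[[cols[2]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) {
      message("pairing ", nm, " skipped: only ", sum(ok), " complete pair(s)")
      return(out)
    }
    pr <- pearson(x[ok], y[ok])
    co <- stats::coef(stats::lm(y[ok] ~ x[ok]))
    out$n <- pr$n; out$pearson_r <- pr$r; out$p_value <- pr$p
    out$slope <- unname(co[2]); out$intercept <- unname(co[1])
    out
  })
  do.call(rbind, rows)
}

#' Storage-dynamics summary of a segment table
#'
#' Per (slurry_type, storage, week) group means and standard errors of the
#' initial pH, the segment amounts, and any extra per-sample columns (e.g.
#' peak CBCs merged in beforehand). Weeks with no records are simply absent
#' from the table — a gap in the series, never a zero.
#'
#' @param segtable a [build_segment_table()] result, optionally with extra
#'   numeric columns.
#' @return tidy data.frame: group columns + `variable`, `mean`, `sem`, `n`.
#' @export
storage_series <- function(segtable) {
  df <- as.data.frame(segtable)
  group_cols <- c("slurry_type", "storage", "week")
  id_cols <- c(group_cols, "sample_id", "replicate", "direction")
  value_cols <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                        c("week", "replicate"))
  key <- interaction(df[group_cols], drop = TRUE)
  rows <- lapply(split(df, key), function(g) {
    do.call(rbind, lapply(value_cols, function(vc) {
      v <- g[[vc]][is.finite(g[[vc]])]
      data.frame(slurry_type = g$slurry_type[1], storage = g$storage[1],
                 week = g$week[1], variable = vc,
                 mean = if (length(v)) mean(v) else NA_real_,
                 sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
                 n = length(v), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$slurry_type, out$storage, out$variable, out$week), ]
  rownames(out) <- NULL
  attr(out, "units") <- "amounts in mol/kg slurry; pH unitless; sem = sd/sqrt(n)"
  out
}

#' Plot a storage series
#'
#' Stacked bars of the three acid segments (initial->7.0, 7.0->5.5,
#' 5.5->3.0) by week with the initial pH overlaid as a line, for one
#' slurry_type x storage group.
#'
#' @param series a [storage_series()] table.
#' @param slurry_type,storage group to plot.
#' @export
plot_storage_series <- function(series, slurry_type, storage) {
  g <- series[series$slurry_type == slurry_type & series$storage == storage, ]
  segs <- c("amount_initial_to_7", "amount_7_to_5p5", "amount_5p5_to_3")
  wk <- sort(unique(g$week))
  m <- sapply(wk, function(w)
    vapply(segs, function(s) {
      v <- g$mean[g$week == w & g$variable == s]
      if (length(v)) v else NA_real_
    }, numeric(1)))
  graphics::barplot(m, names.arg = wk, col = c("grey70", "steelblue", "firebrick"),
                    xlab = "storage week", ylab = "acid amount (mol/kg slurry)",
                    main = paste(slurry_type, storage, sep = ", "),
                    legend.text = c("initial->7.0", "7.0->5.5", "5.5->3.0"))
  ip <- g[g$variable == "initial_pH", ]
  if (nrow(ip)) {
    graphics::par(new = TRUE)
    graphics::plot(seq_along(wk) - 0.5, ip$mean[match(wk, ip$week)], type = "b",
                   pch = 16, axes = FALSE, xlab = "", ylab = "",
                   xlim = c(0, length(wk)), ylim = c(2, 10))
    graphics::axis(4)
    graphics::mtext("initial pH", side = 4, line = 2)
  }
  invisible(series)
}
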