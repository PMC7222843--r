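#' Quality-control thresholds
#'
#' Numeric surrogates for the visual exclusion of erroneous titrations
#' (sensor fouling, titrant retention by foam). All artifact-defined and
#' configurable; report them alongside any excluded records.
#'
#' @param tau_reversal largest tolerated pH reversal against the titration
#'   direction (pH units) before the hard `non_monotone_pH` flag.
#' @param stall_k number of consecutive doses with almost no pH response
#'   that raises `stalled_pH`.
#' @param stall_dpH per-dose pH change regarded as "no response".
#' @param stall_min_dose_frac a stall only counts while the instrument is
#'   dosing at least this fraction of the maximum step (tiny doses with tiny
#'   pH change are ordinary buffer-plateau behaviour, not a stuck sensor).
#' @param max_step_mL protocol's maximum dose; a single step larger than
#'   `gap_factor` times it raises the soft `large_dose_gap` flag.
#' @param gap_factor multiplier on `max_step_mL`.
#' @param tau_noise largest tolerated median absolute residual around a
#'   local linear smooth of pH vs amount (pH units) before `excess_noise`.
#' @param min_window_points fewer in-window points than this raises the hard
#'   `insufficient_range` flag.
#' @return list of thresholds.
#' @export
qc_thresholds <- function(tau_reversal = 0.3, stall_k = 5, stall_dpH = 0.005,
                          stall_min_dose_frac = 0.5, max_step_mL = 0.5,
                          gap_factor = 2, tau_noise = 0.05,
                          min_window_points = 10) {
  list(tau_reversal = tau_reversal, stall_k = stall_k, stall_dpH = stall_dpH,
       stall_min_dose_frac = stall_min_dose_frac, max_step_mL = max_step_mL,
       gap_factor = gap_factor, tau_noise = tau_noise,
       min_window_points = min_window_points)
}

#' Screen a titration record before modelling
#'
#' Deterministic, order-independent flags; the verdict is `exclude` iff a
#' hard flag (`non_monotone_pH`, `insufficient_range`) is present. Soft
#' flags (`stalled_pH`, `large_dose_gap`, `excess_noise`) mark records worth
#' inspecting but do not exclude them. QC never errors on content.
#'
#' @param record a [titration_record()].
#' @param thresholds a [qc_thresholds()] list.
#' @return a `qc_report`: `sample_id`, `flags` (character vector),
#'   `verdict` ("pass" or "exclude").
#' @export
evaluate_qc <- function(record, thresholds = qc_thresholds()) {
  th <- thresholds
  pH <- record$steps$pH
  vol <- record$steps$volume_mL
  going_down <- record$direction == "acidify"
  flags <- character(0)

  # pH running against the titration direction by more than tau_reversal
  run_extreme <- if (going_down) cummin(pH) else cummax(pH)
  reversal <- if (going_down) max(pH - run_extreme) else max(run_extreme - pH)
  if (reversal > th$tau_reversal) flags <- c(flags, "non_monotone_pH")

  # sensor stall: >= k consecutive near-maximal doses with no pH response
  dv <- diff(vol); dp <- abs(diff(pH))
  stalled <- dp < th$stall_dpH & dv >= th$stall_min_dose_frac * th$max_step_mL
  if (length(stalled) >= th$stall_k) {
    runs <- rle(stalled)
    if (any(runs$lengths[runs$values] >= th$stall_k))
      flags <- c(flags, "stalled_pH")
  }

  if (any(dv > th$gap_factor * th$max_step_mL)) flags <- c(flags, "large_dose_gap")

  in_window <- tryCatch(nrow(select_fit_range(record)),
                        slurrycbc_error = function(e) 0L)
  if (in_window < th$min_window_points) flags <- c(flags, "insufficient_range")

  if (length(pH) >= 10) {
    sm <- stats::lowess(vol, pH, f = 0.2)
    res <- pH - stats::approx(sm$x, sm$y, xout = vol, ties = "ordered")$y
    if (stats::median(abs(res), na.rm = TRUE) > th$tau_noise)
      flags <- c(flags, "excess_noise")
  }

  hard <- intersect(flags, c("non_monotone_pH", "insufficient_range"))
  structure(list(sample_id = record$sample_id, flags = flags,
                 verdict = if (length(hard)) "exclude" else "pass",
                 thresholds = th),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: %s%s\n", x$sample_id, toupper(x$verdict),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else " (no flags)"))
  invisible(x)
}

#' QC a batch of records into a flat table
#'
#' @param batch list of [titration_record()] objects.
#' @param thresholds a [qc_thresholds()] list.
#' @return data.frame with one row per record and one logical column per flag.
#' @export
qc_table <- function(batch, thresholds = qc_thresholds()) {
  if (inherits(batch, "titration_record")) batch <- list(batch)
  all_flags <- c("non_monotone_pH", "stalled_pH", "large_dose_gap",
                 "insufficient_range", "excess_noise")
  rows <- lapply(batch, function(rec) {
    rep <- evaluate_qc(rec, thresholds)
    out <- data.frame(sample_id = rep$sample_id, verdict = rep$verdict,
                      stringsAsFactors = FALSE)
    for (f in all_flags) out[[f]] <- f %in% rep$flags
    out
  })
  do.call(rbind, rows)
}
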