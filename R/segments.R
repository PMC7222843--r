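#' Titrant amount between two pH bounds, from raw data
#'
#' Linear interpolation of the cumulative titrant amount at each pH bound on
#' the raw (amount, pH) sequence — deliberately independent of the fitted
#' polynomial, so QC-excluded fits cannot contaminate segment amounts. When
#' the trajectory crosses a bound more than once (noise), the first crossing
#' is used; if the record starts past `pH_from`, the segment starts at
#' amount zero.
#'
#' @param record a [titration_record()].
#' @param pH_from,pH_to segment bounds; for acidification `pH_from > pH_to`,
#'   for alkalization `pH_from < pH_to`.
#' @return titrant amount in the segment, mol kg-1 slurry.
#' @examples
#' # a record falling linearly from pH 7 to 3 over 0.2 mol/kg spends
#' # 0.125 mol/kg between pH 5.5 and 3.0
#' @export
amount_between <- function(record, pH_from, pH_to) {
  going_down <- record$direction == "acidify"
  if (going_down && pH_from <= pH_to)
    stop_slurrycbc("parameter", "acidification segments need pH_from > pH_to")
  if (!going_down && pH_from >= pH_to)
    stop_slurrycbc("parameter", "alkalization segments need pH_from < pH_to")
  amount <- normalize_amount(record)
  pH <- record$steps$pH

  cross_at <- function(bound) {
    past <- if (going_down) pH <= bound else pH >= bound
    if (past[1]) return(0)           # record starts beyond the bound
    i <- which(past)[1]
    if (is.na(i)) {
      deepest <- if (going_down) min(pH) else max(pH)
      stop_slurrycbc("coverage",
        "pH %.2f never reached (deepest pH attained: %.2f)", bound, deepest)
    }
    # first crossing: interpolate between the bracketing steps
    stats::approx(pH[(i - 1):i], amount[(i - 1):i], xout = bound)$y
  }
  abs(cross_at(pH_to) - cross_at(pH_from))
}

#' Segment table for a batch of records
#'
#' One row per record with the storage-dynamics quantities: the acid amounts
#' for initial pH -> 7.0, 7.0 -> 5.5 and 5.5 -> 3.0, the base amount for
#' 9.5 -> 11.5, and the initial pH. Segments a record cannot cover are NA
#' (explicit missing), never zero; an acidification that starts below 7.0
#' legitimately reports 0 for the initial segment.
#'
#' @param batch list of [titration_record()] objects.
#' @return data.frame of class `segment_table`.
#' @export
build_segment_table <- function(batch) {
  if (inherits(batch, "titration_record")) batch <- list(batch)
  if (length(batch) == 0L) {
    out <- data.frame(sample_id = character(0), slurry_type = character(0),
                      storage = character(0), week = integer(0),
                      replicate = integer(0), direction = character(0),
                      initial_pH = numeric(0), amount_initial_to_7 = numeric(0),
                      amount_7_to_5p5 = numeric(0), amount_5p5_to_3 = numeric(0),
                      amount_9p5_to_11p5 = numeric(0), stringsAsFactors = FALSE)
    attr(out, "units") <- "amounts in mol titrant per kg slurry (pre-dilution)"
    class(out) <- c("segment_table", "data.frame")
    return(out)
  }
  rows <- lapply(batch, function(rec) {
    seg <- function(from, to, dir_ok) {
      if (!dir_ok) return(NA_real_)
      tryCatch(amount_between(rec, from, to),
               slurrycbc_error = function(e) NA_real_)
    }
    acid <- rec$direction == "acidify"
    base <- rec$direction != "acidify"
    init <- rec$steps$pH[1]
    data.frame(
      sample_id = rec$sample_id, slurry_type = rec$slurry_type,
      storage = rec$storage, week = rec$week, replicate = rec$replicate,
      direction = rec$direction, initial_pH = init,
      amount_initial_to_7 = if (acid && init <= 7) 0 else seg(init, 7.0, acid),
      amount_7_to_5p5 = seg(7.0, 5.5, acid),
      amount_5p5_to_3 = seg(5.5, 3.0, acid),
      amount_9p5_to_11p5 = seg(9.5, 11.5, base),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "units") <- "amounts in mol titrant per kg slurry (pre-dilution)"
  class(out) <- c("segment_table", "data.frame")
  out
}
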