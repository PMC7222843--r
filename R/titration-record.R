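#' Construct and validate a titration record
#'
#' One instrument log: the ordered dosing steps (cumulative titrant volume in
#' mL, pH, temperature in degC) plus the sample and titrant metadata needed
#' to express doses in mol per kg slurry. Steps are sorted by volume;
#' duplicate volumes (instrument re-reads at equilibrium) collapse to the
#' last pH reading.
#'
#' @param steps data.frame with columns `volume_mL`, `pH`, `temperature`.
#' @param sample_id opaque identifier.
#' @param slurry_type one of fattening_pig, dairy_cow, sow, synthetic.
#' @param storage storage condition: cold, warm or none.
#' @param week non-negative storage week.
#' @param replicate positive replicate index.
#' @param direction acidify, alkalize, or alkalize_after_acid.
#' @param titrant HCl or NaOH; inferred from `direction` when NULL.
#' @param titrant_molarity mol L-1 (> 0).
#' @param sample_mass kg slurry before dilution (> 0).
#' @param diluent_mass kg water added (>= 0).
#' @return a validated `titration_record`.
#' @export
titration_record <- function(steps, sample_id = "sample",
                             slurry_type = c("synthetic", "fattening_pig",
                                             "dairy_cow", "sow"),
                             storage = c("none", "cold", "warm"), week = 0,
                             replicate = 1,
                             direction = c("acidify", "alkalize",
                                           "alkalize_after_acid"),
                             titrant = NULL, titrant_molarity = 0.5,
                             sample_mass = 0.05, diluent_mass = 0.05) {
  slurry_type <- match.arg(slurry_type)
  storage <- match.arg(storage)
  direction <- match.arg(direction)
  need <- c("volume_mL", "pH", "temperature")
  if (!all(need %in% names(steps)))
    stop_slurrycbc("format", "steps must have columns %s", paste(need, collapse = ", "))
  if (is.null(titrant)) titrant <- if (direction == "acidify") "HCl" else "NaOH"
  if (direction == "acidify" && titrant != "HCl")
    stop_slurrycbc("parameter", "acidification requires titrant HCl")
  if (direction != "acidify" && titrant != "NaOH")
    stop_slurrycbc("parameter", "alkalization requires titrant NaOH")
  if (titrant_molarity <= 0) stop_slurrycbc("parameter", "titrant_molarity must be > 0")
  if (sample_mass <= 0) stop_slurrycbc("parameter", "sample_mass must be > 0")
  if (diluent_mass < 0) stop_slurrycbc("parameter", "diluent_mass must be >= 0")
  if (week < 0 || replicate < 1)
    stop_slurrycbc("parameter", "week must be >= 0 and replicate >= 1")

  steps <- steps[order(steps$volume_mL), need, drop = FALSE]
  # duplicate volumes: keep the last reading taken at that volume
  dup <- duplicated(steps$volume_mL, fromLast = TRUE)
  steps <- steps[!dup, , drop = FALSE]
  rownames(steps) <- NULL
  if (nrow(steps) < 10L)
    stop_slurrycbc("insufficient_data",
      "only %d dosing steps; at least 10 are required", nrow(steps))
  if (any(diff(steps$volume_mL) < 0))
    stop_slurrycbc("data", "cumulative volume is not non-decreasing")
  if (any(steps$pH <= 0 | steps$pH >= 14))
    stop_slurrycbc("data", "pH readings must lie in (0, 14)")

  structure(list(sample_id = sample_id, slurry_type = slurry_type,
                 storage = storage, week = week, replicate = replicate,
                 direction = direction, titrant = titrant,
                 titrant_molarity = titrant_molarity,
                 sample_mass = sample_mass, diluent_mass = diluent_mass,
                 steps = steps),
            class = "titration_record")
}

#' @export
print.titration_record <- function(x, ...) {
  cat(sprintf("<titration_record> %s (%s, %s, week %d, rep %d)\n",
              x$sample_id, x$slurry_type, x$storage, x$week, x$replicate))
  cat(sprintf("  %s with %.3g M %s; %d steps, %.2f..%.2f mL, pH %.2f -> %.2f\n",
              x$direction, x$titrant_molarity, x$titrant, nrow(x$steps),
              min(x$steps$volume_mL), max(x$steps$volume_mL),
              x$steps$pH[1], x$steps$pH[nrow(x$steps)]))
  cat(sprintf("  sample %.3g kg slurry + %.3g kg water, %.1f degC\n",
              x$sample_mass, x$diluent_mass, mean(x$steps$temperature)))
  invisible(x)
}

#' Titrant dose per kg slurry
#'
#' Converts the cumulative titrant volumes of a record into amounts of
#' strong acid/base per kg slurry: amount_i = volume_i (L) x molarity /
#' sample_mass. The denominator is the slurry mass before dilution; the
#' dilution water adds no buffering and is excluded.
#'
#' @param record a [titration_record()].
#' @return numeric vector of amounts, mol kg-1 slurry, one per step.
#' @examples
#' # 10 mL of 0.5 M titrant on 0.05 kg slurry is 0.1 mol/kg
#' @export
normalize_amount <- function(record) {
  if (record$sample_mass <= 0) stop_slurrycbc("parameter", "sample_mass must be > 0")
  record$steps$volume_mL / 1000 * record$titrant_molarity / record$sample_mass
}

#' Conversion factor between per-kg-solution and per-kg-slurry bases
#'
#' The simulator's mixture totals and [analytic_buffer_capacity()] are per kg
#' of titrated solution (slurry + dilution water); the determination model
#' reports per kg slurry. beta_slurry = beta_solution * factor.
#'
#' @param record a [titration_record()].
#' @return (sample_mass + diluent_mass) / sample_mass.
#' @export
slurry_basis_factor <- function(record) {
  (record$sample_mass + record$diluent_mass) / record$sample_mass
}
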