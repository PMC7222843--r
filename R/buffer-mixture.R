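# Reference dissociation constants at 25 degC with van 't Hoff enthalpies
# (kJ mol-1). Literature values; only the ammonium pKs of 9.25 is also the
# field's routinely quoted number for slurry.
.BUFFER_CONSTANTS <- list(
  acetic    = list(type = "monoprotic_acid", pKa_ref = 4.757,           dH = -0.4),
  carbonate = list(type = "diprotic_acid",   pKa_ref = c(6.35, 10.33),  dH = c(7.6, 14.9)),
  ammonium  = list(type = "cation_acid",     pKa_ref = 9.25,            dH = 52)
)
.PKW_REF <- 14.00
.DH_W <- 55.8

#' Define one buffer species
#'
#' @param name species label; `"acetic"`, `"carbonate"` and `"ammonium"`
#'   fill in reference constants automatically.
#' @param total analytical total of the species, mol kg-1 solution (>= 0).
#' @param type one of `"monoprotic_acid"` (VFA as acetic),
#'   `"diprotic_acid"` (carbonate: H2CO3*/HCO3-/CO3 2-), `"cation_acid"`
#'   (ammonium NH4+/NH3). Taken from the named defaults when omitted.
#' @param pKa_ref reference pKa value(s) at 25 degC; strictly increasing for
#'   a diprotic acid.
#' @param dH dissociation enthalpy (kJ mol-1) per step, for van 't Hoff
#'   temperature correction.
#' @return a `buffer_species` list.
#' @examples
#' buffer_species("acetic", total = 0.05)
#' buffer_species("ammonium", total = 0.17)
#' @export
buffer_species <- function(name, total, type = NULL, pKa_ref = NULL, dH = NULL) {
  def <- .BUFFER_CONSTANTS[[name]]
  if (is.null(type)) type <- def$type
  if (is.null(pKa_ref)) pKa_ref <- def$pKa_ref
  if (is.null(dH)) dH <- def$dH
  if (is.null(type) || is.null(pKa_ref) || is.null(dH))
    stop_slurrycbc("parameter",
      "species '%s' is not a known preset; supply type, pKa_ref and dH", name)
  if (!is.numeric(total) || length(total) != 1L || total < 0)
    stop_slurrycbc("parameter", "total must be a single number >= 0")
  if (type == "diprotic_acid" && (length(pKa_ref) != 2L || diff(pKa_ref) <= 0))
    stop_slurrycbc("parameter", "a diprotic acid needs two strictly increasing pKa_ref values")
  structure(list(name = name, type = type, total = total,
                 pKa_ref = pKa_ref, dH = rep_len(dH, length(pKa_ref))),
            class = "buffer_species")
}

#' Assemble a buffer mixture for simulation
#'
#' A mixture is the closed-system composition the titration simulator works
#' on: buffer species totals (per kg of titrated solution), the temperature,
#' and a signed inert-charge offset representing non-reacting ions (e.g. the
#' chloride of dissolved ammonium chloride, or background mineral cations);
#' the offset fixes the initial pH. Use `initial_pH` to have the offset
#' solved for you.
#'
#' @param species list of [buffer_species()] objects (may be empty: water).
#' @param temperature degC, default 25.
#' @param inert_charge_offset signed inert ion charge, mol kg-1 solution.
#'   Positive values (surplus inert cations) raise the initial pH.
#' @param initial_pH if given, `inert_charge_offset` is solved so the
#'   untitrated mixture sits at this pH (overrides `inert_charge_offset`).
#' @param pKw_ref,dH_w water autoprotolysis constant at 25 degC and its
#'   van 't Hoff enthalpy (kJ mol-1).
#' @return a `buffer_mixture` list.
#' @examples
#' # half-neutralised acetate buffer: pH == pKa
#' m <- buffer_mixture(list(buffer_species("acetic", 0.05)),
#'                     inert_charge_offset = 0.025)
#' solve_pH(m)
#' @export
buffer_mixture <- function(species = list(), temperature = 25,
                           inert_charge_offset = 0, initial_pH = NULL,
                           pKw_ref = .PKW_REF, dH_w = .DH_W) {
  if (inherits(species, "buffer_species")) species <- list(species)
  mix <- structure(list(species = species, temperature = temperature,
                        inert_charge_offset = inert_charge_offset,
                        pKw_ref = pKw_ref, dH_w = dH_w),
                   class = "buffer_mixture")
  if (!is.null(initial_pH)) {
    if (initial_pH <= 0 || initial_pH >= 14)
      stop_slurrycbc("parameter", "initial_pH must lie in (0, 14)")
    mix$inert_charge_offset <- 0
    # f is linear in the offset, so one evaluation pins it exactly
    mix$inert_charge_offset <- -charge_imbalance(mix, initial_pH)
  }
  solve_pH(mix)  # errors early if the charge balance is unsolvable
  mix
}

#' @export
print.buffer_mixture <- function(x, ...) {
  cat(sprintf("<buffer_mixture> %d species, %.1f degC, offset %+.4g mol/kg, pH0 %.2f\n",
              length(x$species), x$temperature, x$inert_charge_offset, solve_pH(x)))
  for (sp in x$species)
    cat(sprintf("  %-10s %-15s total %.4g mol/kg, pKa(25) %s\n",
                sp$name, sp$type, sp$total, paste(sp$pKa_ref, collapse = "/")))
  invisible(x)
}

# Table-style slurry composition presets: acetic-acid equivalent (g kg-1),
# TAN (kg N m-3) and TIC (kg C m-3) of fresh fattening pig, dairy cow and
# sow slurry at week 0 and after 8 weeks of cold/warm storage.
.SLURRY_PRESETS <- data.frame(
  slurry_type = rep(c("fattening_pig", "dairy_cow", "sow"), each = 3),
  profile     = rep(c("week0", "week8_cold", "week8_warm"), 3),
  acetic_eq   = c(9.30, 8.10, 4.90, 7.70, 7.27, 9.03, 2.90, 3.00, 2.93),
  tan         = c(2.50, 2.35, 3.33, 2.48, 2.31, 2.96, 4.80, 4.88, 4.71),
  tic         = c(1.48, 1.48, 1.99, 1.43, 1.31, 1.33, 1.06, 1.45, 1.89),
  stringsAsFactors = FALSE
)

#' Slurry composition presets for the simulator
#'
#' Builds a [buffer_mixture()] from measured bulk composition of fattening
#' pig, dairy cow or sow slurry (acetic-acid equivalent, total ammoniacal
#' nitrogen TAN, total inorganic carbon TIC), converting to mol kg-1 assuming
#' a slurry density of 1 kg L-1 and the protocol's 1:1 dilution with water.
#' VFA enters as acetic acid, TIC as total carbonate, TAN as ammonium.
#'
#' @param slurry_type `"fattening_pig"`, `"dairy_cow"` or `"sow"`.
#' @param week_profile `"week0"`, `"week8_cold"` or `"week8_warm"`.
#' @param temperature degC.
#' @param initial_pH pH the untitrated diluted sample is set to via the
#'   inert-charge offset; default 7.5, a typical fresh-slurry value.
#' @param dilution_factor factor applied to the per-kg-slurry totals to get
#'   per-kg-solution totals; 0.5 for the 50 g + 50 g protocol.
#' @return a `buffer_mixture`.
#' @examples
#' preset_mixture("sow")                 # fresh sow slurry, diluted 1:1
#' preset_mixture("fattening_pig", "week8_warm", temperature = 23.6)
#' @export
preset_mixture <- function(slurry_type = c("fattening_pig", "dairy_cow", "sow"),
                           week_profile = c("week0", "week8_cold", "week8_warm"),
                           temperature = 25, initial_pH = 7.5,
                           dilution_factor = 0.5) {
  slurry_type <- match.arg(slurry_type)
  week_profile <- match.arg(week_profile)
  row <- .SLURRY_PRESETS[.SLURRY_PRESETS$slurry_type == slurry_type &
                         .SLURRY_PRESETS$profile == week_profile, ]
  # molar masses: acetic acid 60.05 g/mol, N 14.007, C 12.011; density 1 kg/L
  vfa <- row$acetic_eq / 60.05 * dilution_factor
  tan <- row$tan / 14.007 * dilution_factor
  tic <- row$tic / 12.011 * dilution_factor
  buffer_mixture(
    species = list(buffer_species("acetic", vfa),
                   buffer_species("carbonate", tic),
                   buffer_species("ammonium", tan)),
    temperature = temperature, initial_pH = initial_pH
  )
}
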