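#' Titration protocol settings
#'
#' Mirrors the laboratory protocol: dynamic dosing with a capped step volume,
#' 0.5 M titrant, 50 g slurry diluted with 50 g water. The adaptive rule
#' shrinks the dose near steep curve regions so no step changes pH by more
#' than `delta_pH_max`.
#'
#' @param titrant "HCl" or "NaOH".
#' @param molarity titrant molarity, mol L-1.
#' @param target_pH pH at which dosing stops (crossed, not hit exactly);
#'   defaults 2.5 for HCl, 12 for NaOH.
#' @param max_step_mL maximum single dose, mL.
#' @param sample_mass,diluent_mass kg slurry and kg dilution water; their sum
#'   is the solution mass the mixture totals refer to.
#' @param delta_pH_max largest per-step pH change the dosing controller
#'   accepts before halving the dose.
#' @param after_acidification_to if non-NA and `titrant` is NaOH, the sample
#'   is first brought to this pH with strong acid (closed system, acid stays
#'   as inert charge), and the record direction becomes
#'   `alkalize_after_acid`.
#' @return a `titration_protocol` list.
#' @export
titration_protocol <- function(titrant = c("HCl", "NaOH"), molarity = 0.5,
                               target_pH = NULL, max_step_mL = 0.5,
                               sample_mass = 0.05, diluent_mass = 0.05,
                               delta_pH_max = 0.2,
                               after_acidification_to = NA_real_) {
  titrant <- match.arg(titrant)
  if (is.null(target_pH)) target_pH <- if (titrant == "HCl") 2.5 else 12
  if (molarity <= 0 || max_step_mL <= 0)
    stop_slurrycbc("parameter", "molarity and max_step_mL must be > 0")
  if (!is.na(after_acidification_to) && titrant != "NaOH")
    stop_slurrycbc("parameter", "after_acidification_to applies to NaOH titrations")
  structure(list(titrant = titrant, molarity = molarity, target_pH = target_pH,
                 max_step_mL = max_step_mL, sample_mass = sample_mass,
                 diluent_mass = diluent_mass, delta_pH_max = delta_pH_max,
                 after_acidification_to = after_acidification_to),
            class = "titration_protocol")
}

#' Forward-simulate a titration
#'
#' Doses titrant step by step into a closed-system [buffer_mixture()],
#' solving the charge balance after every dose, until the target pH is
#' crossed. The dose controller emulates dynamic titration: it starts at the
#' protocol's maximum step volume and halves the dose until the step's pH
#' change is at most `delta_pH_max`. Optional instrument noise adds Gaussian
#' pH read error and quantises dose volumes to a resolution.
#'
#' @param mixture a [buffer_mixture()]; totals are per kg of titrated
#'   solution (`sample_mass + diluent_mass`).
#' @param protocol a [titration_protocol()].
#' @param noise optional list with elements `pH_sd` (Gaussian pH read noise,
#'   pH units) and `volume_resolution_mL` (dose quantisation); NULL for a
#'   noise-free record.
#' @param seed integer seed for the noise model; required when `noise` is
#'   given. The caller's RNG state is restored afterwards.
#' @param sample_id,slurry_type,storage,week,replicate metadata passed to
#'   [titration_record()].
#' @return a `titration_record` with `slurry_type = "synthetic"` by default.
#' @examples
#' mix <- buffer_mixture(list(buffer_species("acetic", 0.05)), initial_pH = 7.2)
#' rec <- simulate_titration(mix, titration_protocol("HCl"))
#' @export
simulate_titration <- function(mixture, protocol = titration_protocol(),
                               noise = NULL, seed = NULL,
                               sample_id = "synthetic", slurry_type = "synthetic",
                               storage = "none", week = 0, replicate = 1) {
  soln_kg <- protocol$sample_mass + protocol$diluent_mass
  direction <- if (protocol$titrant == "HCl") "acidify" else "alkalize"

  if (!is.null(noise)) {
    if (is.null(seed)) stop_slurrycbc("parameter", "a seed is required with a noise model")
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  pH_sd <- if (is.null(noise)) 0 else noise$pH_sd %||% 0
  vres <- if (is.null(noise)) 0 else noise$volume_resolution_mL %||% 0

  mix <- mixture
  if (!is.na(protocol$after_acidification_to)) {
    direction <- "alkalize_after_acid"
    tgt <- protocol$after_acidification_to
    # the acid dose that holds the mixture at tgt is the charge imbalance there
    a0 <- charge_imbalance(mix, tgt)
    if (a0 < 0)
      stop_slurrycbc("protocol", "mixture already below pre-acidification pH %.2f", tgt)
    # the spent strong acid stays in solution as inert anion charge
    mix$inert_charge_offset <- mix$inert_charge_offset - a0
  }

  going_down <- direction == "acidify"
  dose_max <- protocol$max_step_mL / 1000 * protocol$molarity / soln_kg
  amount <- 0
  pH_true <- solve_pH(mix)
  read <- function(p) if (pH_sd > 0) p + stats::rnorm(1, 0, pH_sd) else p
  vol_of <- function(a) {
    v <- a * soln_kg / protocol$molarity * 1000
    if (vres > 0) round(v / vres) * vres else v
  }
  vols <- 0; pHs <- read(pH_true)
  crossed <- function(p) if (going_down) p <= protocol$target_pH else p >= protocol$target_pH
  n_step <- 0L
  while (!crossed(pH_true)) {
    n_step <- n_step + 1L
    if (n_step > 10000L)
      stop_slurrycbc("protocol",
        "target pH %.2f not reached within 10000 steps (deepest pH %.2f)",
        protocol$target_pH, pH_true)
    st <- dose_max
    repeat {
      p2 <- if (going_down) solve_pH(mix, added_acid = amount + st)
            else solve_pH(mix, added_base = amount + st)
      if (abs(p2 - pH_true) <= protocol$delta_pH_max || st <= dose_max / 512) break
      st <- st / 2
    }
    amount <- amount + st
    pH_true <- p2
    vols <- c(vols, vol_of(amount))
    pHs <- c(pHs, read(pH_true))
  }
  steps <- data.frame(volume_mL = vols, pH = pmin(pmax(pHs, 1e-3), 14 - 1e-3),
                      temperature = mixture$temperature)
  titration_record(steps, sample_id = sample_id, slurry_type = slurry_type,
                   storage = storage, week = week, replicate = replicate,
                   direction = direction,
                   titrant = protocol$titrant,
                   titrant_molarity = protocol$molarity,
                   sample_mass = protocol$sample_mass,
                   diluent_mass = protocol$diluent_mass)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
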