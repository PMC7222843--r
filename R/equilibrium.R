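#' @keywords internal
"_PACKAGE"

# Gas constant, J mol-1 K-1
.R_GAS <- 8.31446
.LN10 <- log(10)

#' Temperature correction of an acidity constant (van 't Hoff)
#'
#' Shifts a reference pKa (25 degC) to the titration temperature using the
#' integrated van 't Hoff relation with a temperature-independent reaction
#' enthalpy: pKa(T) = pKa_ref + dH / (R ln 10) * (1/T_K - 1/298.15 K).
#' A positive dissociation enthalpy therefore lowers the pKa as the sample
#' warms, which is why the pH of maximum buffer capacity of the ammonia and
#' carbonate buffers drifts downward in warm slurry.
#'
#' @param pKa_ref reference pKa at 25 degC (may be a vector, e.g. both
#'   carbonate steps).
#' @param dH reaction enthalpy of the dissociation step, kJ mol-1; recycled
#'   against `pKa_ref`.
#' @param temperature temperature in degC (0-50).
#' @return pKa value(s) at `temperature`.
#' @examples
#' pka_at_temperature(9.25, 52, 25)  # reference point, unchanged
#' pka_at_temperature(9.25, 52, 35)  # warmer -> lower pKa
#' @export
pka_at_temperature <- function(pKa_ref, dH, temperature) {
  if (any(temperature < 0 | temperature > 50))
    stop_slurrycbc("parameter", "temperature must be within 0..50 degC")
  T_K <- temperature + 273.15
  pKa_ref + (dH * 1000 / (.R_GAS * .LN10)) * (1 / T_K - 1 / 298.15)
}

# Charge imbalance f(pH) of a mixture, mol kg-1 solution.
# f = [H+] + inert offset + base counter-ion + protonated cation acids
#     - [OH-] - acid counter-ion - anionic conjugate-base charge.
# Strictly decreasing in pH, so the equilibrium pH is its unique root.
charge_imbalance <- function(mixture, pH, added_acid = 0, added_base = 0) {
  H <- 10^(-pH)
  Kw <- 10^(-pka_at_temperature(mixture$pKw_ref, mixture$dH_w, mixture$temperature))
  f <- H - Kw / H + added_base - added_acid + mixture$inert_charge_offset
  for (sp in mixture$species) {
    Ka <- 10^(-pka_at_temperature(sp$pKa_ref, sp$dH, mixture$temperature))
    f <- f + switch(sp$type,
      monoprotic_acid = -sp$total * Ka[1] / (Ka[1] + H),
      diprotic_acid = {
        den <- H^2 + Ka[1] * H + Ka[1] * Ka[2]
        -sp$total * (Ka[1] * H + 2 * Ka[1] * Ka[2]) / den
      },
      cation_acid = sp$total * H / (Ka[1] + H),
      stop_slurrycbc("parameter", "unknown species type '%s'", sp$type)
    )
  }
  f
}

#' Equilibrium pH of a buffer mixture under a titrant dose
#'
#' Solves the electroneutrality equation of an ideal (activity coefficients 1)
#' closed-system mixture of monoprotic acids, diprotic acids and cation acids
#' for pH, with all equilibrium constants corrected to the mixture
#' temperature. Doses are the strong acid/base already added, expressed per
#' kg of titrated solution.
#'
#' @param mixture a [buffer_mixture()].
#' @param added_acid,added_base strong acid / base dose, mol kg-1 solution.
#' @return equilibrium pH.
#' @examples
#' solve_pH(buffer_mixture(list()))  # pure water at 25 degC -> 7
#' @export
solve_pH <- function(mixture, added_acid = 0, added_base = 0) {
  f <- function(p) charge_imbalance(mixture, p, added_acid, added_base)
  lo <- 0.1; hi <- 13.9
  if (f(lo) < 0 || f(hi) > 0)
    stop_slurrycbc("composition",
      "charge balance has no root in pH (%.1f, %.1f); composition or dose out of range",
      lo, hi)
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Analytic buffer capacity (buffer index) of a mixture
#'
#' The classical buffer index beta = dC_B/dpH, where C_B(pH) is the
#' closed-form strong-base dose implied by the charge balance. Evaluated by a
#' central finite difference (delta pH = 1e-4) on that closed form, it is the
#' brute-force independent oracle against which the reciprocal-slope CBC of
#' [compute_cbc()] is checked. Units are mol per kg of titrated solution per
#' pH; multiply by [slurry_basis_factor()] to compare with CBC reported per
#' kg slurry.
#'
#' @param mixture a [buffer_mixture()].
#' @param pH pH value(s) in (0, 14).
#' @param delta finite-difference half-step in pH.
#' @return beta, mol kg-1 solution pH-1 (vectorised over `pH`).
#' @export
analytic_buffer_capacity <- function(mixture, pH, delta = 1e-4) {
  if (any(pH <= 0 | pH >= 14))
    stop_slurrycbc("parameter", "pH must lie in (0, 14)")
  # base dose to hold the mixture at a given pH: C_B(pH) = -f(pH)
  vapply(pH, function(p) {
    (-charge_imbalance(mixture, p + delta) + charge_imbalance(mixture, p - delta)) /
      (2 * delta)
  }, numeric(1))
}
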