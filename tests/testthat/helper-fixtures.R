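# Fixtures built in code: linear-in-amount records and small mixtures.

# record whose pH falls (or rises) linearly with titrant amount
make_linear_record <- function(pH_from, pH_to, total_amount = 0.2, n = 60,
                               direction = if (pH_to < pH_from) "acidify" else "alkalize",
                               sample_mass = 0.05, molarity = 0.5, ...) {
  amount <- seq(0, total_amount, length.out = n)
  steps <- data.frame(
    volume_mL = amount * sample_mass / molarity * 1000,
    pH = seq(pH_from, pH_to, length.out = n),
    temperature = 25
  )
  titration_record(steps, direction = direction, sample_mass = sample_mass,
                   titrant_molarity = molarity, ...)
}

# record sampled from an explicit pH(amount) polynomial
make_poly_record <- function(coefs, amounts, direction = "acidify",
                             sample_mass = 0.05, molarity = 0.5, ...) {
  pH <- drop(outer(amounts, seq_along(coefs) - 1, `^`) %*% coefs)
  steps <- data.frame(volume_mL = amounts * sample_mass / molarity * 1000,
                      pH = pH, temperature = 25)
  titration_record(steps, direction = direction, sample_mass = sample_mass,
                   titrant_molarity = molarity, ...)
}

acetate_mixture <- function(total = 0.05, temperature = 25, initial_pH = 7.2)
  buffer_mixture(list(buffer_species("acetic", total)),
                 temperature = temperature, initial_pH = initial_pH)

ammonium_chloride_mixture <- function(total = 0.1713, temperature = 25) {
  buffer_mixture(list(buffer_species("ammonium", total)),
                 temperature = temperature, inert_charge_offset = -total)
}

# random realistic slurry-like mixture (acid-side testing)
random_mixture <- function() {
  buffer_mixture(
    list(buffer_species("acetic", stats::runif(1, 0.02, 0.08)),
         buffer_species("carbonate", stats::runif(1, 0.04, 0.09)),
         buffer_species("ammonium", stats::runif(1, 0.08, 0.18))),
    temperature = stats::runif(1, 20, 30), initial_pH = stats::runif(1, 7.2, 7.8)
  )
}
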