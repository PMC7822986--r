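# Shared fixtures: small populations and standard stimuli, built in code.

std_biphasic <- function(ipg = 8e-6, rate = 80, leading = "cathodic") {
  make_biphasic_train(rate, 25e-6, ipg, 0.4, level_uA = 1,
                      leading = leading)
}

std_qp <- function(centre) {
  make_quadraphasic_train(centre, 80, 42e-6, 8e-6, 0.4, level_uA = 1)
}

test_pop <- function(n = 100, sd = 3, mode = "none", k = 1, seed = 42) {
  deg <- if (mode %in% c("none", "peripheral_disabled"))
    degeneration_spec(mode) else degeneration_spec(mode, k)
  sample_population(population_config(n, sd, degeneration = deg,
                                      seed = seed))
}

# a symmetric two-site fibre (identical parameters at both sites), used by
# the polarity-symmetry property
symmetric_fibre <- function(rho = 0.75) {
  s <- site_params(1, 1 / 300e-6, delta_t = 4, sensitivity = 0.009,
                   polarity_gain = rho)
  fibre_params(peripheral = s, central = s, noise_rs = 0)
}
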