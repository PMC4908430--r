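# Shared fixture builders. Everything is generated in code; no data files.

# sampling grid that resolves both phases of a fast/slow biexponential
biphasic_times <- function() c(0, 0.5, 1, 2, 4, 8, 30, 60, 120, 240, 400, 700)

noiseless_mono_tc <- function(k = 0.01, A = 0.9, plateau = 0.1,
                              times = seq(0, 700, 100)) {
  time_course(times, plateau + A * exp(-k * times))
}

noiseless_bi_tc <- function(k1 = 1, k2 = 0.01, A1 = 0.5, A2 = 0.5,
                            plateau = 0, times = biphasic_times()) {
  time_course(times, plateau + A1 * exp(-k1 * times) + A2 * exp(-k2 * times))
}

quiet_titration <- function(n, K, kmax = 1, lo = 0.1, hi = 3, npts = 8,
                            sd = 0, seed = 1) {
  gen_titration(n, K, kmax,
                exp(seq(log(lo), log(hi), length.out = npts)),
                noise_spec("lognormal_multiplicative", sd, seed = seed))
}

# panel -> records with activation energies, against a declared constant
# baseline (absolute value cancels in every slope)
panel_with_Ea <- function(panel, k_uncat = 1e-9) {
  led <- energy_ledger(panel$construct_id, panel$k_obs,
                       uncat_model("constant", k_uncat))
  panel$E_a_apparent <- led$E_a_apparent
  panel
}
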