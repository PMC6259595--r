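# Long-running simulations shared across test files, computed once per run.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

san_traj_default <- function() {
  cached("san_default", simulate(san_model(), tmax = 7000))
}

san_traj_noinact <- function() {
  cached("san_noinact",
         simulate(san_model(san_params(ca_inact = FALSE)), tmax = 7000))
}

fs_traj_80pA <- function() {
  cached("fs_80",
         simulate(fs_model(), tmax = 2500, sample_dt = 0.02, stim = 80,
                  stim_onset = 500, stim_duration = 2000))
}

fs_rheobase_default <- function() {
  cached("fs_rheobase", find_rheobase(fs_model()))
}

# a K channel whose Nernst potential is exactly -89 mV at the default
# temperature, used in several oracle tests
k_channel_exact <- function(bias = 0.5, v_K = -89,
                            constants = transport_constants()) {
  mechanism_catalog("K channel", bias = bias,
                    conc = list(K = c(out = 4, `in` = 4 * exp(-v_K / constants$v_T))))
}

# Na-K ATPase with concentrations composing exactly v_Na = 60, v_K = -89
nak_exact <- function(bias = 0.5, v_atp = -420,
                      constants = transport_constants()) {
  vT <- constants$v_T
  mechanism_catalog("Na-K ATPase", bias = bias, v_atp = v_atp,
                    conc = list(Na = c(out = 12 * exp(60 / vT), `in` = 12),
                                K = c(out = 4, `in` = 4 * exp(89 / vT))))
}
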