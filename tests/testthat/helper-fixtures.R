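# Shared fixtures: all built in code, nothing bundled.

bare_chain <- function(dp = 10) structure_config(cellulose_rings = 1, dp_cellulose = dp)

# amorphous, uninhibited, lignin-free parameter set with selective overrides
plain_params <- function(...) {
  parameter_set(X_cellulose = 0, X_hemicellulose = 0,
                r_cellulose = 1, r_hemicellulose = 1, L_adh = 0,
                omega_EG_glc = 0, omega_CBH_glc = 0, omega_BGL_glc = 0,
                omega_EG_cbs = 0, omega_CBH_cbs = 0, ...)
}

# first grid time at which conversion reaches `level` percent (NA if never)
time_to_conversion <- function(tc, level = 50) {
  i <- which(tc$conversion_pct >= level)
  if (length(i)) tc$time_h[i[1]] else NA_real_
}

# completion time of an absorbing trajectory (time of the last event)
completion_time <- function(params, structure, seed, t_max = 1e5) {
  tc <- ssa_run(params, structure, t_max = t_max, grid = c(0), seed = seed,
                check_mass = FALSE)
  attr(tc, "engine_result")$t_end
}
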