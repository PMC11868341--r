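# small helpers shared across test files

base_params <- function(...) adex_params(...)

# brute-force oracle for fixed_points(): dense sign scan of the equilibrium
# residual, with linear interpolation inside each sign-change cell
scan_roots <- function(params, z, n = 1e5) {
  Vs <- seq(params$E_L - 40, params$V_D, length.out = n)
  fv <- equilibrium_residual_oracle(params, Vs, z)
  i <- which(sign(fv[-1]) * sign(fv[-n]) < 0)
  Vs[i] - fv[i] * (Vs[i + 1] - Vs[i]) / (fv[i + 1] - fv[i])
}

# residual written out independently of the package internals
equilibrium_residual_oracle <- function(p, V, z) {
  p$g_L * ((p$E_L + z) - V) +
    p$g_L * p$Delta_T * exp((V - (p$V_T - p$beta * z)) / p$Delta_T) -
    p$a * (V - (p$E_L + z)) - p$g_p * z + p$I_s
}

# synthetic simulation stub accepted by classify_pattern()
fake_sim <- function(spikes, duration = 20000, t_ref = 5) {
  list(spikes = spikes, duration = duration, params = list(t_ref = t_ref))
}

rest_init <- function(n) {
  list(V = rep(-65, n), w = numeric(n), z = numeric(n),
       g_E = numeric(n), g_I = numeric(n))
}
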