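#' Right-hand side of the extended AdEx equations
#'
#' Evaluates the vector field of the three-variable model at one or more
#' states. The membrane equation is
#' `C dV/dt = g_L((E_L+z)-V) + g_L*Delta_T*exp((V-(V_T-beta*z))/Delta_T) - w - g_p*z + I_s`,
#' the adaptation equation `tau_w dw/dt = a(V-(E_L+z)) - w`, and the slow
#' impairment equation `dz/dt = epsilon*(Z0 - V - z)`.
#'
#' @param state A data frame with numeric columns `V` (mV), `w` (pA), `z` (mV);
#'   one row per state to evaluate.
#' @param params An [adex_params()] object.
#' @return A tibble with columns `dV` (mV/ms), `dw` (pA/ms), `dz` (mV/ms),
#'   one row per input state.
#' @examples
#' p <- adex_params()
#' adex_vector_field(data.frame(V = -55, w = 0, z = 0), p)
#' @export
adex_vector_field <- function(state, params) {
  stopifnot(is.data.frame(state), all(c("V", "w", "z") %in% names(state)))
  validate_adex_params(params)
  V <- state$V; w <- state$w; z <- state$z
  if (!all(is.finite(V) & is.finite(w) & is.finite(z))) {
    abort("non-finite state passed to adex_vector_field()")
  }
  ex <- exp((V - (params$V_T - params$beta * z)) / params$Delta_T)
  if (!all(is.finite(ex))) {
    abort(paste("exponential term overflowed: V is far above V_D, which means",
                "spike detection was missed upstream"))
  }
  dV <- (params$g_L * ((params$E_L + z) - V) + params$g_L * params$Delta_T * ex -
           w - params$g_p * z + params$I_s) / params$C
  dw <- (params$a * (V - (params$E_L + z)) - w) / params$tau_w
  dz <- params$epsilon * (params$Z0 - V - z)
  tibble(dV = dV, dw = dw, dz = dz)
}

#' After-spike reset rule
#'
#' Applies the reset: whenever `V >= V_D`, the membrane potential jumps to
#' `V_R` and the adaptation current is incremented by `b`; `z` is untouched.
#' Calling this on a state whose `V` is still below `V_D` is a contract
#' violation and raises an error rather than silently doing nothing.
#'
#' @param state A data frame with columns `V`, `w`, `z`; every row must
#'   satisfy `V >= V_D`.
#' @param params An [adex_params()] object.
#' @return A tibble with the reset states and a `t_since_spike` column set
#'   to 0.
#' @export
adex_reset <- function(state, params) {
  stopifnot(is.data.frame(state), all(c("V", "w", "z") %in% names(state)))
  validate_adex_params(params)
  if (any(state$V < params$V_D)) {
    abort("adex_reset() called with V < V_D: reset applies only at detection")
  }
  tibble(V = rep(params$V_R, nrow(state)), w = state$w + params$b,
         z = state$z, t_since_spike = 0)
}

#' Simulate one extended AdEx neuron
#'
#' Fixed-step explicit-Euler integration with spike detection at `V >= V_D`
#' checked after each step. The spike time recorded is the end time of the
#' detecting step. During the refractory window `t_ref` the membrane is
#' clamped at `V_R` while `w` and `z` keep integrating against the clamped
#' potential (set `freeze_w_refractory = TRUE` to hold `w` as well).
#'
#' @param params An [adex_params()] object.
#' @param duration Total simulated time (ms).
#' @param dt Time step (ms); must be positive and at most 1 ms.
#' @param init Named list or data frame row with initial `V`, `w`, `z`
#'   (defaults to `V = E_L`, `w = 0`, `z = 0`).
#' @param sample_every Sampling interval of the recorded trace (ms); must be
#'   a multiple of `dt`.
#' @param frozen_z Hold `z` constant (the `epsilon -> 0` fast-subsystem limit).
#' @param freeze_w_refractory Freeze `w` during the refractory window instead
#'   of integrating it against the clamped potential.
#' @return An object of class `adex_sim`: list with `trace` (tibble `time`,
#'   `V`, `w`, `z`), `spikes` (numeric vector of spike times, ms), `duration`,
#'   `dt`, and the parameter set used.
#' @examples
#' sim <- simulate_neuron(adex_params(Z0 = -45), duration = 2000)
#' length(sim$spikes)
#' @export
simulate_neuron <- function(params, duration, dt = 0.1,
                            init = list(V = params$E_L, w = 0, z = 0),
                            sample_every = 1, frozen_z = FALSE,
                            freeze_w_refractory = FALSE) {
  validate_adex_params(params)
  if (dt <= 0) abort("dt must be positive")
  if (dt > 1) abort("dt > 1 ms is rejected: too coarse for the exponential term")
  if (duration < dt) abort("duration must be at least dt")
  stride <- as.integer(round(sample_every / dt))
  if (stride < 1 || abs(stride * dt - sample_every) > 1e-9) {
    abort("sample_every must be a positive multiple of dt")
  }
  init <- as.list(init)
  res <- adex_integrate_cpp(params_vector(params), duration, dt,
                            init$V, init$w, init$z,
                            if (is.null(init$t_since_spike)) Inf else init$t_since_spike,
                            stride, frozen_z, freeze_w_refractory)
  structure(
    list(trace = tibble(time = res$time, V = res$V, w = res$w, z = res$z),
         spikes = res$spikes,
         duration = duration, dt = dt, params = params,
         final = list(V = res$V_end, w = res$w_end, z = res$z_end,
                      t_since_spike = res$t_since_end)),
    class = "adex_sim")
}

#' @export
print.adex_sim <- function(x, ...) {
  cat(sprintf("Extended AdEx simulation: %.0f ms at dt = %g ms, %d spikes (Z0 = %g mV)\n",
              x$duration, x$dt, length(x$spikes), x$params$Z0))
  invisible(x)
}

#' @rdname simulate_neuron
#' @param x An `adex_sim` object.
#' @param ... Unused.
#' @export
tidy.adex_sim <- function(x, ...) x$trace

#' @rdname simulate_neuron
#' @export
glance.adex_sim <- function(x, ...) {
  post <- x$spikes
  tibble(n_spikes = length(post), duration = x$duration, dt = x$dt,
         rate_hz = 1000 * length(post) / x$duration, Z0 = x$params$Z0)
}

#' Reference classical AdEx integrator
#'
#' Plain-R explicit-Euler integration of the two-variable AdEx model (no
#' impairment variable): `C dV/dt = g_L(E_L-V) + g_L*Delta_T*exp((V-V_T)/
#' Delta_T) - w + I_s`, `tau_w dw/dt = a(V-E_L) - w`, with the same reset and
#' refractory semantics as [simulate_neuron()]. Used as the independent
#' reference for the classical limit (`z = 0`, frozen): the extended model
#' must reproduce it sample for sample.
#'
#' @inheritParams simulate_neuron
#' @return A list with `trace` (tibble `time`, `V`, `w`) and `spikes`.
#' @export
simulate_adex_classic <- function(params, duration, dt = 0.1,
                                  init = list(V = params$E_L, w = 0),
                                  sample_every = 1) {
  validate_adex_params(params)
  stride <- as.integer(round(sample_every / dt))
  n_steps <- round(duration / dt)
  V <- init$V; w <- init$w; t_since <- Inf
  n_samp <- n_steps %/% stride + 1
  s_t <- numeric(n_samp); s_V <- numeric(n_samp); s_w <- numeric(n_samp)
  s_V[1] <- V; s_w[1] <- w
  spikes <- numeric(0)
  k <- 1
  for (s in seq_len(n_steps)) {
    t_end <- s * dt
    refractory <- t_since < params$t_ref
    if (refractory) {
      V <- params$V_R
      w <- w + dt * ((params$a * (V - params$E_L) - w) / params$tau_w)
    } else {
      ex <- exp((V - params$V_T) / params$Delta_T)
      dV <- (params$g_L * (params$E_L - V) + params$g_L * params$Delta_T * ex -
               w + params$I_s) / params$C
      dw <- (params$a * (V - params$E_L) - w) / params$tau_w
      V <- V + dt * dV
      w <- w + dt * dw
    }
    t_since <- t_since + dt
    if (!refractory && V >= params$V_D) {
      spikes <- c(spikes, t_end)
      V <- params$V_R
      w <- w + params$b
      t_since <- 0
    }
    if (s %% stride == 0) {
      k <- k + 1
      s_t[k] <- t_end; s_V[k] <- V; s_w[k] <- w
    }
  }
  list(trace = tibble(time = s_t, V = s_V, w = s_w), spikes = spikes)
}

#' Write a sampled trace or a spike train to disk
#'
#' `write_trace()` writes the sampled trajectory as CSV with header
#' `time_ms,V_mV,w_pA,z_mV`; `write_spikes()` writes spike times as a
#' single-column TSV in ms.
#'
#' @param sim An `adex_sim` object (or a data frame with `time`, `V`, `w`,
#'   `z` for `write_trace()`; a numeric vector for `write_spikes()`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(sim, path) {
  tr <- if (inherits(sim, "adex_sim")) sim$trace else sim
  out <- data.frame(time_ms = tr$time, V_mV = tr$V, w_pA = tr$w, z_mV = tr$z)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
write_spikes <- function(sim, path) {
  sp <- if (inherits(sim, "adex_sim")) sim$spikes else sim
  utils::write.table(data.frame(time_ms = sp), path, sep = "\t",
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}
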