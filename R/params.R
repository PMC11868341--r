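#' Parameters of the extended AdEx neuron
#'
#' Constructs a validated parameter set for the extended adaptive exponential
#' integrate-and-fire neuron. The model adds to the classical AdEx a slow
#' impairment variable `z` that shifts the leak reversal to `E_L + z`, the
#' spike-initiation threshold to `V_T - beta * z`, and injects a counteractive
#' current `-g_p * z` (the lumped effect of pumps, co-transporters and
#' exchangers working against the impairment). `z` relaxes towards `Z0 - V` at
#' rate `epsilon`; `Z0` is the attractor potential of the impairment, and
#' less negative values model more severe ionic dysregulation.
#'
#' All quantities are in the canonical unit system mV / ms / pA / nS / pF,
#' which is dimensionally closed (nS * mV = pA, pF * mV / ms = pA). Published
#' tables often quote the adaptation time constant in seconds and the
#' impairment rate in 1/s; see [convert_params_si()] for a logged conversion.
#'
#' @param C Membrane capacitance (pF).
#' @param g_L Leak conductance (nS).
#' @param E_L Resting (leak reversal) potential (mV).
#' @param V_T Exponential spike-initiation threshold (mV).
#' @param Delta_T Sharpness of the exponential rise (mV).
#' @param tau_w Adaptation time constant (ms).
#' @param a Subthreshold adaptation conductance (nS).
#' @param b Spike-triggered adaptation increment (pA).
#' @param I_s External input current (pA).
#' @param V_D Spike-detection potential (mV); crossing it triggers the reset.
#' @param V_R Reset potential (mV); must lie strictly below `V_D`.
#' @param t_ref Refractory period (ms) during which V is clamped at `V_R`.
#' @param epsilon Relaxation rate of the impairment variable z (1/ms).
#' @param Z0 Attractor potential of z (mV).
#' @param g_p Counteractive conductance (nS).
#' @param beta Dimensionless scaling of the threshold shift by z.
#' @param ... Overrides passed as named values, e.g. `adex_params(Z0 = -45)`.
#'
#' @return An object of class `adex_params`: a named list of the sixteen
#'   constants above.
#' @examples
#' p <- adex_params(Z0 = -45)
#' p$Z0
#' @export
adex_params <- function(C = 200, g_L = 10, E_L = -65, V_T = -55, Delta_T = 2,
                        tau_w = 500, a = 1, b = 60, I_s = 0, V_D = -40,
                        V_R = -65, t_ref = 5, epsilon = 5e-4, Z0 = -40,
                        g_p = 10, beta = 0.5, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    abort(paste0("unknown parameter(s): ", paste(names(extra), collapse = ", ")))
  }
  p <- list(C = C, g_L = g_L, E_L = E_L, V_T = V_T, Delta_T = Delta_T,
            tau_w = tau_w, a = a, b = b, I_s = I_s, V_D = V_D, V_R = V_R,
            t_ref = t_ref, epsilon = epsilon, Z0 = Z0, g_p = g_p, beta = beta)
  validate_adex_params(p)
  structure(p, class = "adex_params")
}

validate_adex_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    abort(paste0("non-finite or non-scalar parameter(s): ",
                 paste(names(p)[!num], collapse = ", ")))
  }
  stopifnot(p$C > 0, p$g_L >= 0, p$Delta_T > 0, p$tau_w > 0, p$t_ref >= 0,
            p$epsilon >= 0, p$g_p >= 0)
  if (p$V_R >= p$V_D) abort("V_R must be strictly below V_D")
  invisible(p)
}

#' Convert SI-quoted parameters to the canonical unit system
#'
#' Published parameter tables for this model family quote `tau_w` in seconds
#' and `epsilon` in 1/s while everything else is already in mV / ms / pA / nS /
#' pF. This helper applies the two conversions (s -> ms, 1/s -> 1/ms) and
#' reports them via a message so that unit handling is visible in logs.
#'
#' @param tau_w_s Adaptation time constant in seconds.
#' @param epsilon_per_s Impairment relaxation rate in 1/s.
#' @param ... Remaining parameters, already canonical, passed to [adex_params()].
#' @param quiet Suppress the conversion message.
#' @return An `adex_params` object.
#' @export
convert_params_si <- function(tau_w_s, epsilon_per_s, ..., quiet = FALSE) {
  tau_w <- tau_w_s * 1000
  epsilon <- epsilon_per_s / 1000
  if (!quiet) {
    message(sprintf("converted tau_w = %g s -> %g ms; epsilon = %g /s -> %g /ms",
                    tau_w_s, tau_w, epsilon_per_s, epsilon))
  }
  adex_params(tau_w = tau_w, epsilon = epsilon, ...)
}

#' @export
print.adex_params <- function(x, ...) {
  cat("Extended AdEx parameters (mV / ms / pA / nS / pF):\n")
  print(unlist(x))
  invisible(x)
}

#' Read and write parameter sets as flat JSON
#'
#' Parameter sets are serialised as a single flat JSON object keyed by the
#' field names of [adex_params()].
#'
#' @param params An `adex_params` object.
#' @param path File path.
#' @return `write_adex_params()` returns `path` invisibly;
#'   `read_adex_params()` returns an `adex_params` object.
#' @export
write_adex_params <- function(params, path) {
  stopifnot(inherits(params, "adex_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_adex_params
#' @export
read_adex_params <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(adex_params, as.list(vals))
}

# parameter vector in the column order expected by the compiled cores
params_vector <- function(p) {
  unlist(p[c("C", "g_L", "E_L", "V_T", "Delta_T", "tau_w", "a", "b", "I_s",
             "V_D", "V_R", "t_ref", "epsilon", "Z0", "g_p", "beta")])
}
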