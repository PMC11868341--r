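#' Interspike-interval statistics and burst segmentation
#'
#' Computes summary statistics of a spike train and segments it into bursts.
#' Spikes separated by gaps larger than `t_inter` belong to different
#' segments; a segment counts as a burst when it contains at least two spikes
#' whose median interspike interval is below `t_intra` (a cluster of fast
#' spikes flanked by long silences).
#'
#' @param spikes Numeric vector of spike times (ms), strictly increasing.
#' @param t_intra Maximum within-burst interspike interval (ms).
#' @param t_inter Minimum silence separating bursts (ms).
#' @return A one-row tibble with `n_spikes`, `mean_isi` (ms, `NA` when fewer
#'   than two spikes), `cv_isi` (`NA` likewise), `n_bursts`, and a list-column
#'   `bursts` holding a tibble of segments (`start`, `end`, `n`, `median_isi`,
#'   `is_burst`).
#' @examples
#' isi_statistics(seq(100, 10000, by = 100))
#' @export
isi_statistics <- function(spikes, t_intra = 50, t_inter = 500) {
  stopifnot(is.numeric(spikes))
  if (is.unsorted(spikes, strictly = TRUE)) abort("spike times must be strictly increasing")
  n <- length(spikes)
  if (n == 0) {
    return(tibble(n_spikes = 0L, mean_isi = NA_real_, cv_isi = NA_real_,
                  n_bursts = 0L, bursts = list(empty_segments())))
  }
  isi <- diff(spikes)
  seg_id <- cumsum(c(0, isi > t_inter))
  seg <- tibble(time = spikes, id = seg_id) %>%
    group_by(.data$id) %>%
    summarise(start = min(.data$time), end = max(.data$time), n = dplyr::n(),
              median_isi = if (dplyr::n() > 1) stats::median(diff(.data$time)) else NA_real_,
              .groups = "drop") %>%
    mutate(is_burst = .data$n >= 2 & !is.na(.data$median_isi) &
             .data$median_isi < t_intra) %>%
    dplyr::select(-"id")
  tibble(n_spikes = n,
         mean_isi = if (n > 1) mean(isi) else NA_real_,
         cv_isi = if (n > 2) stats::sd(isi) / mean(isi) else NA_real_,
         n_bursts = sum(seg$is_burst),
         bursts = list(seg))
}

empty_segments <- function() {
  tibble(start = numeric(0), end = numeric(0), n = integer(0),
         median_isi = numeric(0), is_burst = logical(0))
}

#' Classify a firing pattern
#'
#' Labels a simulated trace as `quiescent`, `tonic`, `bursting`, or
#' `sustained_ictal` from its post-transient spike train. The first
#' `transient` ms are discarded so that the slow impairment variable has
#' expressed its regime. Rules, applied in order:
#'
#' * `quiescent` - post-transient firing rate below `quiescent_rate` (Hz);
#' * `sustained_ictal` - mean interspike interval at most
#'   `ictal_isi_factor * t_ref` (firing pinned near the refractory-limited
#'   maximum, where the adaptation current saturates), spiking occupying more
#'   than `ictal_active_frac` of the post-transient window, and at most one
#'   silent gap longer than `ictal_max_gap` ms. A single long silence is
#'   tolerated because the slow passage into the ictal state crosses one
#'   burst-like silence on its way to saturated firing; silences that *recur*
#'   are bursting, not ictal activity;
#' * `bursting` - at least two burst segments (clusters of interspike
#'   intervals below `t_intra`) and at least two recurring silences longer
#'   than `t_inter`;
#' * `tonic` - everything else: sustained spiking paced by adaptation.
#'
#' @param sim An `adex_sim` object from [simulate_neuron()], or a list with
#'   elements `spikes` and `duration`.
#' @param t_intra,t_inter Burst segmentation thresholds (ms), see
#'   [isi_statistics()].
#' @param transient Initial window to discard (ms).
#' @param min_window Minimum post-transient duration (ms); shorter runs are an
#'   error because the slow timescale cannot express its regime.
#' @param quiescent_rate Rate floor (Hz) below which the cell is quiescent.
#' @param ictal_isi_factor Multiple of `t_ref` bounding the mean ISI of
#'   sustained ictal firing.
#' @param ictal_max_gap Gap length (ms) above which a silence counts as long;
#'   more than one long silence disqualifies the ictal label.
#' @param ictal_active_frac Minimum fraction of the window occupied by
#'   spiking for the ictal label.
#' @param t_ref Refractory period (ms); taken from `sim$params` when present.
#' @return A one-row tibble with `label` and the features it was decided on:
#'   `n_spikes`, `rate_hz`, `mean_isi`, `cv_isi`, `n_bursts`,
#'   `max_gap_ms`, `active_fraction`.
#' @export
classify_pattern <- function(sim, t_intra = 50, t_inter = 500,
                             transient = 2000, min_window = 10000,
                             quiescent_rate = 0.1, ictal_isi_factor = 1.5,
                             ictal_max_gap = 200, ictal_active_frac = 0.9,
                             t_ref = NULL) {
  spikes <- sim$spikes
  duration <- sim$duration
  if (is.null(t_ref)) {
    t_ref <- if (!is.null(sim$params)) sim$params$t_ref else 5
  }
  window <- duration - transient
  if (window < min_window) {
    abort(sprintf("post-transient window (%g ms) shorter than %g ms: too short for the slow timescale",
                  window, min_window))
  }
  post <- spikes[spikes > transient]
  stats <- isi_statistics(post, t_intra = t_intra, t_inter = t_inter)
  gaps <- diff(c(transient, post, duration))
  max_gap <- if (length(gaps)) max(gaps) else window
  n_long_gaps <- sum(gaps > ictal_max_gap)
  n_silences <- sum(gaps > t_inter)
  active_fraction <- 1 - sum(gaps[gaps > ictal_max_gap]) / window
  rate_hz <- 1000 * length(post) / window

  label <- if (rate_hz < quiescent_rate) {
    "quiescent"
  } else if (!is.na(stats$mean_isi) && stats$mean_isi <= ictal_isi_factor * t_ref &&
             n_long_gaps <= 1 && active_fraction > ictal_active_frac) {
    "sustained_ictal"
  } else if (stats$n_bursts >= 2 && n_silences >= 2) {
    "bursting"
  } else {
    "tonic"
  }
  tibble(label = label, n_spikes = stats$n_spikes, rate_hz = rate_hz,
         mean_isi = stats$mean_isi, cv_isi = stats$cv_isi,
         n_bursts = stats$n_bursts, n_silences = n_silences,
         max_gap_ms = max_gap, active_fraction = active_fraction)
}

#' Sweep the impairment attractor and label each regime
#'
#' Simulates one neuron per value of `Z0` (all from the same initial
#' conditions) and classifies each run with [classify_pattern()].
#'
#' @param params Base [adex_params()]; `Z0` is overridden per run.
#' @param z0_values Values of `Z0` (mV) to simulate.
#' @param duration,dt Passed to [simulate_neuron()].
#' @param ... Classifier options forwarded to [classify_pattern()].
#' @return A tibble with `Z0` plus the columns of [classify_pattern()].
#' @export
sweep_regimes <- function(params, z0_values, duration = 20000, dt = 0.1, ...) {
  purrr::map_dfr(z0_values, function(z0) {
    cl <- classify_z0(params, z0, duration, dt, ...)
    dplyr::bind_cols(tibble(Z0 = z0), cl)
  })
}

classify_z0 <- function(params, z0, duration, dt, ...) {
  p <- params
  p$Z0 <- z0
  sim <- simulate_neuron(p, duration = duration, dt = dt, sample_every = 10)
  classify_pattern(sim, ...)
}

#' Locate regime boundaries along Z0
#'
#' Sweeps `Z0` over a grid, finds every adjacent label change, and refines
#' each change point by bisection (re-simulating at midpoints) down to
#' `resolution` mV. With default parameters the labels appear in the order
#' quiescent, tonic, bursting, sustained ictal as `Z0` increases; a
#' non-monotone sequence is reported verbatim, one row per change.
#'
#' @inheritParams sweep_regimes
#' @param z0_grid Ascending grid of `Z0` values (mV).
#' @param resolution Bisection stopping width (mV).
#' @param sweep Optional precomputed result of [sweep_regimes()] on
#'   `z0_grid`, to avoid re-simulating the grid.
#' @return A list with `sweep` (the per-grid-point labels) and `boundaries`,
#'   a tibble with `from`, `to` (labels), `Z0` (refined boundary, mV) and
#'   `magnitude` (`|Z0|`, the form in which thresholds are usually quoted).
#' @export
regime_boundaries <- function(params, z0_grid = seq(-65, -10, by = 0.5),
                              duration = 20000, dt = 0.1, resolution = 0.1,
                              sweep = NULL, ...) {
  if (is.unsorted(z0_grid, strictly = TRUE)) abort("z0_grid must be ascending")
  if (is.null(sweep)) {
    sweep <- sweep_regimes(params, z0_grid, duration = duration, dt = dt, ...)
  }
  labels <- sweep$label
  change <- which(labels[-1] != labels[-length(labels)])
  boundaries <- purrr::map_dfr(change, function(i) {
    lo <- z0_grid[i]; hi <- z0_grid[i + 1]
    lab_lo <- labels[i]; lab_hi <- labels[i + 1]
    while (hi - lo > resolution) {
      mid <- (lo + hi) / 2
      lab_mid <- classify_z0(params, mid, duration, dt, ...)$label
      if (lab_mid == lab_lo) lo <- mid else {
        hi <- mid
        lab_hi <- lab_mid
      }
    }
    tibble(from = lab_lo, to = lab_hi, Z0 = (lo + hi) / 2,
           magnitude = abs((lo + hi) / 2))
  })
  list(sweep = sweep, boundaries = boundaries)
}
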