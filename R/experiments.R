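#' Spontaneous single-neuron patterns at the three reference impairments
#'
#' Runs the single neuron from identical initial conditions
#' (`V = E_L`, `w = 0`, `z = 0`) at `Z0 = -45`, `-40` and `-20` mV and
#' classifies each run; with default parameters these produce tonic spiking,
#' pathological bursting, and sustained ictal firing respectively.
#'
#' @param params Base [adex_params()].
#' @param Z0_values Impairment attractors to simulate (mV).
#' @param duration,dt Passed to [simulate_neuron()].
#' @param keep_sims Keep the full `adex_sim` objects in a list-column.
#' @return A tibble with `Z0`, the [classify_pattern()] columns, and (when
#'   `keep_sims`) a `sim` list-column.
#' @export
run_spontaneous_patterns <- function(params = adex_params(),
                                     Z0_values = c(-45, -40, -20),
                                     duration = 20000, dt = 0.1,
                                     keep_sims = FALSE) {
  purrr::map_dfr(Z0_values, function(z0) {
    p <- params
    p$Z0 <- z0
    sim <- simulate_neuron(p, duration = duration, dt = dt, sample_every = 10)
    out <- dplyr::bind_cols(tibble(Z0 = z0), classify_pattern(sim))
    if (keep_sims) out$sim <- list(sim)
    out
  })
}

#' Regime sweep over Z0 with boundary refinement
#'
#' Thin driver over [sweep_regimes()] and [regime_boundaries()] that can
#' write the canonical outputs: a CSV of per-grid-point labels
#' (`Z0_mV,label`) and a JSON list of refined boundaries.
#'
#' @inheritParams regime_boundaries
#' @param out_dir Optional output directory.
#' @return The [regime_boundaries()] list (`sweep`, `boundaries`).
#' @export
run_regime_sweep <- function(params = adex_params(),
                             z0_grid = seq(-65, -10, by = 0.5),
                             duration = 20000, dt = 0.1, resolution = 0.1,
                             out_dir = NULL, ...) {
  res <- regime_boundaries(params, z0_grid, duration = duration, dt = dt,
                           resolution = resolution, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(
      data.frame(Z0_mV = res$sweep$Z0, label = res$sweep$label),
      file.path(out_dir, "regimes.csv"), row.names = FALSE, quote = FALSE)
    jsonlite::write_json(res$boundaries, file.path(out_dir, "boundaries.json"),
                         digits = NA)
  }
  res
}

#' Explore the (Z0, N_SC) parameter plane of the network
#'
#' For every combination of impairment severity `Z0` and impaired-population
#' size `n_impaired` (and seed), builds the network, integrates it, computes
#' the per-population maximum smoothed rates and labels the propagation
#' region. When `out_dir` is given the regime map is written to
#' `regime_map.csv` and completed points (matched on `Z0`, `n_impaired`,
#' `seed`) are skipped on re-runs, making long grids resumable.
#'
#' @param Z0_values Impairment attractors of the impaired cells (mV).
#' @param n_impaired_values Sizes of the impaired subpopulation.
#' @param N,frac_exc,p,Z0_healthy,params,seed Passed to [build_network()];
#'   `seeds` is a vector, one run per seed per grid point.
#' @param seeds Integer seeds.
#' @param syn A [synapse_params()] object.
#' @param duration,dt,ext_rate_hz Passed to [simulate_network()].
#' @param patho_threshold,healthy_threshold Passed to [classify_region()].
#' @param out_dir Optional output directory for `regime_map.csv`.
#' @param verbose Log one line per completed point.
#' @return A tibble (the regime map) with one row per grid point per seed:
#'   `Z0`, `n_impaired`, `seed`, the three maximum rates, `region`, `label`,
#'   and `n_events`.
#' @export
run_grid <- function(Z0_values, n_impaired_values, N = 10000, frac_exc = 0.8,
                     p = 0.05, Z0_healthy = -65, params = adex_params(),
                     seeds = 1L, syn = synapse_params(), duration = 8000,
                     dt = 0.1, ext_rate_hz = 0, patho_threshold = 30,
                     healthy_threshold = 30, out_dir = NULL, verbose = FALSE) {
  grid <- tidyr::expand_grid(Z0 = Z0_values, n_impaired = n_impaired_values,
                             seed = seeds)
  done <- NULL
  map_path <- if (!is.null(out_dir)) file.path(out_dir, "regime_map.csv")
  if (!is.null(map_path) && file.exists(map_path)) {
    done <- utils::read.csv(map_path)
  }
  rows <- purrr::pmap(grid, function(Z0, n_impaired, seed) {
    if (!is.null(done)) {
      hit <- done[done$Z0 == Z0 & done$n_impaired == n_impaired &
                    done$seed == seed, , drop = FALSE]
      if (nrow(hit) == 1) return(as_tibble(hit))
    }
    net <- build_network(N = N, frac_exc = frac_exc, p = p,
                         n_impaired = n_impaired, Z0_impaired = Z0,
                         Z0_healthy = Z0_healthy, params = params, seed = seed)
    sim <- simulate_network(net, syn = syn, duration = duration, dt = dt,
                            ext_rate_hz = ext_rate_hz, seed = seed)
    reg <- classify_region(sim, patho_threshold = patho_threshold,
                           healthy_threshold = healthy_threshold)
    if (verbose) {
      message(sprintf("Z0 = %g, n_impaired = %d, seed = %d: region %d (imp %.1f / exc %.1f / inh %.1f Hz)",
                      Z0, n_impaired, seed, reg$region, reg$max_impaired_hz,
                      reg$max_healthy_exc_hz, reg$max_inhibitory_hz))
    }
    dplyr::bind_cols(tibble(Z0 = Z0, n_impaired = n_impaired, seed = seed),
                     reg, tibble(n_events = nrow(sim$events)))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(map_path)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, map_path, row.names = FALSE, quote = FALSE)
  }
  out
}

#' Deterministic small fixtures for tests and examples
#'
#' Builds a reduced network (200 cells, 5% connectivity) and a set of
#' synthetic spike trains with known structure: a constant-ISI train, a
#' clustered (bursting-like) train, homogeneous Poisson events across a cell
#' population, and a classical-AdEx reference trace for the z = 0 limit.
#'
#' @param seed Integer seed.
#' @return A list with `network`, `spikes_constant`, `spikes_clustered`,
#'   `poisson_events` (tibble `cell`, `time` plus attributes `rate_hz`,
#'   `n_cells`, `duration`), and `classic` (reference trace and spikes).
#' @export
make_fixtures <- function(seed = 1L) {
  set.seed(seed)
  list(
    network = build_network(N = 200, frac_exc = 0.8, p = 0.05,
                            n_impaired = 20, Z0_impaired = -40, seed = seed),
    spikes_constant = constant_train(isi = 100, duration = 10000),
    spikes_clustered = clustered_train(n_clusters = 8, cluster_size = 5,
                                       intra_isi = 10, inter = 1000),
    poisson_events = poisson_events(n_cells = 100, rate_hz = 10,
                                    duration = 10000),
    classic = simulate_adex_classic(adex_params(I_s = 500), duration = 2000)
  )
}

#' Synthetic spike trains with known structure
#'
#' `constant_train()` emits spikes at a fixed interval; `clustered_train()`
#' emits bursts of `cluster_size` spikes at `intra_isi`, clusters `inter` ms
#' apart; `poisson_events()` draws independent homogeneous Poisson trains for
#' `n_cells` cells.
#'
#' @param isi Interspike interval (ms).
#' @param duration Train duration (ms).
#' @param start Time of the first spike (ms).
#' @return A numeric vector of spike times, or for `poisson_events()` a
#'   tibble of events (`cell`, `time`).
#' @export
constant_train <- function(isi, duration, start = isi) {
  seq(start, duration, by = isi)
}

#' @rdname constant_train
#' @param n_clusters,cluster_size,intra_isi,inter Cluster layout (counts, ms).
#' @export
clustered_train <- function(n_clusters, cluster_size, intra_isi, inter,
                            start = 100) {
  starts <- start + (seq_len(n_clusters) - 1) * inter
  sort(unlist(lapply(starts, function(s) s + (seq_len(cluster_size) - 1) * intra_isi)))
}

#' @rdname constant_train
#' @param n_cells Number of cells.
#' @param rate_hz Rate of each cell (Hz).
#' @export
poisson_events <- function(n_cells, rate_hz, duration) {
  ev <- purrr::map_dfr(seq_len(n_cells), function(i) {
    t <- cumsum(rexp(ceiling(2 * rate_hz * duration / 1000) + 20,
                     rate = rate_hz / 1000))
    tibble(cell = i, time = t[t <= duration])
  })
  attr(ev, "rate_hz") <- rate_hz
  attr(ev, "n_cells") <- n_cells
  attr(ev, "duration") <- duration
  ev
}
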