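#' Conductance-based synapse parameters
#'
#' Synaptic input to each cell is `I_syn = g_E (E_E - V) + g_I (E_I - V)`;
#' both conductances decay exponentially with time constant `tau_syn` and are
#' incremented by `Q_E` / `Q_I` for each incoming excitatory / inhibitory
#' spike.
#'
#' @param E_E,E_I Excitatory and inhibitory reversal potentials (mV).
#' @param Q_E,Q_I Quantal conductance increments (nS).
#' @param tau_syn Conductance decay time constant (ms).
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(E_E = 0, E_I = -80, Q_E = 1.5, Q_I = 5,
                           tau_syn = 5) {
  stopifnot(Q_E >= 0, Q_I >= 0, tau_syn > 0)
  if (E_I >= E_E) abort("E_I must be below E_E")
  structure(list(E_E = E_E, E_I = E_I, Q_E = Q_E, Q_I = Q_I,
                 tau_syn = tau_syn), class = "synapse_params")
}

#' Build a random network with an impaired excitatory subpopulation
#'
#' Constructs a directed Erdos-Renyi network of extended-AdEx cells:
#' `frac_exc` of the cells are excitatory regular-spiking (RS) neurons and
#' the rest inhibitory fast-spiking (FS) interneurons; every ordered pair of
#' distinct cells is connected independently with probability `p`.
#' `n_impaired` cells, drawn uniformly without replacement from the
#' excitatory population, receive the impairment attractor `Z0_impaired`;
#' all other cells get `Z0_healthy` (the default, equal to the resting
#' potential, guarantees quiescence in isolation). FS cells are non-adapting
#' (`a = fs_a`, `b = fs_b`, zero by default - a modelling choice, as
#' interneuron adaptation is not separately specified for this model family);
#' all other constants are shared with the RS cells.
#'
#' @param N Total number of cells.
#' @param frac_exc Fraction of excitatory cells.
#' @param p Connection probability for each ordered pair.
#' @param n_impaired Number of impaired excitatory cells (N_SC).
#' @param Z0_impaired,Z0_healthy Impairment attractors (mV).
#' @param params Base [adex_params()] shared by all cells.
#' @param fs_a,fs_b Adaptation parameters of the FS population (nS, pA).
#' @param seed Integer seed making connectivity and impairment assignment
#'   reproducible.
#' @return An object of class `adex_network`: cell labels (`RS_healthy`,
#'   `RS_impaired`, `FS`), the per-cell parameter matrix, and the adjacency
#'   in compressed form (`targets`, `ptr`, both 0-based for the integrator).
#' @examples
#' net <- build_network(N = 200, n_impaired = 20, Z0_impaired = -40, seed = 1)
#' table(net$labels)
#' @export
build_network <- function(N = 10000, frac_exc = 0.8, p = 0.05, n_impaired = 0,
                          Z0_impaired = -40, Z0_healthy = -65,
                          params = adex_params(), fs_a = 0, fs_b = 0,
                          seed = NULL) {
  stopifnot(N >= 2, p >= 0, p <= 1, n_impaired >= 0)
  n_inh <- round((1 - frac_exc) * N)
  n_exc <- N - n_inh
  if (n_impaired > n_exc) {
    abort(sprintf("n_impaired (%d) exceeds the excitatory population (%d)",
                  n_impaired, n_exc))
  }
  if (!is.null(seed)) set.seed(seed)

  labels <- rep(c("RS_healthy", "FS"), c(n_exc, n_inh))
  impaired <- sort(sample.int(n_exc, n_impaired))
  labels[impaired] <- "RS_impaired"

  # directed ER graph: out-degree of each cell is Binomial(N - 1, p), targets
  # drawn without replacement among the other cells
  deg <- rbinom(N, N - 1, p)
  tgt_list <- vector("list", N)
  for (i in seq_len(N)) {
    k <- deg[i]
    if (k == 0) { tgt_list[[i]] <- integer(0); next }
    t0 <- sample.int(N - 1, k)
    tgt_list[[i]] <- ifelse(t0 >= i, t0 + 1L, t0) - 1L  # skip self, 0-based
  }
  targets <- unlist(tgt_list)
  ptr <- c(0L, cumsum(deg))

  par_row <- params_vector(params)
  par_mat <- matrix(par_row, nrow = N, ncol = 16, byrow = TRUE,
                    dimnames = list(NULL, names(par_row)))
  par_mat[labels == "FS", "a"] <- fs_a
  par_mat[labels == "FS", "b"] <- fs_b
  par_mat[, "Z0"] <- ifelse(labels == "RS_impaired", Z0_impaired, Z0_healthy)

  structure(list(N = N, n_exc = n_exc, n_inh = n_inh, labels = labels,
                 impaired = impaired, is_exc = as.integer(labels != "FS"),
                 targets = as.integer(targets), ptr = as.integer(ptr),
                 n_edges = length(targets), p = p, seed = seed,
                 par_matrix = par_mat, params = params,
                 Z0_impaired = Z0_impaired, Z0_healthy = Z0_healthy),
            class = "adex_network")
}

#' @export
print.adex_network <- function(x, ...) {
  cat(sprintf("adex_network: %d cells (%d RS / %d FS), %d impaired, %d edges (p = %g)\n",
              x$N, x$n_exc, x$n_inh, length(x$impaired), x$n_edges, x$p))
  invisible(x)
}

#' Deliver one step's spikes to postsynaptic conductances
#'
#' Reference implementation of the synaptic delivery rule: for every edge
#' `i -> j` with `i` in `spiking_cells`, `g_E[j]` is incremented by `Q_E` if
#' `i` is excitatory (healthy or impaired) and `g_I[j]` by `Q_I` if `i` is
#' inhibitory; simultaneous afferent spikes accumulate additively. The
#' compiled network integrator applies the identical rule internally; this
#' function exists for inspection and testing.
#'
#' @param state A data frame with numeric columns `g_E`, `g_I` (nS), one row
#'   per cell.
#' @param spiking_cells Integer indices (1-based) of the cells that spiked.
#' @param network An [build_network()] object.
#' @param syn A [synapse_params()] object.
#' @return A tibble with the updated `g_E`, `g_I`.
#' @export
deliver_spikes <- function(state, spiking_cells, network, syn) {
  stopifnot(is.data.frame(state), nrow(state) == network$N)
  gE <- state$g_E; gI <- state$g_I
  for (i in spiking_cells) {
    lo <- network$ptr[i] + 1L
    hi <- network$ptr[i + 1L]
    if (hi < lo) next
    tg <- network$targets[lo:hi] + 1L
    if (network$is_exc[i] == 1L) {
      for (j in tg) gE[j] <- gE[j] + syn$Q_E
    } else {
      for (j in tg) gI[j] <- gI[j] + syn$Q_I
    }
  }
  tibble(g_E = gE, g_I = gI)
}

#' Simulate the conductance-based network
#'
#' Synchronous fixed-step integration of every cell's extended-AdEx equations
#' coupled through conductance-based synapses. Each step applies, in order:
#' exact exponential decay of `g_E` and `g_I`; an explicit Euler step of the
#' membrane equations with `I_s + I_syn` evaluated at the pre-step potential;
#' spike detection and reset with refractory clamping; and delivery of
#' quantal increments to postsynaptic conductances, effective from the next
#' step (a one-step synaptic latency; there are no conduction delays). The
#' run is fully deterministic given the network object: identical
#' configuration implies a bit-identical event list.
#'
#' @param network An [build_network()] object.
#' @param syn A [synapse_params()] object.
#' @param duration Simulated time (ms).
#' @param dt Time step (ms); at most 0.2 ms.
#' @param record_cells Integer indices (1-based) of cells whose state
#'   trajectories (`V`, `w`, `z`, `g_E`, `g_I`) are recorded.
#' @param sample_every Sampling interval of recorded trajectories (ms).
#' @param init Optional list of initial vectors `V`, `w`, `z`, `g_E`, `g_I`
#'   (length N). The default starts every cell at `V = E_L` with zero
#'   conductances and the impairment heterogeneously developed:
#'   `z(0) ~ U(0, Z0 - E_L)` per cell (exactly 0 for healthy cells, whose
#'   attractor is the resting potential) with `w` on its nullcline, so that
#'   impaired cells cross into the active regime progressively rather than as
#'   one synchronized volley.
#' @param ext_rate_hz Rate (Hz per cell) of external background excitatory
#'   events, delivered as quantal `Q_E` increments of `g_E` at homogeneous
#'   Poisson times. This stands in for the afferent activity that keeps a
#'   cortical network in its asynchronous-irregular baseline; 0 disables it.
#' @param seed Integer seed for the initial impairment draw and the
#'   background drive; identical seed and configuration give a bit-identical
#'   result.
#' @return An object of class `adex_netsim`: `events` (tibble `cell`,
#'   `time`), per-cell spike `counts`, recorded `traces` (long tibble), the
#'   `network`, `syn`, `duration` and `dt`.
#' @export
simulate_network <- function(network, syn = synapse_params(), duration = 8000,
                             dt = 0.1, record_cells = integer(0),
                             sample_every = 1, init = NULL, ext_rate_hz = 0,
                             seed = NULL) {
  stopifnot(inherits(network, "adex_network"))
  if (dt <= 0 || dt > 0.2) abort("network integration requires 0 < dt <= 0.2 ms")
  if (duration <= 0) abort("duration must be positive")
  stride <- as.integer(round(sample_every / dt))
  N <- network$N
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) {
    z0 <- runif(N) * (network$par_matrix[, "Z0"] - network$par_matrix[, "E_L"])
    init <- list(V = rep(network$params$E_L, N),
                 w = -network$par_matrix[, "a"] * z0,
                 z = z0, g_E = numeric(N), g_I = numeric(N))
  }
  res <- network_integrate_cpp(network$par_matrix, network$targets,
                               network$ptr, network$is_exc,
                               syn$E_E, syn$E_I, syn$Q_E, syn$Q_I,
                               syn$tau_syn, duration, dt,
                               init$V, init$w, init$z, init$g_E, init$g_I,
                               as.integer(record_cells - 1L), stride,
                               ext_rate_hz)
  traces <- NULL
  if (length(record_cells)) {
    traces <- purrr::map_dfr(seq_along(record_cells), function(j) {
      tibble(cell = record_cells[j], time = res$rec_time,
             V = res$rec_V[, j], w = res$rec_w[, j], z = res$rec_z[, j],
             g_E = res$rec_gE[, j], g_I = res$rec_gI[, j])
    })
  }
  structure(list(events = tibble(cell = res$cell, time = res$time),
                 counts = res$counts, traces = traces,
                 g_end = tibble(g_E = res$gE_end, g_I = res$gI_end),
                 network = network, syn = syn, duration = duration, dt = dt,
                 ext_rate_hz = ext_rate_hz, seed = seed),
            class = "adex_netsim")
}

#' @export
print.adex_netsim <- function(x, ...) {
  cat(sprintf("adex_netsim: %d cells, %.0f ms, %d spike events\n",
              x$network$N, x$duration, nrow(x$events)))
  invisible(x)
}

#' @rdname simulate_network
#' @param x An `adex_netsim` object.
#' @param ... Unused.
#' @export
tidy.adex_netsim <- function(x, ...) x$events

#' @rdname simulate_network
#' @export
glance.adex_netsim <- function(x, ...) {
  tibble(n_cells = x$network$N, n_impaired = length(x$network$impaired),
         duration = x$duration, dt = x$dt, n_events = nrow(x$events),
         mean_rate_hz = 1000 * nrow(x$events) / (x$network$N * x$duration))
}

#' Population firing-rate trace
#'
#' Bins the spike events of one population, converts to a per-cell rate in
#' Hz (`count / (n_cells * bin width)`), and smooths with a centred moving
#' average. The maximum of the smoothed trace is the "maximum firing rate"
#' summary used for the parameter-plane maps.
#'
#' @param x An `adex_netsim` object, or a data frame of events with columns
#'   `cell` and `time` (ms).
#' @param population One of `RS_impaired`, `RS_healthy`, `FS` (for
#'   `adex_netsim` input), or `NULL` when `cells` is given.
#' @param bin_ms Bin width (ms).
#' @param smooth_ms Width of the centred moving average (ms).
#' @param cells Integer cell indices defining the population (for data-frame
#'   input).
#' @param n_cells Population size (required for data-frame input).
#' @param duration Total duration (ms; required for data-frame input).
#' @return A tibble with `time` (bin centre, ms) and `rate` (Hz).
#' @export
population_rate <- function(x, population = NULL, bin_ms = 5, smooth_ms = 25,
                            cells = NULL, n_cells = NULL, duration = NULL) {
  stopifnot(bin_ms > 0)
  if (inherits(x, "adex_netsim")) {
    if (is.null(population) ||
        !population %in% c("RS_impaired", "RS_healthy", "FS")) {
      abort("population must be one of RS_impaired, RS_healthy, FS")
    }
    cells <- which(x$network$labels == population)
    n_cells <- length(cells)
    duration <- x$duration
    events <- x$events
  } else {
    events <- x
    if (is.null(cells) || is.null(n_cells) || is.null(duration)) {
      abort("data-frame input needs cells, n_cells and duration")
    }
  }
  breaks <- seq(0, duration, by = bin_ms)
  if (breaks[length(breaks)] < duration) breaks <- c(breaks, duration)
  centres <- (breaks[-1] + breaks[-length(breaks)]) / 2
  widths <- diff(breaks)
  if (n_cells == 0) return(tibble(time = centres, rate = 0))
  tt <- events$time[events$cell %in% cells]
  counts <- if (length(tt)) {
    as.numeric(table(cut(tt, breaks = breaks, include.lowest = TRUE)))
  } else {
    numeric(length(centres))
  }
  rate <- counts / (n_cells * widths / 1000)
  tibble(time = centres, rate = moving_average(rate, max(1L, round(smooth_ms / bin_ms))))
}

# centred moving average with shrinking windows at the edges
moving_average <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  half <- k %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Per-population maximum rates
#'
#' @inheritParams population_rate
#' @return A tibble with `population` and `max_rate_hz` for the three
#'   populations (zero where the population is empty).
#' @export
max_rates <- function(x, bin_ms = 5, smooth_ms = 25) {
  stopifnot(inherits(x, "adex_netsim"))
  purrr::map_dfr(c("RS_impaired", "RS_healthy", "FS"), function(pop) {
    n <- sum(x$network$labels == pop)
    r <- if (n == 0) 0 else
      max(population_rate(x, pop, bin_ms = bin_ms, smooth_ms = smooth_ms)$rate)
    tibble(population = pop, n_cells = n, max_rate_hz = r)
  })
}

#' Classify the network regime from population rates
#'
#' Three regions of the `(Z0, N_SC)` plane: in region 1 the impaired cells
#' stay below `patho_threshold` (asynchronous-irregular, contained); in
#' region 2 the impaired population oscillates at pathological rates but
#' inhibition confines them (healthy excitatory cells stay below
#' `healthy_threshold`); in region 3 the pathological activity propagates to
#' the healthy excitatory population too.
#'
#' @param x An `adex_netsim` object, or a tibble as returned by [max_rates()].
#' @param patho_threshold Sustained rate (Hz) above which the impaired
#'   population counts as pathological.
#' @param healthy_threshold Rate (Hz) above which the healthy excitatory
#'   population counts as recruited.
#' @param ... Passed on to [max_rates()].
#' @return A one-row tibble with `region` (1, 2 or 3), `label`, and the
#'   three maximum rates.
#' @export
classify_region <- function(x, patho_threshold = 30, healthy_threshold = 30,
                            ...) {
  mr <- if (inherits(x, "adex_netsim")) max_rates(x, ...) else x
  get <- function(pop) {
    v <- mr$max_rate_hz[mr$population == pop]
    if (length(v) == 0) 0 else v
  }
  imp <- get("RS_impaired"); healthy <- get("RS_healthy"); inh <- get("FS")
  region <- if (imp < patho_threshold) 1L
  else if (healthy < healthy_threshold) 2L
  else 3L
  tibble(region = region,
         label = c("AI_contained", "impaired_oscillation_inhibition_contained",
                   "global_propagation")[region],
         max_impaired_hz = imp, max_healthy_exc_hz = healthy,
         max_inhibitory_hz = inh)
}

#' Write a raster and rate traces to disk
#'
#' The raster goes to TSV (`cell_id<TAB>time_ms`) with a JSON sidecar holding
#' population sizes, seed and configuration; rate traces go to CSV with
#' columns `time_ms,rate_impaired_Hz,rate_exc_Hz,rate_inh_Hz`.
#'
#' @param sim An `adex_netsim` object.
#' @param raster_path,sidecar_path,rates_path Output paths (`NULL` to skip).
#' @return `raster_path`, invisibly.
#' @export
write_raster <- function(sim, raster_path, sidecar_path = NULL,
                         rates_path = NULL) {
  utils::write.table(
    data.frame(cell_id = sim$events$cell, time_ms = sim$events$time),
    raster_path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(sidecar_path)) {
    net <- sim$network
    jsonlite::write_json(
      list(N = net$N, n_exc = net$n_exc, n_inh = net$n_inh,
           n_impaired = length(net$impaired), p = net$p, seed = net$seed,
           Z0_impaired = net$Z0_impaired, Z0_healthy = net$Z0_healthy,
           duration_ms = sim$duration, dt_ms = sim$dt,
           syn = unclass(sim$syn)),
      sidecar_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(rates_path)) {
    ri <- population_rate(sim, "RS_impaired")
    re <- population_rate(sim, "RS_healthy")
    rn <- population_rate(sim, "FS")
    utils::write.csv(
      data.frame(time_ms = ri$time, rate_impaired_Hz = ri$rate,
                 rate_exc_Hz = re$rate, rate_inh_Hz = rn$rate),
      rates_path, row.names = FALSE, quote = FALSE)
  }
  invisible(raster_path)
}
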