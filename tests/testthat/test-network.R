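test_that("population split, impairment assignment and degenerate p are exact", {
  net <- build_network(N = 200, n_impaired = 20, Z0_impaired = -40, seed = 1)
  expect_equal(net$n_exc, 160)
  expect_equal(net$n_inh, 40)
  expect_equal(sum(net$labels == "RS_impaired"), 20)
  expect_true(all(net$impaired <= 160))  # impaired cells are excitatory
  expect_equal(unname(net$par_matrix[net$impaired[1], "Z0"]), -40)
  expect_equal(unname(net$par_matrix[200, "Z0"]), -65)  # FS healthy attractor
  expect_equal(unname(net$par_matrix[200, "a"]), 0)     # non-adapting FS
  expect_equal(unname(net$par_matrix[1, "a"]), 1)

  expect_equal(build_network(N = 50, p = 0, seed = 1)$n_edges, 0)
  expect_equal(build_network(N = 40, p = 1, seed = 1)$n_edges, 40 * 39)
  expect_error(build_network(N = 100, frac_exc = 0.8, n_impaired = 90),
               "exceeds")
})

test_that("no self-connections and edge counts behave binomially", {
  net <- build_network(N = 120, p = 0.3, seed = 5)
  for (i in seq_len(120)) {
    lo <- net$ptr[i] + 1L; hi <- net$ptr[i + 1L]
    if (hi >= lo) {
      tg <- net$targets[lo:hi] + 1L
      expect_false(any(tg == i))
      expect_false(any(duplicated(tg)))
      expect_true(all(tg >= 1 & tg <= 120))
    }
  }
  # directed ER: total edges ~ Binomial(N(N-1), p), each count within 5 sigma
  N <- 500; p <- 0.05
  m <- N * (N - 1) * p
  s <- sqrt(N * (N - 1) * p * (1 - p))
  counts <- vapply(1:20, function(seed) {
    build_network(N = N, p = p, seed = seed)$n_edges
  }, numeric(1))
  expect_true(all(abs(counts - m) < 5 * s))
  # and the ensemble mean is close on the scale of the standard error
  expect_lt(abs(mean(counts) - m), 5 * s / sqrt(20))
})

test_that("network construction is reproducible from its seed", {
  a <- build_network(N = 300, n_impaired = 30, Z0_impaired = -45, seed = 11)
  b <- build_network(N = 300, n_impaired = 30, Z0_impaired = -45, seed = 11)
  expect_identical(a$targets, b$targets)
  expect_identical(a$impaired, b$impaired)
  c <- build_network(N = 300, n_impaired = 30, Z0_impaired = -45, seed = 12)
  expect_false(identical(a$targets, c$targets))
})

test_that("spike delivery increments conductances quantally and additively", {
  net <- build_network(N = 6, p = 0, n_impaired = 0, seed = 1)
  # hand-wire: cells 1, 2 (exc) -> 4; cell 6 (FS) -> 4
  net$targets <- as.integer(c(3, 3, 3))
  net$ptr <- as.integer(c(0, 1, 2, 2, 2, 2, 3))
  syn <- synapse_params()
  state <- tibble::tibble(g_E = numeric(6), g_I = numeric(6))

  one <- deliver_spikes(state, 1, net, syn)
  expect_equal(one$g_E[4], 1.5)
  expect_equal(one$g_I[4], 0)

  inh <- deliver_spikes(state, 6, net, syn)
  expect_equal(inh$g_I[4], 5)
  expect_equal(inh$g_E[4], 0)

  both <- deliver_spikes(state, c(1, 2, 6), net, syn)
  expect_equal(both$g_E[4], 2 * 1.5)  # simultaneous afferents accumulate
  expect_equal(both$g_I[4], 5)
})

test_that("conductances decay by the exact exponential factor between spikes", {
  net <- build_network(N = 10, p = 0.1, n_impaired = 0, seed = 1)
  init <- rest_init(10)
  init$g_E <- rep(3, 10); init$g_I <- rep(2, 10)
  sim <- simulate_network(net, duration = 50, record_cells = 1, init = init)
  expect_equal(nrow(sim$events), 0)
  tr <- sim$traces
  expect_equal(tr$g_E, 3 * exp(-tr$time / 5), tolerance = 1e-12)
  expect_equal(tr$g_I, 2 * exp(-tr$time / 5), tolerance = 1e-12)
  expect_true(all(tr$g_E >= 0 & tr$g_I >= 0))
})

test_that("a decoupled network cell reproduces the single-neuron integrator", {
  net <- build_network(N = 5, p = 0.3, n_impaired = 1, Z0_impaired = -40,
                       seed = 3)
  imp <- net$impaired[1]
  sim <- simulate_network(net, syn = synapse_params(Q_E = 0, Q_I = 0),
                          duration = 3000, record_cells = imp,
                          init = rest_init(5))
  single <- simulate_neuron(base_params(Z0 = -40), duration = 3000,
                            init = list(V = -65, w = 0, z = 0))
  expect_identical(sum(sim$events$cell == imp), length(single$spikes))
  expect_equal(sim$traces$V, single$trace$V, tolerance = 1e-13)
  expect_equal(sim$traces$w, single$trace$w, tolerance = 1e-13)
  expect_equal(sim$traces$z, single$trace$z, tolerance = 1e-13)
})

test_that("a silent network stays silent and a seeded run is bit-reproducible", {
  net <- build_network(N = 400, n_impaired = 0, seed = 2)
  sim <- simulate_network(net, duration = 2000, seed = 9)
  expect_equal(nrow(sim$events), 0)  # quiescent attractor, no coupling input

  net2 <- build_network(N = 400, n_impaired = 60, Z0_impaired = -30, seed = 2)
  a <- simulate_network(net2, duration = 1500, seed = 9, ext_rate_hz = 50)
  b <- simulate_network(net2, duration = 1500, seed = 9, ext_rate_hz = 50)
  expect_identical(a$events, b$events)
  expect_gt(nrow(a$events), 0)
})

test_that("raster events and per-cell counters agree and respect refractoriness", {
  net <- build_network(N = 300, n_impaired = 60, Z0_impaired = -20, seed = 4)
  sim <- simulate_network(net, duration = 2500, seed = 1)
  expect_gt(nrow(sim$events), 100)
  expect_equal(nrow(sim$events), sum(sim$counts))
  tab <- table(sim$events$cell)
  expect_equal(unname(sim$counts[as.integer(names(tab))]), as.vector(tab))
  floors <- tapply(sim$events$time, sim$events$cell, function(t) {
    if (length(t) > 1) min(diff(t)) else Inf
  })
  expect_true(all(floors >= 5))
})

test_that("population rates recover a known generative rate and handle edge cases", {
  ev <- poisson_events(n_cells = 100, rate_hz = 10, duration = 10000)
  r <- population_rate(ev, cells = 1:100, n_cells = 100, duration = 10000)
  # mean of the binned rate estimates the generative 10 Hz; 3 sigma of the
  # mean over ~10^4 Poisson events is ~0.3 Hz
  expect_lt(abs(mean(r$rate) - 10), 3 * 10 / sqrt(100 * 10 * 10))

  empty <- population_rate(tibble::tibble(cell = integer(0), time = numeric(0)),
                           cells = 1:10, n_cells = 10, duration = 1000)
  expect_true(all(empty$rate == 0))

  net <- build_network(N = 100, n_impaired = 10, Z0_impaired = -30, seed = 1)
  sim <- simulate_network(net, duration = 1000, seed = 1)
  expect_error(population_rate(sim, "granule"), "population")
})

test_that("region labels follow the impaired / healthy thresholds", {
  mk <- function(imp, healthy, inh) {
    tibble::tibble(population = c("RS_impaired", "RS_healthy", "FS"),
                   n_cells = c(10, 80, 20),
                   max_rate_hz = c(imp, healthy, inh))
  }
  expect_equal(classify_region(mk(0, 0, 0))$region, 1L)      # silence contained
  expect_equal(classify_region(mk(120, 4, 80))$region, 2L)   # inhibition holds
  expect_equal(classify_region(mk(120, 60, 80))$region, 3L)  # propagation
  expect_equal(classify_region(mk(29.9, 60, 0))$region, 1L)  # impaired below cutoff
})

test_that("the raster writer produces TSV events, JSON sidecar and rate CSV", {
  net <- build_network(N = 150, n_impaired = 30, Z0_impaired = -20, seed = 6)
  sim <- simulate_network(net, duration = 1200, seed = 1)
  ras <- tempfile(fileext = ".tsv"); sc <- tempfile(fileext = ".json")
  rcsv <- tempfile(fileext = ".csv")
  write_raster(sim, ras, sc, rcsv)
  ev <- utils::read.delim(ras)
  expect_equal(names(ev), c("cell_id", "time_ms"))
  expect_equal(nrow(ev), nrow(sim$events))
  meta <- jsonlite::read_json(sc)
  expect_equal(meta$N, 150)
  expect_equal(meta$n_impaired, 30)
  rates <- utils::read.csv(rcsv)
  expect_equal(names(rates),
               c("time_ms", "rate_impaired_Hz", "rate_exc_Hz", "rate_inh_Hz"))
})
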