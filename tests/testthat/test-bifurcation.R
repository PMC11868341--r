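test_that("Jacobian has its closed form and matches finite differences", {
  p <- base_params()
  # at V = V_T - beta z the exponential bracket vanishes
  z <- 10
  J <- adex_jacobian(p, V = p$V_T - p$beta * z, z = z)
  expect_equal(J[1, 1], 0)
  expect_equal(sum(diag(J)), -1 / p$tau_w)
  expect_equal(J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1], p$a / (p$C * p$tau_w))

  # central finite differences of the frozen-z vector field
  h <- 1e-5
  for (pt in list(c(-60, 0), c(-55, 10), c(-70, 25))) {
    V <- pt[1]; z <- pt[2]; w <- 30
    J <- adex_jacobian(p, V, z)
    fd <- function(dV, dw) {
      adex_vector_field(data.frame(V = V + dV, w = w + dw, z = z), p)
    }
    num <- matrix(c((fd(h, 0)$dV - fd(-h, 0)$dV) / (2 * h),
                    (fd(h, 0)$dw - fd(-h, 0)$dw) / (2 * h),
                    (fd(0, h)$dV - fd(0, -h)$dV) / (2 * h),
                    (fd(0, h)$dw - fd(0, -h)$dw) / (2 * h)), nrow = 2)
    expect_equal(num, J, tolerance = 1e-5)
  }
})

test_that("trace_det agrees with the Jacobian at random points", {
  p <- base_params()
  set.seed(42)
  V <- runif(100, -90, -40)
  z <- runif(100, -20, 40)
  td <- trace_det(p, V, z)
  for (i in seq_len(100)) {
    J <- adex_jacobian(p, V[i], z[i])
    expect_equal(td$trace[i], sum(diag(J)))
    expect_equal(td$det[i], J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1])
  }
})

test_that("without subthreshold adaptation a trace zero implies negative determinant", {
  p <- base_params(a = 0)
  # at tr = 0 the exponential bracket equals C/(g_L tau_w), so
  # det = -(1/(C tau_w)) * C/tau_w < 0: verify numerically along a z sweep
  for (z in seq(-10, 30, by = 5)) {
    V0 <- uniroot(function(V) trace_det(p, V, z)$trace, c(-120, -20))$root
    expect_lt(trace_det(p, V0, z)$det, 0)
  }
})

test_that("fixed points match a dense sign-scan oracle and sit on both nullclines", {
  p <- base_params()
  for (z in c(-10, 0, 5, 10, 13)) {
    fp <- fixed_points(p, z)
    oracle <- scan_roots(p, z)
    expect_equal(nrow(fp), length(oracle))
    if (nrow(fp)) {
      expect_equal(fp$V_star, sort(oracle), tolerance = 1e-6)
      expect_true(all(abs(equilibrium_residual_oracle(p, fp$V_star, z)) < 1e-9))
      expect_equal(fp$w_star, p$a * (fp$V_star - (p$E_L + z)))
    }
  }
  # beyond the fold both equilibria are gone
  expect_equal(nrow(fixed_points(p, 30)), 0)
  expect_equal(nrow(fixed_points(p, 50)), 0)
  # well below the fold: two equilibria, lower non-saddle, upper saddle
  fp <- fixed_points(p, 0)
  expect_equal(nrow(fp), 2)
  expect_false(fp$stability[1] == "saddle")
  expect_equal(fp$stability[2], "saddle")
})

test_that("fixed points equal the oracle under random parameter perturbations", {
  set.seed(7)
  base <- unclass(base_params())
  for (i in seq_len(200)) {
    pert <- purrr::map(base, function(x) x * runif(1, 0.9, 1.1))
    pert$I_s <- 0
    p <- do.call(adex_params, pert)
    z <- runif(1, -10, 15)
    fp <- fixed_points(p, z)
    oracle <- scan_roots(p, z, n = 2e4)
    expect_equal(nrow(fp), length(oracle))
    if (nrow(fp)) expect_equal(fp$V_star, sort(oracle), tolerance = 1e-4)
  }
})

test_that("the diagram finds one Andronov-Hopf then one saddle-node as z grows", {
  bd <- bifurcation_diagram(base_params())
  ev <- bd$events
  expect_equal(sum(ev$kind == "andronov_hopf"), 1)
  expect_equal(sum(ev$kind == "saddle_node"), 1)
  z_ah <- ev$z_value[ev$kind == "andronov_hopf"]
  z_sn <- ev$z_value[ev$kind == "saddle_node"]
  expect_lt(z_ah, z_sn)

  # at the refined Hopf point the trace is tiny and the determinant positive
  fp <- fixed_points(base_params(), z_ah)
  expect_lt(abs(fp$trace[1]), 1e-6)
  expect_gt(fp$det[1], 0)

  # equilibrium residuals across the tracked branch stay below tolerance
  eq <- tidy(bd)
  expect_true(all(abs(equilibrium_residual_oracle(base_params(), eq$V_star, eq$z)) < 1e-9))

  # stability flips exactly at the events: stable below the Hopf, saddle
  # branch unstable everywhere, no stable equilibria between AH and SN
  lower <- eq %>% dplyr::group_by(z) %>% dplyr::slice_min(V_star, n = 1) %>%
    dplyr::ungroup()
  stable <- lower$stability %in% c("stable_node", "stable_focus")
  expect_true(all(stable[lower$z < z_ah - 1e-3]))
  expect_true(all(!stable[lower$z > z_ah + 1e-3]))

  g <- glance(bd)
  expect_equal(g$n_hopf, 1)
  expect_equal(g$n_saddle_node, 1)
})

test_that("the saddle-node location matches a brute-force count transition", {
  p <- base_params()
  bd <- bifurcation_diagram(p, n_grid = 400)
  z_sn <- bd$events$z_value[bd$events$kind == "saddle_node"]
  # 10x finer grid around the event, counting sign-scan roots
  zf <- seq(z_sn - 0.05, z_sn + 0.05, length.out = 1001)
  counts <- vapply(zf, function(z) length(scan_roots(p, z, n = 2e4)), numeric(1))
  flip <- zf[max(which(counts > 0))]
  expect_lt(abs(flip - z_sn), 1e-3)
})

test_that("no Hopf event is reported when a = 0", {
  bd <- bifurcation_diagram(base_params(a = 0))
  expect_equal(sum(bd$events$kind == "andronov_hopf"), 0)
  expect_equal(sum(bd$events$kind == "saddle_node"), 1)
})

nullw <- function(p, V, z) {
  p$g_L * ((p$E_L + z) - V) +
    p$g_L * p$Delta_T * exp((V - (p$V_T - p$beta * z)) / p$Delta_T) -
    p$g_p * z + p$I_s
}

test_that("nullsurface samples solve dV/dt = 0 exactly and mark the analytic fold", {
  p <- base_params()
  ns <- nullsurface(p, n_V = 25, n_z = 25)
  vf <- adex_vector_field(data.frame(V = ns$V, w = ns$w_vnull, z = ns$z), p)
  expect_true(all(abs(vf$dV) < 1e-12))
  expect_equal(ns$w_wnull, p$a * (ns$V - (p$E_L + ns$z)))

  fc <- fold_curve(p, c(0, 10, 20))
  expect_equal(fc$V_fold, p$V_T - p$beta * c(0, 10, 20))
  # the fold satisfies the a-free saddle-node condition: V-slope of the
  # V-nullsurface changes sign there
  for (i in seq_len(3)) {
    h <- 0.01
    slope <- function(V) {
      (nullw(p, V + h, fc$z[i]) - nullw(p, V - h, fc$z[i])) / (2 * h)
    }
    expect_gt(slope(fc$V_fold[i] + 0.5), slope(fc$V_fold[i] - 0.5))
    expect_lt(abs(slope(fc$V_fold[i])), 0.02)
  }

  # the intersection of the two nullsurfaces is the fixed-point set
  z0 <- 5
  fp <- fixed_points(p, z0)
  for (V in fp$V_star) {
    expect_equal(nullw(p, V, z0), p$a * (V - (p$E_L + z0)), tolerance = 1e-6)
  }
})

test_that("diagram writer emits the documented CSV and JSON", {
  bd <- bifurcation_diagram(base_params(), n_grid = 120)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_bifurcation(bd, csv, js)
  got <- utils::read.csv(csv)
  expect_equal(names(got),
               c("z_mV", "V_star_mV", "w_star_pA", "trace", "det", "stability"))
  ev <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_true(all(c("kind", "z_value", "V_value") %in% names(ev)))
})
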