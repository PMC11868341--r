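#' Fixed points of the frozen-z fast subsystem
#'
#' With the slow impairment variable frozen (`epsilon -> 0`), `z` becomes a
#' parameter of the two-dimensional `(V, w)` subsystem. Equilibria satisfy the
#' w-nullcline `w* = a (V* - (E_L + z))` and the scalar V-equation
#' `g_L((E_L+z)-V) + g_L Delta_T exp((V-(V_T-beta z))/Delta_T) - a(V-(E_L+z))
#' - g_p z + I_s = 0`, searched on `V` in `[E_L - 40, V_D]`. Roots are
#' bracketed by a sign scan and refined with [stats::uniroot()]; for generic
#' parameters there are 0, 1 or 2 of them.
#'
#' @param params An [adex_params()] object.
#' @param z Frozen value of the impairment variable (mV).
#' @param n_scan Number of points of the bracketing sign scan.
#' @param V_range Search window in V (mV); defaults to `[E_L - 40, V_D]`.
#' @return A tibble, one row per equilibrium sorted by `V_star`, with columns
#'   `z`, `V_star` (mV), `w_star` (pA), `trace` (1/ms), `det` (1/ms^2) and
#'   `stability` (one of `stable_node`, `stable_focus`, `saddle`,
#'   `unstable_node`, `unstable_focus`).
#' @examples
#' fixed_points(adex_params(), z = 0)
#' @export
fixed_points <- function(params, z, n_scan = 4001, V_range = NULL) {
  validate_adex_params(params)
  if (is.null(V_range)) V_range <- c(params$E_L - 40, params$V_D)
  f <- function(V) equilibrium_residual(params, V, z)
  Vs <- seq(V_range[1], V_range[2], length.out = n_scan)
  fv <- f(Vs)
  roots <- numeric(0)
  sgn <- sign(fv)
  hit <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in hit) {
    r <- uniroot(f, c(Vs[i], Vs[i + 1]), tol = 1e-12)
    roots <- c(roots, r$root)
  }
  exact <- Vs[fv == 0]
  roots <- sort(unique(c(roots, exact)))
  if (length(roots) == 0) {
    return(tibble(z = numeric(0), V_star = numeric(0), w_star = numeric(0),
                  trace = numeric(0), det = numeric(0),
                  stability = character(0)))
  }
  td <- trace_det(params, roots, z)
  tibble(z = z, V_star = roots,
         w_star = params$a * (roots - (params$E_L + z)),
         trace = td$trace, det = td$det,
         stability = stability_label(td$trace, td$det))
}

# residual of the V-equation along the w-nullcline (pA)
equilibrium_residual <- function(params, V, z) {
  ex <- exp((V - (params$V_T - params$beta * z)) / params$Delta_T)
  params$g_L * ((params$E_L + z) - V) + params$g_L * params$Delta_T * ex -
    params$a * (V - (params$E_L + z)) - params$g_p * z + params$I_s
}

stability_label <- function(trace, det) {
  dplyr::case_when(
    det < 0 ~ "saddle",
    trace < 0 & trace^2 - 4 * det >= 0 ~ "stable_node",
    trace < 0 ~ "stable_focus",
    trace^2 - 4 * det >= 0 ~ "unstable_node",
    TRUE ~ "unstable_focus"
  )
}

#' Jacobian of the fast subsystem
#'
#' Closed-form Jacobian of the `(V, w)` subsystem at a point `(V, z)`:
#' `[[ (g_L/C)(-1 + e^X), -1/C ], [ a/tau_w, -1/tau_w ]]` with
#' `X = (V - (V_T - beta z)) / Delta_T`. Rows carry mixed units (first row
#' 1/ms and 1/(ms pA/mV); both diagonal entries are rates in 1/ms).
#'
#' @inheritParams fixed_points
#' @param V Membrane potential (mV).
#' @return A 2x2 numeric matrix.
#' @export
adex_jacobian <- function(params, V, z) {
  ex <- exp((V - (params$V_T - params$beta * z)) / params$Delta_T)
  matrix(c(params$g_L / params$C * (-1 + ex), params$a / params$tau_w,
           -1 / params$C, -1 / params$tau_w),
         nrow = 2)
}

#' Trace and determinant of the fast-subsystem Jacobian
#'
#' Closed forms `tr = (g_L/C)(-1 + e^X) - 1/tau_w` and
#' `det = (1/(C tau_w)) (-g_L(-1 + e^X) + a)`, vectorised over `V` and `z`.
#' An Andronov-Hopf bifurcation requires `tr = 0` with `det > 0`; a
#' saddle-node requires `det = 0`.
#'
#' @inheritParams adex_jacobian
#' @return A tibble with columns `trace` (1/ms) and `det` (1/ms^2).
#' @export
trace_det <- function(params, V, z) {
  ex <- exp((V - (params$V_T - params$beta * z)) / params$Delta_T)
  tibble(trace = params$g_L / params$C * (-1 + ex) - 1 / params$tau_w,
         det = (-params$g_L * (-1 + ex) + params$a) / (params$C * params$tau_w))
}

#' Bifurcation diagram of the fast subsystem along z
#'
#' Tracks the equilibria of the frozen-z fast subsystem over a grid of `z`
#' values and locates the bifurcations that organise spiking onset: the
#' Andronov-Hopf point (trace of the Jacobian crosses zero on the non-saddle
#' branch with positive determinant) and the saddle-node point (the two
#' equilibria collide and disappear; determinant zero at the fold of the
#' V-nullsurface). Both are refined by bisection in `z` to `z_tol`. If the
#' equilibrium branch jumps by more than 5 mV between adjacent grid points the
#' grid is refined locally rather than silently continued.
#'
#' @inheritParams fixed_points
#' @param z_min,z_max Scan window in `z` (mV). The default brackets both
#'   events for the default parameter set.
#' @param n_grid Number of grid points (at least 100).
#' @param z_tol Bisection stopping width in `z` (mV).
#' @return An object of class `adex_bifurcation`: list with `equilibria`
#'   (tibble of tracked fixed points over the grid) and `events` (tibble with
#'   `kind` in `andronov_hopf` / `saddle_node`, `z_value`, `V_value`).
#'   [tidy()] returns the equilibria, [glance()] the event summary.
#' @export
bifurcation_diagram <- function(params, z_min = -30, z_max = 60, n_grid = 400,
                                z_tol = 1e-6) {
  if (z_min >= z_max) abort("z_min must be below z_max")
  if (n_grid < 100) abort("n_grid must be at least 100")
  zs <- seq(z_min, z_max, length.out = n_grid)
  eq <- purrr::map(zs, function(z) fixed_points(params, z))

  # refine where a tracked branch moves by > 5 mV between adjacent z values
  refine <- function(zs, eq, depth = 0) {
    if (depth >= 6) return(list(zs = zs, eq = eq))
    jump <- vapply(seq_len(length(zs) - 1), function(i) {
      a <- eq[[i]]; b <- eq[[i + 1]]
      if (nrow(a) == 0 || nrow(b) == 0 || nrow(a) != nrow(b)) return(FALSE)
      any(abs(a$V_star - b$V_star) > 5)
    }, logical(1))
    if (!any(jump)) return(list(zs = zs, eq = eq))
    idx <- which(jump)
    mid_z <- (zs[idx] + zs[idx + 1]) / 2
    mid_eq <- purrr::map(mid_z, function(z) fixed_points(params, z))
    ord <- order(c(zs, mid_z))
    refine(c(zs, mid_z)[ord], c(eq, mid_eq)[ord], depth + 1)
  }
  r <- refine(zs, eq)
  zs <- r$zs; eq <- r$eq

  counts <- vapply(eq, nrow, integer(1))
  equilibria <- dplyr::bind_rows(eq)

  events <- list()

  # saddle-node: root count drops as z increases (fold of the V-nullsurface)
  z_sn_found <- numeric(0)
  for (i in seq_len(length(zs) - 1)) {
    if (!(counts[i] >= 1 && counts[i + 1] == 0)) next
    lo <- zs[i]; hi <- zs[i + 1]
    while (hi - lo > z_tol) {
      mid <- (lo + hi) / 2
      if (nrow(fixed_points(params, mid)) >= 1) lo <- mid else hi <- mid
    }
    z_sn <- (lo + hi) / 2
    # at the fold the V-residual is tangent: V = (V_T - beta z) + DT log(1 + a/g_L)
    V_sn <- (params$V_T - params$beta * z_sn) +
      params$Delta_T * log(1 + params$a / params$g_L)
    z_sn_found <- c(z_sn_found, z_sn)
    events <- c(events, list(tibble(kind = "saddle_node", z_value = z_sn,
                                    V_value = V_sn)))
  }

  # Andronov-Hopf: trace sign change along the lowest-V (non-saddle) branch.
  # The trace-positive window can be much narrower than the grid spacing just
  # below a fold, so the grid is augmented with samples approaching each
  # saddle-node from below before scanning for sign changes.
  ah_z <- zs
  for (z_sn in z_sn_found) {
    ah_z <- c(ah_z, z_sn - c(1e-1, 1e-2, 1e-3))
  }
  ah_z <- sort(unique(ah_z[ah_z >= z_min & ah_z <= z_max]))
  lower_trace <- vapply(ah_z, function(z) {
    e <- fixed_points(params, z)
    if (nrow(e)) e$trace[1] else NA_real_
  }, numeric(1))
  for (i in seq_len(length(ah_z) - 1)) {
    t1 <- lower_trace[i]; t2 <- lower_trace[i + 1]
    if (is.na(t1) || is.na(t2) || t1 * t2 >= 0) next
    lo <- ah_z[i]; hi <- ah_z[i + 1]; tlo <- t1
    while (hi - lo > z_tol) {
      mid <- (lo + hi) / 2
      e <- fixed_points(params, mid)
      tm <- if (nrow(e)) e$trace[1] else NA_real_
      if (is.na(tm)) break
      if (sign(tm) == sign(tlo)) { lo <- mid; tlo <- tm } else hi <- mid
    }
    z_ah <- (lo + hi) / 2
    e <- fixed_points(params, z_ah)
    if (nrow(e) && e$det[1] > 0) {
      events <- c(events, list(tibble(kind = "andronov_hopf", z_value = z_ah,
                                      V_value = e$V_star[1])))
    }
  }

  events <- if (length(events)) arrange(dplyr::bind_rows(events), .data$z_value) else
    tibble(kind = character(0), z_value = numeric(0), V_value = numeric(0))

  structure(list(equilibria = equilibria, events = events, params = params,
                 z_range = c(z_min, z_max)),
            class = "adex_bifurcation")
}

#' @export
print.adex_bifurcation <- function(x, ...) {
  cat(sprintf("Fast-subsystem bifurcation diagram over z in [%g, %g] mV\n",
              x$z_range[1], x$z_range[2]))
  print(x$events)
  invisible(x)
}

#' @rdname bifurcation_diagram
#' @param x An `adex_bifurcation` object.
#' @param ... Unused.
#' @export
tidy.adex_bifurcation <- function(x, ...) x$equilibria

#' @rdname bifurcation_diagram
#' @export
glance.adex_bifurcation <- function(x, ...) {
  ev <- x$events
  tibble(n_hopf = sum(ev$kind == "andronov_hopf"),
         n_saddle_node = sum(ev$kind == "saddle_node"),
         z_hopf = if (any(ev$kind == "andronov_hopf"))
           ev$z_value[ev$kind == "andronov_hopf"][1] else NA_real_,
         z_saddle_node = if (any(ev$kind == "saddle_node"))
           ev$z_value[ev$kind == "saddle_node"][1] else NA_real_)
}

#' Write a bifurcation diagram to disk
#'
#' The equilibria go to CSV (`z_mV,V_star_mV,w_star_pA,trace,det,stability`),
#' the events to a JSON list of `{kind, z_value, V_value}`.
#'
#' @param bd An `adex_bifurcation` object.
#' @param csv_path,json_path Output paths.
#' @return `csv_path`, invisibly.
#' @export
write_bifurcation <- function(bd, csv_path, json_path) {
  eq <- bd$equilibria
  utils::write.csv(
    data.frame(z_mV = eq$z, V_star_mV = eq$V_star, w_star_pA = eq$w_star,
               trace = eq$trace, det = eq$det, stability = eq$stability),
    csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(bd$events, json_path, digits = NA)
  invisible(csv_path)
}

#' Nullsurfaces of the fast dynamics in (V, z)
#'
#' For each `(V, z)` grid point, solves the V-equation for the unique `w`
#' making `dV/dt = 0` (w enters linearly) and evaluates the w-nullsurface
#' `w = a (V - (E_L + z))`. The fold curve of the V-nullsurface, where its
#' slope in V changes sign, lies exactly on `V = V_T - beta z`.
#'
#' @inheritParams fixed_points
#' @param V_range,z_range Numeric length-2 ranges (mV).
#' @param n_V,n_z Grid sizes.
#' @return A tibble with columns `V`, `z`, `w_vnull` (pA), `w_wnull` (pA) and
#'   `on_fold` (logical, nearest-grid-line marker of the fold curve).
#' @export
nullsurface <- function(params, V_range = c(params$E_L - 25, params$V_D),
                        z_range = c(-5, 40), n_V = 60, n_z = 60) {
  stopifnot(all(is.finite(c(V_range, z_range))))
  grid <- tidyr::expand_grid(V = seq(V_range[1], V_range[2], length.out = n_V),
                             z = seq(z_range[1], z_range[2], length.out = n_z))
  ex <- exp((grid$V - (params$V_T - params$beta * grid$z)) / params$Delta_T)
  grid %>%
    mutate(
      w_vnull = params$g_L * ((params$E_L + .data$z) - .data$V) +
        params$g_L * params$Delta_T * ex - params$g_p * .data$z + params$I_s,
      w_wnull = params$a * (.data$V - (params$E_L + .data$z)),
      on_fold = abs(.data$V - (params$V_T - params$beta * .data$z)) <=
        diff(V_range) / (2 * (n_V - 1)))
}

#' Fold curve of the V-nullsurface
#'
#' @inheritParams fixed_points
#' @param z_values Values of z (mV) at which to evaluate the fold.
#' @return A tibble with `z` and `V_fold = V_T - beta z` (mV).
#' @export
fold_curve <- function(params, z_values) {
  tibble(z = z_values, V_fold = params$V_T - params$beta * z_values)
}
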