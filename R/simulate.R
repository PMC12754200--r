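#' Experimental condition
#'
#' Conditions differ only in the external cytokine forcing: the basal
#' transcription of every cytokine-role gene is multiplied by (1 + u(t)),
#' where u(t) is the condition's forcing profile (see [cytokine_forcing()]).
#'
#' * `control`: u = 0 throughout (osteogenic induction alone).
#' * `inflammatory`: u = A during the acute surge (t <= surge_end), then a
#'   partial exponential taper with half-life `taper_halflife`.
#' * `resolution`: identical to inflammatory until `resolution_start`, then
#'   a four-fold faster decay (half-life `taper_halflife / 4`).
#'
#' `preactivation` models a chronically inflamed milieu at the start of the
#' experiment: cytokine initial levels are raised by
#' `preactivation * A * basal_rate / decay_rate` so that inflamed samples are
#' already cytokine-high at t = 0 and still surge toward the full forced
#' plateau within the first 6 h.
#'
#' @param label one of `"control"`, `"inflammatory"`, `"resolution"`.
#' @param forcing_amplitude A >= 0, dimensionless multiplier on cytokine
#'   basal rates (0 for control; default 14 otherwise, i.e. a 15-fold
#'   induction over the healthy baseline).
#' @param surge_end hours; end of the acute surge window (default 6).
#' @param taper_halflife hours; half-life of the post-surge taper
#'   (default 120, a partial taper: forcing stays above A/4 over 0-48 h).
#' @param resolution_start hours; when the resolution-phase decay begins
#'   (default 24; resolution only).
#' @param preactivation fraction of the forced cytokine steady state already
#'   present at t = 0 (default 0.9 for forced conditions, 0 for control).
#' @return An object of class `grn_condition`.
#' @export
condition <- function(label = c("control", "inflammatory", "resolution"),
                      forcing_amplitude = NULL, surge_end = 6,
                      taper_halflife = 120, resolution_start = 24,
                      preactivation = NULL) {
  label <- match.arg(label)
  if (is.null(forcing_amplitude))
    forcing_amplitude <- if (label == "control") 0 else 14
  if (is.null(preactivation))
    preactivation <- if (label == "control") 0 else 0.9
  if (label == "control" && forcing_amplitude != 0)
    stop("control condition must have forcing_amplitude 0")
  if (label != "control" && forcing_amplitude <= 0)
    stop(label, " condition must have forcing_amplitude > 0")
  if (surge_end <= 0 || taper_halflife <= 0)
    stop("surge_end and taper_halflife must be positive")
  if (label == "resolution" &&
      !(surge_end < resolution_start && resolution_start < 48))
    stop("resolution requires 0 < surge_end < resolution_start < 48")
  structure(list(label = label, forcing_amplitude = forcing_amplitude,
                 surge_end = surge_end, taper_halflife = taper_halflife,
                 resolution_start = resolution_start,
                 preactivation = preactivation),
            class = "grn_condition")
}

#' Simulation configuration
#'
#' @param sample_times strictly increasing hours within `t_span` at which the
#'   trajectory is sampled (default the standard panel 0, 6, 12, 24, 48 h).
#' @param t_span two-element numeric, simulated interval in hours.
#' @param rtol,atol solver relative/absolute tolerances.
#' @param preset name of the parameter preset the configuration accompanies.
#' @return An object of class `grn_sim_config`.
#' @export
sim_config <- function(sample_times = c(0, 6, 12, 24, 48),
                       t_span = c(0, 48), rtol = 1e-8, atol = 1e-10,
                       preset = "moderate") {
  if (any(diff(sample_times) <= 0))
    stop("sample_times must be strictly increasing")
  if (min(sample_times) < t_span[1] || max(sample_times) > t_span[2])
    stop("sample_times must lie within t_span")
  structure(list(sample_times = sample_times, t_span = t_span,
                 rtol = rtol, atol = atol, preset = preset),
            class = "grn_sim_config")
}

#' Cytokine forcing profile u(t)
#'
#' @param t hours, within the 0-48 h window (vectorised).
#' @param cond a [condition()].
#' @return Nonnegative multiplier(s) u(t) applied to cytokine basal rates.
#' @export
cytokine_forcing <- function(t, cond) {
  stopifnot(inherits(cond, "grn_condition"))
  if (any(t < 0 | t > 48)) stop("t must lie within [0, 48] hours")
  A <- cond$forcing_amplitude
  if (cond$label == "control" || A == 0) return(rep(0, length(t)))
  ts <- cond$surge_end; hl <- cond$taper_halflife
  u <- ifelse(t <= ts, A, A * 2^(-(t - ts) / hl))
  if (cond$label == "resolution") {
    tr <- cond$resolution_start
    u_tr <- if (tr <= ts) A else A * 2^(-(tr - ts) / hl)
    late <- t >= tr
    u[late] <- u_tr * 2^(-(t[late] - tr) / (hl / 4))
  }
  u
}

# per-gene regulation terms, precomputed from the edge list once per solve
.compile_network <- function(network) {
  g <- network$genes$symbol
  e <- network$edges
  e <- e[e$weight > 0 | e$sign < 0, , drop = FALSE]  # w = 0 activation is absent
  act <- lapply(seq_along(g), function(i) {
    sel <- e$sign > 0 & e$target == g[i] & e$weight > 0
    list(j = match(e$source[sel], g), w = e$weight[sel],
         K = e$half_saturation[sel], n = e$hill[sel])
  })
  inh <- lapply(seq_along(g), function(i) {
    sel <- e$sign < 0 & e$target == g[i] & e$weight > 0
    list(k = match(e$source[sel], g),
         K = e$half_saturation[sel], n = e$hill[sel])
  })
  list(act = act, inh = inh,
       b = network$genes$basal_rate, d = network$genes$decay_rate,
       cyt = network$genes$role == "cytokine")
}

#' Right-hand side of the regulatory ODE system
#'
#' For each gene i,
#' `dx_i/dt = [ b_i (1 + u_i(t)) + sum_j w_ji x_j^n / (K^n + x_j^n) ]
#'            * prod_k K^n / (K^n + x_k^n)  -  d_i x_i`
#' with activating edges j entering additively through saturating Hill terms,
#' inhibiting edges k entering as a multiplicative Hill repression factor,
#' u_i(t) the condition forcing for cytokine-role genes (0 otherwise) and
#' first-order decay. Inhibitory edges with weight 0 are treated as absent.
#'
#' @param state nonnegative expression vector in network gene order.
#' @param t time in hours.
#' @param network a `grn_network`.
#' @param cond a [condition()].
#' @return Rate vector (expression units per hour).
#' @export
grn_derivative <- function(state, t, network, cond) {
  if (any(state < 0)) stop("state entries must be nonnegative")
  cn <- .compile_network(network)
  .grn_rhs(state, t, cn, cond)
}

.grn_rhs <- function(x, t, cn, cond) {
  x <- pmax(x, 0)
  # adaptive solvers may probe marginally outside the window
  u <- cytokine_forcing(min(max(t, 0), 48), cond)
  prod <- cn$b * (1 + ifelse(cn$cyt, u, 0))
  for (i in seq_along(x)) {
    a <- cn$act[[i]]
    if (length(a$j) > 0) {
      xs <- x[a$j]^a$n
      prod[i] <- prod[i] + sum(a$w * xs / (a$K^a$n + xs))
    }
    h <- cn$inh[[i]]
    if (length(h$k) > 0) {
      Kn <- h$K^h$n
      prod[i] <- prod[i] * base::prod(Kn / (Kn + x[h$k]^h$n))
    }
  }
  prod - cn$d * x
}

#' Simulate one expression trajectory
#'
#' Integrates the regulatory ODE system with an adaptive solver
#' ([deSolve::ode()], `lsoda`) and samples it exactly at
#' `config$sample_times`. Deterministic given its inputs: all stochasticity
#' enters upstream via [perturb_coefficients()] and downstream via the noise
#' module. Sampled values are clamped at 0 from below (the dynamics are
#' nonnegative; clamping removes solver-level round-off excursions).
#'
#' @param network a `grn_network` (possibly perturbed).
#' @param cond a [condition()].
#' @param config a [sim_config()].
#' @return An object of class `grn_trajectory`: list with `condition`,
#'   `times`, `values` (times x genes matrix) and `network_used`.
#' @export
simulate_trajectory <- function(network, cond, config = sim_config()) {
  stopifnot(inherits(network, "grn_network"), inherits(cond, "grn_condition"))
  cn <- .compile_network(network)
  x0 <- network$genes$initial_level
  # chronically inflamed milieu: cytokines start near the forced steady state
  x0 <- x0 + ifelse(cn$cyt,
                    cond$preactivation * cond$forcing_amplitude *
                      cn$b / cn$d, 0)
  times <- config$sample_times
  solve_times <- if (times[1] > config$t_span[1])
    c(config$t_span[1], times) else times
  sol <- deSolve::ode(y = x0, times = solve_times,
                      func = function(t, y, parms) list(.grn_rhs(y, t, cn,
                                                                 cond)),
                      parms = NULL, method = "lsoda",
                      rtol = config$rtol, atol = config$atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed near t = ", max(sol[, 1]), " h")
  vals <- unname(sol[match(times, sol[, 1]), -1, drop = FALSE])
  vals <- pmax(vals, 0)
  dimnames(vals) <- list(NULL, network$genes$symbol)
  structure(list(condition = cond$label, times = times, values = vals,
                 network_used = network),
            class = "grn_trajectory")
}

#' @export
print.grn_trajectory <- function(x, ...) {
  cat("Trajectory (", x$condition, "): ", length(x$times),
      " time points x ", ncol(x$values), " genes\n", sep = "")
  print(round(cbind(time_h = x$times, x$values), 4))
  invisible(x)
}
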