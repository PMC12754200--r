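test_that("cytokine forcing follows the surge/taper/resolution profile", {
  ctrl <- condition("control")
  infl <- condition("inflammatory", forcing_amplitude = 1)
  expect_equal(cytokine_forcing(c(0, 10, 48), ctrl), c(0, 0, 0))
  expect_equal(cytokine_forcing(3, infl), 1)      # inside the surge window
  # partial taper: never below A/4 over the experiment with default half-life
  tt <- seq(0, 48, by = 0.5)
  expect_true(all(cytokine_forcing(tt, infl) >= 1 / 4))
  res <- condition("resolution", forcing_amplitude = 1)
  expect_lt(cytokine_forcing(48, res), cytokine_forcing(48, infl))
  expect_error(cytokine_forcing(49, infl), "48")
  expect_error(condition("control", forcing_amplitude = 2), "control")
})

test_that("the regulatory derivative matches its closed-form pieces", {
  genes <- data.frame(symbol = c("A", "B"), role = "mediator",
                      basal_rate = c(0.2, 0.1), decay_rate = c(0.1, 0.5),
                      initial_level = 0, stringsAsFactors = FALSE)
  iso <- regulatory_network(genes, data.frame())
  ctrl <- condition("control")
  # no edges, no forcing: dx/dt = b - d x, zero at the b/d steady state
  expect_equal(grn_derivative(c(2, 0.2), 0, iso, ctrl), c(0, 0))
  expect_equal(grn_derivative(c(0, 0), 5, iso, ctrl), c(0.2, 0.1))
  expect_error(grn_derivative(c(-1, 0), 0, iso, ctrl), "nonnegative")
  # a saturated inhibitor drives production to zero: dx/dt -> -d x
  inh <- regulatory_network(genes, data.frame(
    source = "A", target = "B", sign = -1, weight = 1,
    half_saturation = 1, hill = 2, stringsAsFactors = FALSE))
  d <- grn_derivative(c(1e6, 1), 0, inh, ctrl)
  expect_equal(d[2], -0.5 * 1, tolerance = 1e-9)
})

test_that("solver reproduces the linear birth-death closed form to 1e-6 relative", {
  set.seed(11)
  cfg <- sim_config()
  for (i in 1:5) {
    rn <- random_network(n_genes = 4)
    rn$edges <- rn$edges[0, ]                 # remove all regulation
    traj <- simulate_trajectory(rn, condition("control"), cfg)
    b <- rn$genes$basal_rate; d <- rn$genes$decay_rate
    x0 <- rn$genes$initial_level
    for (k in seq_along(cfg$sample_times)) {
      t <- cfg$sample_times[k]
      closed <- b / d + (x0 - b / d) * exp(-d * t)
      expect_lt(max(abs(traj$values[k, ] - closed) /
                      pmax(abs(closed), 1e-12)), 1e-6)
    }
  }
})

test_that("sampled trajectories are nonnegative and deterministic", {
  cfg <- sim_config()
  set.seed(3)
  for (i in 1:5) {
    rn <- random_network()
    for (lab in c("control", "inflammatory")) {
      tr <- simulate_trajectory(rn, condition(lab), cfg)
      expect_true(all(tr$values >= 0))
      expect_equal(dim(tr$values), c(5, nrow(rn$genes)))
    }
  }
  net <- default_network()
  t1 <- simulate_trajectory(net, condition("inflammatory"), cfg)
  t2 <- simulate_trajectory(net, condition("inflammatory"), cfg)
  expect_identical(t1$values, t2$values)
})

test_that("moderate preset reproduces the reference expression kinetics", {
  net <- default_network("moderate")
  cfg <- sim_config()
  ctrl <- simulate_trajectory(net, condition("control"), cfg)
  infl <- simulate_trajectory(net, condition("inflammatory"), cfg)
  # control RUNX2 rises then plateaus: nondecreasing to 24 h, <10% move after
  r <- ctrl$values[, "RUNX2"]
  expect_true(all(diff(r[1:4]) >= 0))
  expect_lt(abs(r[5] - r[4]) / r[4], 0.10)
  # ALPL steadily increases over 48 h in control
  expect_true(all(diff(ctrl$values[, "ALPL"]) >= 0))
  # IL1B peaks inside the acute window under inflammation
  dense <- sim_config(sample_times = seq(0, 48, by = 0.25))
  di <- simulate_trajectory(net, condition("inflammatory"), dense)
  peak <- dense$sample_times[which.max(di$values[, "IL1B"])]
  expect_gt(peak, 0)
  expect_lte(peak, 12)
  # unperturbed suppression factors sit in the reference 0.6-0.7 band
  for (g in c("RUNX2", "ALPL")) for (k in 4:5) {
    fold <- infl$values[k, g] / ctrl$values[k, g]
    expect_gte(fold, 0.6)
    expect_lte(fold, 0.7)
  }
})

test_that("suppression direction is robust to 25-50% coefficient perturbation", {
  net <- default_network("moderate")
  cfg <- sim_config(sample_times = c(0, 48))
  ctrl0 <- simulate_trajectory(net, condition("control"), cfg)
  set.seed(99)
  for (f in c(0.25, 0.5)) {
    for (i in 1:5) {
      p <- perturb_coefficients(net, f)
      infl <- simulate_trajectory(p, condition("inflammatory"), cfg)
      ctrl <- simulate_trajectory(p, condition("control"), cfg)
      expect_gt(ctrl$values[2, "RUNX2"] - infl$values[2, "RUNX2"], 0)
      expect_gt(ctrl0$values[2, "RUNX2"] - infl$values[2, "RUNX2"], 0)
    }
  }
})
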