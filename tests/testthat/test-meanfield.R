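test_that("the transfer function is a thresholded saturating sigmoid", {
  p <- default_rate_params()$exc
  expect_equal(naka_rushton(0, 0, p), 0)
  expect_equal(naka_rushton(p$theta, 0, p), 0)
  g <- seq(0, 30, 0.5)
  r <- naka_rushton(g, 0, p)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r >= 0 & r < p$r_max))
  # inhibition shifts the effective drive down
  expect_true(all(naka_rushton(g, 5, p) <= r))
})

test_that("sampled rate surfaces are monotone in the conductances", {
  surf <- cached("surf", sample_rate_surface(
    TRUE, gE_grid = c(8, 10, 12), gI_grid = c(0, 4),
    n_neurons = 30, duration = 800, seed = 7))
  for (gi in unique(surf$gI)) {
    r <- surf$rate[surf$gI == gi]
    expect_true(all(diff(r) >= -1e-4))
  }
  for (ge in unique(surf$gE)) {
    r <- surf$rate[surf$gE == ge]
    expect_true(all(diff(r) <= 1e-4))
  }
  # near-threshold bias alone: very low rate
  expect_lt(clamped_pool_rate(8.35, 0, TRUE, n_neurons = 30, duration = 800,
                              noise_sigma = 0.17) * 1000, 2)
})

test_that("fitting recovers known transfer parameters within 5 percent", {
  truth <- list(r_max = 0.1, theta = 8.5, h = 2.5, c_I = 0.45, M = 2)
  grid <- expand.grid(gE = seq(7, 16, 0.5), gI = seq(0, 6, 1))
  set.seed(42)
  grid$rate <- naka_rushton(grid$gE, grid$gI, truth) *
    (1 + rnorm(nrow(grid), 0, 0.02))
  grid$rate <- pmax(grid$rate, 0)
  fit <- fit_rate_function(grid)
  for (nm in c("r_max", "theta", "h", "c_I"))
    expect_lt(abs(fit[[nm]] - truth[[nm]]) / truth[[nm]], 0.05)
  expect_lt(fit$rms / max(grid$rate), 0.05)
})

test_that("mean-field derivatives have the correct fixed-point structure", {
  cfg <- small_config(N = 200)
  state <- stpnet:::mf_rest_state(cfg)
  # plasticity rest is a fixed point and silent synapses decay purely
  state[paste0("s_", c("A", "B", "C", "D"))] <- 0.05
  d <- mean_field_rhs(0, state, cfg, default_rate_params())[[1]]
  # below threshold all rates are zero: ds/dt = -s / tau_s
  expect_equal(unname(d[paste0("s_", c("A", "B", "C", "D"))]),
               rep(-0.05 / 100, 4), tolerance = 1e-10)
  expect_true(all(d[grep("^[ux][FD]_", names(d))] == 0))
  expect_equal(unname(d["s_IN"]), 0)
})

test_that("stationary synaptic activity matches the event-driven average", {
  # a clamped neuron fires periodically; the time average of its recorded
  # synaptic activity must match the assumed stationary form r*tau/(1+r*tau)
  np <- neuron_params(TRUE)
  npar <- matrix(with(np, c(Cm, gL, VL, Vth, Vreset, tref, VE, VI, 0)), 1)
  n_steps <- 30000
  set.seed(1)
  out <- stpnet:::sim_network_cpp(
    pop_size = 1L, pop_exc = TRUE, npar = npar, classes = list(),
    gextE = matrix(12, n_steps, 1), gextI = matrix(0, n_steps, 1),
    plast = stpnet:::plasticity_vector(plasticity_params()),
    dt = 0.1, n_steps = n_steps, record_every = 1,
    noise_sigma = 0, freeze_plasticity = FALSE)
  r <- length(out$spike_step) / 3000           # kHz
  late <- out$time > 1000
  s_obs <- mean(out$sC[late, 1])
  s_pred <- r * 100 / (1 + r * 100)
  expect_lt(abs(s_obs - s_pred) / s_obs, 0.10)
})

test_that("the mean-field trajectory reproduces the goal-to-action sequence", {
  cfg <- small_config(N = 200)
  mf <- cached("mf_default", simulate_mean_field(cfg))
  early <- which.min(abs(mf$time - 150))
  expect_true(all(mf$rates[early, ] < 1))      # resting before goal display
  fin <- mf$rates[nrow(mf$rates), 1:4]
  on <- fin > 15
  # exactly one action assembly active at trial end
  expect_true(identical(unname(on), c(TRUE, FALSE, FALSE, TRUE)) ||
              identical(unname(on), c(FALSE, TRUE, TRUE, FALSE)))
  expect_true(all(fin[!on] < 2))
  # depression of the goal assembly and facilitation of the action assemblies
  i_goal <- which.min(abs(mf$time - 1200))
  expect_lt(mf$efficacy[i_goal, "AB"], mf$efficacy[1, "AB"])
  expect_gt(mf$efficacy[i_goal, "AD"], mf$efficacy[1, "AD"])
})

test_that("the mean field without any stimulus stays at the resting point", {
  cfg <- small_config(N = 200)
  cfg$protocol$activation_amplitude <- 0
  cfg$protocol$sensory_amplitude <- 0
  cfg$meanfield$perturbation_amplitude <- 0
  mf <- simulate_mean_field(cfg)
  expect_lt(max(mf$rates), 0.5)
  expect_true(all(abs(mf$uF - 0.2) < 1e-6))
})

test_that("mean-field state components remain in the unit interval", {
  mf <- cached("mf_default", simulate_mean_field(small_config(N = 200)))
  expect_true(all(mf$states >= -1e-9 & mf$states <= 1 + 1e-9))
})

test_that("frozen synapses leave the mean field in a persistent goal state", {
  cfg <- small_config(N = 200)
  mf <- simulate_mean_field(cfg, freeze_plasticity = TRUE)
  fin <- mf$rates[nrow(mf$rates), 1:4]
  expect_gt(fin[["A"]], 10); expect_gt(fin[["B"]], 10)
  expect_lt(fin[["C"]], 5); expect_lt(fin[["D"]], 5)
  expect_true(all(abs(mf$uF - 0.2) < 1e-9))
})
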