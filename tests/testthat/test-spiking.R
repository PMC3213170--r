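test_that("membrane dynamics reproduce closed-form steady states", {
  # zero conductance: the leak reversal is a fixed point
  out <- clamp_sim(gE = 0, duration = 200)
  expect_lt(max(abs(out$V - neuron_params(TRUE)$VL)), 1e-9)
  expect_length(out$spike_times, 0)

  # bias-only drive: conductance-weighted steady state, just below threshold
  out <- clamp_sim(gE = 8.35, duration = 400)
  v_inf <- (25 * (-70) + 8.35 * (-5)) / (25 + 8.35)
  expect_equal(v_inf, -53.725, tolerance = 1e-3)
  expect_equal(out$V[length(out$V)], v_inf, tolerance = 1e-3)
  expect_gt(neuron_params(TRUE)$Vth, v_inf)   # subthreshold
  expect_length(out$spike_times, 0)
})

test_that("suprathreshold firing matches the analytic LIF interspike interval", {
  gE <- 12
  out <- clamp_sim(gE = gE, duration = 500)
  np <- neuron_params(TRUE)
  g_tot <- np$gL + gE
  v_inf <- (np$gL * np$VL + gE * np$VE) / g_tot
  tau <- np$Cm * 1000 / g_tot
  t_charge <- tau * log((v_inf - np$Vreset) / (v_inf - np$Vth))
  isi <- diff(out$spike_times)
  expect_gt(length(isi), 10)
  expect_equal(max(isi), min(isi), tolerance = 1e-9)  # periodic
  expect_equal(isi[1], np$tref + t_charge, tolerance = 0.3)
})

test_that("the spike-event plasticity rule matches hand-applied updates", {
  # facilitation/depression share the event rule; first spike from rest
  up <- stp_spike_update(0.2, 1, U = 0.2)
  expect_equal(up$u, 0.36)
  expect_equal(up$s_peak, 0.36)
  expect_equal(up$x, 0.64)
  # constant synapses always release with peak one
  expect_equal(stp_spike_update(0.7, 0.3, kind = "constant")$s_peak, 1)

  # depression contract: two spikes separated by >> tau_u but << tau_x
  pl <- plasticity_params()$depression
  first <- stp_spike_update(0.2, 1)
  dt_gap <- 200
  u2 <- 0.2 + (first$u - 0.2) * exp(-dt_gap / pl$tau_u)
  x2 <- 1 + (first$x - 1) * exp(-dt_gap / pl$tau_x)
  second <- stp_spike_update(u2, x2)
  expect_lt(second$s_peak, first$s_peak)
})

test_that("synaptic transmission is delayed by exactly the wired delay", {
  np_e <- neuron_params(TRUE)
  npar <- rbind(with(np_e, c(Cm, gL, VL, Vth, Vreset, tref, VE, VI, 12)),
                with(np_e, c(Cm, gL, VL, Vth, Vreset, tref, VE, VI, 0)))
  n_steps <- 2000
  delay_steps <- 30L
  cls <- list(list(post_pop = 1L, kind = 2L, w = 1,
                   pre = matrix(0L, 1, 1), delay = matrix(delay_steps, 1, 1)))
  set.seed(1)
  out <- stpnet:::sim_network_cpp(
    pop_size = c(1L, 1L), pop_exc = c(TRUE, TRUE), npar = npar,
    classes = cls, gextE = matrix(0, n_steps, 2),
    gextI = matrix(0, n_steps, 2),
    plast = stpnet:::plasticity_vector(plasticity_params()),
    dt = 0.1, n_steps = n_steps, record_every = 1,
    noise_sigma = 0, freeze_plasticity = FALSE)
  t_spike <- (out$spike_step[out$spike_neuron == 0][1] + 1) * 0.1
  v_post <- out$V[, 2]
  t_dev <- out$time[which(abs(v_post - np_e$VL) > 1e-9)[1]]
  expect_equal(t_dev, t_spike + delay_steps * 0.1 + 0.1, tolerance = 0.11)
})

test_that("plasticity state variables stay within [0, 1] through a trial", {
  tr <- cached("trial50", run_trial(small_config(), seed = 2))
  for (nm in c("uF", "xF", "uD", "xD", "sF", "sD", "sC", "uxF", "uxD")) {
    expect_true(all(tr[[nm]] >= 0), info = nm)
    expect_true(all(tr[[nm]] <= 1 + 1e-12), info = nm)
  }
  expect_true(all(tr$rates >= 0))
  expect_true(all(tr$efficacy >= 0))
})

test_that("without noise or stimulus the resting state is a fixed point", {
  cfg <- small_config(noise_sigma = 0)
  cfg$protocol$activation_amplitude <- 0
  cfg$protocol$sensory_amplitude <- 0
  cfg$protocol$trial_duration <- 10000
  tr <- run_trial(cfg, seed = 1)
  expect_equal(nrow(tr$spikes), 0)
  expect_true(all(tr$rates == 0))
})

test_that("with noise but no stimulus the network stays near rest", {
  cfg <- small_config()
  cfg$protocol$activation_amplitude <- 0
  cfg$protocol$sensory_amplitude <- 0
  cfg$protocol$trial_duration <- 3000
  tr <- run_trial(cfg, seed = 4)
  exc_rate <- sum(tr$spikes$population != "IN") / (4 * 50 * 3)
  expect_lt(exc_rate, 1)   # below 1 Hz per neuron
})

test_that("kernel rate estimates conserve spike counts", {
  tg <- seq(0, 1000, by = 1)
  set.seed(1)
  spikes <- runif(400, 100, 900)
  r <- population_rate(spikes, pop_size = 10, kernel_width = 20, t_grid = tg)
  expect_true(all(r >= 0))
  # integral of rate * pop_size over time ~ spike count
  expect_equal(sum(r) * 10 * 1e-3, 400, tolerance = 0.01 * 400)
  # halving the kernel width leaves the integral unchanged
  r2 <- population_rate(spikes, 10, kernel_width = 10, t_grid = tg)
  expect_equal(sum(r2), sum(r), tolerance = 0.01 * sum(r))
  # single spike: unit-mass bump
  r1 <- population_rate(500, pop_size = 1, kernel_width = 20, t_grid = tg)
  expect_equal(sum(r1) * 1e-3, 1, tolerance = 0.01)
  expect_equal(which.max(r1), 501, tolerance = 2)
  # empty record: zero series
  expect_true(all(population_rate(numeric(0), 10, 20, tg) == 0))
})

test_that("stimulus traces follow the protocol and read-outs sum assemblies", {
  tr <- cached("trial50", run_trial(small_config(), seed = 2))
  pr <- tr$config$protocol
  # half-way up the ramp the activation conductance is half its amplitude
  t_half <- pr$goal_display_onset + pr$activation_ramp / 2
  i <- which.min(abs(tr$time - t_half))
  expect_equal(unname(tr$stimulus[i, "D"]), 0.5 * pr$activation_amplitude,
               tolerance = 0.01)
  # sensory pulse rides on the ramp for the cued assembly only
  expect_equal(unname(tr$stimulus[i, "A"] - tr$stimulus[i, "D"]),
               pr$sensory_amplitude, tolerance = 1e-12)
  expect_true(all(tr$stimulus[, "IN"] == 0))
  expect_equal(tr$readout[, "A1"], tr$rates[, "A"] + tr$rates[, "D"])
  expect_equal(tr$readout[, "A2"], tr$rates[, "B"] + tr$rates[, "C"])
})

test_that("assembly efficacy equals the summed weight for resting constant synapses", {
  cfg <- small_config("depression_only")
  cfg$protocol$activation_amplitude <- 0
  cfg$protocol$sensory_amplitude <- 0
  cfg$protocol$trial_duration <- 200
  cfg$protocol$goal_display_onset <- 0
  cfg$noise_sigma <- 0
  tr <- run_trial(cfg, seed = 1)
  # action assemblies use constant synapses in this variant: efficacy = W
  expect_true(all(abs(tr$efficacy[, "AD"] - 0.5) < 1e-12))
  # goal assemblies are depressing: resting peak is U * W
  expect_true(all(abs(tr$efficacy[, "AB"] - 0.2 * 3) < 1e-12))
  expect_equal(assembly_efficacy(tr, "BC", 100), 0.5)
})

test_that("the compiled core matches the scalar event-driven reference spike-for-spike", {
  cfg <- small_config(N = 10, noise_sigma = 0)
  for (p in c("A", "B", "C", "D")) cfg$populations[[p]]$bias <- 12
  cfg$populations$IN$bias <- 8
  cfg$protocol$trial_duration <- 300
  cfg$protocol$goal_display_onset <- 0
  cfg$protocol$activation_amplitude <- 0
  cfg$protocol$sensory_amplitude <- 0
  net <- build_network(cfg, seed = 6)
  fast <- run_trial(cfg, seed = 1, network = net)
  slow <- reference_sim(net, duration = 300)
  ord <- function(d) d[order(d$time_ms, d$population, d$neuron), ]
  a <- ord(fast$spikes); b <- ord(slow)
  expect_equal(nrow(a), nrow(b))
  expect_equal(a$time_ms, b$time_ms, tolerance = 1e-9)
  expect_equal(a$population, b$population)
  expect_equal(a$neuron, b$neuron)
})
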