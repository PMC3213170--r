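# Low-level clamped simulation of an uncoupled pool, returning the membrane
# trace and spike times (the exported clamped_pool_rate only returns rates).
clamp_sim <- function(gE, gI = 0, excitatory = TRUE, n = 1, duration = 500,
                      noise_sigma = 0, dt = 0.1, record_every = 1, bias = 0,
                      seed = 1) {
  np <- neuron_params(excitatory)
  npar <- matrix(with(np, c(Cm, gL, VL, Vth, Vreset, tref, VE, VI, bias)), 1)
  n_steps <- round(duration / dt)
  set.seed(seed)
  out <- stpnet:::sim_network_cpp(
    pop_size = n, pop_exc = excitatory, npar = npar, classes = list(),
    gextE = matrix(gE, n_steps, 1), gextI = matrix(gI, n_steps, 1),
    plast = stpnet:::plasticity_vector(plasticity_params()),
    dt = dt, n_steps = n_steps, record_every = record_every,
    noise_sigma = noise_sigma, freeze_plasticity = FALSE)
  list(time = out$time, V = out$V[, 1],
       spike_times = (out$spike_step + 1) * dt,
       spike_neuron = out$spike_neuron + 1)
}
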