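# Independent scalar reference simulator.
#
# A deliberately plain, loop-over-everything implementation of the same
# hybrid scheme as the compiled core: RK4 membrane update with conductances
# held over the step, threshold/reset/refractory handling, exact exponential
# relaxation of s/u/x between spikes, the u-then-release event rule, and
# step-quantized delays.  Used to check the vectorized core spike-for-spike
# on small noise-free fixtures.
reference_sim <- function(network, duration, freeze_plasticity = FALSE) {
  cfg <- network$config
  dt <- cfg$dt
  n_steps <- round(duration / dt)
  sizes <- network$sizes
  offset <- network$offset
  n_tot <- sum(sizes)
  pop_of <- rep(names(sizes), sizes)
  pl <- cfg$plasticity
  U <- pl$U

  np <- lapply(cfg$populations, function(p) c(p$neuron, bias = p$bias,
                                              exc = p$excitatory))
  V <- vapply(pop_of, function(p) np[[p]]$VL, 0)
  refrac <- rep(0, n_tot)
  sF <- sD <- sC <- rep(0, n_tot)
  uF <- uD <- rep(U, n_tot)
  xF <- xD <- rep(1, n_tot)
  # full history of synaptic activity; row k = state after step k, row
  # indices <= 0 are silent history
  hF <- hD <- hC <- matrix(0, n_steps + 1, n_tot)

  stim <- stimulus_matrix(cfg, n_steps)
  cls <- lapply(network$classes, function(cl)
    list(post = cl$post_pop, kind = cl$kind, w = cl$weight_per_synapse,
         pre = cl$pre, dstep = round(cl$delay / dt)))

  spike_t <- integer(0); spike_n <- integer(0)
  for (tt in seq_len(n_steps)) {
    gE <- gI <- rep(0, n_tot)
    for (i in seq_len(n_tot)) {
      p <- pop_of[i]
      gE[i] <- np[[p]]$bias + stim$gE[tt, p]
    }
    for (cl in cls) {
      hist <- switch(cl$kind, facilitation = hF, depression = hD,
                     constant = hC, inhibitory = hC)
      for (j in seq_len(sizes[[cl$post]])) {
        post <- offset[[cl$post]] + j
        acc <- 0
        for (k in seq_len(nrow(cl$pre))) {
          row <- tt - cl$dstep[k, j]
          if (row >= 1) acc <- acc + hist[row, cl$pre[k, j]]
        }
        if (cl$kind == "inhibitory") gI[post] <- gI[post] + cl$w * acc
        else gE[post] <- gE[post] + cl$w * acc
      }
    }
    spiked <- integer(0)
    for (i in seq_len(n_tot)) {
      p <- np[[pop_of[i]]]
      if (refrac[i] > 0) {
        refrac[i] <- refrac[i] - dt
        V[i] <- p$Vreset
        next
      }
      Cms <- p$Cm * 1000
      a <- (p$gL * p$VL + gE[i] * p$VE + gI[i] * p$VI) / Cms
      b <- (p$gL + gE[i] + gI[i]) / Cms
      k1 <- a - b * V[i]
      k2 <- a - b * (V[i] + dt / 2 * k1)
      k3 <- a - b * (V[i] + dt / 2 * k2)
      k4 <- a - b * (V[i] + dt * k3)
      v <- V[i] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (v >= p$Vth) {
        spike_t <- c(spike_t, tt); spike_n <- c(spike_n, i)
        spiked <- c(spiked, i)
        v <- p$Vreset
        refrac[i] <- p$tref
      }
      V[i] <- v
    }
    for (i in seq_len(n_tot)) {
      if (np[[pop_of[i]]]$exc) {
        sF[i] <- sF[i] * exp(-dt / pl$tau_s_exc)
        sD[i] <- sD[i] * exp(-dt / pl$tau_s_exc)
        sC[i] <- sC[i] * exp(-dt / pl$tau_s_exc)
        if (!freeze_plasticity) {
          uF[i] <- U + (uF[i] - U) * exp(-dt / pl$facilitation$tau_u)
          xF[i] <- 1 + (xF[i] - 1) * exp(-dt / pl$facilitation$tau_x)
          uD[i] <- U + (uD[i] - U) * exp(-dt / pl$depression$tau_u)
          xD[i] <- 1 + (xD[i] - 1) * exp(-dt / pl$depression$tau_x)
        }
      } else {
        sC[i] <- sC[i] * exp(-dt / pl$tau_s_inh)
      }
    }
    for (i in spiked) {
      if (np[[pop_of[i]]]$exc) {
        if (freeze_plasticity) {
          sF[i] <- U; sD[i] <- U
        } else {
          up <- stp_spike_update(uF[i], xF[i], U)
          uF[i] <- up$u; xF[i] <- up$x; sF[i] <- up$s_peak
          up <- stp_spike_update(uD[i], xD[i], U)
          uD[i] <- up$u; xD[i] <- up$x; sD[i] <- up$s_peak
        }
        sC[i] <- 1
      } else sC[i] <- 1
    }
    hF[tt + 1, ] <- sF; hD[tt + 1, ] <- sD; hC[tt + 1, ] <- sC
  }
  data.frame(time_ms = spike_t * dt,
             population = pop_of[spike_n],
             neuron = spike_n - unname(offset)[match(pop_of[spike_n],
                                                     names(sizes))])
}
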