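#' External input conductance time series
#'
#' Expands a stimulus protocol into per-population excitatory conductance
#' traces on the integration grid: the common activation ramp onto A--D, the
#' rectangular sensory pulse onto the displayed goal's assembly, and an
#' optional rectangular perturbation pulse onto one action assembly.
#'
#' @param config an `stp_config`.
#' @param n_steps number of integration steps (defaults to the whole trial).
#' @return list with matrices `gE` and `gI` (`n_steps` x populations, nS) and
#'   the step times `t` (ms).
#' @keywords internal
stimulus_matrix <- function(config, n_steps = NULL) {
  pr <- config$protocol
  dt <- config$dt
  if (is.null(n_steps)) n_steps <- round(pr$trial_duration / dt)
  t <- (seq_len(n_steps) - 1) * dt
  gE <- matrix(0, n_steps, length(POPS), dimnames = list(NULL, POPS))
  ramp <- pr$activation_amplitude *
    pmin(1, pmax(0, (t - pr$goal_display_onset) / pr$activation_ramp))
  for (p in POPS[1:4]) gE[, p] <- ramp
  sens <- pr$sensory_amplitude *
    (t >= pr$goal_display_onset & t < pr$goal_display_onset + pr$sensory_width)
  for (p in GOAL_ASSEMBLY[[pr$sensory_target]]) gE[, p] <- gE[, p] + sens
  if (pr$perturbation_amplitude > 0) {
    pert <- pr$perturbation_amplitude *
      (t >= pr$perturbation_onset & t < pr$perturbation_onset + pr$perturbation_width)
    for (p in ACTION_ASSEMBLY[[pr$perturbation_target]])
      gE[, p] <- gE[, p] + pert
  }
  list(gE = gE, gI = matrix(0, n_steps, length(POPS)), t = t)
}

kind_code <- function(kind)
  match(kind, c("facilitation", "depression", "constant", "inhibitory")) - 1L

plasticity_vector <- function(pl)
  c(U = pl$U, tau_uF = pl$facilitation$tau_u, tau_xF = pl$facilitation$tau_x,
    tau_uD = pl$depression$tau_u, tau_xD = pl$depression$tau_x,
    tau_sE = pl$tau_s_exc, tau_sI = pl$tau_s_inh)

neuron_param_matrix <- function(config) {
  t(vapply(config$populations, function(p)
    with(p$neuron, c(Cm, gL, VL, Vth, Vreset, tref, VE, VI, p$bias)),
    numeric(9)))
}

#' Run one spiking-network trial
#'
#' Integrates the full noisy leaky integrate-and-fire network with
#' event-driven short-term plasticity for one trial under the configured
#' stimulus protocol and returns the recorded trace.
#'
#' @param config an `stp_config`.
#' @param seed integer seed for the membrane noise stream (the network
#'   connectivity uses `config$seed` unless a prebuilt `network` is supplied).
#' @param network optionally a prebuilt `stp_network` (reused across trials of
#'   a batch).
#' @param freeze_plasticity if `TRUE`, utilization and resources are clamped
#'   at their resting values (u = U, x = 1) so synaptic efficacies are fixed --
#'   the no-plasticity control.
#' @param kernel_width Gaussian smoothing width (SD, ms) for firing-rate
#'   estimates.
#' @param record_every_ms stride (ms) of the recorded trace grid.
#' @return an object of class `stp_trial`: `time` (ms), `rates` (Hz, time x
#'   population), `readout` (Hz, columns A1 = A+D and A2 = B+C), per-population
#'   plasticity means (`uF`, `xF`, `uD`, `xD`, `uxF`, `uxD`) and synaptic
#'   activities (`sF`, `sD`, `sC`), `efficacy` (nS, per assembly), `spikes`
#'   (data frame `time_ms`, `population`, `neuron`), `stimulus` (nS), and the
#'   seeds and config used.
#' @examples
#' \donttest{
#' cfg <- network_config("all_types", N = 50)
#' tr <- run_trial(cfg, seed = 7)
#' matplot(tr$time, tr$rates[, 1:4], type = "l", ylab = "rate (Hz)")
#' }
#' @export
run_trial <- function(config, seed = 1L, network = NULL,
                      freeze_plasticity = FALSE, kernel_width = 20,
                      record_every_ms = 1) {
  validate_config(config)
  if (is.null(network)) network <- build_network(config)
  stopifnot(inherits(network, "stp_network"))
  dt <- config$dt
  stim <- stimulus_matrix(config)
  n_steps <- nrow(stim$gE)
  record_every <- max(1L, round(record_every_ms / dt))
  cls <- lapply(network$classes, function(cl) list(
    post_pop = match(cl$post_pop, POPS) - 1L,
    kind = kind_code(cl$kind),
    w = cl$weight_per_synapse,
    pre = cl$pre - 1L,
    delay = matrix(as.integer(round(cl$delay / dt)), nrow(cl$delay))))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- sim_network_cpp(
    pop_size = unname(network$sizes),
    pop_exc = vapply(config$populations, `[[`, TRUE, "excitatory"),
    npar = neuron_param_matrix(config),
    classes = cls,
    gextE = stim$gE, gextI = stim$gI,
    plast = plasticity_vector(config$plasticity),
    dt = dt, n_steps = n_steps, record_every = record_every,
    noise_sigma = config$noise_sigma,
    freeze_plasticity = freeze_plasticity)
  pop_of <- rep(POPS, unname(network$sizes))
  spikes <- data.frame(time_ms = (out$spike_step + 1) * dt,
                       population = pop_of[out$spike_neuron + 1],
                       neuron = out$spike_neuron + 1 -
                         unname(network$offset)[match(pop_of[out$spike_neuron + 1], POPS)],
                       stringsAsFactors = FALSE)
  tgrid <- out$time
  rates <- vapply(POPS, function(p)
    population_rate(spikes$time_ms[spikes$population == p],
                    pop_size = network$sizes[[p]], kernel_width = kernel_width,
                    t_grid = tgrid),
    numeric(length(tgrid)))
  colnames(rates) <- POPS
  readout <- cbind(A1 = rates[, "A"] + rates[, "D"],
                   A2 = rates[, "B"] + rates[, "C"])
  for (nm in c("sF", "sD", "sC", "uF", "xF", "uD", "xD", "uxF", "uxD"))
    colnames(out[[nm]]) <- POPS
  eff <- assembly_efficacy_trace(config, out)
  # stimulus rows aligned with the recorded trace grid (step-end times)
  ridx <- pmin(seq(record_every, n_steps, by = record_every) + 1L, n_steps)
  structure(list(
    time = tgrid, rates = rates, readout = readout,
    sF = out$sF, sD = out$sD, sC = out$sC,
    uF = out$uF, xF = out$xF, uD = out$uD, xD = out$xD,
    uxF = out$uxF, uxD = out$uxD,
    mV = out$V,
    efficacy = eff,
    spikes = spikes,
    stimulus = stim$gE[ridx, , drop = FALSE],
    freeze_plasticity = freeze_plasticity,
    seed = as.integer(seed), network_seed = network$seed,
    config = config), class = "stp_trial")
}

#' @export
print.stp_trial <- function(x, ...) {
  cat("stp_trial:", x$config$variant, "goal", x$config$protocol$sensory_target,
      "-", nrow(x$spikes), "spikes over", max(x$time), "ms\n")
  act <- selected_action(x)
  cat("  selected action:", if (is.na(act)) "none" else act, "\n")
  invisible(x)
}

#' Kernel firing-rate estimate for a spike train
#'
#' Bins spike times on the trace grid and smooths with a Gaussian kernel,
#' renormalized near the edges so the kernel mass inside the window is one.
#' The time integral of `rate * pop_size` approximates the spike count.
#'
#' @param spike_times numeric vector of spike times (ms).
#' @param pop_size number of neurons the spikes were pooled over.
#' @param kernel_width Gaussian SD (ms); must be positive.
#' @param t_grid output time grid (ms), uniformly spaced.
#' @return numeric vector of rates (Hz) on `t_grid`.
#' @export
population_rate <- function(spike_times, pop_size, kernel_width = 20,
                            t_grid) {
  stopifnot(kernel_width > 0, pop_size >= 1, length(t_grid) >= 2)
  bin <- t_grid[2] - t_grid[1]
  edges <- c(t_grid - bin / 2, t_grid[length(t_grid)] + bin / 2)
  counts <- if (length(spike_times))
    tabulate(findInterval(spike_times, edges, rightmost.closed = TRUE),
             nbins = length(t_grid)) else numeric(length(t_grid))
  half <- max(1L, ceiling(3 * kernel_width / bin))
  k <- exp(-0.5 * ((-half:half) * bin / kernel_width)^2)
  k <- k / sum(k)
  n <- length(counts)
  pad <- function(v) c(numeric(half), v, numeric(half))
  sm <- stats::filter(pad(counts), k, sides = 2)[half + seq_len(n)]
  mass <- stats::filter(pad(rep(1, n)), k, sides = 2)[half + seq_len(n)]
  as.numeric(sm / mass) / (pop_size * bin / 1000)
}

#' Synaptic efficacy of each cell assembly over time
#'
#' The efficacy of an assembly is the summed weight of its between-population
#' connection class times the population mean of the current peak release
#' (u*x for plastic synapses, 1 for constant ones), averaged over the two
#' directions -- the average peak conductance a neuron of the assembly receives
#' from its partner population.
#'
#' @param config an `stp_config`.
#' @param rec recorded per-population plasticity means (internal layout).
#' @return matrix time x assemblies `AB`, `CD`, `AD`, `BC` (nS).
#' @keywords internal
assembly_efficacy_trace <- function(config, rec) {
  cn <- config$connections
  eff <- sapply(names(ASSEMBLIES), function(a) {
    pops <- ASSEMBLIES[[a]]
    role <- if (a %in% c("AB", "CD")) "goal" else "action"
    row <- cn[cn$role == role, ][1, ]
    peak <- switch(row$kind,
      facilitation = (rec$uxF[, pops[1]] + rec$uxF[, pops[2]]) / 2,
      depression   = (rec$uxD[, pops[1]] + rec$uxD[, pops[2]]) / 2,
      constant     = rep(1, nrow(rec$uxF)))
    row$weight * peak
  })
  colnames(eff) <- names(ASSEMBLIES)
  eff
}

#' Instantaneous assembly efficacy at a recorded time
#'
#' Convenience accessor: the `efficacy` column of a trial trace at the grid
#' point nearest `t_ms`.
#'
#' @param trial an `stp_trial`.
#' @param assembly one of `"AB"`, `"CD"`, `"AD"`, `"BC"`.
#' @param t_ms time (ms).
#' @return efficacy in nS.
#' @export
assembly_efficacy <- function(trial, assembly = names(ASSEMBLIES), t_ms) {
  assembly <- match.arg(assembly)
  unname(trial$efficacy[which.min(abs(trial$time - t_ms)), assembly])
}

#' Which action the read-out reports
#'
#' An action is selected once its read-out (A1 = summed rate of A and D,
#' A2 = summed rate of B and C) exceeds twice the other continuously for at
#' least `sustain` ms; the winner at the end of the trial is reported.
#'
#' @param trial an `stp_trial` (or anything with `time` and `readout`).
#' @param sustain dominance duration (ms).
#' @return `"A1"`, `"A2"`, or `NA` if neither read-out dominates.
#' @export
selected_action <- function(trial, sustain = 200) {
  a1 <- trial$readout[, "A1"]; a2 <- trial$readout[, "A2"]
  dom <- ifelse(a1 > 2 * a2 & a1 > 1, 1L, ifelse(a2 > 2 * a1 & a2 > 1, 2L, 0L))
  dt <- trial$time[2] - trial$time[1]
  need <- max(1L, round(sustain / dt))
  r <- rle(dom)
  ok <- r$values != 0L & r$lengths >= need
  if (!any(ok)) return(NA_character_)
  c("A1", "A2")[r$values[max(which(ok))]]
}

#' Event-rule update of a plastic synapse at a presynaptic spike
#'
#' Applies the discrete short-term plasticity update used at every
#' presynaptic spike: utilization increments first, `u <- u + U*(1-u)`; the
#' release peak is `u*x`; resources then drop by the released amount,
#' `x <- x - u*x`.  Constant synapses release with peak 1 and leave `u`, `x`
#' untouched.
#'
#' @param u,x current utilization and resources (in `[0,1]`).
#' @param U resting utilization.
#' @param kind `"facilitation"`, `"depression"` (identical event rule -- the
#'   kinds differ only in their relaxation time constants) or `"constant"`.
#' @return list with updated `u`, `x` and the release peak `s_peak`.
#' @examples
#' stp_spike_update(0.2, 1)   # first spike from rest: u 0.36, peak 0.36
#' @export
stp_spike_update <- function(u, x, U = 0.2, kind = "facilitation") {
  if (kind == "constant") return(list(u = u, x = x, s_peak = 1))
  u2 <- u + U * (1 - u)
  peak <- u2 * x
  list(u = u2, x = x - peak, s_peak = peak)
}
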