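#' Simulate an uncoupled pool of neurons under clamped conductances
#'
#' Runs `n_neurons` independent spiking neurons of one cell class with fixed
#' excitatory and inhibitory conductances (no recurrent synapses, no bias --
#' the clamp is the total drive) and returns the population mean firing rate.
#' Used to sample the firing-rate transfer surface that the mean-field model's
#' Naka-Rushton transfer function is fitted to.
#'
#' @param gE,gI clamped conductances (nS).
#' @param excitatory logical; which cell class.
#' @param n_neurons pool size.
#' @param duration simulated time (ms); the first `discard` ms are dropped.
#' @param discard transient to discard (ms).
#' @param noise_sigma membrane noise amplitude (mV/sqrt(ms)).
#' @param dt integration step (ms).
#' @param seed RNG seed.
#' @return mean rate in kHz (spikes per neuron per ms).
#' @export
clamped_pool_rate <- function(gE, gI = 0, excitatory = TRUE, n_neurons = 40,
                              duration = 2000, discard = 200,
                              noise_sigma = 0.17, dt = 0.1, seed = 1L) {
  np <- neuron_params(excitatory)
  npar <- matrix(with(np, c(Cm, gL, VL, Vth, Vreset, tref, VE, VI, 0)), 1)
  n_steps <- round(duration / dt)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- sim_network_cpp(pop_size = n_neurons, pop_exc = excitatory,
                         npar = npar, classes = list(),
                         gextE = matrix(gE, n_steps, 1),
                         gextI = matrix(gI, n_steps, 1),
                         plast = plasticity_vector(plasticity_params()),
                         dt = dt, n_steps = n_steps, record_every = n_steps,
                         noise_sigma = noise_sigma, freeze_plasticity = TRUE)
  keep <- (out$spike_step + 1) * dt > discard
  sum(keep) / (n_neurons * (duration - discard))
}

#' Sample the firing-rate transfer surface
#'
#' Population mean rate of a clamped spiking pool on a grid of excitatory and
#' inhibitory conductances, covering the operating range of the network.
#'
#' @param excitatory logical; cell class.
#' @param gE_grid,gI_grid conductance grids (nS).
#' @inheritParams clamped_pool_rate
#' @return data frame with columns `gE`, `gI`, `rate` (kHz).
#' @export
sample_rate_surface <- function(excitatory = TRUE,
                                gE_grid = seq(0, 20, by = 2),
                                gI_grid = seq(0, 10, by = 2.5),
                                n_neurons = 40, duration = 2000,
                                noise_sigma = 0.17, seed = 1L) {
  grid <- expand.grid(gE = gE_grid, gI = gI_grid)
  grid$rate <- mapply(function(e, i, s)
    clamped_pool_rate(e, i, excitatory = excitatory, n_neurons = n_neurons,
                      duration = duration, noise_sigma = noise_sigma, seed = s),
    grid$gE, grid$gI, seed + seq_len(nrow(grid)))
  grid
}

#' Naka-Rushton firing-rate transfer function
#'
#' `r(g) = r_max * [g - theta]_+^M / (h^M + [g - theta]_+^M)` evaluated on the
#' effective drive `g = gE - c_I * gI`: a saturating intensity-response curve
#' with threshold `theta` (nS), semi-saturation `h` (nS), maximum rate `r_max`
#' (kHz) and exponent `M`.
#'
#' @param gE,gI conductances (nS).
#' @param params list with `r_max`, `theta`, `h`, `c_I`, `M`.
#' @return rate in kHz, nonnegative and nondecreasing in `gE`.
#' @export
naka_rushton <- function(gE, gI = 0, params) {
  g <- pmax(gE - params$c_I * gI - params$theta, 0)
  params$r_max * g^params$M / (params$h^params$M + g^params$M)
}

#' Fit the Naka-Rushton transfer function to a sampled rate surface
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the Naka-Rushton form
#' composed with the linear effective drive `gE - c_I * gI`; the exponent `M`
#' is fixed (default 2).  By default the residuals are taken on the
#' square-root scale, the variance-stabilizing transform for count-derived
#' rates; this weights the near-threshold region properly, which is what the
#' attractor structure of the reduced model is most sensitive to (an
#' identity-scale fit trades a spurious resting rate for accuracy at high
#' drive).
#'
#' @param surface data frame with columns `gE`, `gI`, `rate` (kHz), from
#'   [sample_rate_surface()] or [network_rate_samples()].
#' @param M transfer-function exponent.
#' @param transform residual scale, `"sqrt"` (default) or `"identity"`.
#' @param fix named list of parameters to hold fixed (e.g.
#'   `list(r_max = 0.1)`; useful when the sample does not constrain the
#'   asymptote).  `c_I` is fixed at 0 automatically when `gI` has no variance.
#' @return list with the fitted `r_max`, `theta`, `h`, `c_I`, `M`, and the
#'   residual RMS (`rms`, kHz, identity scale).
#' @export
fit_rate_function <- function(surface, M = 2,
                              transform = c("sqrt", "identity"),
                              fix = list()) {
  stopifnot(all(c("gE", "gI", "rate") %in% names(surface)))
  transform <- match.arg(transform)
  if (is.null(fix$c_I) && stats::var(surface$gI) == 0) fix$c_I <- 0
  start <- list(r_max = max(surface$rate) * 1.2 + 1e-3,
                theta = stats::quantile(surface$gE, 0.25)[[1]],
                h = diff(range(surface$gE)) / 3, c_I = 0.5)
  lower <- c(r_max = 1e-4, theta = -20, h = 0.1, c_I = 0)
  upper <- c(r_max = 10, theta = 30, h = 100, c_I = 5)
  free <- setdiff(names(start), names(fix))
  env <- c(fix, list(M = M))
  rhs_terms <- "r_max * pmax(gE - c_I * gI - theta, 0)^M /
      (h^M + pmax(gE - c_I * gI - theta, 0)^M)"
  form <- if (transform == "sqrt")
    stats::as.formula(paste("sqrt(rate) ~ sqrt(", rhs_terms, ")"))
  else stats::as.formula(paste("rate ~", rhs_terms))
  dat <- surface
  for (nm in names(env)) dat[[nm]] <- env[[nm]]
  fit <- try(minpack.lm::nlsLM(
    form, data = dat, start = start[free],
    lower = lower[free], upper = upper[free],
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("transfer-function fit failed: ", attr(fit, "condition")$message)
  p <- c(as.list(coef(fit)), fix)
  p$M <- M
  p$rms <- sqrt(mean((surface$rate -
    naka_rushton(surface$gE, surface$gI, p))^2))
  p
}

#' Conductance-rate samples from spiking-network trials
#'
#' Reconstructs, for every population and recorded time point, the exact
#' population-mean excitatory and inhibitory conductances (from the recorded
#' mean synaptic activities, the summed connection weights, bias and
#' stimulus) together with the population firing rate.  These in-operation
#' pairs are what the mean-field transfer function must reproduce: they
#' include the synaptic bombardment and partial synchrony of the recurrent
#' network that a constant-conductance clamp cannot supply.  Only
#' quasi-stationary samples are kept (conductance drift below `drift_tol`
#' over the preceding 100 ms, at `stride_ms` spacing, after `settle_ms`).
#'
#' @param trials list of `stp_trial` objects (ideally spanning rest, goal and
#'   action regimes, both goals).
#' @param stride_ms sample spacing (ms).
#' @param settle_ms initial transient to drop (ms).
#' @param drift_tol maximal conductance change (nS) over 100 ms.
#' @return list of two data frames (`exc`, `inh`) with columns `gE`, `gI`,
#'   `rate` (kHz), suitable for [fit_rate_function()].
#' @export
network_rate_samples <- function(trials, stride_ms = 40, settle_ms = 300,
                                 drift_tol = 0.15) {
  if (inherits(trials, "stp_trial")) trials <- list(trials)
  exc <- list(); inh <- list()
  for (tr in trials) {
    cfg <- tr$config
    cn <- cfg$connections
    nt <- length(tr$time)
    gE <- matrix(0, nt, 5, dimnames = list(NULL, POPS))
    gI <- matrix(0, nt, 5, dimnames = list(NULL, POPS))
    for (p in POPS) gE[, p] <- cfg$populations[[p]]$bias
    gE[, POPS[1:4]] <- gE[, POPS[1:4]] + tr$stimulus[, POPS[1:4]]
    for (i in seq_len(nrow(cn))) {
      s <- switch(cn$kind[i],
                  facilitation = tr$sF[, cn$pre[i]],
                  depression   = tr$sD[, cn$pre[i]],
                  constant     = tr$sC[, cn$pre[i]],
                  inhibitory   = tr$sC[, cn$pre[i]])
      if (cn$kind[i] == "inhibitory")
        gI[, cn$post[i]] <- gI[, cn$post[i]] + cn$weight[i] * s
      else gE[, cn$post[i]] <- gE[, cn$post[i]] + cn$weight[i] * s
    }
    bin <- tr$time[2] - tr$time[1]
    lag <- max(1L, round(100 / bin))
    idx <- seq(max(lag + 1, round(settle_ms / bin)), nt,
               by = max(1L, round(stride_ms / bin)))
    for (p in POPS) {
      keep <- idx[abs(gE[idx, p] - gE[idx - lag, p]) +
                  abs(gI[idx, p] - gI[idx - lag, p]) < drift_tol]
      d <- data.frame(gE = gE[keep, p], gI = gI[keep, p],
                      rate = tr$rates[keep, p] / 1000)
      if (p == "IN") inh[[length(inh) + 1]] <- d
      else exc[[length(exc) + 1]] <- d
    }
  }
  list(exc = do.call(rbind, exc), inh = do.call(rbind, inh))
}

#' Calibrate the mean-field transfer functions against the spiking network
#'
#' The full calibration pipeline: run a small set of full-size spiking trials
#' spanning the network's regimes (both goals, a no-activation resting trial,
#' a stronger-activation trial), collect in-operation conductance-rate
#' samples with [network_rate_samples()], censor rates below `rate_floor`
#' to zero (the reduction treats sparse noise-driven firing as quiescence --
#' the hard-threshold Naka-Rushton family cannot represent the subthreshold
#' tail, and absorbing it into the suprathreshold branch misplaces the
#' threshold that the attractor structure depends on), and fit each cell
#' class with [fit_rate_function()], holding the asymptote `r_max` at the
#' value from a clamped-pool surface fit where it is identifiable.
#'
#' [default_rate_params()] stores the result of this pipeline at the default
#' configuration; rerunning reproduces it up to sampling noise.
#'
#' @param config an `stp_config` (full size recommended).
#' @param seed master seed for the calibration trials.
#' @param rate_floor quiescence floor (kHz).
#' @param r_max fixed asymptotes (kHz) for the two classes.
#' @return list with elements `exc` and `inh` for [naka_rushton()].
#' @export
calibrate_rate_params <- function(config, seed = 1L, rate_floor = 0.003,
                                  r_max = c(exc = 0.09526, inh = 0.22744)) {
  mk <- function(goal, act, s) {
    cf <- config
    cf$protocol$sensory_target <- goal
    cf$protocol$activation_amplitude <- act
    run_trial(cf, seed = s)
  }
  a0 <- config$protocol$activation_amplitude
  trials <- list(mk("G1", a0, seed), mk("G2", a0, seed + 1),
                 mk("G1", 0, seed + 2), mk("G1", a0 + 0.1, seed + 3))
  ns <- network_rate_samples(trials)
  ns$exc$rate[ns$exc$rate < rate_floor] <- 0
  ns$inh$rate[ns$inh$rate < rate_floor] <- 0
  list(exc = fit_rate_function(ns$exc, fix = list(r_max = r_max[["exc"]])),
       inh = fit_rate_function(ns$inh, fix = list(r_max = r_max[["inh"]])))
}

#' Default transfer-function parameters
#'
#' Naka-Rushton parameters for the excitatory and inhibitory cell classes at
#' the default configuration and noise amplitude, produced by
#' [calibrate_rate_params()]: operating-range parameters (`theta`, `h`,
#' `c_I`) fitted to in-network conductance-rate samples, asymptote `r_max`
#' from a clamped-pool surface fit ([sample_rate_surface()]).  See the
#' methods vignette.
#'
#' @return list with elements `exc` and `inh`, each a parameter list for
#'   [naka_rushton()].
#' @export
default_rate_params <- function() {
  list(
    exc = list(r_max = 0.09526, theta = 8.59842, h = 2.32814, c_I = 0.42316,
               M = 2),
    inh = list(r_max = 0.22744, theta = 4.81724, h = 1.78647, c_I = 0,
               M = 2))
}

# Mean-field state layout: s_A..s_D (constant-kind synaptic activity of the
# four excitatory populations), uF/xF/uD/xD per population, s_IN.
MF_STATE <- c(paste0("s_", POPS[1:4]),
              paste0("uF_", POPS[1:4]), paste0("xF_", POPS[1:4]),
              paste0("uD_", POPS[1:4]), paste0("xD_", POPS[1:4]), "s_IN")

mf_connections <- function(config) {
  cn <- config$connections
  if (config$variant == "all_types")
    cn$weight[cn$role == "goal"] <- config$meanfield$goal_weight
  cn
}

# Precompiled numeric view of the mean-field network: 5 x 4 weight matrices
# per synapse kind mapping excitatory population activities to conductances,
# plus the interneuron weights and biases.  Plastic synapses release with
# peak u*x (constant: 1), so their mean activity is the constant-synapse
# occupancy s scaled by u*x -- matching the spiking model, where one summed
# weight multiplies synaptic activities whose peaks differ by kind.
mf_compile <- function(config, rate_params) {
  cn <- mf_connections(config)
  WC <- WF <- WD <- matrix(0, 5, 4, dimnames = list(POPS, POPS[1:4]))
  wI <- setNames(numeric(5), POPS)
  for (i in seq_len(nrow(cn))) {
    if (cn$kind[i] == "inhibitory") {
      wI[cn$post[i]] <- wI[cn$post[i]] + cn$weight[i]
    } else {
      M <- switch(cn$kind[i], constant = "WC", facilitation = "WF",
                  depression = "WD")
      m <- get(M); m[cn$post[i], cn$pre[i]] <- m[cn$post[i], cn$pre[i]] +
        cn$weight[i]
      assign(M, m)
    }
  }
  list(WC = WC, WF = WF, WD = WD, wI = wI,
       bias = vapply(config$populations, `[[`, 0, "bias"),
       pe = rate_params$exc, pi = rate_params$inh)
}

# Population rates (kHz) from numeric state components.
mf_rates_num <- function(cmp, s4, sIN, uF, xF, uD, xD, gext) {
  gE <- cmp$bias + gext +
    as.numeric(cmp$WC %*% s4 + cmp$WF %*% (s4 * uF * xF) +
               cmp$WD %*% (s4 * uD * xD))
  gI <- cmp$wI * sIN
  c(naka_rushton(gE[1:4], gI[1:4], cmp$pe),
    naka_rushton(gE[5], gI[5], cmp$pi))
}

# Population rates (kHz) given a named state list; thin wrapper kept for the
# documented list-based interface.
mf_rates <- function(state, gextE, config, rate_params,
                     cn = NULL, cmp = NULL) {
  if (is.null(cmp)) cmp <- mf_compile(config, rate_params)
  s4 <- unlist(state[paste0("s_", POPS[1:4])], use.names = FALSE)
  setNames(mf_rates_num(cmp, s4, state[["s_IN"]],
    unlist(state[paste0("uF_", POPS[1:4])], use.names = FALSE),
    unlist(state[paste0("xF_", POPS[1:4])], use.names = FALSE),
    unlist(state[paste0("uD_", POPS[1:4])], use.names = FALSE),
    unlist(state[paste0("xD_", POPS[1:4])], use.names = FALSE),
    gext = unname(gextE[POPS])), POPS)
}

s_inf <- function(r, tau) r * tau / (1 + r * tau)

#' Mean-field right-hand side
#'
#' Time derivatives of the mean-field state: constant-synapse activities relax
#' toward their stationary value `r*tau_s/(1 + r*tau_s)` with `tau_s`;
#' utilization and resources follow the rate-driven Tsodyks-Markram mean
#' dynamics `du/dt = (U-u)/tau_u + U(1-u) r`, `dx/dt = (1-x)/tau_x - u x r`;
#' the interneuron channel is analogous with the inhibitory `tau_s`.  Rates
#' are algebraic functions of the state via the fitted transfer functions.
#'
#' @param t time (ms).
#' @param state named numeric vector in the `MF_STATE` layout.
#' @param config an `stp_config`.
#' @param rate_params transfer-function parameters ([default_rate_params()]).
#' @param gextE named external excitatory conductance per population (nS).
#' @param cmp precompiled network view (internal; built when omitted).
#' @return list of derivatives (deSolve convention) in the `MF_STATE`
#'   layout, with rates (kHz) as a second element.
#' @export
mean_field_rhs <- function(t, state, config, rate_params,
                           gextE = setNames(numeric(5), POPS), cmp = NULL) {
  if (is.null(cmp)) cmp <- mf_compile(config, rate_params)
  pl <- config$plasticity
  U <- pl$U
  if (is.list(state)) state <- unlist(state)
  if (!is.null(names(state)) && all(MF_STATE %in% names(state)))
    state <- state[MF_STATE]
  state <- as.numeric(state)
  s4 <- state[1:4]; uF <- state[5:8]; xF <- state[9:12]
  uD <- state[13:16]; xD <- state[17:20]; sIN <- state[21]
  r <- mf_rates_num(cmp, s4, sIN, uF, xF, uD, xD, unname(gextE[POPS]))
  re <- r[1:4]
  d <- c((s_inf(re, pl$tau_s_exc) - s4) / pl$tau_s_exc,
         (U - uF) / pl$facilitation$tau_u + U * (1 - uF) * re,
         (1 - xF) / pl$facilitation$tau_x - uF * xF * re,
         (U - uD) / pl$depression$tau_u + U * (1 - uD) * re,
         (1 - xD) / pl$depression$tau_x - uD * xD * re,
         (s_inf(r[5], pl$tau_s_inh) - sIN) / pl$tau_s_inh)
  names(d) <- MF_STATE
  list(d, rates = setNames(r, POPS))
}

mf_rest_state <- function(config) {
  U <- config$plasticity$U
  setNames(c(rep(0, 4), rep(U, 4), rep(1, 4), rep(U, 4), rep(1, 4), 0),
           MF_STATE)
}

mf_stimulus_fun <- function(config, symmetry_breaking = TRUE) {
  pr <- config$protocol
  pamp <- pr$perturbation_amplitude
  ponset <- pr$perturbation_onset
  pwidth <- pr$perturbation_width
  ptarget <- pr$perturbation_target
  if (pamp == 0 && symmetry_breaking) {
    pamp <- config$meanfield$perturbation_amplitude
    pwidth <- config$meanfield$perturbation_width
    ponset <- pr$goal_display_onset
    ptarget <- config$meanfield$perturbation_target %||% ptarget
  }
  force(pr)
  function(t) {
    g <- setNames(numeric(5), POPS)
    ramp <- pr$activation_amplitude *
      min(1, max(0, (t - pr$goal_display_onset) / pr$activation_ramp))
    g[POPS[1:4]] <- ramp
    if (t >= pr$goal_display_onset && t < pr$goal_display_onset + pr$sensory_width)
      g[GOAL_ASSEMBLY[[pr$sensory_target]]] <-
        g[GOAL_ASSEMBLY[[pr$sensory_target]]] + pr$sensory_amplitude
    if (pamp > 0 && t >= ponset && t < ponset + pwidth)
      g[ACTION_ASSEMBLY[[ptarget]]] <- g[ACTION_ASSEMBLY[[ptarget]]] + pamp
    g
  }
}

#' Simulate the mean-field model
#'
#' Integrates the deterministic mean-field reduction over one trial with the
#' configured stimulus protocol.  Because the model is noise-free, a perfectly
#' symmetric network would sit on the saddle between the two action states
#' forever; by default a small rectangular symmetry-breaking input (amplitude
#' `config$meanfield$perturbation_amplitude`, default 0.01 nS for 200 ms) is
#' applied to one action assembly at goal-display onset.  For the `all_types`
#' variant the goal-assembly summed weight is replaced by
#' `config$meanfield$goal_weight` (default 1.9 nS), compensating for the
#' fluctuation-assisted earlier transition of the spiking network.
#'
#' @param config an `stp_config`.
#' @param rate_params transfer-function parameters.
#' @param dt_out output grid step (ms).
#' @param symmetry_breaking apply the small action-side perturbation when the
#'   protocol itself has none.
#' @param freeze_plasticity clamp utilization and resources at rest (fixed
#'   synapses, the no-plasticity control).
#' @param rtol,atol integration tolerances (lsoda, applied piecewise between
#'   stimulus breakpoints).
#' @return an object of class `stp_meanfield`: `time` (ms), `rates` (Hz,
#'   time x population), `readout` (A1/A2, Hz), state matrices `s`, `uF`,
#'   `xF`, `uD`, `xD` (time x population), `s_IN`, `stimulus`, `efficacy`
#'   (nS per assembly), plus config and fit parameters.
#' @export
simulate_mean_field <- function(config, rate_params = default_rate_params(),
                                dt_out = 1, symmetry_breaking = TRUE,
                                freeze_plasticity = FALSE,
                                rtol = 1e-8, atol = 1e-10) {
  validate_config(config)
  pr <- config$protocol
  stim <- mf_stimulus_fun(config, symmetry_breaking)
  cn <- mf_connections(config)
  cmp <- mf_compile(config, rate_params)
  slow_idx <- grep("^[ux][FD]_", MF_STATE)
  rhs <- function(t, y, parms) {
    out <- mean_field_rhs(t, y, config, rate_params, stim(t), cmp = cmp)
    if (freeze_plasticity) out[[1]][slow_idx] <- 0
    list(out[[1]])
  }
  breaks <- sort(unique(c(0, pr$goal_display_onset,
                          pr$goal_display_onset + pr$sensory_width,
                          pr$goal_display_onset + pr$activation_ramp,
                          pr$perturbation_onset,
                          pr$perturbation_onset + pr$perturbation_width,
                          pr$goal_display_onset + config$meanfield$perturbation_width,
                          pr$trial_duration)))
  breaks <- breaks[breaks >= 0 & breaks <= pr$trial_duration]
  y <- mf_rest_state(config)
  pieces <- list()
  for (i in seq_len(length(breaks) - 1)) {
    times <- seq(breaks[i], breaks[i + 1], by = dt_out)
    if (tail(times, 1) < breaks[i + 1]) times <- c(times, breaks[i + 1])
    sol <- deSolve::ode(y = y, times = times, func = rhs, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    y <- sol[nrow(sol), -1]
    pieces[[i]] <- sol[-nrow(sol), , drop = FALSE]
  }
  sol <- rbind(do.call(rbind, pieces),
               c(tail(breaks, 1), y))
  time <- sol[, 1]
  states <- sol[, -1, drop = FALSE]
  colnames(states) <- MF_STATE
  rates <- matrix(0, length(time), 5)
  for (i in seq_along(time))
    rates[i, ] <- mf_rates_num(cmp, states[i, 1:4], states[i, 21],
                               states[i, 5:8], states[i, 9:12],
                               states[i, 13:16], states[i, 17:20],
                               unname(stim(time[i])[POPS]))
  colnames(rates) <- POPS
  rates_hz <- rates * 1000
  pick <- function(prefix) {
    m <- states[, paste0(prefix, "_", POPS[1:4]), drop = FALSE]
    colnames(m) <- POPS[1:4]
    m
  }
  rec <- list(uxF = pick("uF") * pick("xF"), uxD = pick("uD") * pick("xD"))
  structure(list(
    time = time, rates = rates_hz,
    readout = cbind(A1 = rates_hz[, "A"] + rates_hz[, "D"],
                    A2 = rates_hz[, "B"] + rates_hz[, "C"]),
    s = pick("s"), uF = pick("uF"), xF = pick("xF"),
    uD = pick("uD"), xD = pick("xD"), s_IN = states[, "s_IN"],
    uxF = rec$uxF, uxD = rec$uxD,
    efficacy = assembly_efficacy_trace(mf_efficacy_config(config), rec),
    stimulus = t(vapply(time, stim, numeric(5))),
    states = states,
    config = config, rate_params = rate_params,
    freeze_plasticity = freeze_plasticity,
    symmetry_breaking = symmetry_breaking), class = "stp_meanfield")
}

# config clone whose connection weights reflect the mean-field adjustment, so
# efficacy traces use the weights the mean-field run actually used
mf_efficacy_config <- function(config) {
  config$connections <- mf_connections(config)
  config
}

#' @export
print.stp_meanfield <- function(x, ...) {
  cat("stp_meanfield:", x$config$variant, "goal",
      x$config$protocol$sensory_target, "-", length(x$time), "time points\n")
  invisible(x)
}
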