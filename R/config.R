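#' Default neuron parameters
#'
#' Conductance-based leaky integrate-and-fire parameters for the excitatory
#' (pyramidal) and inhibitory (interneuron) cell classes.  Threshold, reset and
#' reversal potentials are shared; capacitance, leak, resting potential and
#' refractory period differ per class.
#'
#' @param excitatory logical; `TRUE` for the excitatory class.
#' @return named list with elements `Cm` (nF), `gL` (nS), `VL`, `Vth`,
#'   `Vreset`, `VE`, `VI` (mV), `tref` (ms).
#' @export
neuron_params <- function(excitatory = TRUE) {
  base <- list(Vth = -52, Vreset = -60, VE = -5, VI = -75)
  if (excitatory) {
    c(base, list(Cm = 0.5, gL = 25, VL = -70, tref = 2))
  } else {
    c(base, list(Cm = 0.2, gL = 20, VL = -65, tref = 1))
  }
}

#' Default short-term plasticity parameters
#'
#' Both plastic synapse kinds share the resting utilization `U`; they differ in
#' the recovery-time constants.  Depressing synapses recover utilization
#' quickly (`tau_u` = 20 ms) but resources slowly (`tau_x` = 600 ms), so
#' repeated firing depletes them; facilitating synapses hold elevated
#' utilization for long (`tau_u` = 600 ms) while resources recover fast
#' (`tau_x` = 100 ms), so moderate firing potentiates them.  `tau_s_exc` is the
#' slow (NMDA-like) excitatory synaptic decay, `tau_s_inh` the inhibitory one.
#'
#' @return named list: `U`, `facilitation` (`tau_u`, `tau_x` in ms),
#'   `depression` (`tau_u`, `tau_x`), `tau_s_exc`, `tau_s_inh` (ms).
#' @export
plasticity_params <- function() {
  list(U = 0.2,
       facilitation = list(tau_u = 600, tau_x = 100),
       depression   = list(tau_u = 20,  tau_x = 600),
       tau_s_exc = 100, tau_s_inh = 20)
}

#' Default stimulus protocol
#'
#' The trial timeline: the goal display comes on at `goal_display_onset`; from
#' that moment a common activation conductance ramps linearly from 0 to
#' `activation_amplitude` over `activation_ramp` ms on all four excitatory
#' populations and then persists; simultaneously a rectangular sensory pulse of
#' `sensory_amplitude` and `sensory_width` is applied to the assembly of the
#' displayed goal (`G1` targets A and B, `G2` targets C and D).  An optional
#' rectangular perturbation pulse can be applied to one action assembly (`A1`
#' targets A and D, `A2` targets B and C).  `go_time` is the nominal
#' movement-initiation cue used only by analysis summaries.
#'
#' @param goal character, `"G1"` or `"G2"`.
#' @return named list of protocol fields (amplitudes in nS, times in ms).
#' @export
stimulus_protocol <- function(goal = "G1") {
  list(activation_amplitude = 0.35, activation_ramp = 200,
       sensory_amplitude = 0.2, sensory_width = 200, sensory_target = goal,
       perturbation_amplitude = 0, perturbation_onset = 0,
       perturbation_width = 200, perturbation_target = "A1",
       goal_display_onset = 500, trial_duration = 4000, go_time = 3000)
}

POPS <- c("A", "B", "C", "D", "IN")
GOAL_ASSEMBLY <- list(G1 = c("A", "B"), G2 = c("C", "D"))
ACTION_ASSEMBLY <- list(A1 = c("A", "D"), A2 = c("B", "C"))
ASSEMBLIES <- list(AB = c("A", "B"), CD = c("C", "D"),
                   AD = c("A", "D"), BC = c("B", "C"))

variant_weight_table <- function(variant) {
  switch(variant,
    all_types = list(goal = c(3.2, "depression"), action = c(1.55, "facilitation"),
                     self = c(1.7, "constant"), e_to_in = c(0.7, "constant"),
                     in_to_e = c(5, "inhibitory")),
    depression_only = list(goal = c(3, "depression"), action = c(0.5, "constant"),
                           self = c(1.8, "constant"), e_to_in = c(0.7, "constant"),
                           in_to_e = c(5.5, "inhibitory")),
    facilitation_only = list(goal = c(0.8, "constant"), action = c(3.1, "facilitation"),
                             self = c(1.9, "constant"), e_to_in = c(0.7, "constant"),
                             in_to_e = c(7.5, "inhibitory")),
    stop("unknown variant: ", variant))
}

connection_table <- function(variant) {
  wt <- variant_weight_table(variant)
  pair <- function(role, pairs) {
    w <- as.numeric(wt[[role]][1]); kind <- wt[[role]][2]
    data.frame(pre = pairs[, 1], post = pairs[, 2], kind = kind,
               weight = w, role = role, stringsAsFactors = FALSE)
  }
  rbind(
    pair("goal", rbind(c("A", "B"), c("B", "A"), c("C", "D"), c("D", "C"))),
    pair("action", rbind(c("A", "D"), c("D", "A"), c("B", "C"), c("C", "B"))),
    pair("self", cbind(POPS[1:4], POPS[1:4])),
    pair("e_to_in", cbind(POPS[1:4], rep("IN", 4))),
    pair("in_to_e", cbind(rep("IN", 4), POPS[1:4])))
}

#' Build a network configuration
#'
#' Assembles the full parameterization of one of the three network variants:
#' `all_types` (depressing goal synapses, facilitating action synapses,
#' constant self/inhibitory synapses), `depression_only` and
#' `facilitation_only`.  Defaults reproduce the reference parameter set; any
#' field can be overridden afterwards and re-checked with [validate_config()].
#'
#' @param variant one of `"all_types"`, `"depression_only"`,
#'   `"facilitation_only"`.
#' @param N neurons per population (default 200; the inhibitory pool has the
#'   same size).
#' @param goal which goal the sensory input targets (`"G1"` or `"G2"`).
#' @param noise_sigma membrane noise amplitude in mV/sqrt(ms); each integration
#'   step adds a normal deviate of standard deviation `noise_sigma*sqrt(dt)` to
#'   V.  The default is calibrated so that the resting excitatory population
#'   fires below 1 Hz and the goal-to-action transition occurs on the order of
#'   a second after goal activation.
#' @param seed integer seed used for network construction.
#' @return an object of class `stp_config`.
#' @examples
#' cfg <- network_config("all_types", N = 50)
#' cfg$connections[cfg$connections$role == "goal", "weight"]
#' @export
network_config <- function(variant = c("all_types", "depression_only",
                                       "facilitation_only"),
                           N = 200, goal = "G1", noise_sigma = 0.17, seed = 1L) {
  variant <- match.arg(variant)
  pops <- list()
  for (p in POPS) {
    exc <- p != "IN"
    pops[[p]] <- list(size = N, excitatory = exc,
                      neuron = neuron_params(exc),
                      bias = if (exc) 8.35 else 4)
  }
  cfg <- structure(list(
    variant = variant,
    populations = pops,
    connections = cbind(connection_table(variant),
                        c_ratio = 0.2, delay_min = 1, delay_max = 5),
    plasticity = plasticity_params(),
    protocol = stimulus_protocol(goal),
    noise_sigma = noise_sigma,
    dt = 0.1,
    meanfield = list(goal_weight = 1.9, perturbation_amplitude = 0.01,
                     perturbation_width = 200),
    seed = as.integer(seed)), class = "stp_config")
  validate_config(cfg)
}

#' Validate a network configuration
#'
#' Checks every structural invariant of an `stp_config`: population labels,
#' positivity of capacitances, conductances and time constants, reset below
#' threshold, nonnegative refractory period and stimulus amplitudes, bounds on
#' the utilization constant and connectivity ratio, delay ranges, and that
#' every connection references declared populations.  Errors name the
#' offending field path.
#'
#' @param config an `stp_config`.
#' @return the config, invisibly unchanged, if valid.
#' @export
validate_config <- function(config) {
  fail <- function(path, msg) stop("invalid config: ", path, " ", msg, call. = FALSE)
  if (!inherits(config, "stp_config")) fail("<object>", "is not an stp_config")
  if (!all(POPS %in% names(config$populations)))
    fail("populations", paste("must include", paste(POPS, collapse = ", ")))
  for (p in names(config$populations)) {
    pp <- config$populations[[p]]
    np <- pp$neuron
    at <- function(f) paste0("populations$", p, "$neuron$", f)
    if (pp$size < 1) fail(paste0("populations$", p, "$size"), "must be >= 1")
    if (np$Cm <= 0) fail(at("Cm"), "must be > 0")
    if (np$gL <= 0) fail(at("gL"), "must be > 0")
    if (np$tref < 0) fail(at("tref"), "refractory must be >= 0")
    if (np$Vreset >= np$Vth) fail(at("Vreset"), "reset must be below threshold")
    if (pp$bias < 0) fail(paste0("populations$", p, "$bias"), "must be >= 0")
  }
  pl <- config$plasticity
  if (pl$U <= 0 || pl$U > 1) fail("plasticity$U", "must be in (0, 1]")
  taus <- c(facilitation_tau_u = pl$facilitation$tau_u,
            facilitation_tau_x = pl$facilitation$tau_x,
            depression_tau_u = pl$depression$tau_u,
            depression_tau_x = pl$depression$tau_x,
            tau_s_exc = pl$tau_s_exc, tau_s_inh = pl$tau_s_inh)
  for (nm in names(taus)) if (!is.finite(taus[[nm]]) || taus[[nm]] <= 0)
    fail(paste0("plasticity$", nm), "time constant must be > 0")
  cn <- config$connections
  for (i in seq_len(nrow(cn))) {
    at <- function(f) paste0("connections[", i, "]$", f)
    if (!cn$pre[i] %in% POPS) fail(at("pre"), "references undeclared population")
    if (!cn$post[i] %in% POPS) fail(at("post"), "references undeclared population")
    if (!cn$kind[i] %in% c("facilitation", "depression", "constant", "inhibitory"))
      fail(at("kind"), "unknown synapse kind")
    if (cn$weight[i] < 0) fail(at("weight"), "summed weight must be >= 0")
    if (cn$c_ratio[i] <= 0 || cn$c_ratio[i] > 1) fail(at("c_ratio"), "must be in (0, 1]")
    if (cn$delay_min[i] < config$dt) fail(at("delay_min"), "below one integration step")
    if (cn$delay_max[i] < cn$delay_min[i]) fail(at("delay_max"), "below delay_min")
    if (cn$delay_max[i] > config$protocol$trial_duration)
      fail(at("delay_max"), "exceeds trial duration")
  }
  expected <- connection_table(config$variant)
  got <- config$connections[, c("pre", "post", "kind")]
  if (!identical(got$kind[match(paste(expected$pre, expected$post),
                                paste(got$pre, got$post))], expected$kind))
    fail("connections$kind", paste("does not match the", config$variant, "variant table"))
  pr <- config$protocol
  for (f in c("activation_amplitude", "sensory_amplitude", "perturbation_amplitude"))
    if (pr[[f]] < 0) fail(paste0("protocol$", f), "must be >= 0")
  for (f in c("activation_ramp", "sensory_width", "perturbation_width",
              "perturbation_onset", "goal_display_onset"))
    if (pr[[f]] < 0 || pr[[f]] > pr$trial_duration)
      fail(paste0("protocol$", f), "must be within [0, trial_duration]")
  if (!pr$sensory_target %in% c("G1", "G2"))
    fail("protocol$sensory_target", "must be G1 or G2")
  if (!pr$perturbation_target %in% c("A1", "A2"))
    fail("protocol$perturbation_target", "must be A1 or A2")
  if (config$noise_sigma < 0) fail("noise_sigma", "must be >= 0")
  invisible(config)
}

#' @export
print.stp_config <- function(x, ...) {
  cat("stp_config:", x$variant, "\n")
  cat("  populations:", paste(sprintf("%s(%d)", names(x$populations),
      vapply(x$populations, function(p) as.integer(p$size), integer(1))),
      collapse = " "), "\n")
  cat("  goal:", x$protocol$sensory_target,
      " trial:", x$protocol$trial_duration, "ms\n")
  w <- x$connections[!duplicated(x$connections$role), c("role", "weight", "kind")]
  cat("  weights:", paste(sprintf("%s=%g(%s)", w$role, w$weight,
      substr(w$kind, 1, 1)), collapse = " "), "\n")
  invisible(x)
}

#' Read / write a configuration as YAML
#'
#' Round-trips an `stp_config` through the documented key tree.  The canonical
#' files for the three variants ship under `inst/extdata/` as
#' `variant_all.yaml`, `variant_dep.yaml` and `variant_fac.yaml`.
#'
#' @param path file path.
#' @param config an `stp_config`.
#' @return `read_config` returns a validated `stp_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- network_config(variant = raw$variant,
                        N = raw$populations$A$size %||% 200,
                        goal = raw$protocol$sensory_target %||% "G1",
                        noise_sigma = raw$noise_sigma %||% 0.17,
                        seed = raw$seed %||% 1L)
  for (nm in intersect(names(raw$protocol), names(cfg$protocol)))
    cfg$protocol[[nm]] <- raw$protocol[[nm]]
  if (!is.null(raw$connections))
    for (i in seq_along(raw$connections)) {
      rc <- raw$connections[[i]]
      j <- which(cfg$connections$pre == rc$pre & cfg$connections$post == rc$post)
      if (!length(j)) stop("config file names unknown connection ", rc$pre, "->", rc$post)
      cfg$connections$weight[j] <- rc$weight
      cfg$connections$kind[j] <- rc$kind
    }
  if (!is.null(raw$plasticity))
    cfg$plasticity <- modifyList(cfg$plasticity, raw$plasticity)
  if (!is.null(raw$meanfield))
    cfg$meanfield <- modifyList(cfg$meanfield, raw$meanfield)
  validate_config(cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  cn <- config$connections
  conns <- lapply(seq_len(nrow(cn)), function(i)
    list(pre = cn$pre[i], post = cn$post[i], kind = cn$kind[i],
         weight = cn$weight[i]))
  yaml::write_yaml(list(
    variant = config$variant,
    seed = config$seed,
    noise_sigma = config$noise_sigma,
    populations = lapply(config$populations, function(p)
      list(size = p$size, bias = p$bias, excitatory = p$excitatory)),
    connections = conns,
    plasticity = config$plasticity,
    protocol = config$protocol,
    meanfield = config$meanfield), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
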