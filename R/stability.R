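#' Frozen slow state
#'
#' Packs the slow plasticity variables (mean utilization and resources per
#' population and plastic kind) into the named layout used by the fast
#' subsystem.  With no arguments returns the resting slow state (u = U,
#' x = 1).
#'
#' @param uF,xF,uD,xD numeric vectors of length 4 (populations A--D).
#' @param U resting utilization (used for defaults).
#' @return named numeric vector of the 16 frozen components.
#' @export
frozen_slow_state <- function(uF = rep(U, 4), xF = rep(1, 4),
                              uD = rep(U, 4), xD = rep(1, 4), U = 0.2) {
  setNames(c(uF, xF, uD, xD),
           c(paste0("uF_", POPS[1:4]), paste0("xF_", POPS[1:4]),
             paste0("uD_", POPS[1:4]), paste0("xD_", POPS[1:4])))
}

# Right-hand side of the fast subsystem: the five synaptic-activity components
# (four excitatory populations + interneuron pool) with the slow plasticity
# variables and the external stimulus frozen.  `frozen` follows the
# frozen_slow_state() layout (uF, xF, uD, xD blocks of four); `cmp` is the
# precompiled network view.
fast_rhs <- function(s5, frozen, config, rate_params,
                     gextE = setNames(numeric(5), POPS),
                     cmp = mf_compile(config, rate_params)) {
  pl <- config$plasticity
  r <- mf_rates_num(cmp, s5[1:4], s5[[5]], frozen[1:4], frozen[5:8],
                    frozen[9:12], frozen[13:16], unname(gextE[POPS]))
  c((s_inf(r[1:4], pl$tau_s_exc) - s5[1:4]) / pl$tau_s_exc,
    (s_inf(r[5], pl$tau_s_inh) - s5[5]) / pl$tau_s_inh)
}

fast_jacobian <- function(s5, frozen, config, rate_params, gextE, cmp,
                          h = 1e-6) {
  J <- matrix(0, 5, 5)
  for (j in 1:5) {
    up <- dn <- s5
    up[j] <- up[j] + h; dn[j] <- dn[j] - h
    J[, j] <- (fast_rhs(up, frozen, config, rate_params, gextE, cmp) -
               fast_rhs(dn, frozen, config, rate_params, gextE, cmp)) / (2 * h)
  }
  J
}

#' Find equilibria of the fast synaptic-activity subsystem
#'
#' With the slow plasticity variables (and the stimulus) frozen, runs
#' Newton-Raphson on the five-dimensional fast vector field from a
#' deterministic seed grid -- every on/off combination of the four excitatory
#' populations crossed with a low/high interneuron guess (32 seeds; "on" is
#' the stationary activity at half the maximal rate).  Converged roots are
#' deduplicated (max-norm tolerance `dedup_tol`) and classified by the
#' eigenvalues of the finite-difference Jacobian: stable if every real part is
#' below `-margin`, marginal if any real part lies within `margin` of zero.
#'
#' @param frozen frozen slow state from [frozen_slow_state()] (default: rest).
#' @param config an `stp_config`.
#' @param rate_params transfer-function parameters.
#' @param gextE frozen external excitatory conductance per population (nS).
#' @param tol Newton convergence tolerance on the residual max-norm.
#' @param dedup_tol deduplication tolerance (max-norm on the root).
#' @param margin eigenvalue stability margin.
#' @param max_iter Newton iteration cap; non-converging seeds are skipped.
#' @return an object of class `stp_equilibria`: a list of records, each with
#'   `location` (named 5-vector), `eigenvalues`, `stable`, `marginal`,
#'   `residual` and `seed` (index of the seed that found it).
#' @export
find_equilibria <- function(frozen = frozen_slow_state(U = config$plasticity$U),
                            config, rate_params = default_rate_params(),
                            gextE = setNames(numeric(5), POPS),
                            tol = 1e-10, dedup_tol = 1e-6, margin = 1e-9,
                            max_iter = 100) {
  cmp <- mf_compile(config, rate_params)
  pl <- config$plasticity
  s_on_E <- s_inf(rate_params$exc$r_max / 2, pl$tau_s_exc)
  s_on_I <- s_inf(rate_params$inh$r_max / 2, pl$tau_s_inh)
  seeds <- as.matrix(expand.grid(A = c(0, s_on_E), B = c(0, s_on_E),
                                 C = c(0, s_on_E), D = c(0, s_on_E),
                                 IN = c(0, s_on_I)))
  roots <- list()
  for (k in seq_len(nrow(seeds))) {
    s <- seeds[k, ]
    converged <- FALSE
    fnorm <- max(abs(fast_rhs(s, frozen, config, rate_params, gextE, cmp)))
    for (it in seq_len(max_iter)) {
      f <- fast_rhs(s, frozen, config, rate_params, gextE, cmp)
      if (max(abs(f)) < tol) { converged <- TRUE; break }
      J <- fast_jacobian(s, frozen, config, rate_params, gextE, cmp)
      step <- try(solve(J, f), silent = TRUE)
      if (inherits(step, "try-error") || any(!is.finite(step))) break
      if (max(abs(step)) > 0.5) step <- step * 0.5 / max(abs(step))
      # damped update: halve the step while the residual grows
      lambda <- 1
      repeat {
        s_new <- s - lambda * step
        fn_new <- max(abs(fast_rhs(s_new, frozen, config, rate_params,
                                   gextE, cmp)))
        if (fn_new <= fnorm || lambda < 1 / 64) break
        lambda <- lambda / 2
      }
      s <- s_new; fnorm <- fn_new
      if (max(abs(s)) > 10) break
    }
    if (!converged) next
    dup <- any(vapply(roots, function(r)
      max(abs(r$location - s)) < dedup_tol, logical(1)))
    if (dup) next
    J <- fast_jacobian(s, frozen, config, rate_params, gextE, cmp)
    ev <- eigen(J, only.values = TRUE)$values
    roots[[length(roots) + 1]] <- list(
      location = setNames(as.numeric(s), POPS),
      eigenvalues = ev,
      stable = all(Re(ev) < -margin),
      marginal = any(abs(Re(ev)) <= margin),
      residual = max(abs(fast_rhs(s, frozen, config, rate_params, gextE, cmp))),
      seed = k)
  }
  structure(roots, class = "stp_equilibria")
}

#' @export
print.stp_equilibria <- function(x, ...) {
  cat("stp_equilibria:", length(x), "equilibria (",
      sum(vapply(x, `[[`, TRUE, "stable")), "stable )\n")
  invisible(x)
}

#' Population rates at a fast-subsystem state
#'
#' @param s5 fast state (named 5-vector of synaptic activities).
#' @param frozen frozen slow state.
#' @param config,rate_params,gextE as in [find_equilibria()].
#' @return named rates in Hz.
#' @export
equilibrium_rates <- function(s5, frozen, config,
                              rate_params = default_rate_params(),
                              gextE = setNames(numeric(5), POPS)) {
  cmp <- mf_compile(config, rate_params)
  setNames(mf_rates_num(cmp, s5[1:4], s5[[5]], frozen[1:4], frozen[5:8],
                        frozen[9:12], frozen[13:16],
                        unname(gextE[POPS])), POPS) * 1000
}

#' Relaxation check of an equilibrium's stability label
#'
#' Integrates the frozen fast subsystem from the equilibrium displaced by
#' `delta` along each fast coordinate and reports the final distance to the
#' equilibrium: small for a stable fixed point, growing for an unstable one.
#'
#' @param eq one record from [find_equilibria()].
#' @param frozen,config,rate_params,gextE as in [find_equilibria()].
#' @param delta displacement size.
#' @param t_end integration horizon (ms).
#' @param direction optional unit displacement direction (length 5); by
#'   default all coordinates are displaced equally.  For saddles, displacing
#'   along the leading eigenvector guarantees the unstable component is
#'   excited.
#' @return final max-norm distance from the equilibrium.
#' @export
relax_from <- function(eq, frozen, config,
                       rate_params = default_rate_params(),
                       gextE = setNames(numeric(5), POPS),
                       delta = 1e-3, t_end = 1500, direction = NULL) {
  cmp <- mf_compile(config, rate_params)
  rhs <- function(t, y, parms)
    list(fast_rhs(y, frozen, config, rate_params, gextE, cmp))
  if (is.null(direction)) direction <- rep(1, 5)
  direction <- direction / max(abs(direction))
  y0 <- eq$location + delta * direction
  sol <- deSolve::ode(y0, times = c(0, t_end), func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  max(abs(sol[nrow(sol), -1] - eq$location))
}

#' Track the attractor set along a mean-field trajectory
#'
#' At sampled times of a mean-field run, freezes the slow plasticity state and
#' the stimulus at their instantaneous values, finds all equilibria of the
#' fast subsystem and projects them onto the first two principal-component
#' axes of the supplied basis.  This reproduces the temporal evolution of the
#' attractor landscape: initially the resting state plus two goal attractors
#' on the first PC axis; around the switching event the goal attractor is
#' destabilized and two action attractors emerge on the second PC axis.
#'
#' @param mf an `stp_meanfield` run.
#' @param basis a PC basis from [fit_pca()] (fitted on population rates, Hz).
#' @param stride_ms sampling stride along the trajectory (ms).
#' @param rate_params transfer-function parameters (defaults to those of the
#'   run).
#' @return an object of class `stp_attractors`: a data frame with one row per
#'   (time, equilibrium): `time`, `eq`, `PC1`, `PC2`, `stable`, `marginal`,
#'   `lead_re` (largest eigenvalue real part), `residual`, `axis` (`"rest"`,
#'   `"goal"` or `"action"`), and per-population rates (Hz).
#' @export
track_attractors <- function(mf, basis, stride_ms = 50,
                             rate_params = mf$rate_params) {
  stopifnot(inherits(mf, "stp_meanfield"))
  config <- mf$config
  idx <- unique(c(seq(1, length(mf$time), by = max(1L, round(stride_ms /
    (mf$time[2] - mf$time[1])))), length(mf$time)))
  rows <- list()
  for (i in idx) {
    frozen <- frozen_slow_state(uF = mf$uF[i, ], xF = mf$xF[i, ],
                                uD = mf$uD[i, ], xD = mf$xD[i, ])
    gextE <- setNames(mf$stimulus[i, ], POPS)
    eqs <- find_equilibria(frozen, config, rate_params, gextE)
    for (j in seq_along(eqs)) {
      r <- equilibrium_rates(eqs[[j]]$location, frozen, config, rate_params,
                             gextE)
      pc <- project_pc(matrix(r[POPS[1:4]], 1), basis)
      rows[[length(rows) + 1]] <- data.frame(
        time = mf$time[i], eq = j, PC1 = pc[1], PC2 = pc[2],
        stable = eqs[[j]]$stable, marginal = eqs[[j]]$marginal,
        lead_re = max(Re(eqs[[j]]$eigenvalues)),
        residual = eqs[[j]]$residual,
        rA = r[["A"]], rB = r[["B"]], rC = r[["C"]], rD = r[["D"]],
        rIN = r[["IN"]])
    }
  }
  out <- do.call(rbind, rows)
  out$axis <- apply(out[, c("rA", "rB", "rC", "rD")], 1, classify_state)
  class(out) <- c("stp_attractors", "data.frame")
  out
}

# Label a population-rate pattern: resting (all low), a goal assembly
# (A&B or C&D high, the other pair low), an action assembly (A&D or B&C),
# or mixed.  `hi` is the activation threshold in Hz.
classify_state <- function(r, hi = 5) {
  on <- r > hi
  names(on) <- c("A", "B", "C", "D")
  if (!any(on)) return("rest")
  pat <- paste(names(on)[on], collapse = "")
  if (pat %in% c("AB", "CD")) "goal"
  else if (pat %in% c("AD", "BC")) "action"
  else "mixed"
}

#' Count stable attractors per sampled time
#'
#' @param timeline an `stp_attractors` table.
#' @return data frame per time: total stable equilibria and the counts on the
#'   rest/goal/action axes.
#' @export
attractor_counts <- function(timeline) {
  st <- timeline[timeline$stable, ]
  times <- sort(unique(timeline$time))
  data.frame(
    time = times,
    n_stable = vapply(times, function(t) sum(st$time == t), 0L),
    n_rest = vapply(times, function(t) sum(st$time == t & st$axis == "rest"), 0L),
    n_goal = vapply(times, function(t) sum(st$time == t & st$axis == "goal"), 0L),
    n_action = vapply(times, function(t)
      sum(st$time == t & st$axis == "action"), 0L),
    n_mixed = vapply(times, function(t)
      sum(st$time == t & st$axis == "mixed"), 0L))
}
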