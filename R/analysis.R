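# Architectural preference of each excitatory population: membership in a
# goal assembly (A&B = G1, C&D = G2) and an action assembly (A&D = A1,
# B&C = A2).
PREFERENCE <- data.frame(
  pop = c("A", "B", "C", "D"),
  goal = c("G1", "G1", "G2", "G2"),
  action = c("A1", "A2", "A2", "A1"),
  stringsAsFactors = FALSE)

trial_rates <- function(x) {
  if (inherits(x, c("stp_trial", "stp_meanfield"))) x$rates[, POPS[1:4]]
  else as.matrix(x)[, 1:4]
}
trial_time <- function(x) if (is.list(x) && !is.null(x$time)) x$time else
  stop("cannot recover a time grid; pass stp_trial/stp_meanfield objects")

#' Fit a principal-component basis to population-rate trajectories
#'
#' Pools the four excitatory population rates over all supplied trajectories,
#' subtracts the resting-state rates (the mean over the pre-goal-display
#' window, so the resting state projects to the origin), and computes an
#' uncentred PCA.  With a balanced batch the first component separates the two
#' goals and the second the two actions.
#'
#' When `align = TRUE` the first two components are relabeled (and
#' sign-fixed) so that component 1 is the one best aligned with the
#' structural goal contrast (A, B versus C, D; positive toward G1) and
#' component 2 with the action contrast (A, D versus B, C; positive toward
#' A1).  With long, balanced goal and action epochs this coincides with the
#' variance ordering; aligning makes the goal/action reading of the axes
#' robust when one epoch carries much less variance (e.g. single-goal
#' batches).
#'
#' @param traces list of `stp_trial` / `stp_meanfield` objects (or plain rate
#'   matrices, in which case `rest_rows` indexes the resting window).
#' @param rest_rows for plain matrices: row indices of the resting window.
#' @param align relabel the first two components as goal and action axes.
#' @return an object of class `stp_pca`: `rotation` (4 x 4 loadings, columns
#'   orthonormal), `center` (resting rates, Hz), `var_explained` (fractions;
#'   nonincreasing when `align = FALSE`).
#' @export
fit_pca <- function(traces, rest_rows = NULL, align = FALSE) {
  if (inherits(traces, c("stp_trial", "stp_meanfield"))) traces <- list(traces)
  stopifnot(length(traces) >= 1)
  mats <- lapply(traces, trial_rates)
  pooled <- do.call(rbind, mats)
  if (nrow(pooled) <= 4) stop("fewer samples than dimensions for PCA")
  rest <- do.call(rbind, lapply(traces, function(x) {
    m <- trial_rates(x)
    rows <- if (!is.null(rest_rows)) rest_rows
      else if (is.list(x) && !is.null(x$time))
        which(x$time < x$config$protocol$goal_display_onset)
      else seq_len(min(10, nrow(m)))
    m[rows, , drop = FALSE]
  }))
  center <- colMeans(rest)
  pc <- prcomp(sweep(pooled, 2, center), center = FALSE, scale. = FALSE)
  rot <- pc$rotation
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  sdev <- pc$sdev
  if (align) {
    gdir <- c(1, 1, -1, -1) / 2
    adir <- c(1, -1, -1, 1) / 2
    gi <- which.max(abs(crossprod(rot, gdir)))
    rest_i <- setdiff(seq_len(ncol(rot)), gi)
    ai <- rest_i[which.max(abs(crossprod(rot[, rest_i, drop = FALSE], adir)))]
    ord <- c(gi, ai, setdiff(seq_len(ncol(rot)), c(gi, ai)))
    rot <- rot[, ord, drop = FALSE]
    ve <- ve[ord]; sdev <- sdev[ord]
    if (sum(rot[, 1] * gdir) < 0) rot[, 1] <- -rot[, 1]
    if (sum(rot[, 2] * adir) < 0) rot[, 2] <- -rot[, 2]
    colnames(rot) <- paste0("PC", seq_len(ncol(rot)))
  }
  structure(list(rotation = rot, center = center, sdev = sdev,
                 var_explained = ve, aligned = align),
            class = "stp_pca")
}

#' @export
print.stp_pca <- function(x, ...) {
  cat("stp_pca: variance explained",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = " "), "\n")
  invisible(x)
}

#' Project population rates onto a PC basis
#'
#' @param rates matrix (time x 4 populations, Hz) or an `stp_trial` /
#'   `stp_meanfield`.
#' @param basis an `stp_pca`.
#' @param k number of components.
#' @return matrix (time x k) of PC scores.
#' @export
project_pc <- function(rates, basis, k = 2) {
  if (is.list(rates) && !is.null(rates$rates)) rates <- trial_rates(rates)
  sweep(as.matrix(rates), 2, basis$center) %*% basis$rotation[, seq_len(k),
                                                              drop = FALSE]
}

gaussian_smooth <- function(v, bin, width) {
  if (width <= 0) return(v)
  half <- max(1L, ceiling(3 * width / bin))
  k <- exp(-0.5 * ((-half:half) * bin / width)^2); k <- k / sum(k)
  n <- length(v)
  pad <- function(z, edge) c(rep(edge[1], half), z, rep(edge[2], half))
  sm <- stats::filter(pad(v, c(v[1], v[n])), k, sides = 2)
  as.numeric(sm[half + seq_len(n)])
}

#' Goal- and action-selectivity time courses by dummy-variable regression
#'
#' At every time step, the firing rate of each analysed unit (by default the
#' four excitatory populations) is regressed across trials on two binary dummy
#' regressors: goal preference (1 when the trial's goal is the unit's
#' preferred goal) and action preference (1 when the selected action is the
#' unit's preferred action).  The two coefficient time courses per unit are
#' jointly normalized by their single global maximum magnitude, so the peak
#' selectivity is 1.  High goal selectivity early and high action selectivity
#' late, crossing mid-delay, is the signature of representational switching.
#'
#' @param batch an `stp_batch` from [run_batch()], or a list of trials plus
#'   explicit labels.
#' @param goals,actions per-trial labels (`"G1"`/`"G2"`, `"A1"`/`"A2"`);
#'   taken from the batch when omitted.
#' @param units which populations to analyse.
#' @param smooth_ms extra Gaussian smoothing (SD, ms) applied to the rate
#'   series before the regression.
#' @return an object of class `stp_selectivity`: `time`, matrices `goal` and
#'   `action` (time x units, normalized to global peak 1 per unit), their
#'   across-unit means `goal_mean` / `action_mean`, and the raw (unnormalized)
#'   coefficients and intercepts.
#' @export
selectivity_timecourse <- function(batch, goals = NULL, actions = NULL,
                                   units = POPS[1:4], smooth_ms = 50) {
  if (inherits(batch, "stp_batch")) {
    trials <- batch$traces
    goals <- goals %||% batch$results$goal
    actions <- actions %||% batch$results$action
  } else trials <- batch
  stopifnot(length(trials) == length(goals), length(goals) == length(actions))
  if (length(unique(goals)) < 2)
    stop("rank-deficient design: only goal condition ", unique(goals),
         " present")
  if (length(unique(actions[!is.na(actions)])) < 2)
    stop("rank-deficient design: only action condition ",
         unique(actions[!is.na(actions)]), " present")
  time <- trial_time(trials[[1]])
  bin <- time[2] - time[1]
  nt <- length(time)
  out_goal <- out_action <- out_int <- matrix(
    0, nt, length(units), dimnames = list(NULL, units))
  for (u in units) {
    pref <- PREFERENCE[PREFERENCE$pop == u, ]
    G <- as.numeric(goals == pref$goal)
    A <- as.numeric(actions == pref$action)
    X <- cbind(1, G, A)
    XtXi <- solve(crossprod(X))
    Y <- vapply(trials, function(tr)
      gaussian_smooth(trial_rates(tr)[, u], bin, smooth_ms), numeric(nt))
    B <- XtXi %*% crossprod(X, t(Y))   # 3 x time
    out_int[, u] <- B[1, ]; out_goal[, u] <- B[2, ]; out_action[, u] <- B[3, ]
  }
  goal_n <- action_n <- out_goal
  for (u in units) {
    peak <- max(abs(out_goal[, u]), abs(out_action[, u]))
    if (peak == 0) peak <- 1
    goal_n[, u] <- out_goal[, u] / peak
    action_n[, u] <- out_action[, u] / peak
  }
  structure(list(time = time, goal = goal_n, action = action_n,
                 goal_mean = rowMeans(goal_n), action_mean = rowMeans(action_n),
                 raw = list(intercept = out_int, goal = out_goal,
                            action = out_action)),
            class = "stp_selectivity")
}

#' @export
print.stp_selectivity <- function(x, ...) {
  tt <- detect_transition_time(x)
  cat("stp_selectivity: transition at",
      if (is.na(tt)) "none" else paste(round(tt), "ms"), "\n")
  invisible(x)
}

#' Detect the representational-switching time
#'
#' The transition is the first time the action measure exceeds the goal
#' measure and remains higher for at least `sustain` ms.  For a selectivity
#' object the measures are the across-unit mean normalized coefficients; for a
#' single trial (given a PC basis) they are the absolute projections onto the
#' second and first PC axes.  `NA` is returned when no transition occurs
#' (e.g. the no-plasticity control).
#'
#' @param x an `stp_selectivity`, an `stp_trial`/`stp_meanfield` (with
#'   `basis`), or a numeric goal-measure vector (with `action` and `time`).
#' @param action,time action measure and time grid when `x` is numeric.
#' @param basis PC basis for the single-trial definition.
#' @param sustain required dominance duration (ms).
#' @param after ignore times before this (ms).
#' @param min_frac for the single-trial definition, the action projection
#'   must also exceed this fraction of the trial's maximal PC amplitude
#'   (rejects spurious dominance while both projections are near zero, e.g.
#'   during ignition or in a no-transition control).
#' @return transition time in ms, or `NA_real_`.
#' @export
detect_transition_time <- function(x, action = NULL, time = NULL, basis = NULL,
                                   sustain = 200, after = -Inf,
                                   min_frac = 0.2) {
  if (inherits(x, "stp_selectivity"))
    return(first_sustained(x$action_mean > x$goal_mean, x$time, sustain, after))
  if (inherits(x, c("stp_trial", "stp_meanfield"))) {
    if (is.null(basis)) stop("single-trial detection needs a PC basis")
    pc <- project_pc(x, basis)
    floor_amp <- min_frac * max(sqrt(pc[, 1]^2 + pc[, 2]^2))
    return(first_sustained(abs(pc[, 2]) > pmax(abs(pc[, 1]), floor_amp),
                           x$time, sustain, after))
  }
  first_sustained(action > x, time, sustain, after)
}

first_sustained <- function(cond, time, sustain, after = -Inf) {
  cond[time < after] <- FALSE
  cond[is.na(cond)] <- FALSE
  bin <- time[2] - time[1]
  need <- max(1L, round(sustain / bin))
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= need)
  if (!length(ok)) return(NA_real_)
  time[ends[ok[1]] - r$lengths[ok[1]] + 1]
}

#' Entry time into the goal state
#'
#' First time the first-PC projection dominates (`|PC1| > |PC2|`) and exceeds
#' `frac` of its trial maximum, sustained for `sustain` ms.
#'
#' @param trial an `stp_trial` or `stp_meanfield`.
#' @param basis PC basis.
#' @param frac activation fraction of the trial maximum.
#' @param sustain required duration (ms); shorter than the transition
#'   criterion because entry marks the first commitment to the goal axis,
#'   which in fast-switching trials can precede the switch by only a few
#'   hundred milliseconds.
#' @return time in ms, or `NA_real_`.
#' @export
goal_entry_time <- function(trial, basis, frac = 0.25, sustain = 100) {
  pc <- project_pc(trial, basis)
  thr <- frac * max(abs(pc[, 1]))
  first_sustained(abs(pc[, 1]) > abs(pc[, 2]) & abs(pc[, 1]) > thr,
                  trial$time, sustain)
}

#' Structural goal/action contrast basis
#'
#' The orthonormal basis whose first two axes are the architectural goal
#' contrast (A, B versus C, D) and action contrast (A, D versus B, C),
#' centred on supplied resting rates.  Used in place of an empirical PC
#' basis when a batch cannot identify both axes from variance alone (e.g.
#' every trial selected the same action).
#'
#' @param center resting-rate offset (Hz, length 4).
#' @return an `stp_pca` basis.
#' @export
structural_basis <- function(center = rep(0, 4)) {
  rot <- cbind(PC1 = c(1, 1, -1, -1) / 2, PC2 = c(1, -1, -1, 1) / 2,
               PC3 = c(1, 1, 1, 1) / 2, PC4 = c(1, -1, 1, -1) / 2)
  rownames(rot) <- POPS[1:4]
  structure(list(rotation = rot, center = center,
                 sdev = rep(NA_real_, 4), var_explained = rep(NA_real_, 4),
                 aligned = TRUE, structural = TRUE), class = "stp_pca")
}

#' Run a batch of spiking trials
#'
#' Runs `n_trials` trials on one fixed network instance (built from the master
#' seed) with independent per-trial noise seeds derived from the master seed,
#' goals balanced by default.  Fits the batch PC basis, projects every trial,
#' and assembles per-trial results (selected action, goal-entry, transition
#' and dwell times) and aggregates (pattern counts over goal x action,
#' transition-time mean and SD).
#'
#' @param config an `stp_config`.
#' @param n_trials number of trials.
#' @param seed master seed; the same master seed reproduces the batch exactly.
#' @param goals per-trial goal labels (default: alternating G1/G2).
#' @param freeze_plasticity run the no-plasticity control.
#' @param keep_spikes retain per-trial spike tables (memory-heavy).
#' @param basis_type `"batch"` fits the aligned PC basis to the batch and
#'   falls back to [structural_basis()] when the fitted axes align poorly
#'   (absolute cosine below 0.9) with the architectural contrasts -- which
#'   happens when one goal or one action dominates the batch;
#'   `"structural"` always uses the contrast basis.
#' @param ... passed to [run_trial()].
#' @return an object of class `stp_batch`: `results` (one row per trial:
#'   `goal`, `action`, `entry_ms`, `transition_ms`, `dwell_ms`, `seed`,
#'   `failed`), `pattern` (2 x 2 contingency table), `transition_mean`,
#'   `transition_sd`, `basis`, `traces`.
#' @export
run_batch <- function(config, n_trials = 40, seed = 1L, goals = NULL,
                      freeze_plasticity = FALSE, keep_spikes = FALSE,
                      basis_type = c("batch", "structural"), ...) {
  basis_type <- match.arg(basis_type)
  if (is.null(goals)) goals <- rep(c("G1", "G2"), length.out = n_trials)
  stopifnot(length(goals) == n_trials)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
  network <- build_network(config, seed = seed)
  traces <- vector("list", n_trials)
  failed <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    cfg_i <- config
    cfg_i$protocol$sensory_target <- goals[i]
    tr <- try(run_trial(cfg_i, seed = trial_seeds[i], network = network,
                        freeze_plasticity = freeze_plasticity, ...),
              silent = TRUE)
    if (inherits(tr, "try-error")) { failed[i] <- TRUE; next }
    if (!keep_spikes) tr$spikes <- tr$spikes[0, ]
    traces[[i]] <- tr
  }
  okidx <- which(!failed)
  basis <- fit_pca(traces[okidx], align = TRUE)
  quality <- min(abs(sum(basis$rotation[, 1] * c(1, 1, -1, -1) / 2)),
                 abs(sum(basis$rotation[, 2] * c(1, -1, -1, 1) / 2)))
  if (basis_type == "structural" || quality < 0.9)
    basis <- structural_basis(center = basis$center)
  results <- data.frame(goal = goals, action = NA_character_,
                        entry_ms = NA_real_, transition_ms = NA_real_,
                        dwell_ms = NA_real_, seed = trial_seeds,
                        failed = failed, stringsAsFactors = FALSE)
  for (i in okidx) {
    tr <- traces[[i]]
    results$action[i] <- selected_action(tr)
    results$entry_ms[i] <- goal_entry_time(tr, basis)
    results$transition_ms[i] <- detect_transition_time(
      tr, basis = basis, after = results$entry_ms[i])
    results$dwell_ms[i] <- results$transition_ms[i] - results$entry_ms[i]
  }
  pattern <- table(factor(results$goal, c("G1", "G2")),
                   factor(results$action, c("A1", "A2")))
  structure(list(results = results, pattern = pattern,
                 transition_mean = mean(results$transition_ms, na.rm = TRUE),
                 transition_sd = sd(results$transition_ms, na.rm = TRUE),
                 basis = basis, traces = traces, config = config,
                 seed = as.integer(seed)), class = "stp_batch")
}

#' @export
print.stp_batch <- function(x, ...) {
  cat("stp_batch:", nrow(x$results), "trials,",
      sum(!is.na(x$results$transition_ms)), "with transitions\n")
  print(x$pattern)
  cat("  transition:", round(x$transition_mean), "+/-",
      round(x$transition_sd), "ms\n")
  invisible(x)
}
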