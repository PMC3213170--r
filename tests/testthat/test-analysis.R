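fake_trial <- function(rates, time = seq(0, 1000, by = 10)) {
  structure(list(time = time,
                 rates = rates[rep(1, length(time)), , drop = FALSE]),
            class = "stp_trial")
}

test_that("PCA recovers a single direction of variance and centres on rest", {
  v <- c(1, 1, -1, -1) / 2
  t_axis <- seq(0, 1, length.out = 50)
  m1 <- 10 + outer(t_axis * 20, v)     # moves along +v
  m2 <- 10 + outer(t_axis * -20, v)    # moves along -v
  colnames(m1) <- colnames(m2) <- c("A", "B", "C", "D")
  basis <- fit_pca(list(m1, m2), rest_rows = 1)
  expect_equal(abs(sum(basis$rotation[, 1] * v)), 1, tolerance = 1e-6)
  expect_true(all(diff(basis$var_explained) <= 1e-12))
  # the resting state projects to the origin
  expect_equal(as.numeric(project_pc(matrix(10, 1, 4), basis)), c(0, 0),
               tolerance = 1e-9)
})

test_that("PCA alignment orders components as goal then action axes", {
  gdir <- c(1, 1, -1, -1) / 2; adir <- c(1, -1, -1, 1) / 2
  t_axis <- seq(0, 1, length.out = 40)
  mk <- function(dir, amp) {
    m <- 5 + outer(t_axis * amp, dir); colnames(m) <- c("A", "B", "C", "D"); m
  }
  # action variance dominates: unaligned PC1 would be the action axis
  traces <- list(mk(gdir, 5), mk(-gdir, 5), mk(adir, 30), mk(-adir, 30))
  basis <- fit_pca(traces, rest_rows = 1, align = TRUE)
  expect_gt(abs(sum(basis$rotation[, 1] * gdir)), 0.99)
  expect_gt(abs(sum(basis$rotation[, 2] * adir)), 0.99)
  expect_gt(sum(basis$rotation[, 1] * gdir), 0)   # sign fixed toward G1
})

test_that("PCA refuses fewer samples than dimensions", {
  m <- matrix(1:8 + 0.5, 2, 4)
  expect_error(fit_pca(list(m), rest_rows = 1), "fewer samples")
})

test_that("selectivity regression isolates pure goal and pure action coding", {
  pats <- expand.grid(goal = c("G1", "G2"), action = c("A1", "A2"),
                      rep = 1:2, stringsAsFactors = FALSE)
  mk_rates <- function(f) {
    trials <- lapply(seq_len(nrow(pats)), function(i) {
      r <- vapply(c("A", "B", "C", "D"), function(p)
        f(p, pats$goal[i], pats$action[i]), 0)
      fake_trial(matrix(r, 1, dimnames = list(NULL, names(r))))
    })
    trials
  }
  pref <- stpnet:::PREFERENCE
  # rates depend only on the goal
  trials <- mk_rates(function(p, g, a)
    if (pref$goal[pref$pop == p] == g) 10 else 2)
  sel <- selectivity_timecourse(trials, goals = pats$goal,
                                actions = pats$action, smooth_ms = 0)
  expect_true(all(abs(sel$goal - 1) < 1e-9))
  expect_true(all(abs(sel$action) < 1e-9))
  # rates depend only on the action
  trials <- mk_rates(function(p, g, a)
    if (pref$action[pref$pop == p] == a) 12 else 3)
  sel <- selectivity_timecourse(trials, goals = pats$goal,
                                actions = pats$action, smooth_ms = 0)
  expect_true(all(abs(sel$action - 1) < 1e-9))
  expect_true(all(abs(sel$goal) < 1e-9))
})

test_that("selectivity regression rejects rank-deficient designs", {
  trials <- replicate(4, fake_trial(
    matrix(5, 1, 4, dimnames = list(NULL, c("A", "B", "C", "D")))),
    simplify = FALSE)
  expect_error(selectivity_timecourse(trials, goals = rep("G1", 4),
                                      actions = c("A1", "A2", "A1", "A2")),
               "G1")
  expect_error(selectivity_timecourse(trials, goals = c("G1", "G2", "G1", "G2"),
                                      actions = rep("A1", 4)),
               "A1")
})

test_that("transition detection finds a constructed step and rejects none", {
  tg <- seq(0, 2000, by = 10)
  goal <- as.numeric(tg < 1200)
  action <- as.numeric(tg >= 1200)
  expect_equal(detect_transition_time(goal, action, tg), 1200, tolerance = 10)
  expect_true(is.na(detect_transition_time(rep(1, length(tg)),
                                           rep(0.2, length(tg)), tg)))
  # dominance shorter than the sustain window is ignored
  blip <- rep(0, length(tg)); blip[50:55] <- 2
  expect_true(is.na(detect_transition_time(rep(1, length(tg)), blip, tg)))
})

test_that("batches are reproducible and account for every trial", {
  cfg <- small_config()
  cfg$protocol$trial_duration <- 2500
  b1 <- run_batch(cfg, n_trials = 4, seed = 7)
  b2 <- run_batch(cfg, n_trials = 4, seed = 7)
  expect_identical(b1$results, b2$results)
  expect_identical(b1$pattern, b2$pattern)
  expect_equal(b1$results$goal, c("G1", "G2", "G1", "G2"))
  expect_equal(sum(b1$pattern), sum(!is.na(b1$results$action)))
  expect_true(all(b1$results$dwell_ms == b1$results$transition_ms -
                    b1$results$entry_ms | is.na(b1$results$dwell_ms)))
})

test_that("selectivity normalization peaks at one for every analysed unit", {
  b <- cached("batch16", run_batch(small_config(), n_trials = 16, seed = 42))
  ok <- !is.na(b$results$action)
  sel <- selectivity_timecourse(b$traces[ok], goals = b$results$goal[ok],
                                actions = b$results$action[ok])
  for (u in colnames(sel$goal))
    expect_equal(max(abs(sel$goal[, u]), abs(sel$action[, u])), 1,
                 tolerance = 1e-9)
})
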