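sp <- build_state_space(c("CVD", "MTD", "SMD"))

test_that("state space encodes the progression DAG", {
  expect_equal(sum(sp$adjacency), 16)
  want <- list(`1` = c(2, 3, 4, 5), `2` = c(3, 4, 5), `3` = c(6, 7),
               `4` = c(6, 8), `5` = c(7, 8), `6` = 9, `7` = 9, `8` = 9)
  for (from in names(want)) {
    expect_equal(which(sp$adjacency[as.integer(from), ]),
                 want[[from]], ignore_attr = TRUE)
  }
  expect_equal(sum(sp$adjacency[9, ]), 0)       # absorbing: no exits
  expect_false(sp$adjacency[3, 8])              # CVD-only cannot jump to MTD+SMD
  expect_error(build_state_space(c("CVD", "MTD")), "3 distinct")
})

test_that("profiles map to states; trio components dominate", {
  expect_equal(assign_state(profile_vec("cvd", "mtd"), sp), 6)
  expect_equal(assign_state(profile_vec(), sp), 1)
  expect_equal(assign_state(profile_vec("rpd"), sp), 2)
  expect_equal(assign_state(profile_vec("rpd", "cvd"), sp), 3)
  expect_equal(assign_state(profile_vec("cvd", "mtd", "smd"), sp), 9)
  expect_equal(assign_state(profile_vec("cvd", "smd"), sp), 7)
  expect_equal(assign_state(profile_vec("mtd", "smd"), sp), 8)
})

test_that("intensity matrices are valid generators", {
  Q <- default_intensity_matrix(sp)
  expect_equal(rowSums(Q), rep(0, 9), ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(all(Q[sp$edges] > 0))
  bad <- Q
  bad[3, 8] <- 0.1
  bad[3, 3] <- bad[3, 3] - 0.1
  expect_error(morbiditrail:::validate_intensity_matrix(bad, sp),
               "disallowed")
})

test_that("transition probabilities behave like a semigroup", {
  Q <- default_intensity_matrix(sp)
  expect_equal(transition_probabilities(Q, 0), diag(9), ignore_attr = TRUE,
               tolerance = 1e-12)
  P5 <- transition_probabilities(Q, 5)
  P10 <- transition_probabilities(Q, 10)
  expect_lt(max(abs(P5 %*% P5 - P10)), 1e-8)    # Chapman-Kolmogorov
  expect_equal(rowSums(P5), rep(1, 9), ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(P5[9, ], c(rep(0, 8), 1), ignore_attr = TRUE)
  expect_error(transition_probabilities(Q, -1), "non-negative")
  # mass in the absorbing state is nondecreasing in t from every start
  horizons <- c(1, 2, 5, 10, 20, 40)
  mass <- sapply(horizons, function(t) transition_probabilities(Q, t)[, 9])
  expect_true(all(diff(t(mass)) >= -1e-12))
})

test_that("short-horizon probabilities expand as I + Q dt", {
  Q <- default_intensity_matrix(sp)
  dt <- 1e-4
  P <- transition_probabilities(Q, dt)
  # second-order remainder: off-DAG direct probabilities vanish as o(dt)
  expect_lt(max(abs(P - diag(9) - Q * dt)), max(abs(Q %*% Q)) * dt^2)
})

test_that("matrix exponential agrees with an independent implementation", {
  skip_if_not_installed("Matrix")
  Q <- default_intensity_matrix(sp)
  P <- transition_probabilities(Q, 7.3)
  Pref <- as.matrix(Matrix::expm(Matrix::Matrix(Q * 7.3)))
  expect_lt(max(abs(P - Pref)), 1e-10)
})

test_that("two-state stay probability matches the closed form", {
  Q2 <- matrix(c(-0.1, 0.1, 0, 0), 2, 2, byrow = TRUE)
  P <- morbiditrail:::ctmc_expm_cpp(Q2, 5)
  expect_equal(P[1, 1], exp(-0.5), tolerance = 1e-10)
})

test_that("expected absorption times solve the first-passage system", {
  Q <- default_intensity_matrix(sp)
  tau <- expected_absorption_time(Q)
  expect_equal(unname(tau[9]), 0)
  # linear chain 1 -> 2 -> 3 with rates 0.5, 0.25: 1/0.5 + 1/0.25 = 6
  Q3 <- matrix(c(-0.5, 0.5, 0, 0, -0.25, 0.25, 0, 0, 0), 3, 3, byrow = TRUE)
  tau3 <- as.numeric(morbiditrail:::absorption_times_cpp(Q3, 3))
  expect_equal(tau3[1], 6, tolerance = 1e-8)
  expect_equal(tau3[2], 4, tolerance = 1e-8)
  # time rescaling: doubling every intensity halves every expected time
  tau_fast <- expected_absorption_time(2 * Q)
  expect_equal(unname(tau_fast[1:8]), unname(tau[1:8]) / 2, tolerance = 1e-10)
  # unreachable absorbing state -> infinite expected time
  Qz <- Q
  Qz[6, 9] <- 0
  Qz[6, 6] <- 0
  expect_equal(unname(expected_absorption_time(Qz)[6]), Inf)
  # dual states are never slower than their constituent single states
  expect_true(all(tau[6:8] <= tau[3:5] + 1e-12))
})

test_that("analytic likelihood gradient matches central finite differences", {
  set.seed(3)
  ns <- asNamespace("morbiditrail")
  Q <- default_intensity_matrix(sp)
  edges <- sp$edges
  reach <- morbiditrail:::reachability(sp$adjacency)
  counts <- array(0, c(9, 9, 2))
  for (s in 1:2) {
    cm <- matrix(rpois(81, 6), 9, 9)
    cm[!reach] <- 0
    counts[, , s] <- cm
  }
  dts <- c(2, 3.5)
  logr <- log(Q[edges]) + rnorm(16, 0, 0.3)
  g <- ns$panel_nll_grad_cpp(logr, counts, dts, edges, 9L)
  fd <- vapply(seq_along(logr), function(k) {
    e <- 1e-6
    up <- dn <- logr
    up[k] <- up[k] + e
    dn[k] <- dn[k] - e
    (ns$panel_nll_cpp(up, counts, dts, edges, 9L) -
       ns$panel_nll_cpp(dn, counts, dts, edges, 9L)) / (2 * e)
  }, numeric(1))
  expect_equal(as.numeric(g), fd, tolerance = 1e-5)
})

test_that("nearly-exact observation recovers the events/person-time rate", {
  ns <- asNamespace("morbiditrail")
  # two-state chain observed every 0.05y: 50 events over ~500 person-years
  counts <- array(0, c(2, 2, 1))
  counts[1, 1, 1] <- 500 / 0.05 - 50
  counts[1, 2, 1] <- 50
  edges <- cbind(from = 1L, to = 2L)
  fit <- ns$fit_panel_cpp(counts, 0.05, edges, 2L, log(0.5))
  expect_equal(exp(fit$logr), 0.1, tolerance = 0.01)
})

test_that("a panel with no transitions yields a flagged boundary fit", {
  p <- make_panel(rep(c("a", "b", "c"), each = 3), rep(0:2, 3))
  st <- panel_to_states(p, sp)
  fit <- fit_intensities(st, sp, n_starts = 1)
  expect_true(all(fit$boundary))
  expect_true(all(fit$rates[!fit$no_information] < 1e-5))
  expect_true(all(fit$rates[fit$no_information] < 1e-5))
})

test_that("impossible observed transitions are rejected with context", {
  st <- data.frame(id = c("a", "a"), time = c(0, 2), state = c(9L, 3L))
  expect_error(fit_intensities(st, sp), "participant a")
  st2 <- data.frame(id = c("a", "a"), time = c(0, 0), state = c(1L, 2L))
  expect_error(fit_intensities(st2, sp), "non-increasing")
})

test_that("likelihood at the truth beats perturbed intensities on large data", {
  set.seed(9)
  cfg <- synthetic_config()
  panel <- generate_panel(cfg, n = 3000)
  iv <- morbiditrail:::panel_intervals(panel_to_states(panel, sp), sp)
  ns <- asNamespace("morbiditrail")
  logr_true <- log(cfg$true_Q[sp$edges])
  nll_true <- ns$panel_nll_cpp(logr_true, iv$counts, iv$dts, sp$edges, 9L)
  for (r in 1:5) {
    nll_pert <- ns$panel_nll_cpp(logr_true + rnorm(16, 0, 0.5),
                                 iv$counts, iv$dts, sp$edges, 9L)
    expect_gt(nll_pert, nll_true)
  }
})

test_that("expected absorption time agrees with Monte-Carlo first passage", {
  set.seed(17)
  Q <- default_intensity_matrix(sp)
  tau4 <- expected_absorption_time(Q)[4]
  n <- 10000
  hits <- vapply(seq_len(n), function(i) {
    traj <- morbiditrail:::simulate_trajectory(Q, 4L, 1000)
    w <- which(traj[, "state"] == 9L)
    traj[w[1], "time"]
  }, numeric(1))
  se <- sd(hits) / sqrt(n)
  expect_lt(abs(mean(hits) - tau4), 3 * se)
})

test_that("bootstrap comparison rejects invalid inputs and detects speed gaps", {
  set.seed(23)
  sp2 <- build_state_space()
  Q0 <- morbiditrail:::equal_speed_intensity_matrix(sp2)
  # MTD path twice as fast: double every intensity out of state 4 and keep
  # the dual -> trio legs so tau(4) is clearly below tau(3) = tau(5)
  Qf <- Q0
  Qf[4, 6] <- 2 * Q0[4, 6]
  Qf[4, 8] <- 2 * Q0[4, 8]
  diag(Qf) <- 0
  diag(Qf) <- -rowSums(Qf)
  cfg <- synthetic_config(true_Q = Qf)
  panel <- generate_panel(cfg, n = 2000)
  fit <- fit_intensities(panel_to_states(panel, sp2), sp2, n_starts = 1)
  expect_error(compare_absorption_times(fit, n_boot = 0), "positive")
  hits <- 0L
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    panel <- generate_panel(cfg, n = 2000)
    fit <- fit_intensities(panel_to_states(panel, sp2), sp2, n_starts = 1)
    cmp <- compare_absorption_times(fit, 3:5, n_boot = 200)
    mtd <- cmp$pairwise$state_a == 4 | cmp$pairwise$state_b == 4
    if (all(cmp$pairwise$p_bonferroni[mtd] < 0.05)) hits <- hits + 1L
  }
  expect_gt(hits / n_rep, 0.8)
})
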