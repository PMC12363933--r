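test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config()
  set.seed(5)
  a <- generate_cross_section(cfg, n = 500)
  set.seed(5)
  b <- generate_cross_section(cfg, n = 500)
  expect_identical(a, b)
  set.seed(5)
  pa <- generate_panel(cfg, n = 100)
  set.seed(5)
  pb <- generate_panel(cfg, n = 100)
  expect_identical(pa, pb)
})

test_that("infeasible planting is rejected", {
  expect_error(
    synthetic_config(planted_itemsets = list(
      list(items = c("CVD", "MTD", "SMD"), lift = 200))) |>
      generate_cross_section(n = 10),
    "infeasible")
  expect_error(
    generate_cross_section(synthetic_config(planted_itemsets = list(
      list(items = c("CVD", "MTD"), lift = 2),
      list(items = c("MTD", "SMD"), lift = 2))), n = 10),
    "disjoint")
})

test_that("planted marginals and joint lift are realised", {
  cfg <- synthetic_config()
  set.seed(41)
  cs <- generate_cross_section(cfg, n = 50000)
  m <- as.matrix(cs[c("CVD", "MTD", "SMD", "RPD", "NRD", "MD", "CC")])
  prev <- colMeans(m)
  expect_equal(prev[names(cfg$cross_section_prevalences)],
               cfg$cross_section_prevalences, tolerance = 0.03)
  joint <- mean(rowSums(m[, c("CVD", "MTD", "SMD")]) == 3)
  lift <- joint / prod(prev[c("CVD", "MTD", "SMD")])
  expect_equal(lift, 12, tolerance = 0.08)
})

test_that("mean pairwise lift approaches 1 as the sample grows", {
  cfg <- synthetic_config(planted_itemsets = list())
  mean_abs_loglift <- function(n) {
    cs <- generate_cross_section(cfg, n = n)
    m <- as.matrix(cs[c("CVD", "MTD", "SMD", "RPD", "NRD", "MD", "CC")])
    devs <- vapply(utils::combn(colnames(m), 2, simplify = FALSE),
                   function(pair) {
                     pa <- mean(m[, pair[1]])
                     pb <- mean(m[, pair[2]])
                     p11 <- mean(m[, pair[1]] & m[, pair[2]])
                     abs(log(p11 / (pa * pb)))
                   }, numeric(1))
    mean(devs)
  }
  set.seed(43)
  small <- mean(replicate(4, mean_abs_loglift(1250)))
  big <- mean_abs_loglift(20000)
  expect_lt(big, 0.05)          # lifts concentrate at 1
  expect_lt(big, small / 2)     # deviation shrinks roughly like 1/sqrt(n)
})

test_that("a frozen chain never moves and state 9 is never left", {
  sp <- build_state_space()
  zeroQ <- matrix(0, 9, 9, dimnames = dimnames(default_intensity_matrix(sp)))
  cfg <- synthetic_config(true_Q = zeroQ)
  set.seed(47)
  panel <- generate_panel(cfg, n = 200)
  st <- panel_to_states(panel, sp)
  moved <- tapply(st$state, st$id, function(s) any(diff(s) != 0))
  expect_false(any(moved))
  cfg2 <- synthetic_config()
  set.seed(48)
  panel2 <- generate_panel(cfg2, n = 500)
  truth <- attr(panel2, "truth")
  after9 <- apply(truth$states, 1, function(s) {
    w <- which(s == 9L)
    length(w) == 0 || all(s[w[1]:length(s)] == 9L)
  })
  expect_true(all(after9))
})

test_that("simulated trajectories never traverse a disallowed edge", {
  sp <- build_state_space()
  cfg <- synthetic_config()
  set.seed(49)
  panel <- generate_panel(cfg, n = 400)
  st <- panel_to_states(panel, sp)
  reach <- morbiditrail:::reachability(sp$adjacency)
  pairs <- do.call(rbind, tapply(st$state, st$id, function(s)
    cbind(s[-length(s)], s[-1]), simplify = FALSE))
  expect_true(all(reach[pairs]))
})

test_that("wave occupancy matches the matrix-exponential oracle", {
  sp <- build_state_space()
  cfg <- synthetic_config()
  n <- 5000
  for (mode in c("continuous", "discrete")) {
    set.seed(51)
    panel <- generate_panel(cfg, n = n, mode = mode)
    truth <- attr(panel, "truth")
    t_check <- 6  # wave 3
    occ <- tabulate(truth$states[, 4], 9) / n
    p_t <- trajectory_oracle(cfg$true_Q, cfg$initial_state_distribution,
                             t_check)
    se <- sqrt(p_t * (1 - p_t) / n)
    expect_true(all(abs(occ - p_t) <= 3 * se + 1e-12))
  }
})

test_that("trajectory oracle obeys identity, closed form and semigroup", {
  Q2 <- matrix(c(-0.1, 0.1, 0, 0), 2, 2, byrow = TRUE)
  expect_equal(trajectory_oracle(Q2, c(1, 0), 0), c(1, 0))
  expect_equal(trajectory_oracle(Q2, c(1, 0), 5)[1], exp(-0.5),
               tolerance = 1e-10)
  Q <- default_intensity_matrix(build_state_space())
  p0 <- c(1, rep(0, 8))
  p_s <- trajectory_oracle(Q, p0, 4)
  expect_equal(trajectory_oracle(Q, p_s, 6), trajectory_oracle(Q, p0, 10),
               tolerance = 1e-10)
})

test_that("burden outcomes follow the onset-conditional probabilities", {
  cfg <- synthetic_config()
  ids <- sprintf("p%05d", 1:30000)
  onsets <- setNames(sample(c("CVD", "MTD", "SMD"), 30000, TRUE), ids)
  panel <- data.frame(id = ids)
  set.seed(61)
  out <- generate_burden(cfg, panel, onsets)
  for (g in c("CVD", "MTD", "SMD")) {
    sel <- out$id %in% ids[onsets == g]
    n <- sum(sel)
    p_dep <- cfg$burden_conditionals[[g]]$depressed
    expect_lt(abs(mean(out$depressed[sel]) - p_dep),
              3 * sqrt(p_dep * (1 - p_dep) / n))
    p_sleep <- sum(cfg$burden_conditionals[[g]]$sleep[c("fair", "poor")])
    got <- mean(out$sleep_quality[sel] %in% c("fair", "poor"))
    expect_lt(abs(got - p_sleep), 3 * sqrt(p_sleep * (1 - p_sleep) / n))
  }
  # zero depression probability -> no depressed flags
  cfg0 <- cfg
  for (g in names(cfg0$burden_conditionals)) {
    cfg0$burden_conditionals[[g]]$depressed <- 0
  }
  out0 <- generate_burden(cfg0, panel, onsets)
  expect_equal(sum(out0$depressed), 0)
})
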