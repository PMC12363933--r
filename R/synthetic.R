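#' Default ground-truth generator for the synthetic cohort
#'
#' Per-year intensities on the 16 allowed edges, calibrated qualitatively to
#' the dynamics the model is meant to exhibit: roughly 40% of healthy obese
#' adults acquire some chronic disease within 5 years, progression is faster
#' for people already holding a non-trio disease, and the metabolic-onset
#' path to triple comorbidity is the fastest of the three single-disease
#' paths while the cardiovascular and skeletal-muscular paths are similar
#' and slower.
#'
#' @param state_space A [build_state_space()] object (default trio
#'   CVD-MTD-SMD).
#' @return A 9x9 generator matrix.
#' @export
default_intensity_matrix <- function(state_space = build_state_space()) {
  rates <- c(
    "1->2" = 0.040, "1->3" = 0.028, "1->4" = 0.022, "1->5" = 0.014,
    "2->3" = 0.055, "2->4" = 0.045, "2->5" = 0.035,
    "3->6" = 0.100, "3->7" = 0.060,
    "4->6" = 0.160, "4->8" = 0.100,
    "5->7" = 0.070, "5->8" = 0.090,
    "6->9" = 0.220, "7->9" = 0.120, "8->9" = 0.160
  )
  key <- paste0(state_space$edges[, "from"], "->", state_space$edges[, "to"])
  intensity_matrix(rates[key], state_space)
}

# Equal-speed variant: identical expected first-passage time to state 9
# from each single-disease state (used for null-calibration studies).
equal_speed_intensity_matrix <- function(state_space = build_state_space()) {
  rates <- c(
    "1->2" = 0.040, "1->3" = 0.021, "1->4" = 0.021, "1->5" = 0.021,
    "2->3" = 0.045, "2->4" = 0.045, "2->5" = 0.045,
    "3->6" = 0.100, "3->7" = 0.100,
    "4->6" = 0.100, "4->8" = 0.100,
    "5->7" = 0.100, "5->8" = 0.100,
    "6->9" = 0.160, "7->9" = 0.160, "8->9" = 0.160
  )
  key <- paste0(state_space$edges[, "from"], "->", state_space$edges[, "to"])
  intensity_matrix(rates[key], state_space)
}

ordinal_levels <- function() c("excellent", "very good", "good", "fair", "poor")

# 5-level ordinal distribution with a prescribed adverse (fair+poor) mass.
ordinal_from_adverse <- function(adverse) {
  stopifnot(adverse >= 0, adverse <= 1)
  good <- 1 - adverse
  c(excellent = 0.10 * good, `very good` = 0.35 * good, good = 0.55 * good,
    fair = 0.60 * adverse, poor = 0.40 * adverse)
}

default_burden_conditionals <- function() {
  list(
    CVD  = list(depressed = 0.040, work_limited = 0.55,
                sleep = ordinal_from_adverse(0.65),
                self_rated_health = ordinal_from_adverse(0.45)),
    MTD  = list(depressed = 0.045, work_limited = 0.72,
                sleep = ordinal_from_adverse(0.70),
                self_rated_health = ordinal_from_adverse(0.60)),
    SMD  = list(depressed = 0.063, work_limited = 0.74,
                sleep = ordinal_from_adverse(0.77),
                self_rated_health = ordinal_from_adverse(0.50)),
    baseline = list(depressed = 0.030, work_limited = 0.40,
                    sleep = ordinal_from_adverse(0.55),
                    self_rated_health = ordinal_from_adverse(0.35))
  )
}

#' Configuration for the synthetic ELSA-like cohort
#'
#' Bundles every knob of the generator with defaults that emulate the study
#' conditions: biennial waves over ~20 years, an obese cohort, monotone
#' accumulation of the CVD-MTD-SMD trio under a known intensity matrix,
#' planted cross-sectional co-occurrence making that trio the top 3-pattern,
#' and burden outcomes whose prevalences depend on the onset disease (with
#' skeletal-muscular onset planted worst: depression 6.3%, adverse sleep
#' 77%, work limitation 74%).
#'
#' @param seed Integer seed recorded in the config (used by [run_pipeline()];
#'   the generator functions also accept data produced under any seed set by
#'   the caller).
#' @param n_participants Longitudinal cohort size (default 16114).
#' @param n_cross_section Cross-sectional sample size (default 22355).
#' @param wave_interval Years between waves (default 2).
#' @param n_waves Number of observation waves (default 11).
#' @param entry_age_mean,entry_age_sd Entry-age distribution for the panel.
#' @param prop_female Proportion female.
#' @param true_Q Ground-truth generator matrix
#'   (default [default_intensity_matrix()]).
#' @param initial_state_distribution Probability vector over the 9 states at
#'   the first wave.
#' @param cross_section_prevalences Named marginal prevalences of the 7
#'   disease systems in the cross-section.
#' @param planted_itemsets List of `list(items =, lift =)` entries planting
#'   co-occurrence above independence (disjoint itemsets); default plants
#'   \{CVD, MTD, SMD\} at lift 12.
#' @param burden_conditionals Per-onset burden outcome distributions.
#' @param dropout Per-wave probability of missing an observation after the
#'   first (default 0).
#' @param trio The trio whose accumulation the panel simulates.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_participants = 16114L,
                             n_cross_section = 22355L,
                             wave_interval = 2,
                             n_waves = 11L,
                             entry_age_mean = 60.23,
                             entry_age_sd = 9.97,
                             prop_female = 0.45,
                             true_Q = NULL,
                             initial_state_distribution =
                               c(0.33, 0.20, 0.14, 0.06, 0.10,
                                 0.07, 0.03, 0.03, 0.04),
                             cross_section_prevalences =
                               c(CVD = 0.30, MTD = 0.18, RPD = 0.12,
                                 SMD = 0.22, NRD = 0.10, MD = 0.06,
                                 CC = 0.06),
                             planted_itemsets = list(
                               list(items = c("CVD", "MTD", "SMD"),
                                    lift = 12)),
                             burden_conditionals = default_burden_conditionals(),
                             dropout = 0,
                             trio = c("CVD", "MTD", "SMD")) {
  sp <- build_state_space(trio)
  if (is.null(true_Q)) true_Q <- default_intensity_matrix(sp)
  validate_intensity_matrix(true_Q, sp)
  if (abs(sum(initial_state_distribution) - 1) > 1e-9 ||
      any(initial_state_distribution < 0) ||
      length(initial_state_distribution) != 9) {
    stop("initial_state_distribution must be a probability vector over 9 states")
  }
  prev <- cross_section_prevalences[DISEASE_SYSTEMS]
  if (any(is.na(prev)) || any(prev <= 0) || any(prev >= 1)) {
    stop("cross_section_prevalences must name all 7 systems with values in (0,1)")
  }
  cfg <- list(seed = as.integer(seed), n_participants = as.integer(n_participants),
              n_cross_section = as.integer(n_cross_section),
              wave_interval = wave_interval, n_waves = as.integer(n_waves),
              entry_age_mean = entry_age_mean, entry_age_sd = entry_age_sd,
              prop_female = prop_female, true_Q = true_Q,
              initial_state_distribution = initial_state_distribution,
              cross_section_prevalences = prev,
              planted_itemsets = planted_itemsets,
              burden_conditionals = burden_conditionals,
              dropout = dropout, trio = toupper(trio),
              state_space = sp)
  class(cfg) <- "synthetic_config"
  cfg
}

# Solve the latent-class planting: with probability p_k all items of set k
# are present; otherwise items are independent with adjusted base rates so
# that the configured marginals hold exactly. Disjoint sets only. Returns
# list(p = per-set mixing weights, base = adjusted per-item rates).
solve_planting <- function(prev, planted) {
  base <- prev
  p <- numeric(length(planted))
  seen <- character(0)
  for (k in seq_along(planted)) {
    items <- toupper(planted[[k]]$items)
    lift <- planted[[k]]$lift
    if (!all(items %in% names(prev))) stop("planted itemset has unknown items")
    if (length(intersect(items, seen))) {
      stop("planted itemsets must be disjoint")
    }
    seen <- c(seen, items)
    target <- lift * prod(prev[items])
    if (target > min(prev[items]) + 1e-12) {
      stop("infeasible planting: implied joint probability ",
           signif(target, 4), " exceeds the smallest marginal ",
           signif(min(prev[items]), 4))
    }
    f <- function(pk) {
      pk + (1 - pk) * prod((prev[items] - pk) / (1 - pk)) - target
    }
    if (f(0) >= 0) {
      p[k] <- 0  # independence already meets/exceeds the target
    } else {
      upper <- min(prev[items]) - 1e-12
      p[k] <- stats::uniroot(f, c(0, upper), tol = 1e-12)$root
    }
    base[items] <- (prev[items] - p[k]) / (1 - p[k])
  }
  if (sum(p) >= 1) stop("infeasible planting: mixing weights exceed 1")
  list(p = p, base = base)
}

age_band <- function(age) {
  cut(age, breaks = c(19, 37, 56, 75, 94), include.lowest = TRUE,
      labels = c("19-37", "38-56", "57-75", "76-94"), right = TRUE)
}

#' Generate a cross-sectional transaction sample with planted co-occurrence
#'
#' Draws one record per participant over the 7 disease-system items. A
#' latent-class mixture plants each configured itemset: with the solved
#' mixing probability the whole itemset is present, otherwise items are
#' independent with base rates adjusted so the configured marginal
#' prevalences hold exactly. The joint probability of a planted itemset then
#' exceeds independence by the configured lift.
#'
#' @param config A [synthetic_config()].
#' @param n Sample size (default `config$n_cross_section`).
#' @return Data frame with `id`, `age`, `age_band`, `sex` and one logical
#'   column per disease system.
#' @export
generate_cross_section <- function(config, n = config$n_cross_section) {
  plant <- solve_planting(config$cross_section_prevalences,
                          config$planted_itemsets)
  K <- length(plant$p)
  z <- sample.int(K + 1, n, replace = TRUE, prob = c(1 - sum(plant$p), plant$p))
  m <- matrix(runif(n * 7) < rep(plant$base, each = n), n, 7,
              dimnames = list(NULL, DISEASE_SYSTEMS))
  for (k in seq_len(K)) {
    items <- toupper(config$planted_itemsets[[k]]$items)
    m[z == k + 1, items] <- TRUE
  }
  age <- pmin(94, pmax(19, rnorm(n, 64, 13)))
  data.frame(
    id = sprintf("cs%06d", seq_len(n)),
    age = age,
    age_band = age_band(age),
    sex = ifelse(runif(n) < config$prop_female, "female", "male"),
    m,
    stringsAsFactors = FALSE
  )
}

#' Exact state-occupancy distribution under a generator
#'
#' Independent oracle for the trajectory simulator:
#' `p(t) = p0 %*% expm(Q t)`.
#'
#' @param Q Generator matrix.
#' @param p0 Initial distribution over states.
#' @param t Years.
#' @return Probability vector over states.
#' @export
trajectory_oracle <- function(Q, p0, t) {
  stopifnot(length(p0) == nrow(Q), abs(sum(p0) - 1) < 1e-9, t >= 0)
  as.numeric(p0 %*% ctmc_expm_cpp(Q, t))
}

# Simulate one continuous-time trajectory by competing exponential clocks;
# returns matrix with columns (time, state) of jump times, starting at t=0.
simulate_trajectory <- function(Q, s0, t_max) {
  times <- 0
  states <- s0
  s <- s0
  t <- 0
  repeat {
    out_rate <- -Q[s, s]
    if (out_rate <= 0) break
    t <- t + rexp(1, out_rate)
    if (t >= t_max) break
    rates <- Q[s, ]
    rates[s] <- 0
    s <- sample.int(length(rates), 1, prob = rates)
    times <- c(times, t)
    states <- c(states, s)
  }
  cbind(time = times, state = states)
}

state_profile_matrix <- function(state_space) {
  # 9 x 7 matrix of disease flags implied by each state (trio components
  # only; the non-trio disease of state 2 is added separately).
  trio_cols <- tolower(state_space$trio)
  present <- list(character(0), character(0), trio_cols[1], trio_cols[2],
                  trio_cols[3], trio_cols[1:2], trio_cols[c(1, 3)],
                  trio_cols[2:3], trio_cols)
  m <- matrix(0L, 9, 7, dimnames = list(NULL, disease_cols()))
  for (s in 1:9) m[s, present[[s]]] <- 1L
  m
}

#' Generate a longitudinal panel from the ground-truth intensity matrix
#'
#' Each participant starts in a state drawn from the configured initial
#' distribution, follows a continuous-time trajectory simulated with
#' competing exponential clocks on the allowed edges of `true_Q`, and is
#' observed only at biennial wave times (interval censoring). Observed
#' states are decoded back into disease profiles; participants entering the
#' non-trio state receive a persistent non-trio disease so that decoded
#' profiles map back to the same state. Onset-conditional burden outcomes
#' are attached via [generate_burden()].
#'
#' @param config A [synthetic_config()].
#' @param n Number of participants (default `config$n_participants`).
#' @param mode `"continuous"` (competing exponential clocks, default) or
#'   `"discrete"` (per-wave multinomial steps with `P(wave_interval)`,
#'   provided as a cross-check mode).
#' @return Long-format panel data frame (`id`, `wave`, `time_years`, `age`,
#'   `sex`, `race`, `bmi`, disease flags, burden columns) with attribute
#'   `truth`: a list holding `true_Q`, the per-participant true onset type
#'   and time, and the observed state matrix.
#' @export
generate_panel <- function(config, n = config$n_participants,
                           mode = c("continuous", "discrete")) {
  mode <- match.arg(mode)
  sp <- config$state_space
  Q <- config$true_Q
  n_waves <- config$n_waves
  dt <- config$wave_interval
  wave_times <- (seq_len(n_waves) - 1) * dt
  s0 <- sample.int(9, n, replace = TRUE,
                   prob = config$initial_state_distribution)
  states <- matrix(NA_integer_, n, n_waves)
  onset_type <- rep(NA_character_, n)
  onset_time <- rep(NA_real_, n)
  trio_states <- c(3L, 4L, 5L)
  if (mode == "discrete") {
    P <- ctmc_expm_cpp(Q, dt)
    P[P < 0] <- 0
  }
  for (i in seq_len(n)) {
    if (mode == "continuous") {
      traj <- simulate_trajectory(Q, s0[i], max(wave_times) + 1e-9)
      idx <- findInterval(wave_times, traj[, "time"])
      states[i, ] <- traj[idx, "state"]
      # true onset: first single-trio state entered from a trio-free state
      if (s0[i] %in% c(1L, 2L)) {
        hit <- which(traj[, "state"] %in% trio_states)
        if (length(hit)) {
          onset_time[i] <- traj[hit[1], "time"]
          onset_type[i] <- sp$trio[traj[hit[1], "state"] - 2L]
        } else {
          onset_type[i] <- "none"
        }
      } else {
        onset_type[i] <- "prevalent"
      }
    } else {
      s <- s0[i]
      states[i, 1] <- s
      for (w in 2:n_waves) {
        s <- sample.int(9, 1, prob = P[s, ])
        states[i, w] <- s
      }
      onset_type[i] <- NA_character_
    }
  }
  prof <- state_profile_matrix(sp)
  nontrio_cols <- setdiff(disease_cols(), tolower(sp$trio))
  nontrio_prev <- config$cross_section_prevalences[toupper(nontrio_cols)]
  entry_age <- pmin(90, pmax(30, rnorm(n, config$entry_age_mean,
                                       config$entry_age_sd)))
  sex <- ifelse(runif(n) < config$prop_female, "female", "male")
  race <- ifelse(runif(n) < 0.955, "white", "non-white")
  bmi0 <- 30 + rgamma(n, shape = 2, scale = 1.5)
  # persistent non-trio disease for anyone who occupies state 2
  nontrio_pick <- sample(nontrio_cols, n, replace = TRUE,
                         prob = nontrio_prev / sum(nontrio_prev))
  id <- sprintf("p%06d", seq_len(n))
  long <- data.frame(
    id = rep(id, each = n_waves),
    wave = rep(seq_len(n_waves) - 1L, n),
    time_years = rep(wave_times, n),
    age = rep(entry_age, each = n_waves) + rep(wave_times, n),
    sex = rep(sex, each = n_waves),
    race = rep(race, each = n_waves),
    bmi = rep(bmi0, each = n_waves) + rnorm(n * n_waves, 0, 0.4),
    stringsAsFactors = FALSE
  )
  st <- as.integer(t(states))
  flags <- prof[st, , drop = FALSE]
  # a participant's non-trio disease switches on at their first state-2 wave
  # and is carried forward (states 3-9 keep it; monotone coding)
  ever2 <- t(apply(states == 2L, 1, cummax)) == 1
  ever2_flat <- as.logical(t(ever2))
  for (col in nontrio_cols) {
    sel <- ever2_flat & rep(nontrio_pick == col, each = n_waves)
    flags[sel, col] <- 1L
  }
  long <- cbind(long, as.data.frame(flags))
  if (config$dropout > 0) {
    drop <- runif(nrow(long)) < config$dropout & long$wave > 0
    long <- long[!drop, , drop = FALSE]
  }
  long <- generate_burden(config, long, setNames(onset_type, id))
  attr(long, "truth") <- list(
    true_Q = Q, onset_type = setNames(onset_type, id),
    onset_time = setNames(onset_time, id),
    states = states, initial_states = s0
  )
  long
}

#' Attach onset-conditional burden outcomes to a panel
#'
#' Binary burdens (depression, work limitation) are Bernoulli draws and the
#' two 5-level ordinals (self-rated health, sleep quality) categorical draws
#' from the onset-type-conditional distributions in the config; participants
#' with no (or unknown) onset draw from the baseline distribution. Outcomes
#' are constant within participant, representing the burden assessment at
#' the end of follow-up.
#'
#' @param config A [synthetic_config()].
#' @param panel Long-format panel rows.
#' @param onsets Named character vector (by participant id) of onset types.
#' @return The panel with `self_rated_health`, `work_limited`,
#'   `sleep_quality`, `depressed` columns.
#' @export
generate_burden <- function(config, panel, onsets) {
  ids <- unique(panel$id)
  ot <- onsets[ids]
  ot[is.na(ot) | !ot %in% names(config$burden_conditionals)] <- "baseline"
  lv <- ordinal_levels()
  srh <- wl <- slp <- dep <- setNames(vector("list", 0), NULL)
  per <- data.frame(id = ids, stringsAsFactors = FALSE)
  per$depressed <- per$work_limited <- NA_integer_
  per$self_rated_health <- per$sleep_quality <- NA_character_
  for (type in unique(ot)) {
    cond <- config$burden_conditionals[[type]]
    sel <- which(ot == type)
    m <- length(sel)
    per$depressed[sel] <- as.integer(runif(m) < cond$depressed)
    per$work_limited[sel] <- as.integer(runif(m) < cond$work_limited)
    per$self_rated_health[sel] <- sample(lv, m, replace = TRUE,
                                         prob = cond$self_rated_health)
    per$sleep_quality[sel] <- sample(lv, m, replace = TRUE, prob = cond$sleep)
  }
  idx <- match(panel$id, per$id)
  panel$self_rated_health <- per$self_rated_health[idx]
  panel$work_limited <- per$work_limited[idx]
  panel$sleep_quality <- per$sleep_quality[idx]
  panel$depressed <- per$depressed[idx]
  panel
}
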