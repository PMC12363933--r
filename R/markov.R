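#' Build a transition-intensity matrix from per-edge rates
#'
#' @param rates Numeric vector of non-negative rates (per year), one per
#'   allowed edge of `state_space` in edge order, or a named vector with
#'   names like `"1->3"`.
#' @param state_space A [build_state_space()] object.
#' @return A 9x9 generator matrix `Q`: off-diagonal entries are the supplied
#'   rates on allowed edges and zero elsewhere; each diagonal entry is the
#'   negated row sum, so rows sum to zero.
#' @export
intensity_matrix <- function(rates, state_space) {
  edges <- state_space$edges
  n <- state_space$n_states
  if (!is.null(names(rates))) {
    key <- paste0(edges[, "from"], "->", edges[, "to"])
    if (!all(key %in% names(rates))) {
      stop("named `rates` must cover every allowed edge: ",
           paste(setdiff(key, names(rates)), collapse = ", "))
    }
    rates <- rates[key]
  }
  if (length(rates) != nrow(edges)) {
    stop("need one rate per allowed edge (", nrow(edges), ")")
  }
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("rates must be finite and non-negative")
  }
  Q <- matrix(0, n, n, dimnames = list(state_space$labels, state_space$labels))
  Q[edges] <- rates
  diag(Q) <- -rowSums(Q)
  Q
}

validate_intensity_matrix <- function(Q, state_space, tol = 1e-8) {
  off <- Q
  diag(off) <- 0
  if (any(off < -tol)) stop("off-diagonal intensities must be >= 0")
  if (any(abs(rowSums(Q)) > tol)) stop("rows of Q must sum to 0")
  if (any(off[!state_space$adjacency] > tol)) {
    stop("Q has positive intensity on a disallowed edge")
  }
  invisible(TRUE)
}

#' Transition-probability matrix at a time horizon
#'
#' Computes `P(t) = expm(Q t)`, the matrix of probabilities of being in each
#' state after `t` years given the current state, under the fitted (or
#' supplied) generator.
#'
#' @param Q A generator matrix or a [fit_intensities()] result.
#' @param t Horizon in years (`t >= 0`).
#' @return A row-stochastic matrix with attribute `horizon`.
#' @examples
#' sp <- build_state_space()
#' Q <- default_intensity_matrix(sp)
#' P5 <- transition_probabilities(Q, 5)
#' rowSums(P5)
#' @export
transition_probabilities <- function(Q, t) {
  if (inherits(Q, "markov_fit")) Q <- Q$Q
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0) {
    stop("`t` must be a single non-negative number of years")
  }
  P <- ctmc_expm_cpp(Q, t)
  dimnames(P) <- dimnames(Q)
  attr(P, "horizon") <- t
  P
}

#' Expected first-passage time to the absorbing state
#'
#' Solves the linear system `(-Q_TT) tau = 1` on the transient states from
#' which the absorbing state is reachable; from the absorbing state the time
#' is 0, and from states that cannot reach it the time is `Inf`.
#'
#' @param Q Generator matrix or [fit_intensities()] result.
#' @param from States to report (default all).
#' @param absorbing Index of the absorbing state (default 9).
#' @return Named numeric vector of expected years.
#' @export
expected_absorption_time <- function(Q, from = NULL, absorbing = 9L) {
  if (inherits(Q, "markov_fit")) Q <- Q$Q
  tau <- as.numeric(absorption_times_cpp(Q, absorbing))
  names(tau) <- rownames(Q) %||% paste0("S", seq_len(nrow(Q)))
  if (is.null(from)) tau else tau[from]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a disease panel to state sequences
#'
#' @param panel A long-format panel data frame (one row per participant per
#'   wave) with `id`, `time_years` and the seven disease flags.
#' @param state_space A [build_state_space()] object.
#' @return Data frame `id`, `time`, `state`, ordered by participant and time.
#' @export
panel_to_states <- function(panel, state_space) {
  need <- c("id", "time_years", disease_cols())
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    id = panel$id,
    time = panel$time_years,
    state = assign_state(panel[disease_cols()], state_space),
    stringsAsFactors = FALSE
  )
  out[order(out$id, out$time), , drop = FALSE]
}

# Internal: turn state sequences into interval-censored sufficient
# statistics (per-interval-length transition-count tables) plus the
# observation design reused by the parametric bootstrap.
panel_intervals <- function(panel_states, state_space) {
  ps <- panel_states[order(panel_states$id, panel_states$time), , drop = FALSE]
  if (any(is.na(ps$state)) || any(!ps$state %in% seq_len(state_space$n_states))) {
    stop("states must be integers in 1..", state_space$n_states)
  }
  n <- nrow(ps)
  same <- ps$id[-1] == ps$id[-n]
  from <- ps$state[-n][same]
  to <- ps$state[-1][same]
  dt <- (ps$time[-1] - ps$time[-n])[same]
  ids <- ps$id[-n][same]
  if (!length(from)) stop("no observation intervals: need >= 2 waves per participant")
  if (any(dt <= 0)) {
    bad <- ids[dt <= 0][1]
    stop("non-increasing observation times for participant ", bad)
  }
  reach <- reachability(state_space$adjacency)
  ok <- reach[cbind(from, to)]
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop("impossible transition for participant ", ids[bad],
         ": state ", from[bad], " -> ", to[bad],
         " has no allowed path (check monotone disease coding)")
  }
  dtr <- round(dt, 9)
  dts <- sort(unique(dtr))
  dt_idx <- match(dtr, dts)
  dt_all <- dts[dt_idx]
  ns <- state_space$n_states
  counts <- array(0, dim = c(ns, ns, length(dts)))
  for (s in seq_along(dts)) {
    sel <- dt_idx == s
    counts[, , s] <- counts[, , s] +
      as.matrix(table(factor(from[sel], levels = 1:ns),
                      factor(to[sel], levels = 1:ns)))
  }
  first_row <- !c(FALSE, ps$id[-1] == ps$id[-n])
  part_ids <- ps$id[first_row]
  init_states <- ps$state[first_row]
  n_int <- as.integer(table(factor(ids, levels = part_ids)))
  offsets <- c(0L, cumsum(n_int))
  keep <- n_int > 0
  list(counts = counts, dts = dts, from = from, to = to, dt_all = dt_all,
       n_participants = sum(keep), n_obs = nrow(ps),
       design = list(init_states = as.integer(init_states[keep]),
                     dt_idx = as.integer(dt_idx),
                     offsets = as.integer(c(0L, cumsum(n_int[keep]))),
                     dts = dts))
}

#' Fit transition intensities to interval-censored panel data
#'
#' Maximum-likelihood estimation of the continuous-time Markov model from
#' states observed only at survey waves. The likelihood of each observed
#' interval is the matrix-exponential entry `[expm(Q dt)]_{s0, s1}`;
#' optimisation is quasi-Newton (BFGS) over unconstrained log-intensities of
#' the allowed edges, with analytic gradients and multiple seeded starts.
#'
#' @param panel_states Data frame `id`, `time`, `state` from
#'   [panel_to_states()], at least two observations per participant.
#' @param state_space A [build_state_space()] object.
#' @param init Optional initial rates (one per edge); default is a crude
#'   events/person-time rate.
#' @param n_starts Number of optimisation starts (first from `init`, the
#'   rest perturbed); default 3.
#' @param maxit,reltol BFGS iteration cap and relative-convergence tolerance
#'   on the log-likelihood.
#' @param seed Optional seed controlling the perturbed starts.
#' @param compute_se If `TRUE`, standard errors of the log-intensities from
#'   the observed information matrix (delta-method transformed to rates).
#' @return Object of class `markov_fit`: `Q`, `rates`, `logr`, `loglik`,
#'   `se_logr`, `se_rates`, `transition_counts` (observed interval pairs per
#'   state pair), `convergence`, `boundary` flags, sample sizes, and the
#'   observation design reused by [compare_absorption_times()].
#' @export
fit_intensities <- function(panel_states, state_space, init = NULL,
                            n_starts = 3, maxit = 500, reltol = 1e-8,
                            seed = NULL, compute_se = TRUE) {
  iv <- panel_intervals(panel_states, state_space)
  edges <- state_space$edges
  ns <- state_space$n_states
  # an edge out of state i carries information iff some observed pair
  # (a, b) has a path through i (reach a -> i and i -> b); the likelihood
  # is exactly flat in the others, which are pinned at ~0 and flagged
  reach <- reachability(state_space$adjacency)
  cp_obs <- apply(iv$counts, c(1, 2), sum)
  obs <- which(cp_obs > 0, arr.ind = TRUE)
  informative <- vapply(seq_len(nrow(edges)), function(k) {
    i <- edges[k, 1]
    any(reach[obs[, 1], i] & reach[i, obs[, 2]])
  }, logical(1))
  if (is.null(init)) {
    # crude per-edge rate: smoothed direct transitions over person-time at risk
    pt <- vapply(seq_len(ns), function(i) sum(iv$dt_all[iv$from == i]),
                 numeric(1))
    n_direct <- table(factor(iv$from, levels = 1:ns),
                      factor(iv$to, levels = 1:ns))
    init <- (n_direct[edges] + 0.5) / (pt[edges[, "from"]] + 1)
  }
  if (length(init) != nrow(edges) || any(init <= 0)) {
    stop("`init` must give a positive rate for each of the ",
         nrow(edges), " allowed edges")
  }
  logr0 <- pmax(pmin(log(init), 5), -10)
  logr0[!informative] <- -20
  if (!is.null(seed)) set.seed(seed)
  starts <- list(logr0)
  if (n_starts > 1) {
    for (k in seq_len(n_starts - 1)) {
      pert <- logr0
      pert[informative] <- pert[informative] +
        rnorm(sum(informative), 0, 0.7)
      starts[[k + 1]] <- pert
    }
  }
  fits <- lapply(starts, function(s) {
    fit_panel_cpp(iv$counts, iv$dts, edges, ns, s, maxit = maxit,
                  reltol = reltol)
  })
  values <- vapply(fits, function(f) f$value, numeric(1))
  best <- fits[[which.min(values)]]
  logr <- as.numeric(best$logr)
  rates <- exp(logr)
  Q <- intensity_matrix(rates, state_space)
  se_logr <- se_rates <- rep(NA_real_, length(logr))
  if (compute_se && any(informative)) {
    # observed information over the informative log-intensities only
    fn_sub <- function(lr) {
      full <- logr
      full[informative] <- lr
      panel_nll_cpp(full, iv$counts, iv$dts, edges, ns)
    }
    gr_sub <- function(lr) {
      full <- logr
      full[informative] <- lr
      panel_nll_grad_cpp(full, iv$counts, iv$dts, edges, ns)[informative]
    }
    H <- tryCatch(optimHess(logr[informative], fn = fn_sub, gr = gr_sub),
                  error = function(e) NULL)
    if (!is.null(H)) {
      cov <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(cov)) {
        d <- diag(cov)
        se_logr[informative] <- ifelse(d > 0, sqrt(d), NA_real_)
        se_rates <- rates * se_logr
      }
    }
  }
  counts_pair <- apply(iv$counts, c(1, 2), sum)
  dimnames(counts_pair) <- list(state_space$labels, state_space$labels)
  edge_counts <- counts_pair[edges]
  structure(
    list(Q = Q, rates = setNames(rates, paste0(edges[, 1], "->", edges[, 2])),
         logr = logr, loglik = -best$value,
         se_logr = se_logr, se_rates = se_rates,
         transition_counts = counts_pair, edge_counts = edge_counts,
         convergence = best$convergence,
         converged = best$convergence == 0,
         boundary = rates < 1e-5 | !informative,
         no_information = !informative,
         n_participants = iv$n_participants, n_obs = iv$n_obs,
         n_intervals = length(iv$from),
         state_space = state_space, design = iv$design,
         counts = iv$counts, dts = iv$dts),
    class = "markov_fit"
  )
}

#' @export
print.markov_fit <- function(x, ...) {
  cat("Interval-censored CTMC fit:", x$n_participants, "participants,",
      x$n_obs, "person-observations,", x$n_intervals, "intervals\n")
  cat("log-likelihood:", format(x$loglik, digits = 8),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  tab <- data.frame(edge = names(x$rates), rate = round(x$rates, 5),
                    se = round(x$se_rates, 5), n_pairs = x$edge_counts,
                    boundary = x$boundary)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Compare expected progression times to triple comorbidity by start state
#'
#' Parametric bootstrap: panels are re-simulated under the fitted generator
#' on the observed design (same initial states and observation grids), the
#' model is refitted to each, and expected first-passage times to the
#' absorbing state are recomputed. The bootstrap distribution yields
#' percentile confidence intervals, a global Wald chi-square test of
#' equality of the log expected times across start states, and
#' Bonferroni-adjusted pairwise contrasts.
#'
#' @param fit A converged [fit_intensities()] result.
#' @param start_states States to compare (default 3:5, the single trio
#'   diseases).
#' @param n_boot Number of bootstrap replicates (>= 1; >= 200 recommended).
#' @param seed Optional seed for reproducibility.
#' @param max_fail_frac Abort if more than this fraction of bootstrap refits
#'   fail to converge or give non-finite times.
#' @return Object of class `absorption_comparison` with elements `table`
#'   (expected years and percentile CIs per start state), `global`
#'   (chi-square statistic, df, p-value), `pairwise` (differences and raw /
#'   Bonferroni p-values), `n_boot`, `n_fail`, and `method`.
#' @export
compare_absorption_times <- function(fit, start_states = 3:5, n_boot = 500,
                                     seed = NULL, max_fail_frac = 0.2) {
  if (!inherits(fit, "markov_fit")) stop("`fit` must be a markov_fit")
  if (!is.numeric(n_boot) || length(n_boot) != 1 || n_boot < 1) {
    stop("`n_boot` must be a positive integer")
  }
  if (!fit$converged) stop("fit did not converge; refusing to bootstrap")
  k <- length(start_states)
  if (k < 2) stop("need at least two start states to compare")
  sp <- fit$state_space
  if (!is.null(seed)) set.seed(seed)
  tau_obs <- expected_absorption_time(fit$Q, absorbing = sp$absorbing)
  tau_obs <- tau_obs[start_states]
  boot <- parboot_tau_cpp(fit$logr, sp$edges, sp$n_states, fit$design$dts,
                          fit$design$init_states, fit$design$dt_idx,
                          fit$design$offsets, as.integer(n_boot),
                          as.integer(start_states),
                          as.integer(sp$absorbing))
  tau_boot <- boot$tau
  finite <- apply(is.finite(tau_boot) & tau_boot > 0, 1, all)
  conv_ok <- boot$convergence == 0
  use <- finite & conv_ok
  n_fail <- sum(!use)
  if (n_fail / n_boot > max_fail_frac) {
    stop("parametric bootstrap unstable: ", n_fail, "/", n_boot,
         " replicates failed (non-convergence or unreachable absorbing state)")
  }
  tb <- tau_boot[use, , drop = FALSE]
  lt_obs <- log(tau_obs)
  lt_boot <- log(tb)
  A <- cbind(-1, diag(1, k - 1))  # contrasts vs the first start state
  d <- as.numeric(A %*% lt_obs)
  S <- A %*% stats::cov(lt_boot) %*% t(A)
  W <- tryCatch(drop(t(d) %*% solve(S, d)), error = function(e) NA_real_)
  p_global <- if (is.finite(W)) pchisq(W, df = k - 1, lower.tail = FALSE) else NA_real_
  pairs <- combn(seq_len(k), 2)
  n_pairs <- ncol(pairs)
  pw <- data.frame(
    state_a = start_states[pairs[1, ]],
    state_b = start_states[pairs[2, ]],
    difference_years = tau_obs[pairs[1, ]] - tau_obs[pairs[2, ]]
  )
  pw$z <- pw$p_value <- NA_real_
  for (m in seq_len(n_pairs)) {
    dd <- lt_boot[, pairs[1, m]] - lt_boot[, pairs[2, m]]
    se <- sd(dd)
    z <- (lt_obs[pairs[1, m]] - lt_obs[pairs[2, m]]) / se
    pw$z[m] <- z
    pw$p_value[m] <- 2 * pnorm(-abs(z))
  }
  pw$p_bonferroni <- pmin(1, pw$p_value * n_pairs)
  ci <- apply(tb, 2, quantile, probs = c(0.025, 0.975))
  tab <- data.frame(
    state = start_states,
    label = sp$labels[start_states],
    expected_years = as.numeric(tau_obs),
    ci_lower = ci[1, ], ci_upper = ci[2, ],
    row.names = NULL
  )
  structure(
    list(table = tab,
         global = list(statistic = W, df = k - 1, p_value = p_global),
         pairwise = pw, n_boot = n_boot, n_fail = n_fail,
         method = paste("parametric bootstrap (refit under the fitted",
                        "generator on the observed design); Wald chi-square",
                        "on log expected first-passage times")),
    class = "absorption_comparison"
  )
}

#' @export
print.absorption_comparison <- function(x, ...) {
  cat("Expected years to triple comorbidity (", x$n_boot, " bootstrap reps, ",
      x$n_fail, " failed)\n", sep = "")
  print(transform(x$table, expected_years = round(expected_years, 2),
                  ci_lower = round(ci_lower, 2), ci_upper = round(ci_upper, 2)),
        row.names = FALSE)
  cat(sprintf("Global test: chi-square = %.3f, df = %d, p = %.4g\n",
              x$global$statistic, x$global$df, x$global$p_value))
  pw <- x$pairwise
  for (m in seq_len(nrow(pw))) {
    cat(sprintf("  S%d vs S%d: diff = %+.2f y, p = %.4g (Bonferroni %.4g)\n",
                pw$state_a[m], pw$state_b[m], pw$difference_years[m],
                pw$p_value[m], pw$p_bonferroni[m]))
  }
  cat("Method:", x$method, "\n")
  invisible(x)
}
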