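#' Identify each participant's onset disease
#'
#' The onset is the single trio disease present at the first wave where any
#' trio component appears, provided an earlier trio-free wave was observed.
#' Participants already holding a trio component at their first observed
#' wave, or acquiring two or more components between consecutive waves, are
#' `ambiguous`; participants never observed with a trio component are
#' `none`.
#'
#' @param panel_states Data frame `id`, `time`, `state` from
#'   [panel_to_states()] (monotone-coded states).
#' @param state_space A [build_state_space()] object.
#' @return Data frame `id`, `onset_type` (`CVD`/`MTD`/`SMD` labels from the
#'   trio, `none`, or `ambiguous`), `onset_wave` (index of the wave where
#'   onset was observed, `NA` otherwise).
#' @export
identify_onset <- function(panel_states, state_space) {
  ps <- panel_states[order(panel_states$id, panel_states$time), , drop = FALSE]
  ids <- unique(ps$id)
  trio <- state_space$trio
  res <- data.frame(id = ids, onset_type = NA_character_,
                    onset_wave = NA_integer_, stringsAsFactors = FALSE)
  state_list <- split(ps$state, factor(ps$id, levels = ids))
  for (i in seq_along(ids)) {
    st <- state_list[[i]]
    has_trio <- st >= 3L
    if (!any(has_trio)) {
      res$onset_type[i] <- "none"
      next
    }
    w <- which(has_trio)[1]
    if (w == 1L) {
      res$onset_type[i] <- "ambiguous"  # prevalent at entry
      next
    }
    s <- st[w]
    if (s %in% 3:5) {
      res$onset_type[i] <- trio[s - 2L]
      res$onset_wave[i] <- w
    } else {
      res$onset_type[i] <- "ambiguous"  # two+ components appeared at once
    }
  }
  res
}

adverse_levels_default <- c("fair", "poor")

#' Tabulate health burden by onset disease
#'
#' Burden is assessed at each participant's last observed wave. Binary
#' measures (depression, work limitation) are summarised as prevalences;
#' the 5-level ordinals are collapsed to adverse vs not (default adverse =
#' \{fair, poor\}) and summarised as adverse prevalence. Participants with
#' `none` or `ambiguous` onset are excluded.
#'
#' @param panel Long-format panel with burden columns.
#' @param onsets Result of [identify_onset()].
#' @param adverse_levels Ordinal levels counted as adverse.
#' @param assess `"last"` (default) or `"onset"`: wave at which burden is
#'   read.
#' @return Object of class `burden_table`: `prevalence` (long data frame of
#'   per-group prevalences), `tests` (per measure: statistic, df, p-value,
#'   test name, low-expected-count flag), `n` per group.
#' @export
burden_by_onset <- function(panel, onsets,
                            adverse_levels = adverse_levels_default,
                            assess = c("last", "onset")) {
  assess <- match.arg(assess)
  keep <- onsets$id[!onsets$onset_type %in% c("none", "ambiguous") &
                      !is.na(onsets$onset_type)]
  if (length(unique(onsets$onset_type[onsets$id %in% keep])) < 2) {
    stop("need at least two non-empty onset groups")
  }
  panel <- panel[panel$id %in% keep, , drop = FALSE]
  panel <- panel[order(panel$id, panel$wave), , drop = FALSE]
  rec <- if (assess == "last") {
    panel[!duplicated(panel$id, fromLast = TRUE), , drop = FALSE]
  } else {
    ow <- setNames(onsets$onset_wave, onsets$id)
    sel <- unlist(lapply(split(seq_len(nrow(panel)), panel$id), function(ix) {
      w <- ow[panel$id[ix[1]]]
      ix[min(length(ix), max(1, w, na.rm = TRUE))]
    }), use.names = FALSE)
    panel[sel, , drop = FALSE]
  }
  rec$onset <- onsets$onset_type[match(rec$id, onsets$id)]
  rec$poor_sleep <- as.integer(rec$sleep_quality %in% adverse_levels)
  rec$poor_health <- as.integer(rec$self_rated_health %in% adverse_levels)
  measures <- c(depressed = "depression",
                work_limited = "work limitation",
                poor_sleep = "poor or fair sleep quality",
                poor_health = "poor or fair self-rated health")
  groups <- sort(unique(rec$onset))
  prev <- do.call(rbind, lapply(names(measures), function(mcol) {
    data.frame(measure = measures[[mcol]], onset = groups,
               n = as.integer(table(rec$onset)[groups]),
               prevalence = vapply(groups, function(g)
                 mean(rec[[mcol]][rec$onset == g], na.rm = TRUE), numeric(1)),
               row.names = NULL)
  }))
  tests <- do.call(rbind, lapply(names(measures), function(mcol) {
    tab <- table(rec$onset, rec[[mcol]])
    tst <- test_burden(tab)
    data.frame(measure = measures[[mcol]], statistic = tst$statistic,
               df = tst$df, p_value = tst$p_value, test = tst$test,
               low_expected = tst$low_expected, row.names = NULL)
  }))
  structure(list(prevalence = prev, tests = tests,
                 n = table(rec$onset), assess = assess,
                 adverse_levels = adverse_levels),
            class = "burden_table")
}

#' @export
print.burden_table <- function(x, ...) {
  cat("Health burden by onset disease (assessed at", x$assess, "wave)\n")
  wide <- stats::reshape(x$prevalence[c("measure", "onset", "prevalence")],
                         direction = "wide", idvar = "measure",
                         timevar = "onset")
  names(wide) <- sub("prevalence\\.", "", names(wide))
  wide[-1] <- lapply(wide[-1], function(p) sprintf("%.1f%%", 100 * p))
  print(merge(wide, x$tests[c("measure", "statistic", "df", "p_value")],
              by = "measure"), row.names = FALSE)
  invisible(x)
}

#' Chi-square / ANOVA test of a burden measure across onset groups
#'
#' Categorical measures (contingency table input) are tested with Pearson's
#' chi-square without continuity correction; continuous measures (a list of
#' numeric group vectors) with one-way ANOVA.
#'
#' @param x A contingency table/matrix (groups x categories) or a list of
#'   numeric vectors.
#' @return List `statistic`, `df` (numeric; length 2 for ANOVA), `p_value`,
#'   `test`, `low_expected` (any expected cell below 1).
#' @examples
#' test_burden(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))   # 6.667, df 1
#' test_burden(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))     # F = 3, df 2, 6
#' @export
test_burden <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    if (length(x) < 2) stop("need at least two groups")
    values <- unlist(x, use.names = FALSE)
    g <- factor(rep(seq_along(x), lengths(x)))
    fit <- aov(values ~ g)
    s <- summary(fit)[[1]]
    list(statistic = s$`F value`[1], df = s$Df,
         p_value = s$`Pr(>F)`[1], test = "one-way ANOVA",
         low_expected = FALSE)
  } else {
    tab <- as.matrix(x)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                  test = "Pearson chi-square", low_expected = TRUE))
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    low <- any(expected < 1)
    if (low) warning("expected cell count below 1; chi-square unreliable")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value, test = "Pearson chi-square",
         low_expected = low)
  }
}
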