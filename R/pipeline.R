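#' Load a run configuration from YAML or JSON
#'
#' Scalar fields mirror [synthetic_config()] / [run_pipeline()] arguments;
#' `true_Q` may be given as a named `rates` map (`"1->3": 0.028`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of settings.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

config_from_list <- function(lst) {
  args <- lst[intersect(names(lst), names(formals(synthetic_config)))]
  if (!is.null(lst$rates)) {
    sp <- build_state_space(lst$trio %||% c("CVD", "MTD", "SMD"))
    args$true_Q <- intensity_matrix(unlist(lst$rates), sp)
  }
  do.call(synthetic_config, args)
}

#' Run the full comorbidity-trajectory pipeline
#'
#' Stages, mirroring the analysis plan: simulate (or read) the panel and
#' cross-section; obesity filter and sample construction; descriptive
#' summaries; Apriori pattern mining and trio selection; nine-state
#' intensity fitting on the longitudinal sample; transition-probability
#' matrices at the requested horizons; bootstrap comparison of expected
#' progression times to triple comorbidity by onset state; burden tables
#' and tests by onset disease. All stage outputs, a reproducibility
#' manifest and a human-readable report are written under `out_dir`.
#'
#' @param config A [synthetic_config()] (data are simulated) or a list with
#'   `input` (path to a panel CSV) plus optional settings.
#' @param out_dir Output directory (created); `NULL` skips writing.
#' @param obesity_threshold BMI cut-off (default 30).
#' @param min_support,min_confidence Apriori thresholds (defaults 0.005,
#'   0.07).
#' @param horizons Transition-probability horizons in years (default 5, 10,
#'   20).
#' @param trio Override the mined trio (default `NULL`: auto-select).
#' @param n_boot Bootstrap replicates for the progression-time comparison.
#' @param seed Seed for every stochastic stage (default: `config$seed`).
#' @param quiet Suppress progress messages.
#' @return Object of class `morbiditrail_run` with every stage result.
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir = NULL,
                         obesity_threshold = 30, min_support = 0.005,
                         min_confidence = 0.07, horizons = c(5, 10, 20),
                         trio = NULL, n_boot = 200, seed = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message("[morbiditrail] ", ...)
  synthetic <- inherits(config, "synthetic_config")
  if (!synthetic) {
    if (is.null(config$input)) stop("config must be a synthetic_config or name an `input` panel CSV")
    if (!file.exists(config$input)) stop("input file not found: ", config$input)
  }
  if (is.null(seed)) seed <- config$seed %||% 1L
  set.seed(seed)
  if (synthetic) {
    say("simulating cross-section (n=", config$n_cross_section,
        ") and panel (n=", config$n_participants, ")")
    cross <- generate_cross_section(config)
    panel <- generate_panel(config)
  } else {
    say("reading panel from ", config$input)
    panel <- read_panel(config$input)
    cross <- NULL
  }
  validate_panel(panel)
  panel <- carry_forward_diseases(panel)
  panel <- filter_obese(panel, threshold = obesity_threshold)
  independent <- build_independent_sample(panel)
  longitudinal <- build_longitudinal_sample(panel)
  if (is.null(cross)) {
    cross <- independent
    names(cross)[match(disease_cols(), names(cross))] <- DISEASE_SYSTEMS
    if (!"age_band" %in% names(cross)) cross$age_band <- age_band(cross$age)
  }
  say("summarising cohort (", nrow(independent), " independent, ",
      attr(longitudinal, "n_person_observations"), " person-observations)")
  summaries <- list(
    independent = summarize_cohort(independent),
    followup = followup_summary(longitudinal)
  )
  say("mining patterns (min_support=", min_support,
      ", min_confidence=", min_confidence, ")")
  itemsets <- mine_frequent_itemsets(cross, min_support = min_support)
  rules <- generate_rules(itemsets, cross, min_confidence = min_confidence)
  patterns <- list(
    overall = stratified_patterns(cross, "overall", min_support),
    sex = stratified_patterns(cross, "sex", min_support),
    age = stratified_patterns(cross, "age_band", min_support)
  )
  trio_used <- if (is.null(trio)) select_trio(cross, min_support) else toupper(trio)
  say("trio: ", paste(trio_used, collapse = "-"))
  sp <- build_state_space(trio_used)
  states <- panel_to_states(longitudinal, sp)
  say("fitting transition intensities")
  fit <- fit_intensities(states, sp, seed = seed + 1L)
  P <- lapply(horizons, function(t) transition_probabilities(fit, t))
  names(P) <- paste0("P", horizons)
  say("bootstrap comparison of progression times (n_boot=", n_boot, ")")
  comparison <- compare_absorption_times(fit, 3:5, n_boot = n_boot,
                                         seed = seed + 2L)
  say("burden analysis")
  onsets <- identify_onset(states, sp)
  # report observed onsets under trio disease names
  burden <- burden_by_onset(longitudinal, onsets)
  run <- structure(
    list(config = config, trio = trio_used, state_space = sp,
         panel = panel, independent = independent,
         longitudinal = longitudinal, cross_section = cross,
         summaries = summaries, itemsets = itemsets, rules = rules,
         patterns = patterns, fit = fit, transition_matrices = P,
         comparison = comparison, onsets = onsets, burden = burden,
         seed = seed, horizons = horizons,
         n_boot = n_boot),
    class = "morbiditrail_run")
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

# First/last follow-up summary of the longitudinal sample. Each wave
# stratum covers every participant, so the stratum n IS the full
# longitudinal sample size and percentages are shares of the whole cohort.
followup_summary <- function(longitudinal) {
  first <- longitudinal[!duplicated(longitudinal$id), , drop = FALSE]
  last <- longitudinal[!duplicated(longitudinal$id, fromLast = TRUE), ,
                       drop = FALSE]
  both <- rbind(transform(first, .fu = "first"), transform(last, .fu = "last"))
  summarize_cohort(both, stratify_by = ".fu", denominator = "stratum")
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "summary"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "rules"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "fit"), showWarnings = FALSE)
  write.csv(run$panel, file.path(out_dir, "panel.csv"), row.names = FALSE)
  write.csv(run$summaries$independent,
            file.path(out_dir, "summary", "independent.csv"), row.names = FALSE)
  write.csv(run$summaries$followup,
            file.path(out_dir, "summary", "followup.csv"), row.names = FALSE)
  write.csv(run$rules, file.path(out_dir, "rules", "rules.csv"),
            row.names = FALSE)
  for (nm in names(run$patterns)) {
    write.csv(run$patterns[[nm]],
              file.path(out_dir, "rules", paste0("patterns_", nm, ".csv")),
              row.names = FALSE)
  }
  edges <- run$state_space$edges
  qdf <- data.frame(from = edges[, 1], to = edges[, 2],
                    rate = as.numeric(run$fit$rates),
                    se = run$fit$se_rates, n_pairs = run$fit$edge_counts)
  write.csv(qdf, file.path(out_dir, "fit", "intensities.csv"),
            row.names = FALSE)
  for (nm in names(run$transition_matrices)) {
    write.csv(run$transition_matrices[[nm]],
              file.path(out_dir, "fit", paste0(nm, ".csv")))
  }
  write.csv(run$comparison$table, file.path(out_dir, "fit",
                                            "absorption_times.csv"),
            row.names = FALSE)
  write.csv(run$comparison$pairwise, file.path(out_dir, "fit",
                                               "absorption_contrasts.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(loglik = run$fit$loglik, converged = run$fit$converged,
         n_participants = run$fit$n_participants, n_obs = run$fit$n_obs,
         n_intervals = run$fit$n_intervals,
         global_test = run$comparison$global),
    file.path(out_dir, "fit", "fit_report.json"), auto_unbox = TRUE,
    digits = NA)
  write.csv(merge(run$burden$prevalence, run$burden$tests, by = "measure"),
            file.path(out_dir, "burden.csv"), row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("morbiditrail")),
    r_version = as.character(getRversion()),
    seed = run$seed, n_boot = run$n_boot, horizons = run$horizons,
    trio = run$trio,
    adjacency = apply(run$state_space$adjacency, 1, as.integer),
    synthetic = inherits(run$config, "synthetic_config"),
    config_hash = config_hash(run$config)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(render_report(run), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)
  unname(tools::md5sum(tmp))
}

render_report <- function(run) {
  tau <- run$comparison$table
  ord <- tau[order(tau$expected_years), ]
  c(
    "# Comorbidity trajectory report",
    "",
    sprintf("- Independent sample: %d participants; longitudinal sample: %d participants, %d person-observations.",
            nrow(run$independent), run$fit$n_participants, run$fit$n_obs),
    sprintf("- Selected trio: %s.", paste(run$trio, collapse = "-")),
    sprintf("- Log-likelihood at the optimum: %.2f (%s).", run$fit$loglik,
            if (run$fit$converged) "converged" else "not converged"),
    "",
    "## Expected years to triple comorbidity",
    "",
    sprintf("- %s: %.2f years (95%% CI %.2f-%.2f)", ord$label,
            ord$expected_years, ord$ci_lower, ord$ci_upper),
    sprintf("- Fastest onset path: %s.", ord$label[1]),
    sprintf("- Global equality test: chi-square = %.2f, df = %d, p = %.3g.",
            run$comparison$global$statistic, run$comparison$global$df,
            run$comparison$global$p_value),
    "",
    "## Health burden by onset",
    "",
    vapply(unique(run$burden$prevalence$measure), function(m) {
      sub <- run$burden$prevalence[run$burden$prevalence$measure == m, ]
      worst <- sub[which.max(sub$prevalence), ]
      sprintf("- %s: highest in %s onset (%.1f%%).", m, worst$onset,
              100 * worst$prevalence)
    }, character(1))
  )
}

#' @export
print.morbiditrail_run <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
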