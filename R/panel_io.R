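#' Default mapping from reported conditions to the seven disease systems
#'
#' ICD-11-oriented grouping: cardiovascular (CVD), metabolic (MTD),
#' respiratory (RPD), skeletal-muscular (SMD), neurological (NRD), mental
#' disorders (MD) and cancer (CC).
#'
#' @return Data frame with columns `condition`, `group`.
#' @export
default_condition_mapping <- function() {
  groups <- list(
    CVD = c("heart disease", "angina", "hypertension", "varicose veins",
            "thrombosis", "heart failure", "heart murmur", "arrhythmia"),
    MTD = c("high cholesterol", "high blood glucose", "diabetes",
            "abnormal endocrine metabolism"),
    RPD = c("bronchitis", "emphysema", "asthma", "hay fever", "lung disease",
            "respiratory ailment"),
    SMD = c("arthritis", "rheumatism", "fibromyalgia", "slipped disc", "gout",
            "back problem", "spine problem", "neck problem", "joint problem",
            "muscle problem"),
    NRD = c("epilepsy", "migraine", "stroke", "cerebral hemorrhage",
            "parkinson's disease", "alzheimer's disease", "dementia",
            "multiple sclerosis", "motor neuron disease"),
    MD = c("mental illness", "psychiatric disorder", "anxiety"),
    CC = c("cancer")
  )
  data.frame(
    condition = unlist(groups, use.names = FALSE),
    group = rep(names(groups), lengths(groups)),
    stringsAsFactors = FALSE
  )
}

#' Map reported condition labels to a disease-system profile
#'
#' A system flag is 1 iff at least one member condition is reported, so the
#' mapping is monotone: adding a condition never clears a flag.
#'
#' @param condition_labels Character vector (or list-like set) of reported
#'   condition strings; matching is case-insensitive after trimming.
#' @param mapping Two-column data frame `condition`, `group` (default
#'   [default_condition_mapping()]).
#' @param unknown `"warn"` (default) to warn and drop unknown labels, or
#'   `"error"` to fail.
#' @return Named integer vector `cvd, mtd, rpd, smd, nrd, md, cc` of 0/1
#'   flags.
#' @examples
#' map_conditions_to_profile(c("angina", "diabetes"))
#' @export
map_conditions_to_profile <- function(condition_labels,
                                      mapping = default_condition_mapping(),
                                      unknown = c("warn", "error")) {
  unknown <- match.arg(unknown)
  profile <- setNames(integer(7), disease_cols())
  labels <- tolower(trimws(as.character(unlist(condition_labels))))
  labels <- labels[nzchar(labels)]
  if (!length(labels)) return(profile)
  idx <- match(labels, tolower(mapping$condition))
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    msg <- paste("unknown condition label(s):", paste(bad, collapse = ", "))
    if (unknown == "error") stop(msg)
    warning(msg, " - excluded")
  }
  hit <- tolower(mapping$group[idx[!is.na(idx)]])
  profile[unique(hit)] <- 1L
  profile
}

#' Read a long-format panel CSV
#'
#' Expects UTF-8, comma-separated, header row; missing values as empty
#' string or `NA`. Required columns: `id`, `wave`, `time_years`, `age`,
#' `sex`, `race`, `bmi` and the seven 0/1 disease flags; burden columns
#' (`self_rated_health`, `work_limited`, `sleep_quality`, `depressed`) are
#' optional.
#'
#' @param path CSV file path.
#' @param validate Run [validate_panel()] (default `TRUE`).
#' @return Panel data frame ordered by participant and wave.
#' @export
read_panel <- function(path, validate = TRUE) {
  panel <- read.csv(path, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"), fileEncoding = "UTF-8")
  if (validate) validate_panel(panel)
  panel[order(panel$id, panel$wave), , drop = FALSE]
}

#' Validate a panel data frame
#'
#' Checks required columns, strictly increasing waves and times within
#' participant, positive BMI where present, and 0/1 disease flags.
#'
#' @param panel Panel data frame.
#' @return The panel, invisibly; errors describe the first offending
#'   participant.
#' @export
validate_panel <- function(panel) {
  need <- c("id", "wave", "time_years", "bmi", disease_cols())
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  flags <- as.matrix(panel[disease_cols()])
  if (any(!flags %in% c(0, 1, NA))) stop("disease flags must be 0/1")
  if (any(panel$bmi <= 0, na.rm = TRUE)) stop("bmi must be positive")
  ord <- order(panel$id, panel$wave)
  p <- panel[ord, ]
  same <- p$id[-1] == p$id[-nrow(p)]
  if (any(same & diff(p$wave) <= 0)) {
    bad <- p$id[-1][same & diff(p$wave) <= 0][1]
    stop("waves not strictly increasing for participant ", bad)
  }
  if (any(same & diff(p$time_years) <= 0)) {
    bad <- p$id[-1][same & diff(p$time_years) <= 0][1]
    stop("time_years not strictly increasing for participant ", bad)
  }
  invisible(panel)
}

#' Carry disease indicators forward within participant
#'
#' Chronic conditions are reported as ever-diagnosed, and the progression
#' model has no backward arrows, so once a flag is 1 it stays 1 at later
#' waves (running maximum within participant).
#'
#' @param panel Panel data frame.
#' @param diseases Columns to code monotonically (default all seven).
#' @return The panel with monotone flags.
#' @export
carry_forward_diseases <- function(panel, diseases = disease_cols()) {
  panel <- panel[order(panel$id, panel$wave), , drop = FALSE]
  for (col in diseases) {
    panel[[col]] <- as.integer(
      unlist(tapply(panel[[col]], panel$id, cummax, simplify = FALSE)
             [unique(panel$id)], use.names = FALSE))
  }
  panel
}

#' Restrict a panel to obese participants
#'
#' A participant qualifies when their qualifying BMI is at or above the
#' threshold; all of a qualifying participant's waves are retained.
#' Participants with no BMI measurement at any wave are excluded and logged.
#'
#' @param panel Panel data frame.
#' @param threshold BMI cut-off in kg/m^2 (default 30, inclusive).
#' @param rule `"first"` (default): classify once at the first non-missing
#'   BMI; `"any"`: qualify if any wave's BMI meets the threshold.
#' @return The filtered panel; attribute `excluded_no_bmi` lists dropped
#'   participants without any BMI.
#' @export
filter_obese <- function(panel, threshold = 30, rule = c("first", "any")) {
  rule <- match.arg(rule)
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  panel <- panel[order(panel$id, panel$wave), , drop = FALSE]
  qual <- tapply(panel$bmi, factor(panel$id, levels = unique(panel$id)),
                 function(b) {
                   b <- b[!is.na(b)]
                   if (!length(b)) return(NA)
                   if (rule == "first") b[1] >= threshold else any(b >= threshold)
                 })
  no_bmi <- names(qual)[is.na(qual)]
  if (length(no_bmi)) {
    message(length(no_bmi), " participant(s) excluded: no BMI at any wave")
  }
  keep_ids <- names(qual)[!is.na(qual) & qual]
  out <- panel[panel$id %in% keep_ids, , drop = FALSE]
  attr(out, "excluded_no_bmi") <- no_bmi
  out
}

#' Cross-sectional (independent) sample: last observation per participant
#'
#' @param panel Panel data frame.
#' @return One row per participant — the last available wave.
#' @export
build_independent_sample <- function(panel) {
  if (!nrow(panel)) return(panel)
  panel <- panel[order(panel$id, panel$wave), , drop = FALSE]
  last <- !duplicated(panel$id, fromLast = TRUE)
  panel[last, , drop = FALSE]
}

#' Longitudinal sample: participants with at least two complete records
#'
#' @param panel Panel data frame.
#' @param required_fields Columns that must be non-missing for a record to
#'   count as complete (default: id, timing, BMI and the disease flags).
#' @return The retained complete records; attributes `n_participants` and
#'   `n_person_observations` give the sample sizes.
#' @export
build_longitudinal_sample <- function(panel,
                                      required_fields = c("id", "wave",
                                                          "time_years", "bmi",
                                                          disease_cols())) {
  missing_cols <- setdiff(required_fields, names(panel))
  if (length(missing_cols)) {
    stop("required fields absent from panel: ",
         paste(missing_cols, collapse = ", "))
  }
  complete <- complete.cases(panel[required_fields])
  kept <- panel[complete, , drop = FALSE]
  tab <- table(kept$id)
  keep_ids <- names(tab)[tab >= 2]
  out <- kept[kept$id %in% keep_ids, , drop = FALSE]
  attr(out, "n_participants") <- length(keep_ids)
  attr(out, "n_person_observations") <- nrow(out)
  out
}

comorbidity_band <- function(counts) {
  factor(ifelse(counts >= 3, "3+", as.character(counts)),
         levels = c("0", "1", "2", "3+"))
}

#' Stratified descriptive summary of a cohort
#'
#' Continuous variables are summarised as mean and SD, categorical variables
#' as count and percentage. Strata are comorbidity-count bands (0 / 1 / 2 /
#' 3+) or any grouping column. Percentages use the stratum n as denominator
#' by default; with `denominator = "total"` they use the full sample n
#' (follow-up-style tables where strata partition the same cohort).
#'
#' @param records One-row-per-participant data frame with the disease flags.
#' @param stratify_by `"comorbidity"` (default) or the name of a column.
#' @param continuous Continuous variables to summarise.
#' @param categorical Categorical variables to summarise (the comorbidity
#'   band is always included).
#' @param denominator `"stratum"` or `"total"`.
#' @return Long data frame: `stratum`, `n`, `variable`, `level`, `count`,
#'   `pct`, `mean`, `sd`; empty strata appear with `n = 0` and no
#'   percentages.
#' @export
summarize_cohort <- function(records, stratify_by = "comorbidity",
                             continuous = intersect(c("age", "bmi"),
                                                    names(records)),
                             categorical = intersect(c("sex", "race"),
                                                     names(records)),
                             denominator = c("stratum", "total")) {
  denominator <- match.arg(denominator)
  if (!nrow(records)) stop("records must be non-empty")
  ncom <- rowSums(records[disease_cols()])
  records$.band <- comorbidity_band(ncom)
  strat <- if (identical(stratify_by, "comorbidity")) {
    records$.band
  } else {
    factor(records[[stratify_by]])
  }
  total_n <- nrow(records)
  out <- list()
  for (s in levels(strat)) {
    sub <- records[which(strat == s), , drop = FALSE]
    n <- nrow(sub)
    out[[length(out) + 1]] <- data.frame(
      stratum = s, n = n, variable = "n", level = NA, count = n,
      pct = NA_real_, mean = NA_real_, sd = NA_real_)
    if (n == 0) next
    denom <- if (denominator == "stratum") n else total_n
    for (v in continuous) {
      out[[length(out) + 1]] <- data.frame(
        stratum = s, n = n, variable = v, level = NA, count = NA_integer_,
        pct = NA_real_, mean = mean(sub[[v]], na.rm = TRUE),
        sd = sd(sub[[v]], na.rm = TRUE))
    }
    cats <- unique(c(categorical,
                     if (!identical(stratify_by, "comorbidity")) ".band"))
    for (v in cats) {
      tab <- table(sub[[v]])
      out[[length(out) + 1]] <- data.frame(
        stratum = s, n = n, variable = ifelse(v == ".band", "comorbidity", v),
        level = names(tab), count = as.integer(tab),
        pct = 100 * as.integer(tab) / denom, mean = NA_real_, sd = NA_real_)
    }
    for (v in disease_cols()) {
      cnt <- sum(sub[[v]], na.rm = TRUE)
      out[[length(out) + 1]] <- data.frame(
        stratum = s, n = n, variable = toupper(v), level = "present",
        count = cnt, pct = 100 * cnt / denom, mean = NA_real_, sd = NA_real_)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
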