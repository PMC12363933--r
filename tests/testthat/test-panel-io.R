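test_that("condition labels map to disease-system flags", {
  p <- map_conditions_to_profile(c("angina", "diabetes"))
  expect_identical(p, profile_vec("cvd", "mtd"))
  expect_identical(map_conditions_to_profile(character(0)), profile_vec())
  p3 <- map_conditions_to_profile(c("gout", "migraine", "asthma"))
  expect_identical(p3, profile_vec("smd", "nrd", "rpd"))
})

test_that("unknown condition labels warn (or error) and are excluded", {
  expect_warning(p <- map_conditions_to_profile(c("angina", "zzz")),
                 "unknown")
  expect_identical(p, profile_vec("cvd"))
  expect_error(map_conditions_to_profile("zzz", unknown = "error"), "unknown")
})

test_that("condition mapping is monotone: adding a condition never clears a flag", {
  conds <- default_condition_mapping()$condition
  set.seed(11)
  for (r in 1:25) {
    base <- sample(conds, sample(0:5, 1))
    extra <- sample(conds, 1)
    p1 <- map_conditions_to_profile(base)
    p2 <- map_conditions_to_profile(c(base, extra))
    expect_true(all(p2 >= p1))
  }
})

test_that("obesity filter keeps BMI >= threshold at first measurement", {
  p <- rbind(make_panel("a", 0:2, bmi = c(31.2, 28, 27)),
             make_panel("b", 0:1, bmi = c(30.0, 35)),
             make_panel("c", 0:1, bmi = c(29.9, 35)),
             make_panel("d", 0:1, bmi = NA_real_))
  expect_message(out <- filter_obese(p), "excluded")
  expect_setequal(unique(out$id), c("a", "b"))       # 30.0 retained: >=, not >
  expect_equal(sum(out$id == "a"), 3)                # all waves kept
  expect_identical(attr(out, "excluded_no_bmi"), "d")
  any_rule <- filter_obese(p, rule = "any")
  expect_true("c" %in% any_rule$id)
})

test_that("independent sample takes the last available wave per participant", {
  p <- rbind(make_panel("a", c(2, 4, 6)), make_panel("b", 3))
  ind <- build_independent_sample(p)
  expect_equal(nrow(ind), 2)
  expect_equal(ind$wave[ind$id == "a"], 6)
  expect_equal(nrow(build_independent_sample(p[0, ])), 0)
  # output size equals the number of distinct participants
  expect_equal(nrow(ind), length(unique(p$id)))
})

test_that("longitudinal sample keeps participants with >= 2 complete records", {
  p <- rbind(make_panel("a", 0), make_panel("b", 0:1), make_panel("c", 0:4))
  out <- build_longitudinal_sample(p)
  expect_equal(attr(out, "n_participants"), 2)
  expect_equal(attr(out, "n_person_observations"), 7)
  single <- build_longitudinal_sample(make_panel(c("x", "y"), c(0, 0)))
  expect_equal(nrow(single), 0)
})

test_that("longitudinal selection matches a brute-force row scan", {
  set.seed(21)
  ids <- rep(sprintf("p%02d", 1:30), times = sample(1:5, 30, replace = TRUE))
  waves <- unlist(lapply(table(ids)[unique(ids)], seq_len)) - 1
  p <- make_panel(ids, waves, bmi = 31)
  p$bmi[sample(nrow(p), 12)] <- NA  # plant missingness
  out <- build_longitudinal_sample(p)
  complete <- p[!is.na(p$bmi), ]
  keep <- names(which(table(complete$id) >= 2))
  expect_equal(attr(out, "n_participants"), length(keep))
  expect_equal(nrow(out), sum(complete$id %in% keep))
})

test_that("cohort summary percentages and counts are conserved", {
  set.seed(31)
  n <- 400
  flags <- matrix(rbinom(n * 7, 1, 0.25), n, 7,
                  dimnames = list(NULL, tolower(
                    c("CVD", "MTD", "RPD", "SMD", "NRD", "MD", "CC"))))
  rec <- make_panel(sprintf("p%03d", 1:n), rep(0, n), flags = flags)
  s <- summarize_cohort(rec)
  for (st in unique(s$stratum)) {
    sex <- s[s$stratum == st & s$variable == "sex", ]
    if (nrow(sex)) {
      expect_lt(abs(sum(sex$pct) - 100), 0.05)
      expect_equal(sum(sex$count), s$n[s$stratum == st][1])
    }
  }
  # equals a brute-force group-by count
  band <- ifelse(rowSums(flags) >= 3, "3+", rowSums(flags))
  for (st in unique(band)) {
    expect_equal(s$n[s$stratum == st][1], sum(band == st))
  }
})

test_that("empty strata are reported with n = 0", {
  rec <- make_panel("a", 0)  # healthy only; bands 1,2,3+ empty
  s <- summarize_cohort(rec)
  expect_setequal(s$stratum[s$variable == "n"], c("0", "1", "2", "3+"))
  expect_equal(s$count[s$variable == "n" & s$stratum == "3+"], 0)
})

test_that("carry-forward coding is monotone within participant", {
  p <- make_panel("a", 0:3, flags = cbind(cvd = c(0L, 1L, 0L, 0L)))
  out <- carry_forward_diseases(p)
  expect_equal(out$cvd, c(0, 1, 1, 1))
})

test_that("panel CSVs round-trip through read_panel", {
  p <- rbind(make_panel("a", 0:2, bmi = c(31, NA, 32)), make_panel("b", 0:1))
  p$depressed <- c(0L, 1L, 1L, 0L, NA)
  f <- tempfile(fileext = ".csv")
  write.csv(p, f, row.names = FALSE, na = "")
  got <- read_panel(f)
  expect_equal(got$bmi, p$bmi)            # empty string read as missing
  expect_equal(got$depressed, p$depressed)
  expect_equal(got[disease_cols <- tolower(c("CVD", "MTD", "RPD", "SMD",
                                             "NRD", "MD", "CC"))],
               p[disease_cols], ignore_attr = TRUE)
  unlink(f)
})

test_that("panel validation catches structural errors", {
  p <- make_panel("a", c(0, 0))
  expect_error(validate_panel(p), "strictly increasing")
  p2 <- make_panel("a", 0:1, bmi = c(-1, 31))
  expect_error(validate_panel(p2), "positive")
  expect_error(validate_panel(data.frame(id = 1)), "missing columns")
})
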