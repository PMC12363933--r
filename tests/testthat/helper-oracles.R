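# Independent oracles and fixture builders shared across tests.

# Brute-force frequent-itemset oracle: enumerate every non-empty subset of
# the item universe and keep those meeting min_support. Independent of the
# levelwise miner.
enumerate_frequent <- function(m, min_support) {
  storage.mode(m) <- "logical"
  items <- colnames(m)
  out <- list()
  for (k in seq_along(items)) {
    cmb <- utils::combn(items, k)
    for (j in seq_len(ncol(cmb))) {
      it <- cmb[, j]
      supp <- mean(rowSums(m[, it, drop = FALSE]) == k)
      if (supp >= min_support) {
        out[[length(out) + 1]] <- data.frame(
          items = paste(sort(it), collapse = ","), order = k, support = supp)
      }
    }
  }
  df <- if (length(out)) do.call(rbind, out) else {
    data.frame(items = character(0), order = integer(0), support = numeric(0))
  }
  df[order(df$order, df$items), , drop = FALSE]
}

# Delta-method SE of log(lift) for a pair of items under the multinomial
# over the 2x2 cell probabilities.
se_log_lift <- function(n, p11, pa, pb) {
  g11 <- 1 / p11 - 1 / pa - 1 / pb
  g10 <- -1 / pa
  g01 <- -1 / pb
  p10 <- pa - p11
  p01 <- pb - p11
  p00 <- 1 - p11 - p10 - p01
  gs <- c(g11, g10, g01, 0)
  ps <- c(p11, p10, p01, p00)
  mu <- sum(gs * ps)
  sqrt((sum(gs^2 * ps) - mu^2) / n)
}

# Spec-style toy transaction set: {CVD},{CVD,MTD},{MTD},{CVD,MTD,SMD},
# {SMD},{CVD,SMD}.
toy_transactions <- function() {
  data.frame(
    CVD = c(1, 1, 0, 1, 0, 1),
    MTD = c(0, 1, 1, 1, 0, 0),
    SMD = c(0, 0, 0, 1, 1, 1)
  )
}

# Minimal long-format panel with all required columns.
make_panel <- function(ids, waves, bmi = 31, flags = NULL) {
  n <- max(length(ids), length(waves))
  ids <- rep_len(ids, n)
  waves <- rep_len(waves, n)
  p <- data.frame(
    id = ids, wave = waves, time_years = 2 * waves,
    age = 60 + 2 * waves, sex = "female", race = "white", bmi = bmi,
    stringsAsFactors = FALSE
  )
  zero <- matrix(0L, n, 7, dimnames = list(NULL, tolower(
    c("CVD", "MTD", "RPD", "SMD", "NRD", "MD", "CC"))))
  if (!is.null(flags)) zero[, colnames(flags)] <- flags
  cbind(p, as.data.frame(zero))
}

profile_vec <- function(...) {
  v <- stats::setNames(integer(7), tolower(
    c("CVD", "MTD", "RPD", "SMD", "NRD", "MD", "CC")))
  on <- tolower(c(...))
  v[on] <- 1L
  v
}
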