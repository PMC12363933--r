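#' @title Apriori mining of disease co-occurrence
#' @name arm
#' @description Frequent-itemset mining, rule generation and stratified
#'   pattern tables over the seven disease-system items (the miner itself is
#'   generic over any transaction matrix).
NULL

# Coerce transactions to a logical matrix with item columns.
as_transaction_matrix <- function(transactions, items = NULL) {
  if (is.matrix(transactions)) {
    m <- transactions
  } else {
    if (is.null(items)) {
      items <- intersect(DISEASE_SYSTEMS, names(transactions))
      if (!length(items)) {
        # generic universe: any logical / 0-1 column counts as an item
        items <- names(transactions)[vapply(transactions, function(x) {
          is.logical(x) || (is.numeric(x) && all(x %in% c(0, 1)))
        }, logical(1))]
      }
    }
    if (!length(items)) stop("no item columns found in transactions")
    m <- as.matrix(transactions[items])
  }
  storage.mode(m) <- "logical"
  if (is.null(colnames(m))) stop("transaction matrix needs item column names")
  m
}

itemset_id <- function(items) paste(sort(items), collapse = ",")

split_items <- function(id) strsplit(id, ",", fixed = TRUE)

support_of <- function(m, items) {
  mean(rowSums(m[, items, drop = FALSE]) == length(items))
}

#' Mine frequent itemsets with the Apriori algorithm
#'
#' Levelwise candidate generation with the anti-monotone prune: a k-itemset
#' is a candidate only if all of its (k-1)-subsets are frequent, and the
#' output contains all and only itemsets with support at or above
#' `min_support`.
#'
#' @param transactions Data frame with logical/0-1 item columns (disease
#'   systems by default) or a logical matrix.
#' @param min_support Minimum support in (0, 1] (default 0.005).
#' @param max_order Largest itemset size to mine (default: number of items).
#' @return Data frame `items` (comma-joined, alphabetical), `order`,
#'   `count`, `support`, ordered by order, support (desc), items.
#' @examples
#' tr <- data.frame(CVD = c(1, 1, 0, 1, 0, 1), MTD = c(0, 1, 1, 1, 0, 0),
#'                  SMD = c(0, 0, 0, 1, 1, 1))
#' mine_frequent_itemsets(tr, min_support = 0.3)
#' @export
mine_frequent_itemsets <- function(transactions, min_support = 0.005,
                                   max_order = NULL) {
  m <- as_transaction_matrix(transactions)
  if (!nrow(m)) stop("transactions must be non-empty")
  if (!is.numeric(min_support) || min_support <= 0 || min_support > 1) {
    stop("min_support must be in (0, 1]")
  }
  items <- colnames(m)
  if (is.null(max_order)) max_order <- length(items)
  n <- nrow(m)
  res <- list()
  # level 1
  supp1 <- colMeans(m)
  freq <- lapply(items[supp1 >= min_support], identity)
  supps <- supp1[supp1 >= min_support]
  if (length(freq)) {
    res[[1]] <- data.frame(items = vapply(freq, itemset_id, ""),
                           order = 1L,
                           count = as.integer(round(supps * n)),
                           support = as.numeric(supps))
  }
  level <- freq[order(vapply(freq, itemset_id, ""))]
  k <- 1L
  while (length(level) >= 2 && k < max_order) {
    k <- k + 1L
    frequent_prev <- vapply(level, itemset_id, "")
    cand <- list()
    for (a in seq_along(level)) {
      for (b in seq_along(level)) {
        if (b <= a) next
        ia <- sort(level[[a]]); ib <- sort(level[[b]])
        if (k > 2 && !identical(ia[1:(k - 2)], ib[1:(k - 2)])) next
        if (k == 2 || ia[k - 1] < ib[k - 1]) {
          c_items <- sort(union(ia, ib))
          if (length(c_items) != k) next
          # anti-monotone prune: every (k-1)-subset must be frequent
          subs <- vapply(seq_len(k), function(d)
            itemset_id(c_items[-d]), "")
          if (all(subs %in% frequent_prev)) {
            cand[[length(cand) + 1]] <- c_items
          }
        }
      }
    }
    if (!length(cand)) break
    cand <- unique(cand)
    supp <- vapply(cand, function(it) support_of(m, it), numeric(1))
    keep <- supp >= min_support
    level <- cand[keep]
    if (length(level)) {
      res[[k]] <- data.frame(items = vapply(level, itemset_id, ""),
                             order = k,
                             count = as.integer(round(supp[keep] * n)),
                             support = supp[keep])
    }
    level <- level[order(vapply(level, itemset_id, ""))]
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(items = character(0), order = integer(0),
               count = integer(0), support = numeric(0))
  }
  out <- out[order(out$order, -out$support, out$items), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate association rules from frequent itemsets
#'
#' Emits every rule `A -> B` with `A`, `B` disjoint non-empty, `A U B`
#' frequent, and confidence at or above `min_confidence`. Confidence is
#' `support(A U B) / support(A)` and lift is `confidence / support(B)`.
#'
#' @param itemsets Result of [mine_frequent_itemsets()].
#' @param transactions The same transactions the itemsets came from.
#' @param min_confidence Minimum confidence (default 0.07).
#' @return Data frame `antecedent`, `consequent`, `support`, `confidence`,
#'   `lift`.
#' @export
generate_rules <- function(itemsets, transactions, min_confidence = 0.07) {
  m <- as_transaction_matrix(transactions)
  supp_lookup <- setNames(itemsets$support, itemsets$items)
  get_supp <- function(items) {
    id <- itemset_id(items)
    s <- supp_lookup[id]
    if (is.na(s)) s <- support_of(m, items)
    as.numeric(s)
  }
  rules <- list()
  for (r in which(itemsets$order >= 2)) {
    items <- split_items(itemsets$items[r])[[1]]
    s_joint <- itemsets$support[r]
    k <- length(items)
    for (asize in seq_len(k - 1)) {
      for (aidx in seq_len(ncol(combn(k, asize)))) {
        A <- items[combn(k, asize)[, aidx]]
        B <- setdiff(items, A)
        s_a <- get_supp(A)
        conf <- s_joint / s_a
        if (conf >= min_confidence) {
          rules[[length(rules) + 1]] <- data.frame(
            antecedent = itemset_id(A), consequent = itemset_id(B),
            support = s_joint, confidence = conf,
            lift = conf / get_supp(B))
        }
      }
    }
  }
  out <- if (length(rules)) do.call(rbind, rules) else {
    data.frame(antecedent = character(0), consequent = character(0),
               support = numeric(0), confidence = numeric(0),
               lift = numeric(0))
  }
  out <- out[order(-out$support, -out$confidence, out$antecedent,
                   out$consequent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Direction-free lift of an itemset: the maximum rule lift over all
# bipartitions A -> B (one lift per combination, as pattern tables print).
itemset_lift <- function(m, items) {
  s_joint <- support_of(m, items)
  if (s_joint == 0) return(NA_real_)
  best <- 0
  k <- length(items)
  for (asize in seq_len(k - 1)) {
    cmb <- combn(k, asize)
    for (j in seq_len(ncol(cmb))) {
      A <- items[cmb[, j]]
      B <- setdiff(items, A)
      l <- s_joint / (support_of(m, A) * support_of(m, B))
      if (is.finite(l) && l > best) best <- l
    }
  }
  best
}

#' Ranked comorbidity-pattern tables by stratum and itemset order
#'
#' For each stratum and order 1-3, ranks patterns by within-order relative
#' frequency: the share of participants with exactly `order` diseases whose
#' disease set equals the pattern. Raw support (share of all stratum
#' transactions containing the pattern) and, for orders >= 2, the
#' maximum-lift rule's lift are also emitted. Ranking ties break by lift
#' (desc), then lexically.
#'
#' @param transactions Data frame with disease-item columns and any stratum
#'   columns (`sex`, `age_band`).
#' @param stratify `"overall"`, `"sex"` or `"age_band"`.
#' @param min_support Patterns below this support in the stratum are
#'   dropped (default 0.005).
#' @param top_k Patterns reported per stratum and order (default 7).
#' @param min_cell Strata with fewer transactions than this are flagged
#'   sparse (default 30).
#' @return Data frame `stratum`, `order`, `rank`, `items`, `count`, `pct`,
#'   `support`, `lift`, `sparse`.
#' @export
stratified_patterns <- function(transactions, stratify = "overall",
                                min_support = 0.005, top_k = 7,
                                min_cell = 30) {
  if (identical(stratify, "overall")) {
    strata <- factor(rep("overall", nrow(transactions)))
  } else {
    if (!stratify %in% names(transactions)) {
      stop("stratum column not found: ", stratify)
    }
    strata <- factor(transactions[[stratify]])
    if (identical(stratify, "age_band")) {
      # ages outside the printed bands are excluded from age stratification
      keep <- !is.na(strata)
      transactions <- transactions[keep, , drop = FALSE]
      strata <- strata[keep]
    }
  }
  out <- list()
  for (s in levels(strata)) {
    sub <- transactions[which(strata == s), , drop = FALSE]
    n_s <- nrow(sub)
    if (n_s == 0) {
      out[[length(out) + 1]] <- data.frame(
        stratum = s, order = NA_integer_, rank = NA_integer_,
        items = NA_character_, count = NA_integer_, pct = NA_real_,
        support = NA_real_, lift = NA_real_, sparse = TRUE)
      next
    }
    m <- as_transaction_matrix(sub)
    sparse <- n_s < min_cell
    sizes <- rowSums(m)
    for (ord in 1:3) {
      rows <- which(sizes == ord)
      denom <- length(rows)
      if (!denom) next
      pats <- vapply(rows, function(i) itemset_id(colnames(m)[m[i, ]]), "")
      tab <- sort(table(pats), decreasing = TRUE)
      df <- data.frame(items = names(tab), count = as.integer(tab))
      df$pct <- 100 * df$count / denom
      df$support <- vapply(split_items(df$items),
                           function(it) support_of(m, it), numeric(1))
      df$lift <- if (ord >= 2) {
        vapply(split_items(df$items),
               function(it) itemset_lift(m, it), numeric(1))
      } else NA_real_
      df <- df[df$support >= min_support, , drop = FALSE]
      if (!nrow(df)) next
      lift_key <- ifelse(is.na(df$lift), 0, df$lift)
      df <- df[order(-df$pct, -lift_key, df$items), , drop = FALSE]
      df <- utils::head(df, top_k)
      out[[length(out) + 1]] <- data.frame(
        stratum = s, order = ord, rank = seq_len(nrow(df)),
        items = df$items, count = df$count, pct = df$pct,
        support = df$support, lift = df$lift, sparse = sparse)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select the modelling trio
#'
#' The frequent 3-itemset with the highest support; ties break by higher
#' direction-free lift, then lexically.
#'
#' @param transactions Transaction data frame or matrix.
#' @param min_support Minimum support for the trio search (default 0.005).
#' @return Character vector of the three items, in canonical disease-system
#'   order.
#' @export
select_trio <- function(transactions, min_support = 0.005) {
  m <- as_transaction_matrix(transactions)
  fi <- mine_frequent_itemsets(m, min_support = min_support, max_order = 3)
  trios <- fi[fi$order == 3, , drop = FALSE]
  if (!nrow(trios)) {
    stop("no frequent 3-itemset at min_support = ", min_support,
         "; lower min_support")
  }
  trios$lift <- vapply(split_items(trios$items),
                       function(it) itemset_lift(m, it), numeric(1))
  trios <- trios[order(-trios$support, -trios$lift, trios$items), ,
                 drop = FALSE]
  best <- split_items(trios$items[1])[[1]]
  best[order(match(best, DISEASE_SYSTEMS))]
}
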