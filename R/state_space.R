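#' Nine-state progression state space for a comorbidity trio
#'
#' Builds the state space used by the multi-state model: state 1 is healthy
#' (no chronic disease), state 2 holds at least one disease outside the trio
#' but no trio component, states 3-5 are the single trio diseases (first,
#' second, third), states 6-8 the dual combinations (first+second,
#' first+third, second+third) and state 9 — the absorbing state — all three.
#'
#' Allowed transitions follow single-acquisition steps only:
#' 1 -> \{2,3,4,5\}, 2 -> \{3,4,5\}, 3 -> \{6,7\}, 4 -> \{6,8\},
#' 5 -> \{7,8\}, 6/7/8 -> 9. From a single-disease state only dual states
#' containing that disease are reachable, and state 9 has no outgoing edges.
#'
#' @param trio Character vector of exactly three disease-system codes (from
#'   `CVD, MTD, RPD, SMD, NRD, MD, CC`), in the order first/second/third.
#' @return An object of class `state_space`: list with `trio`, `labels`
#'   (length 9), `adjacency` (9x9 logical), `edges` (16x2 integer matrix),
#'   `n_states`, and `absorbing`.
#' @examples
#' sp <- build_state_space(c("CVD", "MTD", "SMD"))
#' sum(sp$adjacency)  # 16 allowed edges
#' @export
build_state_space <- function(trio = c("CVD", "MTD", "SMD")) {
  trio <- toupper(trio)
  if (length(trio) != 3 || anyDuplicated(trio) ||
      !all(trio %in% DISEASE_SYSTEMS)) {
    stop("`trio` must be 3 distinct disease-system codes among: ",
         paste(DISEASE_SYSTEMS, collapse = ", "))
  }
  labels <- c("Healthy", "NonTrio",
              trio[1], trio[2], trio[3],
              paste(trio[1], trio[2], sep = "+"),
              paste(trio[1], trio[3], sep = "+"),
              paste(trio[2], trio[3], sep = "+"),
              paste(trio, collapse = "+"))
  edges <- rbind(
    cbind(1L, c(2L, 3L, 4L, 5L)),
    cbind(2L, c(3L, 4L, 5L)),
    cbind(3L, c(6L, 7L)),
    cbind(4L, c(6L, 8L)),
    cbind(5L, c(7L, 8L)),
    cbind(c(6L, 7L, 8L), 9L)
  )
  colnames(edges) <- c("from", "to")
  adjacency <- matrix(FALSE, 9, 9, dimnames = list(labels, labels))
  adjacency[edges] <- TRUE
  structure(
    list(trio = trio, labels = labels, adjacency = adjacency,
         edges = edges, n_states = 9L, absorbing = 9L),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat("9-state progression space, trio:", paste(x$trio, collapse = "-"), "\n")
  cat("States:", paste(sprintf("S%d=%s", 1:9, x$labels), collapse = ", "), "\n")
  cat(sum(x$adjacency), "allowed transitions; absorbing state:",
      x$absorbing, "\n")
  invisible(x)
}

#' Map disease profiles to progression states
#'
#' The state is determined by the subset of trio components present: none of
#' them and no other disease is state 1 (healthy); none of them but at least
#' one non-trio disease is state 2; otherwise the trio subset selects states
#' 3-9 regardless of any additional non-trio disease (trio components
#' dominate, so that single/dual trio states remain reachable for
#' participants who also carry, say, a respiratory condition).
#'
#' @param profiles A data frame (or named vector for a single profile) with
#'   0/1 columns `cvd, mtd, rpd, smd, nrd, md, cc`.
#' @param state_space A [build_state_space()] object.
#' @return Integer vector of states in 1..9.
#' @examples
#' sp <- build_state_space()
#' assign_state(c(cvd = 1, mtd = 1, rpd = 0, smd = 0, nrd = 0, md = 0, cc = 0), sp)
#' @export
assign_state <- function(profiles, state_space) {
  if (is.null(dim(profiles))) {
    profiles <- as.data.frame(as.list(profiles))
  }
  cols <- disease_cols()
  missing_cols <- setdiff(cols, names(profiles))
  if (length(missing_cols)) {
    stop("profile is missing disease columns: ",
         paste(missing_cols, collapse = ", "))
  }
  m <- as.matrix(profiles[cols])
  if (any(is.na(m)) || any(!m %in% c(0, 1))) {
    stop("disease indicators must be 0 or 1 with no missing values")
  }
  trio_cols <- tolower(state_space$trio)
  a <- m[, trio_cols[1]]
  b <- m[, trio_cols[2]]
  c_ <- m[, trio_cols[3]]
  other <- rowSums(m[, setdiff(cols, trio_cols), drop = FALSE]) > 0
  code <- a + 2L * b + 4L * c_  # bitmask over (first, second, third)
  state <- integer(nrow(m))
  state[code == 0L] <- ifelse(other[code == 0L], 2L, 1L)
  state[code == 1L] <- 3L
  state[code == 2L] <- 4L
  state[code == 4L] <- 5L
  state[code == 3L] <- 6L
  state[code == 5L] <- 7L
  state[code == 6L] <- 8L
  state[code == 7L] <- 9L
  state
}

# Multi-step reachability (reflexive-transitive closure) of an adjacency.
reachability <- function(adjacency) {
  n <- nrow(adjacency)
  reach <- adjacency | diag(TRUE, n)
  for (k in seq_len(n)) {
    reach <- reach | (reach %*% reach) > 0
  }
  reach
}
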