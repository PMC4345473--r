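#' @title Mann-Whitney U comparison of behaviour responses
#'
#' @description
#' Rank-based two-sample comparison used to compare the behaviour of cells
#' near a forming aggregation with those far from it (or simulated against
#' observed cells). The U statistic for the first sample counts pairwise
#' wins, ties counted one half. For small samples (combined n <= 16) the
#' two-sided p-value is exact, by full enumeration of the permutation
#' null, which remains valid under ties; for larger samples a normal
#' approximation with tie and continuity corrections is used.
#'
#' @name gsn-utest
NULL

MWU_EXACT_LIMIT <- 16L

#' Mann-Whitney U test
#'
#' @param x,y Non-empty numeric samples.
#' @return A list of class `mwu_test`: `u_statistic` (for `x`:
#'   `#\{x > y\} + 0.5 #\{x = y\}` over all pairs), `n1`, `n2`,
#'   `p_two_sided`, `method` (`"exact"` or `"normal_approximation"`).
#' @examples
#' mann_whitney_u(c(3, 4, 5), c(1, 2, 6)) # U = 6
#' @export
mann_whitney_u <- function(x, y) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x) ||
      !is.numeric(y) || length(y) == 0 || anyNA(y)) {
    abort_invalid("both samples must be non-empty numeric vectors without NA")
  }
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)                     # midranks handle ties
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (n1 + n2 <= MWU_EXACT_LIMIT) {
    method <- "exact"
    p <- mwu_exact_p(r, n1, u1)
  } else {
    method <- "normal_approximation"
    mu <- n1 * n2 / 2
    n <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u1 - mu) - 0.5) / sqrt(sigma2)   # continuity correction
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
  }
  structure(list(u_statistic = u1, n1 = n1, n2 = n2, p_two_sided = p,
                 method = method), class = "mwu_test")
}

# exact two-sided p by enumerating every assignment of n1 pooled ranks to
# the first sample; two-sided via distance of U from its null mean
mwu_exact_p <- function(ranks, n1, u_obs) {
  n <- length(ranks)
  mu <- n1 * (n - n1) / 2
  offset <- n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  u_all <- colSums(matrix(ranks[combs], nrow = n1)) - offset
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s)\n", x$method))
  cat(sprintf("  U = %g, n1 = %d, n2 = %d, two-sided p = %.4g\n",
              x$u_statistic, x$n1, x$n2, x$p_two_sided))
  invisible(x)
}

#' Compare near and far track groups on a behaviour response
#'
#' Summarizes every track ([track_summaries()]), splits tracks by
#' proximity of their start position to the aggregation centre
#' ([partition_tracks()]) and compares the chosen response between the
#' near (first sample) and far (second sample) groups with
#' [mann_whitney_u()].
#'
#' @param tracks A track data frame.
#' @param centre Aggregation centre `c(x, y)` in um.
#' @param threshold_um Proximity threshold in um (default 50).
#' @param response `"velocity"` or `"displacement"`.
#' @return An `mwu_test` with extra fields `response`, `threshold_um`,
#'   `near_ids`, `far_ids`.
#' @export
compare_groups <- function(tracks, centre, threshold_um = 50,
                           response = c("velocity", "displacement")) {
  response <- match.arg(response)
  summ <- track_summaries(tracks)
  part <- partition_tracks(tracks, centre, threshold_um)
  if (length(part$near) == 0) {
    abort_invalid("the near group is empty after partitioning")
  }
  if (length(part$far) == 0) {
    abort_invalid("the far group is empty after partitioning")
  }
  col <- if (response == "velocity") "velocity_um_min" else "displacement_um"
  vals <- stats::setNames(summ[[col]], summ$track_id)
  res <- mann_whitney_u(unname(vals[part$near]), unname(vals[part$far]))
  res$response <- response
  res$threshold_um <- threshold_um
  res$near_ids <- part$near
  res$far_ids <- part$far
  res
}

#' Attach a Mann-Whitney result to the argument as evidence
#'
#' Appends an evidence node under a goal, with a statement auto-composed
#' from the description, the test numbers and a verdict: "no significant
#' difference" when `p >= alpha`, "significant difference" otherwise.
#' Non-significance is deliberately worded as absence of a detected
#' difference, never as demonstrated equivalence.
#'
#' @param g A `gsn_graph`.
#' @param goal_uid uid of the goal to substantiate.
#' @param result An `mwu_test`.
#' @param description Short text naming the comparison (e.g. the response
#'   and groups compared).
#' @param alpha Significance level for the verdict wording (default 0.05).
#' @param link Optional URI to the underlying data or publication.
#' @return The updated graph; the evidence node's uid is available via
#'   [gsn_last_uid()].
#' @export
attach_evidence <- function(g, goal_uid, result, description,
                            alpha = 0.05, link = NULL) {
  stopifnot(inherits(g, "gsn_graph"))
  if (!inherits(result, "mwu_test")) {
    abort_invalid("result must be an mwu_test object")
  }
  if (is.null(g$nodes[[goal_uid]])) {
    abort_not_found(sprintf("node '%s' does not exist", goal_uid))
  }
  if (node_kind(g, goal_uid) != "goal") {
    abort_typing("evidence can only be attached to a goal node")
  }
  verdict <- if (result$p_two_sided >= alpha) {
    sprintf("no significant difference at alpha = %g", alpha)
  } else {
    sprintf("significant difference at alpha = %g", alpha)
  }
  statement <- sprintf(
    "%s: Mann-Whitney U = %g (n1 = %d, n2 = %d), two-sided p = %.4g, %s; %s.",
    description, result$u_statistic, result$n1, result$n2,
    result$p_two_sided, result$method, verdict
  )
  gsn_add_child(g, goal_uid, "evidence", statement,
                links = if (is.null(link)) character() else link)
}
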