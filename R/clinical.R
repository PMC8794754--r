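#' Kaplan-Meier product-limit estimate per group
#'
#' @param table SurvivalTable data.frame with columns `time` (>= 0) and
#'   `event` (1 = death observed, 0 = censored).
#' @param group per-sample group labels (single group if NULL).
#' @return named list, one data.frame per group with columns `time`
#'   (distinct event times), `n_risk`, `n_event`, `surv` (non-increasing,
#'   starting from 1 implicitly at time 0).
#' @export
km_estimate <- function(table, group = NULL) {
  check_survival_table(table)
  group <- group %||% rep("all", nrow(table))
  if (length(group) != nrow(table)) stop("group length mismatch")
  out <- lapply(split(seq_len(nrow(table)), group), function(idx) {
    time <- table$time[idx]; event <- table$event[idx]
    if (!length(time)) stop("empty group")
    ev_times <- sort(unique(time[event == 1]))
    n_risk <- vapply(ev_times, function(t) sum(time >= t), numeric(1))
    n_event <- vapply(ev_times, function(t) sum(time == t & event == 1),
                      numeric(1))
    data.frame(time = ev_times, n_risk = n_risk, n_event = n_event,
               surv = cumprod(1 - n_event / n_risk))
  })
  out
}

check_survival_table <- function(table) {
  stopifnot(is.data.frame(table), all(c("time", "event") %in% names(table)))
  if (any(table$time < 0)) stop("negative survival time")
  if (!all(table$event %in% c(0, 1))) stop("event must be 0/1")
  invisible(table)
}

#' Two-group log-rank test
#'
#' Standard observed-vs-expected log-rank: at each distinct event time the
#' expected group-1 events are `d * n1 / n` with hypergeometric variance;
#' the statistic `(sum(O1 - E1))^2 / sum(V)` is referred to chi-square with
#' 1 df.
#'
#' @param table SurvivalTable (`time`, `event`).
#' @param group per-sample labels with exactly two levels, both non-empty.
#' @return list `statistic`, `p`, `df = 1`, `observed`, `expected` (per
#'   group, in level order).
#' @export
logrank_test <- function(table, group) {
  check_survival_table(table)
  lev <- sort(unique(as.character(group)))
  if (length(lev) != 2) stop("log-rank test needs exactly two groups")
  if (sum(table$event) < 1) stop("no events observed")
  g1 <- as.character(group) == lev[1]
  ev_times <- sort(unique(table$time[table$event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ev_times) {
    at_risk <- table$time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(table$time == t & table$event == 1)
    d1 <- sum(table$time == t & table$event == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O1 - E1)^2 / V else 0
  O <- sum(table$event)
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
       df = 1,
       observed = stats::setNames(c(O1, O - O1), lev),
       expected = stats::setNames(c(E1, O - E1), lev))
}

#' Minimum-p expression-cutoff scan
#'
#' Scans every integer percentile from 5 to 95 (91 cutoffs) of the
#' expression values; at each cutoff samples are split into low
#' (expression <= cutoff) and high groups and a log-rank test is run.
#' Cutoffs producing an empty group or a group with zero events are
#' skipped (and recorded). The best cutoff minimizes p, ties broken by the
#' percentile nearest 50. The minimum-p selection is NOT corrected for
#' multiple testing over cutoffs — `selection_bias_uncorrected` is set as
#' an explicit caveat flag.
#'
#' @param table SurvivalTable with an `expression` column.
#' @return list of class `cutoff_scan`: `table` (percentile, cutoff, p,
#'   skipped), `best_percentile`, `best_cutoff`, `best_p`, `group_sizes`,
#'   `groups` (low/high labels at the best cutoff),
#'   `selection_bias_uncorrected = TRUE`.
#' @export
cutoff_scan <- function(table) {
  check_survival_table(table)
  if (!"expression" %in% names(table)) stop("need an `expression` column")
  if (nrow(table) < 20) stop("need >= 20 samples for a cutoff scan")
  if (sum(table$event) < 1) stop("no events observed")
  percentiles <- 5:95
  cutoffs <- stats::quantile(table$expression, percentiles / 100,
                             type = 7, names = FALSE)
  res <- data.frame(percentile = percentiles, cutoff = cutoffs,
                    p = NA_real_, skipped = FALSE)
  for (i in seq_along(percentiles)) {
    low <- table$expression <= cutoffs[i]
    if (all(low) || !any(low) ||
        sum(table$event[low]) == 0 || sum(table$event[!low]) == 0) {
      res$skipped[i] <- TRUE
      next
    }
    res$p[i] <- logrank_test(table, ifelse(low, "low", "high"))$p
  }
  if (all(res$skipped)) stop("no valid cutoff: every split is degenerate")
  ok <- which(!res$skipped)
  best_p <- min(res$p[ok])
  cand <- ok[res$p[ok] == best_p]
  best <- cand[which.min(abs(res$percentile[cand] - 50))]
  low <- table$expression <= res$cutoff[best]
  structure(list(table = res,
                 best_percentile = res$percentile[best],
                 best_cutoff = res$cutoff[best],
                 best_p = best_p,
                 group_sizes = c(low = sum(low), high = sum(!low)),
                 groups = ifelse(low, "low", "high"),
                 selection_bias_uncorrected = TRUE),
            class = "cutoff_scan")
}

#' Pearson chi-square test for a 2x2 table (no continuity correction)
#'
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, referred to chi-square
#' with 1 df. The continuity correction is deliberately omitted — this is
#' the convention under which published clinicopathological association
#' tables of this kind reproduce.
#'
#' @param a,b,c,d cell counts, row-wise (`a`,`b` = first row). A 2x2 matrix
#'   may be given as `a`.
#' @return list `statistic`, `p`, `df = 1`.
#' @export
chi_square_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  N <- sum(counts)
  if (N < 1) stop("empty table")
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("degenerate margin in 2x2 table")
  stat <- N * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
       df = 1)
}
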