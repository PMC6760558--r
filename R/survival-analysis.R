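#' Median split of per-sample scores
#'
#' Dichotomizes samples at the median score: `high` strictly above the
#' median, `low` at or below it (median ties go to `low`).
#'
#' @param scores Named numeric vector with at least 4 samples.
#' @return Named character vector of `"high"` / `"low"` labels.
#' @export
median_split <- function(scores) {
  if (is.null(names(scores))) abort("`scores` must be named by sample id")
  if (length(scores) < 4L) abort("need >= 4 samples for a median split")
  if (any(!is.finite(scores))) abort("scores must be finite")
  med <- stats::median(scores)
  if (all(scores == scores[1L])) abort("all scores equal: degenerate split")
  stats::setNames(ifelse(scores > med, "high", "low"), names(scores))
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] and reports the curve at the distinct
#' event times: the estimate steps only where events occur, censored
#' times reduce the risk set after their time, and ties between events
#' and censorings at the same time are resolved events-first (the
#' standard convention).
#'
#' @param surv Survival `data.frame` (`sample_id`, `time_months`,
#'   `event`); see [read_survival()].
#' @return A list of class `km_curve`: `times` (distinct event times,
#'   increasing), `survival`, `at_risk`, `events`, `n`.
#' @export
km_estimate <- function(surv) {
  surv <- validate_survival(surv)
  if (!nrow(surv)) abort("empty survival table")
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1,
    data = surv, conf.type = "none"
  )
  keep <- fit$n.event > 0
  structure(
    list(
      times = fit$time[keep],
      survival = fit$surv[keep],
      at_risk = fit$n.risk[keep],
      events = fit$n.event[keep],
      n = nrow(surv)
    ),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> n = ", x$n, ", ", sum(x$events), " events at ",
    length(x$times), " distinct times\n",
    sep = ""
  )
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank test via [survival::survdiff()]:
#' observed minus expected events summed over distinct event times,
#' chi-squared on 1 degree of freedom.
#'
#' @param group_a,group_b Survival `data.frame`s for the two groups.
#' @return A list of class `logrank_result`: `chi2`, `df` (= 1), `p`,
#'   `n_per_group`.
#' @export
logrank_test <- function(group_a, group_b) {
  group_a <- validate_survival(group_a)
  group_b <- validate_survival(group_b)
  if (!nrow(group_a) || !nrow(group_b)) abort("both groups must be non-empty")
  if (!any(c(group_a$event, group_b$event))) {
    abort("no events in either group: log-rank test undefined")
  }
  df <- rbind(
    data.frame(time = group_a$time_months, event = group_a$event, grp = "a"),
    data.frame(time = group_b$time_months, event = group_b$event, grp = "b")
  )
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = df)
  chi2 <- unname(sd$chisq)
  structure(
    list(
      chi2 = chi2, df = 1L,
      p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
      n_per_group = c(a = nrow(group_a), b = nrow(group_b))
    ),
    class = "logrank_result"
  )
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("<logrank_result> chi2 = ", sprintf("%.3f", x$chi2),
    " (1 df), p = ", format.pval(x$p, digits = 3),
    "; n = ", x$n_per_group[["a"]], " vs ", x$n_per_group[["b"]], "\n",
    sep = ""
  )
  invisible(x)
}

#' Median-split biochemical-recurrence analysis of a signature score
#'
#' Splits the scored samples at the median score, estimates a
#' Kaplan-Meier curve per group, and compares the groups with the
#' log-rank test. Only samples present in both `scores` and `surv` are
#' used.
#'
#' @param scores Named per-sample scores (e.g. from [pc1_score()]).
#' @param surv Survival `data.frame`.
#' @return A list of class `bcr_result`: `groups` (named high/low
#'   labels), `km` (list of `high` and `low` [km_estimate()] curves)
#'   and `logrank` ([logrank_test()] result).
#' @export
bcr_analysis <- function(scores, surv) {
  surv <- validate_survival(surv)
  shared <- intersect(names(scores), surv$sample_id)
  if (length(shared) < 4L) {
    abort("need >= 4 samples with both a score and survival data")
  }
  groups <- median_split(scores[shared])
  ss <- surv[match(shared, surv$sample_id), ]
  hi <- ss[groups[ss$sample_id] == "high", ]
  lo <- ss[groups[ss$sample_id] == "low", ]
  structure(
    list(
      groups = groups,
      km = list(high = km_estimate(hi), low = km_estimate(lo)),
      logrank = logrank_test(hi, lo)
    ),
    class = "bcr_result"
  )
}

#' @export
print.bcr_result <- function(x, ...) {
  cat("<bcr_result> high n = ", x$km$high$n, ", low n = ", x$km$low$n,
    "; log-rank p = ", format.pval(x$logrank$p, digits = 3), "\n",
    sep = ""
  )
  invisible(x)
}
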