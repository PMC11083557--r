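#' Define a composite methylation-expression risk rule
#'
#' A gene-specific pairing of a methylation direction and an expression
#' direction defining the high-risk stratum, e.g. hypomethylated AND
#' highly expressed for an oncogene-like marker.
#'
#' @param gene_id Gene the rule applies to.
#' @param methylation One of `"hypo"`, `"hyper"`.
#' @param expression One of `"high"`, `"low"`.
#' @return An object of class `risk_rule`.
#' @examples
#' risk_rule("ATP1A1-like", "hypo", "high")
#' @export
risk_rule <- function(gene_id, methylation, expression) {
  methylation <- match.arg(methylation, c("hypo", "hyper"))
  expression <- match.arg(expression, c("high", "low"))
  structure(
    list(gene_id = gene_id, methylation = methylation, expression = expression),
    class = "risk_rule"
  )
}

#' @export
print.risk_rule <- function(x, ...) {
  cat(sprintf(
    "<risk_rule> %s: high risk = %smethylated & %s expression\n",
    x$gene_id, x$methylation, x$expression
  ))
  invisible(x)
}

#' Split subjects at the median
#'
#' Values strictly above the median are labeled `high`; values at or
#' below it (ties included) are labeled `low`.
#'
#' @param values Numeric vector, length at least 2, not all identical.
#' @return Character vector of `"high"`/`"low"` labels.
#' @examples
#' median_split(c(1, 2, 2, 4))
#' @export
median_split <- function(values) {
  if (length(values) < 2L) abort("At least 2 subjects are required.")
  if (anyNA(values)) abort("`values` must not contain missing values.")
  if (max(values) == min(values)) abort("degenerate split: all values identical.")
  ifelse(values > median(values), "high", "low")
}

#' Combine methylation and expression splits into a composite risk label
#'
#' A subject is `high_risk` exactly when its methylation group matches
#' the rule's methylation direction (`hypo` corresponds to the
#' below-median, `low` methylation group) AND its expression group
#' matches the rule's expression direction; every other combination is
#' `low_risk`.
#'
#' @param meth_labels,expr_labels `"high"`/`"low"` labels per subject
#'   (same order and length).
#' @param rule A [risk_rule()].
#' @return Character vector of `"high_risk"`/`"low_risk"` labels.
#' @export
composite_risk <- function(meth_labels, expr_labels, rule) {
  if (!inherits(rule, "risk_rule")) abort("`rule` must be a risk_rule object.")
  if (length(meth_labels) != length(expr_labels)) {
    abort("Methylation and expression labels must cover the same subjects.")
  }
  if (anyNA(meth_labels) || anyNA(expr_labels)) {
    abort("Every subject needs both a methylation and an expression label.")
  }
  if (!all(meth_labels %in% c("high", "low")) ||
      !all(expr_labels %in% c("high", "low"))) {
    abort("Labels must be 'high' or 'low'.")
  }
  meth_wanted <- if (rule$methylation == "hypo") "low" else "high"
  ifelse(meth_labels == meth_wanted & expr_labels == rule$expression,
    "high_risk", "low_risk"
  )
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times,
#' with subjects censored at an event time counted as still at risk at
#' that time (the standard convention).
#'
#' @param records Data frame with columns `time` (non-negative) and
#'   `event` (1 = event observed, 0 = censored).
#' @return An object of class `km_fit`: a list with a `steps` tibble
#'   (`time`, `n_risk`, `n_event`, `n_censor`, `survival`) over distinct
#'   event times, plus `n` and `n_events`.
#' @examples
#' km_estimate(tibble::tibble(time = c(1, 2, 3), event = 1))
#' @export
km_estimate <- function(records) {
  records <- check_survival_records(records)
  if (!nrow(records)) abort("At least 1 record is required.")
  times <- sort(unique(records$time[records$event == 1L]))
  st <- sort(records$time)
  # at risk at t = subjects with time >= t; findInterval(left.open) counts time < t
  n_risk <- nrow(records) - findInterval(times, st, left.open = TRUE)
  n_event <- tabulate(match(records$time[records$event == 1L], times), length(times))
  n_censor <- tabulate(
    match(records$time[records$event == 0L], times), length(times)
  )
  surv <- cumprod(1 - n_event / n_risk)
  structure(
    list(
      steps = tibble::tibble(
        time = times, n_risk = n_risk, n_event = n_event,
        n_censor = n_censor, survival = surv
      ),
      n = nrow(records),
      n_events = sum(records$event)
    ),
    class = "km_fit"
  )
}

check_survival_records <- function(records) {
  if (!is.data.frame(records) || !all(c("time", "event") %in% names(records))) {
    abort("`records` must be a data frame with columns `time` and `event`.")
  }
  if (any(records$time < 0)) abort("Negative follow-up time.")
  if (!all(records$event %in% c(0, 1))) abort("`event` must be 0 or 1.")
  records$event <- as.integer(records$event)
  records
}

#' Survival probability at given times from a KM fit
#' @param fit A `km_fit`.
#' @param times Times at which to evaluate the step function.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(fit, times) {
  stopifnot(inherits(fit, "km_fit"))
  vapply(times, function(t) {
    drops <- fit$steps$survival[fit$steps$time <= t]
    if (length(drops)) drops[length(drops)] else 1
  }, numeric(1L))
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf(
    "<km_fit> n=%d, events=%d, %d distinct event times\n",
    x$n, x$n_events, nrow(x$steps)
  ))
  invisible(x)
}

#' @rdname km_estimate
#' @param x A `km_fit` object.
#' @param ... Unused.
#' @export
tidy.km_fit <- function(x, ...) {
  x$steps
}

#' @rdname km_estimate
#' @export
glance.km_fit <- function(x, ...) {
  below <- x$steps$time[x$steps$survival <= 0.5]
  tibble::tibble(
    n = x$n,
    n_events = x$n_events,
    median_survival = if (length(below)) below[1L] else NA_real_
  )
}

#' Two-group log-rank (Mantel-Haenszel) test
#'
#' At each distinct event time, compares the observed number of events in
#' the first group with its expectation under hypergeometric margins;
#' the statistic is `(sum(O - E))^2 / sum(V)`, referred to a chi-square
#' distribution with 1 degree of freedom. Zero total variance (no
#' informative stratum) yields p = 1 with a warning.
#'
#' @param records Data frame with columns `time`, `event`, `group`
#'   (exactly two non-empty groups, at least one event overall).
#' @return An object of class `logrank_test`: `statistic`, `p_value`,
#'   `df`, `observed`, `expected` (per group, first-group order is the
#'   sorted label order), `o_minus_e`, `variance`.
#' @examples
#' rec <- tibble::tibble(
#'   time = c(1, 2), event = c(1, 0), group = c("A", "B")
#' )
#' logrank_test(rec)
#' @export
logrank_test <- function(records) {
  records <- check_survival_records(records)
  if (!"group" %in% names(records)) abort("`records` must contain a `group` column.")
  labs <- sort(unique(as.character(records$group)))
  if (length(labs) != 2L) abort("Exactly two groups are required.")
  if (any(table(records$group) == 0L)) abort("Both groups must be non-empty.")
  if (sum(records$event) < 1L) abort("At least one event is required.")

  g1 <- records$group == labs[1L]
  event_times <- sort(unique(records$time[records$event == 1L]))
  st <- sort(records$time)
  st1 <- sort(records$time[g1])
  n_risk <- nrow(records) - findInterval(event_times, st, left.open = TRUE)
  n1_risk <- sum(g1) - findInterval(event_times, st1, left.open = TRUE)
  d <- tabulate(
    match(records$time[records$event == 1L], event_times), length(event_times)
  )
  d1 <- tabulate(
    match(records$time[records$event == 1L & g1], event_times),
    length(event_times)
  )
  O <- sum(d1)
  E <- sum(d * n1_risk / n_risk)
  ok <- n_risk > 1
  V <- sum((d * (n1_risk / n_risk) * (1 - n1_risk / n_risk) *
              (n_risk - d) / (n_risk - 1))[ok])
  if (V == 0) {
    warn("Zero log-rank variance; p-value reported as 1.")
    stat <- 0
    p <- 1
  } else {
    stat <- (O - E)^2 / V
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(
    list(
      statistic = stat, p_value = p, df = 1L,
      groups = labs,
      observed = c(O, sum(records$event) - O),
      expected = c(E, sum(records$event) - E),
      o_minus_e = O - E,
      variance = V
    ),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf(
    "<logrank_test> chi-square = %.4f on %d df, p = %.4g\n",
    x$statistic, x$df, x$p_value
  ))
  invisible(x)
}

#' @rdname logrank_test
#' @param x A `logrank_test` object.
#' @param ... Unused.
#' @export
glance.logrank_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p_value = x$p_value, df = x$df,
    o_minus_e = x$o_minus_e, variance = x$variance
  )
}

#' Optimal survival cutoff with permutation-adjusted significance
#'
#' Scans every distinct observed value of `values` inside the quantile
#' range as a candidate cutoff (subjects above the cutoff form the
#' `high` group), computes the log-rank p-value for each split, and
#' returns the cutoff minimizing it. Because minimum-p selection is
#' anti-conservative, a permutation-adjusted p-value — the fraction of
#' label permutations whose own minimum p is at least as small — is
#' always reported alongside the uncorrected one.
#'
#' @param values Numeric marker values, one per subject.
#' @param records Survival records aligned with `values` (`time`,
#'   `event`).
#' @param quantile_range Candidate cutoffs are restricted to values
#'   between these quantiles (default `c(0.2, 0.8)`).
#' @param n_permutations Permutations for the adjusted p (default 200).
#' @param seed Seed for the permutation draw.
#' @return A list of class `cutoff_scan`: `cutoff`, `labels`,
#'   `p_uncorrected`, `p_adjusted`, `scan` (tibble of all candidate
#'   cutoffs and p-values).
#' @export
optimal_cutoff <- function(values, records, quantile_range = c(0.2, 0.8),
                           n_permutations = 200L, seed = 1L) {
  records <- check_survival_records(records)
  if (length(values) != nrow(records)) {
    abort("`values` and `records` must cover the same subjects.")
  }
  if (length(values) < 10L) abort("At least 10 subjects are required.")
  if (max(values) == min(values)) abort("No valid cutoff: all values identical.")

  time <- records$time
  event <- records$event
  ut <- sort(unique(time[event == 1L]))
  if (!length(ut)) abort("At least one event is required.")
  st <- sort(time)
  n <- length(time)
  n_risk <- n - findInterval(ut, st, left.open = TRUE)
  d <- tabulate(match(time[event == 1L], ut), length(ut))
  vfac <- (n_risk - d) / pmax(n_risk - 1, 1) * ifelse(n_risk > 1, 1, 0)

  # lean log-rank p for one split; validated against logrank_test() in tests
  split_p <- function(high) {
    n1 <- sum(high)
    if (n1 == 0L || n1 == n) return(NA_real_)
    n1_risk <- n1 - findInterval(ut, sort(time[high]), left.open = TRUE)
    d1 <- tabulate(match(time[event == 1L & high], ut), length(ut))
    frac <- n1_risk / n_risk
    V <- sum(d * frac * (1 - frac) * vfac)
    if (V == 0) return(NA_real_)
    pchisq((sum(d1) - sum(d * frac))^2 / V, df = 1, lower.tail = FALSE)
  }

  min_p_scan <- function(v) {
    qs <- quantile(v, quantile_range, names = FALSE)
    cands <- sort(unique(v[v >= qs[1L] & v <= qs[2L]]))
    cands <- cands[cands < max(v)] # 'high' group must be non-empty
    ps <- vapply(cands, function(cut) split_p(v > cut), numeric(1L))
    keep <- !is.na(ps)
    list(cands = cands[keep], ps = ps[keep])
  }

  scan <- min_p_scan(values)
  if (!length(scan$cands)) abort("No valid cutoff within the quantile range.")
  best <- which.min(scan$ps)
  cutoff <- scan$cands[best]
  p_unc <- scan$ps[best]

  perm_min <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      s <- min_p_scan(sample(values))
      if (length(s$ps)) min(s$ps) else 1
    }, numeric(1L))
  })
  p_adj <- (1 + sum(perm_min <= p_unc)) / (n_permutations + 1)

  structure(
    list(
      cutoff = cutoff,
      labels = ifelse(values > cutoff, "high", "low"),
      p_uncorrected = p_unc,
      p_adjusted = p_adj,
      scan = tibble::tibble(cutoff = scan$cands, p_value = scan$ps)
    ),
    class = "cutoff_scan"
  )
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat(sprintf(
    "<cutoff_scan> cutoff = %.4g; uncorrected p = %.4g; permutation-adjusted p = %.4g\n",
    x$cutoff, x$p_uncorrected, x$p_adjusted
  ))
  invisible(x)
}
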