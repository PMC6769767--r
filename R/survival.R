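# Kaplan-Meier product-limit estimation and the two-group log-rank test,
# implemented directly so responder-stratification results are testable
# without external statistics services.

#' Kaplan-Meier product-limit estimate
#'
#' Computes `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the distinct
#' event times `t_i`, with `d_i` deaths and `n_i` subjects at risk
#' (subjects censored at an event time count as at risk at that time).
#' The estimator is right-continuous with `S(0) = 1`.
#'
#' @param time Non-negative follow-up times (days).
#' @param event Event indicators: 1 = death, 0 = censored.
#' @return Object of class `km_fit`: tibble `steps` with one row per
#'   distinct time (`time`, `n_risk`, `n_event`, `n_censor`, `surv`),
#'   plus `n` and `n_events`.
#' @export
km_estimate <- function(time, event) {
  time <- as.numeric(time)
  event <- as.integer(event)
  ct_assert(length(time) >= 1, "need at least one record")
  ct_assert(length(time) == length(event), "time and event lengths differ")
  ct_assert(all(!is.na(time) & time >= 0), "times must be non-negative")
  ct_assert(all(event %in% c(0L, 1L)), "event indicator must be 0 or 1")

  tt <- sort(unique(time))
  n_risk <- vapply(tt, function(t) sum(time >= t), 1L)
  n_event <- vapply(tt, function(t) sum(time == t & event == 1L), 1L)
  n_censor <- vapply(tt, function(t) sum(time == t & event == 0L), 1L)
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(
    steps = tibble::tibble(time = tt, n_risk = n_risk, n_event = n_event,
                           n_censor = n_censor, surv = surv),
    n = length(time), n_events = sum(event)
  ), class = "km_fit")
}

#' Evaluate a Kaplan-Meier fit at arbitrary times
#'
#' @param fit A `km_fit`.
#' @param t Numeric vector of times.
#' @return Survival probabilities `S(t)` (right-continuous step function,
#'   `S(t) = 1` before the first observed time).
#' @export
km_surv <- function(fit, t) {
  stopifnot(inherits(fit, "km_fit"))
  s <- fit$steps
  vapply(as.numeric(t), function(x) {
    i <- findInterval(x, s$time)
    if (i == 0) 1 else s$surv[i]
  }, 1.0)
}

#' Median survival time of a Kaplan-Meier fit
#'
#' Smallest observed time at which `S(t) <= 0.5`; `NA` when the curve
#' never reaches 0.5.
#'
#' @param fit A `km_fit`.
#' @return A time, or `NA`.
#' @export
km_median <- function(fit) {
  stopifnot(inherits(fit, "km_fit"))
  s <- fit$steps
  i <- which(s$surv <= 0.5)
  if (length(i) == 0) NA_real_ else s$time[min(i)]
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit> n = ", x$n, ", events = ", x$n_events,
      ", median = ", format(km_median(x)), "\n", sep = "")
  invisible(x)
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed number of deaths in group A is
#' compared with its hypergeometric expectation given the pooled risk
#' sets; the statistic `(sum(O - E))^2 / sum(V)` is referred to a
#' chi-square distribution with 1 degree of freedom (two-sided). Tied
#' event times use the standard hypergeometric variance with `d_i >= 1`.
#'
#' @param time_a,event_a Follow-up times and indicators for group A.
#' @param time_b,event_b Follow-up times and indicators for group B.
#' @return List: `statistic`, `p_value`, `observed` and `expected` deaths
#'   in group A, `n_a`, `n_b`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  ct_assert(length(time_a) >= 1 && length(time_b) >= 1,
            "both groups must be non-empty")
  event_a <- as.integer(event_a); event_b <- as.integer(event_b)
  ct_assert(all(c(event_a, event_b) %in% c(0L, 1L)),
            "event indicator must be 0 or 1")
  time <- c(as.numeric(time_a), as.numeric(time_b))
  event <- c(event_a, event_b)
  ina <- c(rep(TRUE, length(time_a)), rep(FALSE, length(time_b)))
  ct_assert(sum(event) >= 1, "log-rank test undefined with zero events")

  tt <- sort(unique(time[event == 1L]))
  o_minus_e <- 0
  v_sum <- 0
  obs <- 0
  exp_a <- 0
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & ina)
    d <- sum(time == t & event == 1L)
    d1 <- sum(time == t & event == 1L & ina)
    e1 <- d * n1 / n
    v <- if (n > 1) d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1) else 0
    o_minus_e <- o_minus_e + (d1 - e1)
    v_sum <- v_sum + v
    obs <- obs + d1
    exp_a <- exp_a + e1
  }
  stat <- if (v_sum > 0) o_minus_e^2 / v_sum else 0
  list(statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       observed = obs, expected = exp_a,
       n_a = length(time_a), n_b = length(time_b))
}

#' Read a survival table
#'
#' TSV with columns `patient_id`, `time_days`, `event` (1 = death,
#' 0 = censored) and optionally `group`.
#'
#' @param path TSV path.
#' @return Tibble of survival records.
#' @export
read_survival <- function(path) {
  ct_assert(file.exists(path), "survival table not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character")
  ct_assert(all(c("patient_id", "time_days", "event") %in% names(df)),
            "survival table needs columns patient_id, time_days, event")
  out <- tibble::tibble(
    patient_id = df$patient_id,
    time_days = as.numeric(df$time_days),
    event = as.integer(df$event)
  )
  if ("group" %in% names(df)) out$group <- df$group
  out
}

#' Stratified overall-survival analysis
#'
#' Joins responder labels to survival records on `patient_id`, fits a
#' Kaplan-Meier curve per stratum and compares the strata with the
#' log-rank test. Patients present in only one of the two tables are
#' reported and dropped; an empty stratum aborts the analysis.
#'
#' @param labels Tibble with columns `patient_id` and `label`
#'   (`responder` / `non_responder`).
#' @param records Tibble with columns `patient_id`, `time_days`, `event`.
#' @return Object of class `os_report`: per-group `km_fit`s, group sizes
#'   and event counts, median survival per group, log-rank `statistic`
#'   and `p_value`.
#' @export
stratified_os_analysis <- function(labels, records) {
  labels <- tibble::as_tibble(labels)
  records <- tibble::as_tibble(records)
  ct_assert(all(c("patient_id", "label") %in% names(labels)),
            "labels need columns patient_id, label")
  ct_assert(all(c("patient_id", "time_days", "event") %in% names(records)),
            "records need columns patient_id, time_days, event")
  ct_assert(all(labels$label %in% c("responder", "non_responder")),
            "labels must be 'responder' or 'non_responder'")

  unmatched <- c(setdiff(labels$patient_id, records$patient_id),
                 setdiff(records$patient_id, labels$patient_id))
  if (length(unmatched) > 0)
    warning(length(unmatched), " patient(s) without a label/survival match ",
            "were dropped: ", paste(head(unmatched, 5), collapse = ", "),
            if (length(unmatched) > 5) ", ...", call. = FALSE)
  joined <- dplyr::inner_join(labels, records, by = "patient_id")
  groups <- split(joined, joined$label)
  ct_assert(length(groups) == 2,
            "both strata must be non-empty (got only: ",
            paste(names(groups), collapse = ", "), ")")

  fits <- lapply(groups, function(g) km_estimate(g$time_days, g$event))
  r <- groups[["responder"]]
  nr <- groups[["non_responder"]]
  lr <- logrank_test(r$time_days, r$event, nr$time_days, nr$event)
  structure(list(
    fits = fits,
    group_sizes = vapply(groups, nrow, 1L),
    group_events = vapply(groups, function(g) sum(g$event), 1L),
    medians = vapply(fits, km_median, 1.0),
    statistic = lr$statistic,
    p_value = lr$p_value
  ), class = "os_report")
}

#' @export
print.os_report <- function(x, ...) {
  cat("<os_report> log-rank chi-square = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 3), "\n", sep = "")
  for (g in names(x$fits))
    cat("  ", g, ": n = ", x$group_sizes[[g]],
        ", events = ", x$group_events[[g]],
        ", median = ", format(x$medians[[g]]), "\n", sep = "")
  invisible(x)
}
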