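# Survival evaluation: risk stratification from predicted response labels,
# Kaplan-Meier product-limit curves, and the log-rank test.

#' Map predicted response labels to risk groups
#'
#' Predicted progressors (`PD`) become `High-risk`, predicted
#' non-progressors (`NPD`) become `Low-risk`; the mapping is bijective.
#'
#' @param predictions Character vector (or factor) of `"PD"` / `"NPD"`
#'   labels, optionally named by sample id.
#' @return Character vector of `"High-risk"` / `"Low-risk"`, names preserved.
#' @export
stratify_by_prediction <- function(predictions) {
  nm <- names(predictions)
  predictions <- as.character(predictions)
  bad <- setdiff(unique(predictions), c("PD", "NPD"))
  if (length(bad)) stop("unknown prediction label(s): ", paste(bad, collapse = ", "))
  out <- ifelse(predictions == "PD", "High-risk", "Low-risk")
  names(out) <- nm
  out
}

#' Kaplan-Meier product-limit estimator
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times, with
#' the simultaneous-death convention for tied events and censoring at an
#' event time counted after the event (censored subjects remain in the risk
#' set at that time). Greenwood variance is attached.
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators (1 = death observed).
#' @return A `SurvivalCurve`: list with `time` (distinct event times),
#'   `n_risk`, `n_event`, `surv`, `var` (Greenwood), plus `n` and
#'   `n_censored`. A censored-only input yields an empty event table
#'   (survival identically 1).
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events)) stop("times and events must align")
  if (any(times < 0)) stop("negative survival times")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  ev_times <- sort(unique(times[events == 1]))
  n_risk <- vapply(ev_times, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw <- surv^2 * cumsum(n_event / (n_risk * (n_risk - n_event)))
  structure(list(time = ev_times, n_risk = n_risk, n_event = n_event,
                 surv = surv, var = gw, n = length(times),
                 n_censored = sum(events == 0)),
            class = "SurvivalCurve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve A `SurvivalCurve`.
#' @param t Times at which to evaluate the right-continuous step function.
#' @return Survival probabilities `S(t)`.
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "SurvivalCurve"))
  vapply(t, function(tt) {
    i <- sum(curve$time <= tt)
    if (i == 0) 1 else curve$surv[i]
  }, numeric(1))
}

#' @export
print.SurvivalCurve <- function(x, ...) {
  cat(sprintf("SurvivalCurve: n=%d (%d censored), %d event times, S(max)=%.3f\n",
              x$n, x$n_censored, length(x$time),
              if (length(x$surv)) min(x$surv) else 1))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank over the pooled distinct event times:
#' `chi^2 = (sum(O - E))^2 / sum(V)` with the hypergeometric variance at
#' each event time, referred to a chi-squared distribution with 1 df.
#' A `rho = 1` flag gives the Peto-Wilcoxon weighting (weights `S(t-)`).
#'
#' @param group_a,group_b Lists or `data.frame`s with elements/columns
#'   `time` and `event`.
#' @param rho 0 for the log-rank test (default), 1 for the Wilcoxon-type
#'   weighting.
#' @return List with `chi_square`, `p_value`, `observed` and `expected`
#'   (per group) and `n_events`.
#' @export
logrank_test <- function(group_a, group_b, rho = 0) {
  ta <- group_a$time; ea <- group_a$event
  tb <- group_b$time; eb <- group_b$event
  if (sum(ea) + sum(eb) == 0) stop("no events in either group")
  times <- c(ta, tb)
  events <- c(ea, eb)
  in_a <- rep(c(TRUE, FALSE), c(length(ta), length(tb)))
  ev_times <- sort(unique(times[events == 1]))
  km_all <- km_estimate(times, events)
  oe <- 0; v <- 0; obs_a <- 0; exp_a <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & in_a)
    d <- sum(times == t & events == 1)
    d_a <- sum(times == t & events == 1 & in_a)
    w <- if (rho == 0) 1 else km_survival_at(km_all, t - 1e-12)^rho
    e_a <- n_a * d / n
    oe <- oe + w * (d_a - e_a)
    if (n > 1) {
      v <- v + w^2 * d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
    }
    obs_a <- obs_a + d_a
    exp_a <- exp_a + e_a
  }
  chi2 <- if (v > 0) oe^2 / v else 0
  list(chi_square = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = c(A = obs_a, B = sum(events) - obs_a),
       expected = c(A = exp_a, B = sum(events) - exp_a),
       n_events = sum(events))
}
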