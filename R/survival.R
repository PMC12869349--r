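# Kaplan-Meier estimation, log-rank testing, and maximally selected cutpoint
# stratification of a continuous per-sample score.

validate_survival <- function(time, event) {
  if (length(time) != length(event)) stopf("time/event length mismatch")
  if (any(!is.finite(time)) || any(time <= 0))
    stopf("all survival times must be positive and finite")
  if (!all(event %in% c(0, 1))) stopf("`event` must be 0 (censored) or 1 (event)")
  invisible(NULL)
}

#' Kaplan-Meier product-limit estimator
#'
#' Censored subjects at an event time remain at risk for the event at that
#' time (the standard convention). Greenwood's formula gives the variance of
#' the survival estimate.
#'
#' @param time positive event/censoring times.
#' @param event 1 = event, 0 = censored.
#' @return A `km_curve` data.frame: `time` (distinct event times, ascending),
#'   `n_risk`, `n_event`, `surv`, `greenwood_var`.
#' @export
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 0, 1))  # S(1)=2/3, S(3)=0
km_estimate <- function(time, event) {
  validate_survival(time, event)
  ev_times <- sort(unique(time[event == 1]))
  if (!length(ev_times)) {
    out <- data.frame(time = numeric(0), n_risk = numeric(0),
                      n_event = numeric(0), surv = numeric(0),
                      greenwood_var = numeric(0))
    class(out) <- c("km_curve", class(out))
    return(out)
  }
  n_risk <- vapply(ev_times, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(time == t & event == 1),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw <- surv^2 * cumsum(n_event / (n_risk * pmax(n_risk - n_event,
                                                 .Machine$double.eps)))
  gw[n_risk == n_event] <- 0   # S = 0: variance degenerate
  out <- data.frame(time = ev_times, n_risk = n_risk, n_event = n_event,
                    surv = surv, greenwood_var = gw)
  class(out) <- c("km_curve", class(out))
  out
}

# log-rank O, E, V for group-1 membership; shared by the test and the
# cutpoint scan (vectorised over distinct times via reverse cumulative
# at-risk counts)
logrank_oev <- function(time, event, in_g1) {
  ut <- sort(unique(time))
  idx <- match(time, ut)
  K <- length(ut)
  risk_all <- rev(cumsum(rev(tabulate(idx, K))))
  risk_g1 <- rev(cumsum(rev(tabulate(idx[in_g1], K))))
  d_all <- tabulate(idx[event == 1], K)
  d_g1 <- tabulate(idx[event == 1 & in_g1], K)
  ev <- d_all > 0
  n <- risk_all[ev]; n1 <- risk_g1[ev]; d <- d_all[ev]; d1 <- d_g1[ev]
  E <- sum(d * n1 / n)
  v_terms <- ifelse(n > 1, d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1), 0)
  c(O = sum(d1), E = E, V = sum(v_terms))
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank with the hypergeometric variance at each
#' distinct event time; the statistic is chi-square with 1 df. The test
#' depends on event-time ranks only, so it is invariant to strictly
#' increasing time transforms.
#'
#' @param time,event pooled survival data.
#' @param group length-2-level grouping vector (factor, character, logical).
#' @return List with `statistic`, `p_value`, `observed` and `expected`
#'   (group-1 events), `n` per group.
#' @export
logrank_test <- function(time, event, group) {
  validate_survival(time, event)
  g <- as.factor(group)
  if (nlevels(g) != 2L) stopf("`group` must have exactly 2 levels")
  if (any(table(g) == 0L)) stopf("both groups must be nonempty")
  if (sum(event) == 0) {
    warnf("no events observed; log-rank statistic is 0")
    return(list(statistic = 0, p_value = 1, observed = 0, expected = 0,
                n = table(g)))
  }
  oev <- logrank_oev(time, event, g == levels(g)[1L])
  stat <- if (oev["V"] > 0) (oev["O"] - oev["E"])^2 / oev["V"] else 0
  list(statistic = unname(stat),
       p_value = stats::pchisq(unname(stat), df = 1, lower.tail = FALSE),
       observed = unname(oev["O"]), expected = unname(oev["E"]),
       n = table(g))
}

#' Maximally selected survival cutpoint
#'
#' Scans candidate cutpoints (midpoints between adjacent distinct score
#' values) that leave at least `minprop` of the samples on each side, and
#' picks the one maximising the absolute standardised log-rank statistic
#' `|O - E| / sqrt(V)` for the induced high/low dichotomy. The reported
#' p-value is the *naive* log-rank p at the selected cutpoint — it ignores
#' the selection over candidates and is anti-conservative under the null;
#' `bonferroni = TRUE` additionally reports a p multiplied by the number of
#' candidates (crude but honest upper bound).
#'
#' @param time,event survival data.
#' @param score continuous per-sample score; at least 2 distinct values.
#' @param minprop minimum fraction of samples on each side (default 0.1).
#' @param bonferroni also report a Bonferroni-over-candidates p (default
#'   FALSE).
#' @return A `cutpoint_result`: list with `cutpoint`, `statistic` (the
#'   standardised log-rank Z at the cutpoint), `p_value` (naive),
#'   `p_adjusted` (if requested), `n_high`, `n_low`, `n_candidates`.
#' @export
optimal_cutpoint <- function(time, event, score, minprop = 0.1,
                             bonferroni = FALSE) {
  validate_survival(time, event)
  if (length(score) != length(time)) stopf("`score` length mismatch")
  if (any(!is.finite(score))) stopf("`score` must be finite")
  assert_scalar_number(minprop, "minprop", lower = 0, upper = 0.5,
                       strict_lower = TRUE)
  uniq <- sort(unique(score))
  if (length(uniq) < 2L) stopf("need >= 2 distinct score values")
  n <- length(score)
  cand <- (uniq[-1L] + uniq[-length(uniq)]) / 2
  admissible <- vapply(cand, function(cp) {
    nh <- sum(score > cp)
    nh >= minprop * n && (n - nh) >= minprop * n && nh > 0 && nh < n
  }, logical(1))
  cand <- cand[admissible]
  if (!length(cand)) stopf("no admissible cutpoint under minprop = %g", minprop)

  z <- vapply(cand, function(cp) {
    oev <- logrank_oev(time, event, score > cp)
    if (oev["V"] <= 0) return(0)
    unname((oev["O"] - oev["E"]) / sqrt(oev["V"]))
  }, numeric(1))
  best <- which.max(abs(z))
  cp <- cand[best]
  lr <- logrank_test(time, event, score > cp)
  out <- list(cutpoint = cp, statistic = z[best], p_value = lr$p_value,
              n_high = sum(score > cp), n_low = sum(score <= cp),
              n_candidates = length(cand))
  if (bonferroni) out$p_adjusted <- min(1, lr$p_value * length(cand))
  class(out) <- "cutpoint_result"
  out
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(paste0("optimal cutpoint %.4g (|Z| = %.3f, naive log-rank ",
                     "p = %.3g; high n = %d, low n = %d, %d candidates)\n"),
              x$cutpoint, abs(x$statistic), x$p_value, x$n_high, x$n_low,
              x$n_candidates))
  invisible(x)
}
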