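## Self-contained clinical statistics: two-sided Fisher exact test on a
## 2x2 table, Kaplan-Meier product-limit estimation with median and
## log-log confidence interval, and the two-sided log-rank test.  These
## are implemented from first principles (with the survival package used
## only as an independent oracle in the test suite).

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Uses the probability-mass definition: the p-value is the sum of the
#' hypergeometric probabilities of all tables with the same margins whose
#' probability does not exceed that of the observed table (within a
#' relative tolerance of 1e-7).  This is the convention of R's
#' `fisher.test`; mid-p and tail-doubling conventions give different
#' values and are not used.
#'
#' @param a,b,c,d cell counts, rows = groups, columns = outcome yes/no; or
#'   pass a 2x2 matrix as `a`.
#' @return p-value in (0, 1].  A zero row or column margin is degenerate
#'   and returns 1 with a message.
#' @examples
#' fisher_exact_two_sided(2, 9, 58, 38)   # second-CR response table
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)), any(cells > 0))
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    message("degenerate 2x2 table (zero margin): p = 1")
    return(1)
  }
  m <- a + c        # column-1 margin
  n2 <- b + d       # column-2 margin
  k <- a + b        # row-1 margin
  support <- max(0, k - n2):min(k, m)
  pr <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  min(sum(pr[pr <= p_obs * (1 + 1e-7)]), 1)
}

#' Kaplan-Meier estimate of remission duration
#'
#' Product-limit estimator with Greenwood variance and log-log pointwise
#' confidence intervals.  The median is the smallest time at which the
#' survival curve reaches 0.5 or below ("not reached", NA, when the curve
#' never does); its confidence interval is read off the times at which
#' the confidence bands cross 0.5.
#'
#' @param time non-negative event/censoring times (months).
#' @param event logical, `TRUE` = event (relapse), `FALSE` = censored.
#' @param conf_level confidence level for the bands, default 0.95.
#' @return list of class `km_fit`: `surv` (data.frame with `time`,
#'   `n_risk`, `n_event`, `n_censor`, `estimate`, `std_err`, `lower`,
#'   `upper`), `median`, `median_ci`, `n`, `conf_level`.
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  stopifnot(length(time) == length(event), length(time) >= 1, all(time >= 0))
  event <- as.logical(event)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- sort(unique(time))
  n <- length(time)
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & !event), numeric(1))
  s <- cumprod(1 - n_event / n_risk)
  ## Greenwood variance and log-log confidence bands
  gw <- cumsum(ifelse(n_risk > n_event,
                      n_event / (n_risk * (n_risk - n_event)), 0))
  se <- s * sqrt(gw)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lower <- upper <- rep(NA_real_, length(s))
  ok <- s > 0 & s < 1
  theta <- z * sqrt(gw[ok]) / log(s[ok])   # negative: log S < 0
  lower[ok] <- s[ok]^exp(-theta)
  upper[ok] <- s[ok]^exp(theta)
  lower[s == 0] <- 0
  upper[s == 0] <- 0
  lower[s == 1] <- 1
  upper[s == 1] <- 1
  surv <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                     n_censor = n_censor, estimate = s, std_err = se,
                     lower = lower, upper = upper)
  med <- .first_crossing(ut, s)
  med_ci <- c(.first_crossing(ut, lower), .first_crossing(ut, upper))
  structure(list(surv = surv, median = med, median_ci = med_ci,
                 n = n, conf_level = conf_level),
            class = "km_fit")
}

.first_crossing <- function(t, s, level = 0.5) {
  i <- which(!is.na(s) & s <= level + 1e-12)
  if (length(i)) t[min(i)] else NA_real_   # NA = not reached
}

#' @export
print.km_fit <- function(x, ...) {
  med <- if (is.na(x$median)) "not reached" else format(x$median)
  ci <- ifelse(is.na(x$median_ci), "not reached", format(x$median_ci))
  cat("Kaplan-Meier fit: n =", x$n, "\n median:", med,
      sprintf(" (%d%% CI %s - %s)\n", round(100 * x$conf_level),
              ci[1], ci[2]))
  invisible(x)
}

#' Two-sided log-rank test
#'
#' Standard log-rank chi-square on one degree of freedom comparing two
#' survival distributions, using the hypergeometric variance of the
#' group-1 event count at each distinct event time.
#'
#' @param time_a,event_a times and event indicators for group A.
#' @param time_b,event_b times and event indicators for group B.
#' @return list of class `logrank_test`: `chisq`, `p_value`,
#'   `observed` and `expected` (length-2, groups A and B).
#' @export
logrank_two_sided <- function(time_a, event_a, time_b, event_b) {
  stopifnot(length(time_a) >= 1, length(time_b) >= 1)
  event_a <- as.logical(event_a); event_b <- as.logical(event_b)
  if (!any(c(event_a, event_b))) stop("no events in either group")
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(1L, 2L), c(length(time_a), length(time_b)))
  dtimes <- sort(unique(time[event]))
  o1 <- e1 <- v1 <- 0
  for (t in dtimes) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1L)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & grp == 1L)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1)
      v1 <- v1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (v1 > 0) (o1 - e1)^2 / v1 else 0
  o2 <- sum(event) - o1
  structure(list(chisq = chisq,
                 p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
                 observed = c(o1, o2),
                 expected = c(e1, sum(event) - e1)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("log-rank test: chisq = %.3f (1 df), two-sided p = %.4g\n",
              x$chisq, x$p_value))
  invisible(x)
}

#' Clinical summary of a cohort table
#'
#' Convenience wrapper reproducing the clinical endpoints for a
#' two-group cohort: Kaplan-Meier medians of remission duration per
#' group, the two-sided log-rank comparison, and the Fisher exact test on
#' the second-CR response table (patients with `second_cr = na` are
#' excluded from the Fisher table).
#'
#' @param clin a `clinical_table` (see [read_clinical()]).
#' @return list with `km` (per-group `km_fit`), `logrank`,
#'   `second_cr_table` (2x2 matrix) and `fisher_p`.
#' @export
clinical_summary <- function(clin) {
  stopifnot(all(clin$group %in% CLINICAL_GROUPS))
  g1 <- clin[clin$group == "npm1_loss", ]
  g2 <- clin[clin$group == "npm1_persistent", ]
  km <- list(
    npm1_loss = km_estimate(g1$remission_duration_months, g1$relapse_event),
    npm1_persistent = km_estimate(g2$remission_duration_months,
                                  g2$relapse_event))
  lr <- logrank_two_sided(g1$remission_duration_months, g1$relapse_event,
                          g2$remission_duration_months, g2$relapse_event)
  evaluable <- clin[clin$second_cr %in% c("yes", "no"), ]
  tab <- matrix(c(sum(evaluable$group == "npm1_loss" & evaluable$second_cr == "yes"),
                  sum(evaluable$group == "npm1_loss" & evaluable$second_cr == "no"),
                  sum(evaluable$group == "npm1_persistent" & evaluable$second_cr == "yes"),
                  sum(evaluable$group == "npm1_persistent" & evaluable$second_cr == "no")),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("npm1_loss", "npm1_persistent"),
                                c("second_cr", "no_second_cr")))
  list(km = km, logrank = lr, second_cr_table = tab,
       fisher_p = fisher_exact_two_sided(tab))
}
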