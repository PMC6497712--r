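test_that("Fisher exact matches enumeration, fisher.test and symmetries", {
  # printed salvage-response table; the standard two-sided value
  p <- fisher_exact_two_sided(2, 9, 58, 38)
  expect_equal(p, stats::fisher.test(matrix(c(2, 9, 58, 38), 2,
                                            byrow = TRUE))$p.value,
               tolerance = 1e-9)
  # degenerate margins
  expect_message(p0 <- fisher_exact_two_sided(0, 5, 0, 7), "degenerate")
  expect_equal(p0, 1)
  # exhaustive hypergeometric oracle on a small table
  oracle <- function(a, b, c, d) {
    k <- a + b; m <- a + c; n2 <- b + d; N <- a + b + c + d
    as_all <- max(0, k - n2):min(k, m)
    pr <- vapply(as_all, function(x)
      choose(m, x) * choose(n2, k - x) / choose(N, k), numeric(1))
    obs <- choose(m, a) * choose(n2, k - a) / choose(N, k)
    sum(pr[pr <= obs * (1 + 1e-7)])
  }
  expect_equal(fisher_exact_two_sided(3, 1, 1, 3), oracle(3, 1, 1, 3),
               tolerance = 1e-12)
  # invariance under simultaneous row and column swap
  set.seed(601)
  for (i in 1:50) {
    t4 <- rpois(4, 6)
    if (all(t4 == 0)) t4[1] <- 1
    expect_equal(fisher_exact_two_sided(t4[1], t4[2], t4[3], t4[4]),
                 fisher_exact_two_sided(t4[4], t4[3], t4[2], t4[1]),
                 tolerance = 1e-12)
  }
})

test_that("Kaplan-Meier estimates agree with the survival package", {
  skip_if_not_installed("survival")
  set.seed(602)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    time <- round(rexp(n, 0.05), 1)
    event <- runif(n) < 0.8
    fit <- km_estimate(time, event)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                            conf.type = "log-log")
    ss <- summary(sf, times = fit$surv$time)
    expect_equal(fit$surv$estimate, ss$surv, tolerance = 1e-9)
    expect_equal(fit$surv$n_risk, ss$n.risk, ignore_attr = TRUE)
    fin <- is.finite(ss$std.err)
    expect_equal(fit$surv$std_err[fin], ss$std.err[fin], tolerance = 1e-9)
    keep <- !is.na(ss$lower)
    expect_equal(fit$surv$lower[keep], ss$lower[keep], tolerance = 1e-9)
    expect_equal(fit$surv$upper[keep], ss$upper[keep], tolerance = 1e-9)
    med <- unname(summary(sf)$table["median"])
    expect_equal(fit$median, if (is.na(med)) NA_real_ else med)
  }
  # degenerate shapes
  allev <- km_estimate(rep(5, 7), rep(TRUE, 7))
  expect_equal(allev$median, 5)
  expect_equal(allev$surv$estimate, 0)
  expect_true(is.na(km_estimate(c(3, 9, 12), rep(FALSE, 3))$median))
  # curve is non-increasing and starts at/below 1
  fit <- km_estimate(rexp(40, 0.1), runif(40) < 0.7)
  expect_true(all(diff(fit$surv$estimate) <= 1e-12))
  expect_lte(fit$surv$estimate[1], 1)
})

test_that("log-rank agrees with survdiff and a permutation oracle", {
  skip_if_not_installed("survival")
  set.seed(603)
  for (rep in 1:10) {
    n1 <- sample(8:25, 1); n2 <- sample(8:25, 1)
    t1 <- rexp(n1, 0.05); e1 <- runif(n1) < 0.8
    t2 <- rexp(n2, 0.10); e2 <- runif(n2) < 0.8
    lr <- logrank_two_sided(t1, e1, t2, e2)
    sd <- survival::survdiff(survival::Surv(c(t1, t2), c(e1, e2)) ~
                               rep(1:2, c(n1, n2)))
    expect_equal(lr$chisq, sd$chisq, tolerance = 1e-9)
    # symmetry in group order
    expect_equal(logrank_two_sided(t2, e2, t1, e1)$chisq, lr$chisq,
                 tolerance = 1e-12)
  }
  # identical groups
  t0 <- c(2, 5, 9, 14); e0 <- c(TRUE, TRUE, FALSE, TRUE)
  same <- logrank_two_sided(t0, e0, t0, e0)
  expect_equal(same$chisq, 0)
  expect_equal(same$p_value, 1)
  expect_error(logrank_two_sided(1:3, rep(FALSE, 3), 4:6, rep(FALSE, 3)),
               "no events")

  # permutation-based log-rank on a 20-sample fixture
  set.seed(604)
  time <- c(rexp(10, log(2) / 20), rexp(10, log(2) / 8))
  event <- runif(20) < 0.9
  grp <- rep(1:2, each = 10)
  obs <- logrank_two_sided(time[grp == 1], event[grp == 1],
                           time[grp == 2], event[grp == 2])
  perm <- replicate(2000, {
    g <- sample(grp)
    logrank_two_sided(time[g == 1], event[g == 1],
                      time[g == 2], event[g == 2])$chisq
  })
  p_perm <- mean(perm >= obs$chisq - 1e-12)
  expect_lt(abs(p_perm - obs$p_value), 0.02)
})

test_that("clinical summaries assemble the endpoints", {
  set.seed(605)
  coh <- generate_cohort(11, 95)
  cs <- clinical_summary(coh$clinical)
  expect_named(cs$km, c("npm1_loss", "npm1_persistent"))
  expect_gt(cs$km$npm1_loss$median, cs$km$npm1_persistent$median)
  expect_lt(cs$logrank$p_value, 0.05)
  expect_equal(sum(cs$second_cr_table),
               sum(coh$clinical$second_cr != "na"))
})
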