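test_that("response_chisq reproduces published contingency-table p-values", {
  # published 3x2 validation tables (responders, non-responders per genotype)
  kcnab1 <- rbind(c(42, 9), c(66, 17), c(19, 17))
  out <- response_chisq(kcnab1)
  expect_equal(round(out$raw_p, 3), 0.003)
  expect_equal(out$df, 2)

  atp7a <- rbind(c(88, 16), c(29, 24), c(9, 2))
  expect_lt(response_chisq(atp7a)$raw_p, 0.001)

  # identical row proportions: statistic 0, p 1
  flat <- rbind(c(10, 20), c(5, 10), c(20, 40))
  expect_equal(response_chisq(flat)$statistic, 0)
  expect_equal(response_chisq(flat)$raw_p, 1)

  expect_error(response_chisq(rbind(c(0, 0), c(1, 2))), "degenerate")
})

test_that("response_chisq equals the uncorrected Pearson reference", {
  set.seed(5)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 20) + 1, 3, 2)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    out <- response_chisq(tab)
    expect_equal(out$statistic, unname(ref$statistic))
    expect_equal(out$raw_p, unname(ref$p.value))
  }
})

test_that("truncate_dfs caps follow-up at the horizon and censors", {
  out <- truncate_dfs(c(130, 120, 60), c(TRUE, TRUE, FALSE))
  expect_equal(out$dfs_months, c(120, 120, 60))
  expect_equal(out$dfs_event, c(FALSE, TRUE, FALSE))
  expect_error(truncate_dfs(-1, TRUE), "negative")
})

test_that("km_estimate matches hand products and the survfit reference", {
  # no censoring: empirical survival
  km <- km_estimate(1:4, rep(TRUE, 4))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  # all censored: flat at 1
  expect_true(all(km_estimate(1:5, rep(FALSE, 5))$surv == 1))
  # 1 event, 2 censored, 3 event: S(3) = 0.75 * 0.5 = 0.375
  km2 <- km_estimate(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(km2$surv[km2$time == 3], 0.75 * 0.5)
  expect_error(km_estimate(numeric(0), logical(0)), "empty")

  set.seed(6)
  for (i in 1:20) {
    n <- 8
    t <- sample(1:6, n, replace = TRUE)
    e <- runif(n) < 0.6
    km <- km_estimate(t, e)
    sf <- survival::survfit(survival::Surv(t, e) ~ 1)
    expect_equal(km$surv, summary(sf, times = km$time)$surv,
                 tolerance = 1e-12)
    # brute-force risk-set oracle
    expect_equal(km$surv, km_oracle(t, e)$surv, tolerance = 1e-12)
  }
})

test_that("logrank matches survdiff and the brute-force oracle", {
  # identical groups: statistic 0, p 1
  g <- list(list(times = c(1, 2, 3), events = c(TRUE, TRUE, FALSE)),
            list(times = c(1, 2, 3), events = c(TRUE, TRUE, FALSE)))
  out <- logrank(g)
  expect_equal(out$statistic, 0)
  expect_equal(out$raw_p, 1)

  # three groups: df = 2
  set.seed(7)
  t <- rexp(30); e <- runif(30) < 0.7; grp <- factor(sample(1:3, 30, TRUE))
  expect_equal(logrank(list(time = t, event = e, group = grp))$df, 2)

  for (i in 1:25) {
    n <- sample(6:8, 1)
    t <- sample(1:5, n, replace = TRUE)
    e <- runif(n) < 0.7
    grp <- factor(sample(1:2, n, replace = TRUE))
    if (nlevels(droplevels(grp)) < 2 || !any(e)) next
    mine <- logrank(list(time = t, event = e, group = grp))
    ref <- survival::survdiff(survival::Surv(t, e) ~ grp)
    expect_equal(mine$statistic, ref$chisq, tolerance = 1e-9)
    expect_equal(mine$statistic, logrank_oracle(t, e, grp), tolerance = 1e-9)
  }

  # all censored everywhere: degenerate, p 1 with flag
  dg <- logrank(list(time = c(1, 2, 3, 4), event = rep(FALSE, 4),
                     group = factor(c(1, 1, 2, 2))))
  expect_true(dg$degenerate)
  expect_equal(dg$raw_p, 1)
})

test_that("perm_adjust handles degenerate outcomes and matches enumeration", {
  g <- factor(c("a", "a", "a", "b", "b", "b"))
  # constant outcome: every permutation identical
  out <- perm_adjust("response_chisq", rep("responder", 6), g, B = 50,
                     seed = 1)
  expect_equal(out$adjusted_p, 1)
  expect_equal(out$flag, "degenerate_outcome")

  # exact enumeration oracle at n = 6 (response endpoint)
  y <- c("responder", "responder", "responder", "responder",
         "non-responder", "non-responder")
  obs <- response_chisq(table(g, factor(y, c("responder", "non-responder"))))
  allp <- vapply(all_perms(1:6), function(ix) {
    response_chisq(table(g, factor(y[ix],
                                   c("responder", "non-responder"))))$raw_p
  }, numeric(1))
  exact <- mean(allp <= obs$raw_p * (1 + 1e-9))
  mc <- perm_adjust("response_chisq", y, g, B = 20000, seed = 2)
  expect_equal(mc$raw_p, obs$raw_p)
  expect_lt(abs(mc$adjusted_p - exact),
            0.02 + 3 * sqrt(exact * (1 - exact) / 20000))

  # survival flavor: exact enumeration at n = 6
  tt <- c(1, 2, 3, 4, 5, 6)
  ee <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  obs_lr <- logrank(list(time = tt, event = ee, group = g))
  allp_lr <- vapply(all_perms(1:6), function(ix) {
    logrank(list(time = tt[ix], event = ee[ix], group = g))$raw_p
  }, numeric(1))
  exact_lr <- mean(allp_lr <= obs_lr$raw_p * (1 + 1e-9))
  mc_lr <- perm_adjust("dfs_logrank", data.frame(time = tt, event = ee), g,
                       B = 20000, seed = 3)
  expect_lt(abs(mc_lr$adjusted_p - exact_lr),
            0.02 + 3 * sqrt(exact_lr * (1 - exact_lr) / 20000))
})

test_that("perm_adjust respects strata and the add-one grid", {
  set.seed(9)
  n <- 40
  g <- factor(rbinom(n, 1, 0.4))
  y <- ifelse(runif(n) < 0.5, "responder", "non-responder")
  strata <- rep(c("neo", "adj"), each = n / 2)
  out <- perm_adjust("response_chisq", y, g, B = 99, strata = strata,
                     seed = 10)
  expect_true(out$adjusted_p %in% ((1:100) / 100))
  out2 <- perm_adjust("response_chisq", y, g, B = 99, strata = strata,
                      seed = 10)
  expect_identical(out$adjusted_p, out2$adjusted_p)
})

test_that("the vectorized response scan agrees with perm_adjust exactly", {
  set.seed(11)
  n <- 60
  g <- factor(rbinom(n, 2, 0.4), levels = 0:2)
  y <- ifelse(runif(n) < plogis(-0.3 + 0.8 * as.integer(as.character(g))),
              "responder", "non-responder")
  pa <- perm_adjust("response_chisq", y, g, B = 400, seed = 12)
  sc <- pgxprio:::.perm_scan_response(list(v = g), y, B = 400, seed = 12)
  expect_equal(sc$raw_p, pa$raw_p)
  expect_equal(sc$adjusted_p, pa$adjusted_p)

  # survival scan vs perm_adjust under the same seed
  tt <- rexp(n, 0.02 * 1.5^as.integer(as.character(g)))
  ee <- tt < 80
  pa2 <- perm_adjust("dfs_logrank", data.frame(time = tt, event = ee), g,
                     B = 200, seed = 13)
  sc2 <- pgxprio:::.perm_scan_dfs(list(v = g), tt, ee, B = 200, seed = 13)
  expect_equal(sc2$raw_p, pa2$raw_p)
  expect_equal(sc2$adjusted_p, pa2$adjusted_p)
})

test_that("cox_fit reproduces the log-rank score test and flags degeneracy", {
  # tie-free two-group data: score test at beta = 0 equals the log-rank
  set.seed(14)
  n <- 60
  g <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.05 * 2^g) + cumsum(rep(1e-7, n))  # break ties
  e <- rep(TRUE, n)
  lr <- logrank(list(time = t, event = e, group = factor(g)))
  cf <- survival::coxph(survival::Surv(t, e) ~ g)
  expect_equal(unname(cf$score), lr$statistic, tolerance = 1e-6)

  # LRT p present and CI brackets the estimate
  fit <- cox_fit(t, e, g)
  expect_true(fit$ci[1, 1] <= fit$hr[1] && fit$hr[1] <= fit$ci[1, 2])
  expect_lt(fit$p_lrt, 0.05)
  expect_equal(fit$flag, "ok")

  # monotone likelihood (no events in a group) is flagged
  t2 <- c(rexp(20, 1), rep(50, 20))
  e2 <- c(rep(TRUE, 20), rep(FALSE, 20))
  g2 <- rep(0:1, each = 20)
  fit2 <- cox_fit(t2, e2, g2)
  expect_true(fit2$flag != "ok")
  expect_error(cox_fit(c(1, 2), c(FALSE, FALSE), c(0, 1)), "no events")
})

test_that("logistic_fit agrees asymptotically with Pearson and flags separation", {
  set.seed(15)
  n <- 400
  g <- rbinom(n, 1, 0.5)
  y <- runif(n) < plogis(-0.2 + 0.9 * g)
  fit <- logistic_fit(y, g)
  tab <- table(factor(g), factor(!y))  # rows groups, col1 = responders
  chis <- response_chisq(tab)
  expect_lt(abs(fit$p_lrt - chis$raw_p) / chis$raw_p, 0.2)
  expect_equal(fit$flag, "ok")

  # perfect separation flagged, not silently estimated
  ys <- g == 1
  fit2 <- logistic_fit(ys, g)
  expect_true(fit2$flag != "ok")
})

test_that("multiplicity corrections match hand-stepped procedures", {
  p <- c(0.011, 0.02, 0.04, 0.4, 0.009)
  expect_equal(adjust_pvalues(p, "bonferroni"), pmin(5 * p, 1))
  expect_equal(adjust_pvalues(p, "holm"), holm_oracle(p))
  expect_equal(adjust_pvalues(p, "hochberg"), hochberg_oracle(p))
  expect_equal(adjust_pvalues(p, "hommel"), hommel_oracle(p))
  expect_equal(adjust_pvalues(p, "fdr_bh"), bh_oracle(p))
  # single p unchanged under every method
  for (m in c("bonferroni", "holm", "hochberg", "hommel", "fdr_bh")) {
    expect_equal(adjust_pvalues(0.03, m), 0.03)
  }
  expect_equal(adjust_pvalues(c(0.01, 0.04), "bonferroni"), c(0.02, 0.08))
  # dominance: bonferroni >= holm >= raw
  set.seed(16)
  pr <- runif(10)
  expect_true(all(adjust_pvalues(pr, "bonferroni") >=
                    adjust_pvalues(pr, "holm") - 1e-12))
  expect_true(all(adjust_pvalues(pr, "holm") >= pr - 1e-12))
  expect_error(adjust_pvalues(c(0.5, 1.2), "holm"), "\\[0, 1\\]")
})
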