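strata_row <- function(pid, discharge, arm = "HOSPITALIZED",
                       hf_group = "pHF", index_ed = paste0(pid, "-ed"),
                       index_hosp = paste0(pid, "-h")) {
  s <- data.frame(patient_id = pid, arm = arm, hf_group = hf_group,
                  index_episode_id = index_ed, index_hosp_id = index_hosp,
                  index_admission_date = as.Date(discharge) - 8,
                  index_discharge_date = as.Date(discharge))
  class(s) <- c("cohort_strata", class(s))
  s
}

test_that("crude event rates count patients with events in the window", {
  s <- do.call(rbind, lapply(1:4, function(k)
    strata_row(paste0("p", k), "2018-03-01")))
  class(s) <- c("cohort_strata", class(s))
  # two of four patients readmitted within 30 days of discharge
  eps <- bind_episodes(
    make_episode("p1", "p1-r", "HOSPITALIZATION", "2018-03-10",
                 "2018-03-15", disposition = "HOME"),
    make_episode("p2", "p2-r", "HOSPITALIZATION", "2018-03-25",
                 "2018-03-28", disposition = "HOME"),
    make_episode("p3", "p3-r", "HOSPITALIZATION", "2018-06-01",
                 "2018-06-04", disposition = "HOME"))
  r <- event_rate(s, eps, no_vitals(), "READMISSION", 30L)
  expect_equal(r$numerator, 2L)
  expect_equal(r$denominator, 4L)
  expect_equal(r$rate, 0.5)

  # no post-discharge episodes at all
  r0 <- event_rate(s, eps[0, ], no_vitals(), "READMISSION", 30L)
  expect_equal(r0$rate, 0)

  # the index hospitalization itself never counts
  eps_idx <- make_episode("p1", "p1-h", "HOSPITALIZATION", "2018-02-21",
                          "2018-03-01", disposition = "HOME")
  r1 <- event_rate(s[1, ], eps_idx, no_vitals(), "READMISSION", 30L)
  expect_equal(r1$numerator, 0L)

  # mortality is cumulative at the cut-off (in-hospital deaths included)
  vit <- vitals_of(c("p1", "p2", "p3", "p4"),
                   c("2018-03-01", "2018-03-20", "2018-06-30", NA))
  rd30 <- event_rate(s, eps, vit, "DEATH", 30L)
  expect_equal(rd30$numerator, 2L)  # death at discharge + death day 19
  rd365 <- event_rate(s, eps, vit, "DEATH", 365L)
  expect_equal(rd365$numerator, 3L)

  # monotone in the cut-off for every event type
  for (ev in c("DEATH", "READMISSION", "RE_ED_VISIT")) {
    expect_lte(event_rate(s, eps, vit, ev, 30L)$rate,
               event_rate(s, eps, vit, ev, 365L)$rate)
  }

  expect_error(event_rate(s[0, ], eps, vit, "DEATH", 30L), "empty")
})

test_that("planted readmission risk is recovered from a generated cohort", {
  coh <- small_cohort(seed = 5150, n_hosp = 700L, n_home = 0L, n_died = 0L)
  s <- build_strata(coh$episodes, coh$vitals, 2018)
  r <- event_rate(s, coh$episodes, coh$vitals, "READMISSION", 30L)
  # pooled planted probability ~0.1335 across the two groups
  p <- 0.1335
  se <- sqrt(p * (1 - p) / r$denominator)
  expect_lt(abs(r$rate - p), 3 * se)
})

test_that("Kaplan-Meier estimate equals the hand product-limit oracle", {
  # no deaths: flat at 1
  km0 <- km_estimate(rep(10, 6), rep(0, 6))
  expect_true(all(km0$survival == 1))

  # 5 patients, one death at day 2: S(2) = 0.8
  km1 <- km_estimate(c(2, 5, 7, 9, 11), c(1, 0, 0, 0, 0))
  expect_equal(km1$survival[km1$times == 2], 0.8)

  # random data vs an independent product over risk sets
  set.seed(88)
  time <- sample(1:50, 10, replace = TRUE)
  status <- rbinom(10, 1, 0.6)
  km <- km_estimate(time, status)
  hand <- function(t) {
    s <- 1
    for (u in sort(unique(time[status == 1]))) {
      if (u > t) break
      d <- sum(time == u & status == 1)
      n <- sum(time >= u)
      s <- s * (1 - d / n)
    }
    s
  }
  for (i in seq_len(nrow(km)))
    expect_equal(km$survival[i], hand(km$times[i]))

  # without censoring, KM is the empirical survival function
  t2 <- c(3, 5, 5, 8, 12)
  km2 <- km_estimate(t2, rep(1, 5))
  for (i in seq_len(nrow(km2)))
    expect_equal(km2$survival[i], mean(t2 > km2$times[i]))
})

test_that("log-rank behaves at its boundary cases and matches the O-E form", {
  # identical groups: no evidence
  t <- c(2, 4, 6, 8); st <- c(1, 0, 1, 0)
  lr0 <- log_rank(t, st, t, st)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)

  # 6-patient example: hand observed-minus-expected over risk sets
  ta <- c(1, 3, 5); sa <- c(1, 1, 0)
  tb <- c(2, 4, 6); sb <- c(0, 1, 1)
  lr <- log_rank(ta, sa, tb, sb)
  oe <- local({
    time <- c(ta, tb); status <- c(sa, sb)
    grp <- rep(c(0, 1), each = 3)
    o <- e <- v <- 0
    for (u in sort(unique(time[status == 1]))) {
      at_risk <- time >= u
      n <- sum(at_risk); n1 <- sum(at_risk & grp == 1)
      d <- sum(time == u & status == 1)
      d1 <- sum(time == u & status == 1 & grp == 1)
      o <- o + d1
      e <- e + d * n1 / n
      if (n > 1)
        v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (o - e)^2 / v
  })
  expect_equal(lr$statistic, oe, tolerance = 1e-10)

  expect_error(log_rank(c(1, 2), c(0, 0), c(3, 4), c(0, 0)), "no events")
})

test_that("log-rank p agrees with a permutation oracle on a small cohort", {
  set.seed(321)
  ta <- rexp(15, 0.05); tb <- rexp(15, 0.12)
  ca <- pmin(ta, 30); cb <- pmin(tb, 30)
  sa <- as.integer(ta <= 30); sb <- as.integer(tb <= 30)
  obs <- log_rank(ca, sa, cb, sb)
  time <- c(ca, cb); status <- c(sa, sb)
  perm <- replicate(200, {
    pick <- sample(30, 15)
    log_rank(time[pick], status[pick], time[-pick],
             status[-pick])$statistic
  })
  p_perm <- mean(perm >= obs$statistic)
  mc_err <- 3 * sqrt(max(obs$p_value * (1 - obs$p_value), 0.002) / 200)
  expect_lt(abs(p_perm - obs$p_value), mc_err + 0.02)
})

test_that("null log-rank p-values are approximately uniform", {
  set.seed(777)
  pvals <- replicate(200, {
    t1 <- rexp(40, 0.05); t2 <- rexp(40, 0.05)
    log_rank(pmin(t1, 60), as.integer(t1 <= 60),
             pmin(t2, 60), as.integer(t2 <= 60))$p_value
  })
  frac <- mean(pvals < 0.05)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.10)
})

test_that("group comparisons dispatch to the declared scale", {
  # hand-computed chi-square on (10,90) vs (20,80): expecteds 15/85
  ch <- compare_groups(c(10, 90), c(20, 80), "categorical")
  expect_equal(ch$test_name, "chi_square")
  expect_equal(round(ch$statistic, 2), 3.92)

  same <- compare_groups(c(30, 70), c(30, 70), "categorical")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  x <- c(1, 2, 3, 4, 5)
  tt <- compare_groups(x, x + 0, "continuous_normal")
  expect_equal(tt$test_name, "t")
  expect_equal(tt$statistic, 0)

  mw <- compare_groups(rexp(20), rexp(20), "continuous_skewed")
  expect_equal(mw$test_name, "mann_whitney")
  expect_true(mw$p_value >= 0 && mw$p_value <= 1)

  expect_error(compare_groups(numeric(), 1:3, "continuous_normal"), "empty")
})
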