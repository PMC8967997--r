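test_that("episode cost roll-ups sum components and enforce contracts", {
  items <- data.frame(
    episode_id = "e1",
    category = c("DIRECT", "CATALOG", "RESIDUAL"),
    description = c("stay", "labs", "overhead"),
    quantity = c(NA, 2, NA), unit_cost = c(NA, 50, NA),
    amount = c(100, 100, 30))
  ec <- episode_cost(items)
  expect_equal(ec$direct, 100)
  expect_equal(ec$catalog, 100)
  expect_equal(ec$residual, 30)
  expect_equal(ec$total, 230)

  empty <- episode_cost(items[0, ])
  expect_equal(empty$total, 0)

  mixed <- items; mixed$episode_id <- c("e1", "e1", "e2")
  expect_error(episode_cost(mixed), "single episode")
  neg <- items; neg$amount[1] <- -5
  expect_error(episode_cost(neg), "negative")
})

test_that("ledger roll-up equals an independent group-by-sum oracle", {
  set.seed(12)
  n <- 1000
  ledger <- data.frame(
    episode_id = sprintf("e%03d", sample(60, n, replace = TRUE)),
    category = sample(cost_categories(), n, replace = TRUE),
    description = "x", quantity = NA_real_, unit_cost = NA_real_,
    amount = round(runif(n, 0, 500), 2))
  tab <- episode_cost_table(ledger)
  oracle <- tapply(ledger$amount, ledger$episode_id, sum)
  expect_equal(tab$total, as.numeric(oracle[tab$episode_id]))
  by_cat <- tapply(ledger$amount[ledger$category == "DIRECT"],
                   ledger$episode_id[ledger$category == "DIRECT"], sum)
  got <- tab$direct[match(names(by_cat), tab$episode_id)]
  expect_equal(got, as.numeric(by_cat))
})

test_that("residual allocation is proportional and conserves the pool in cents", {
  eps <- data.frame(episode_id = c("h1", "h2"), kind = "HOSPITALIZATION",
                    start_date = as.Date(c("2018-01-01", "2018-02-01")),
                    end_date = as.Date(c("2018-01-04", "2018-02-08")))
  a <- allocate_residual(1000, eps)
  expect_equal(a$amount, c(300, 700))
  expect_equal(a$category, rep("RESIDUAL", 2))

  single <- allocate_residual(123.45, eps[1, ])
  expect_equal(single$amount, 123.45)

  # largest-remainder: three equal weights split 100.00 as 33.34/33.33/33.33
  eq <- data.frame(episode_id = c("a", "b", "c"), kind = "HOSPITALIZATION",
                   start_date = as.Date("2018-01-01"),
                   end_date = as.Date("2018-01-02"))
  a3 <- allocate_residual(100, eq)
  expect_equal(a3$amount, c(33.34, 33.33, 33.33))
  expect_equal(sum(a3$amount), 100)

  expect_error(split_amount(10, c(0, 0)), "zero")

  # conservation holds for arbitrary pools and weights
  set.seed(5)
  for (k in 1:25) {
    pool <- round(runif(1, 0, 1e5), 2)
    w <- runif(sample(2:8, 1))
    shares <- split_amount(pool, w)
    expect_equal(sum(shares), pool)
    expect_true(all(shares >= 0))
  }
})

test_that("journey cost summaries aggregate a generated cohort exactly", {
  coh <- small_cohort(seed = 303, n_hosp = 50L, n_home = 15L, n_died = 1L)
  s <- build_strata(coh$episodes, coh$vitals, 2018)
  ec <- episode_cost_table(coh$costs)
  hosp <- s[s$arm == "HOSPITALIZED", ]
  cs <- journey_cost_summary(hosp, coh$episodes, ec, horizon = 365L)

  # cost conservation: items -> episodes -> status splits -> group totals
  expect_equal(sum(ec$total), sum(coh$costs$amount))
  for (g in cs$by_group$hf_group) {
    grp <- cs$by_group[cs$by_group$hf_group == g, ]
    st <- cs$by_status[cs$by_status$hf_group == g, ]
    expect_equal(sum(st$cost), grp$total_cost, tolerance = 1e-9)
    expect_equal(sum(st$pct_of_total), 100, tolerance = 1e-6)
    expect_equal(grp$patient_days, grp$n_patients * 365)
    # per-day x horizon identity under the fixed-horizon convention
    expect_equal(grp$mean_cost_per_patient_day * 365,
                 grp$mean_cost_per_journey, tolerance = 1e-9)
    kinds <- cs$by_kind[cs$by_kind$hf_group == g, ]
    expect_equal(sum(kinds$cost), grp$total_cost, tolerance = 1e-9)
    expect_equal(sum(kinds$n_episodes), grp$n_episodes)
  }

  expect_error(journey_cost_summary(hosp[0, ], coh$episodes, ec),
               "no patients")
})

test_that("reference aggregates reproduce the published derived figures", {
  chk <- reference_cost_checks()
  expect_equal(chk$patient_days_pHF, 375585)
  expect_equal(chk$patient_days_sHF, 458805)
  expect_equal(round(chk$mean_cost_per_journey_pHF, 1), 8887.2)
  expect_equal(round(chk$mean_cost_per_journey_sHF, 1), 9755.3)
  expect_equal(round(chk$mean_cost_per_patient_day_sHF, 2), 26.73)
  expect_equal(round(chk$mean_cost_per_episode_pHF, 2), 1856.84)
  expect_equal(round(chk$mean_index_hosp_episode_cost_sHF, 1), 4656.1)
  expect_equal(round(chk$pct_total_cost_excess_sHF), 34)
  expect_equal(round(chk$pct_journey_mean_excess_sHF, 1), 9.8)
  expect_equal(round(chk$pct_index_hosp_episode_excess_sHF, 1), 19.2)
  expect_equal(round(chk$pct_readmission_episode_excess_sHF, 1), 5.3)
  expect_equal(round(chk$pct_day_hospital_episode_excess_sHF, 1), 35.7)
})

test_that("pct_diff satisfies its antisymmetry identity", {
  for (pair in list(c(3, 2), c(10, 25), c(1.5, 1.5))) {
    d <- pct_diff(pair[1], pair[2])
    expect_equal(pct_diff(pair[2], pair[1]), -d / (1 + d), tolerance = 1e-12)
  }
})

test_that("daily cost curves spread episodes uniformly and conserve totals", {
  eps <- make_episode("p", "h", "HOSPITALIZATION", "2018-01-01",
                      "2018-01-09", disposition = "HOME")
  j <- patient_journey("p", eps, no_vitals(), "2018-01-01", 30, "h")
  ec <- data.frame(episode_id = "h", direct = 800, catalog = 0,
                   residual = 0, total = 800)
  curve <- daily_cost_curve(j, ec)
  expect_equal(curve$cost[1:8], rep(100, 8))
  expect_equal(curve$cost[9:30], rep(0, 22))
  expect_equal(curve$cumulative[30], 800)

  # empty journey: zero curve
  j0 <- patient_journey("q", eps[0, ], no_vitals(), "2018-01-01", 30)
  expect_true(all(daily_cost_curve(j0, ec)$cost == 0))

  # conservation on a generated journey
  coh <- small_cohort(seed = 99, n_hosp = 5L, n_home = 0L, n_died = 0L)
  s <- build_strata(coh$episodes, coh$vitals, 2018)
  ectab <- episode_cost_table(coh$costs)
  js <- cohort_journeys(s, coh$episodes, coh$vitals, 365L)
  for (j1 in js) {
    cur <- daily_cost_curve(j1, ectab)
    in_window <- j1$episodes$episode_id
    expect_equal(cur$cumulative[365],
                 sum(ectab$total[ectab$episode_id %in% in_window],
                     na.rm = TRUE),
                 tolerance = 0.02)
    expect_true(all(diff(cur$cumulative) >= -1e-9))
  }
})
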