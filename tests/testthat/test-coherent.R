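test_that("daily states follow episode coverage, death and the hierarchy", {
  # ED index on days 0-1, death on day 10, horizon 30
  eps <- make_episode("p1", "e1", "ED", "2018-02-01", "2018-02-02",
                      disposition = "HOME")
  j <- patient_journey("p1", eps, vitals_of("p1", "2018-02-11"),
                       "2018-02-01", 30, "e1")
  st <- as.character(assign_daily_states(j))
  expect_equal(st, c(rep("IN_ED_INDEX", 2), rep("AT_HOME", 8),
                     rep("DEAD", 20)))

  # same-day ED + admission: hierarchy renders day 0 as hospital
  eps2 <- bind_episodes(
    make_episode("p2", "ed", "ED", "2018-02-01", disposition = "ADMITTED"),
    make_episode("p2", "h", "HOSPITALIZATION", "2018-02-01", "2018-02-09",
                 disposition = "HOME"))
  j2 <- patient_journey("p2", eps2, no_vitals(), "2018-02-01", 30,
                        c("ed", "h"))
  st2 <- as.character(assign_daily_states(j2))
  expect_equal(st2, c(rep("IN_HOSPITAL_INDEX", 8), rep("AT_HOME", 22)))

  # outpatient visit during an ongoing readmission loses to the hierarchy
  eps3 <- bind_episodes(
    make_episode("p3", "r", "HOSPITALIZATION", "2018-02-04", "2018-02-10",
                 disposition = "HOME"),
    make_episode("p3", "o", "OUTPATIENT", "2018-02-06"))
  j3 <- patient_journey("p3", eps3, no_vitals(), "2018-02-01", 30)
  st3 <- as.character(assign_daily_states(j3))
  expect_equal(st3[6], "IN_HOSPITAL_READMISSION")
  expect_equal(st3[4:9], rep("IN_HOSPITAL_READMISSION", 6))

  # hospital days are half-open: discharge day is not in hospital
  expect_equal(st3[10], "AT_HOME")

  # episode order must not matter
  j3r <- patient_journey("p3", eps3[2:1, ], no_vitals(), "2018-02-01", 30)
  expect_equal(assign_daily_states(j3r), assign_daily_states(j3))
})

test_that("state sequences match a brute-force day-by-day oracle", {
  set.seed(7321)
  for (k in 1:60) {
    j <- random_journey(sprintf("r%03d", k),
                        horizon = sample(c(30L, 365L), 1))
    expect_equal(assign_daily_states(j), oracle_states(j),
                 info = paste("journey", k))
  }
})

test_that("occupancy fractions are column-stochastic and match a tally oracle", {
  # 1 patient always home
  j_home <- patient_journey("a", make_episode("a", "x", "ED",
                                              "2018-01-01")[0, ],
                            no_vitals(), "2018-01-01", 30)
  m <- occupancy(list(j_home))
  expect_equal(unname(m[, "AT_HOME"]), rep(1, 30))

  # 2 patients, one dies on day 0
  j_dead <- patient_journey("b", make_episode("b", "x", "ED",
                                              "2018-01-01")[0, ],
                            vitals_of("b", "2018-01-01"), "2018-01-01", 30)
  m2 <- occupancy(list(j_home, j_dead))
  expect_equal(unname(m2[, "DEAD"]), rep(0.5, 30))
  expect_equal(attr(m2, "n"), 2L)

  # independent per-patient tally on a batch of random journeys
  set.seed(991)
  js <- lapply(1:40, function(k) random_journey(sprintf("t%02d", k), 30L))
  m3 <- occupancy(js)
  tally <- matrix(0, 30, length(clinical_states()),
                  dimnames = list(NULL, clinical_states()))
  for (j in js) {
    st <- oracle_states(j)
    for (d in 1:30) tally[d, as.character(st[d])] <-
      tally[d, as.character(st[d])] + 1
  }
  expect_equal(unclass(m3), tally / length(js), ignore_attr = TRUE)
  expect_equal(unname(rowSums(m3)), rep(1, 30))
  expect_true(all(diff(m3[, "DEAD"]) >= 0))

  expect_error(occupancy(list()), "empty")
})

test_that("journey summaries count days by category and conserve the horizon", {
  # 365-day journey: 12 hospital days, 2 ED days, 10 outpatient, no death
  eps <- bind_episodes(
    make_episode("p", "ed", "ED", "2018-01-01", "2018-01-02",
                 disposition = "ADMITTED"),
    make_episode("p", "h", "HOSPITALIZATION", "2018-01-02", "2018-01-14",
                 disposition = "HOME"),
    do.call(rbind, lapply(1:10, function(k)
      make_episode("p", paste0("o", k), "OUTPATIENT",
                   as.Date("2018-02-01") + 3 * k))))
  j <- patient_journey("p", eps, no_vitals(), "2018-01-01", 365,
                       c("ed", "h"))
  s <- summarize_journey(j)
  expect_equal(s$days_in_hospital, 12L)
  expect_equal(s$days_with_ED_visit, 1L)  # day 0 only; day 1 is admission
  expect_equal(s$days_with_outpatient_visit, 10L)
  expect_equal(s$days_at_home, 365L - 12L - 1L - 10L)
  expect_equal(s$days_at_home + s$days_in_hospital + s$days_with_ED_visit +
                 s$days_in_day_hospital + s$days_with_outpatient_visit +
                 s$days_dead, 365L)

  # death on day 0: everything is DEAD, share-at-home defined as 1
  j0 <- patient_journey("q", eps[0, ], vitals_of("q", "2018-01-01"),
                        "2018-01-01", 365)
  s0 <- summarize_journey(j0)
  expect_equal(s0$days_dead, 365L)
  expect_equal(s0$pct_home_of_alive_out_of_hospital, 1)

  # hand-computed share: alive 300, hospital 20, home 270, other contact 10
  eps2 <- bind_episodes(
    make_episode("w", "h", "HOSPITALIZATION", "2018-01-01", "2018-01-21",
                 disposition = "HOME"),
    do.call(rbind, lapply(1:10, function(k)
      make_episode("w", paste0("d", k), "DAY_HOSPITAL",
                   as.Date("2018-01-21") + k))))
  j2 <- patient_journey("w", eps2, vitals_of("w", "2018-10-28"),
                        "2018-01-01", 365, "h")
  s2 <- summarize_journey(j2)
  expect_equal(s2$days_dead, 65L)
  expect_equal(s2$days_in_hospital, 20L)
  expect_equal(s2$days_at_home, 270L)
  expect_equal(s2$pct_home_of_alive_out_of_hospital, 270 / 280)
})

test_that("journey day counts always sum to the horizon", {
  set.seed(4821)
  for (k in 1:50) {
    j <- random_journey(sprintf("c%02d", k), 365L)
    s <- summarize_journey(j)
    expect_equal(s$days_at_home + s$days_in_hospital +
                   s$days_with_ED_visit + s$days_in_day_hospital +
                   s$days_with_outpatient_visit + s$days_dead, 365L)
  }
})

test_that("length of stay uses the discharge-minus-admission and dates-touched conventions", {
  expect_equal(length_of_stay("HOSPITALIZATION", "2018-03-01", "2018-03-09"),
               8L)
  expect_equal(length_of_stay("HOSPITALIZATION", "2018-03-01", "2018-03-01"),
               0L)
  expect_equal(length_of_stay("ED", "2018-03-01", "2018-03-01"), 1L)
  expect_equal(length_of_stay("ED", "2018-03-01", "2018-03-02"), 2L)
  expect_equal(length_of_stay(c("HOSPITALIZATION", "ED"),
                              c("2018-03-01", "2018-03-01"),
                              c("2018-03-05", "2018-03-02")), c(4L, 2L))
  expect_error(length_of_stay("OUTPATIENT", "2018-03-01", "2018-03-01"),
               "defined for")
  expect_error(length_of_stay("ED", "2018-03-02", "2018-03-01"), "before")
})
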