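test_that("kaplan_meier matches hand product-limit computations", {
  # all censored: survival never drops
  km0 <- kaplan_meier(rep(2, 5), rep(0, 5))
  expect_true(all(km0$survival == 1))

  # no censoring: S = 3/4, 2/4, 1/4, 0
  km1 <- kaplan_meier(1:4, rep(1, 4))
  expect_equal(km1$survival, c(3, 2, 1, 0) / 4)

  # tied event and censoring at t = 1: the event comes first (risk set 3),
  # the censored subject then leaves, so S(1) = 2/3 and S(2) = 0
  km2 <- kaplan_meier(c(1, 1, 2), c(1, 0, 1))
  expect_equal(survival_at(km2, 1), 2 / 3)
  expect_equal(survival_at(km2, 2), 0)
  expect_equal(survival_at(km2, 0.5), 1)

  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "non-negative")
  expect_error(kaplan_meier(1:3, c(1, 1)), "equal length")
})

test_that("aalen_johansen handles the no-event and hand-derived cases", {
  # no events: P(0, t) is the identity at every t
  quiet <- make_cohort("q", t_rec = rep(NA_real_, 6), t_death = rep(NA_real_, 6),
                       t_cens = rep(4, 6))
  f0 <- aalen_johansen(quiet)
  expect_equal(length(f0$times), 0)
  expect_equal(unname(aj_prob(f0, 2)), diag(3))

  # 4 subjects, no censoring: stable->death at 0.5; stable->recurrence at
  # 0.6 with death at 0.9; two event-free. Hand product-integral:
  # P(0,1) row 1 = (1/2, 0, 1/2), row 2 = (0, 0, 1)
  coh4 <- make_cohort("x", t_rec = c(NA, 0.6, NA, NA),
                      t_death = c(0.5, 0.9, NA, NA), t_cens = rep(5, 4))
  f4 <- aalen_johansen(coh4)
  P1 <- aj_prob(f4, 1)
  expect_equal(unname(P1[1, ]), c(0.5, 0, 0.5), tolerance = 1e-14)
  expect_equal(unname(P1[2, ]), c(0, 0, 1), tolerance = 1e-14)
  # matches the enumeration oracle
  expect_equal(P1[1, ], occupancy_at(coh4, 1), tolerance = 1e-14)

  # inconsistent record rejected
  bad <- make_cohort("b", t_rec = 3, t_death = 2, t_cens = 10)
  expect_error(aalen_johansen(bad), "recurrence after death")
})

test_that("aalen_johansen equals empirical occupancy on censoring-free cohorts", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(3:20, 1)
    coh <- random_uncensored_cohort(n)
    fit <- aalen_johansen(coh)
    for (t in c(0.5, 1, 2.5, 4.9)) {
      expect_equal(aj_prob(fit, t)[1, ], occupancy_at(coh, t), tolerance = 1e-12)
    }
    # conservation at every transition time
    for (k in seq_along(fit$times))
      expect_equal(rowSums(fit$P[, , k]), c(stable = 1, recurrence = 1, death = 1),
                   tolerance = 1e-12)
  }
})

test_that("aalen_johansen agrees with survival::survfit multi-state under censoring", {
  coh <- generate_cohort(cohort_params(n_per_arm = 120, seed = 31))
  d <- coh[coh$arm == "C-TACE", ]
  fit <- aalen_johansen(d)

  # independent route: survfit on the counting-process representation
  rec <- d$event_recurrence == 1
  start <- c(rep(0, nrow(d)), d$t_recurrence[rec])
  stop_ <- c(ifelse(rec, d$t_recurrence,
                    ifelse(d$event_death == 1, d$t_death, d$t_censor)),
             ifelse(d$event_death[rec] == 1, d$t_death[rec], d$t_censor[rec]))
  to <- c(ifelse(rec, "recurrence", ifelse(d$event_death == 1, "death", "censor")),
          ifelse(d$event_death[rec] == 1, "death", "censor"))
  ev <- factor(ifelse(to == "censor", "censor", to),
               levels = c("censor", "recurrence", "death"))
  sf <- survival::survfit(
    survival::Surv(start, stop_, ev) ~ 1,
    id = c(d$id, d$id[rec]),
    istate = factor(c(rep("stable", nrow(d)), rep("recurrence", sum(rec))),
                    levels = c("stable", "recurrence", "death")))
  # occupancy starting from stable = first row of P(0, t)
  for (t in c(0.5, 1, 3, 8)) {
    idx <- max(which(sf$time <= t))
    expect_equal(unname(aj_prob(fit, t)[1, ]),
                 unname(sf$pstate[idx, ]), tolerance = 1e-10)
  }
})

test_that("two-state reduction reproduces Kaplan-Meier exactly", {
  # no recurrence possible: 1 - P_stable,death must equal the KM estimate
  # at every transition time
  h <- c(h_sr = 0, h_sd = 0.15, h_rd = 0.3)
  coh <- generate_cohort(cohort_params(n_per_arm = 150,
                                       hazards = list("C-TACE" = h, "DEM-TACE" = h),
                                       seed = 21))
  d <- coh[coh$arm == "C-TACE", ]
  expect_equal(sum(d$event_recurrence), 0)
  fit <- aalen_johansen(d)
  t_ev <- ifelse(d$event_death == 1, d$t_death, d$t_censor)
  km <- kaplan_meier(t_ev, d$event_death)
  for (t in fit$times) {
    expect_equal(1 - aj_prob(fit, t)[1, 3], survival_at(km, t), tolerance = 1e-12)
  }
})

test_that("annual_matrix extracts row-stochastic cycle matrices", {
  # identity fit -> identity matrix
  quiet <- make_cohort("q", t_rec = rep(NA_real_, 5), t_death = rep(NA_real_, 5),
                       t_cens = rep(6, 5))
  m0 <- annual_matrix(aalen_johansen(quiet))
  expect_equal(unname(unclass(m0)), diag(3), ignore_attr = TRUE)

  # hand-derived 4-subject cohort, cycle 0: empirical 1-year fractions
  coh4 <- make_cohort("x", t_rec = c(NA, 0.6, NA, NA),
                      t_death = c(0.5, 0.9, NA, NA), t_cens = rep(5, 4))
  m <- annual_matrix(aalen_johansen(coh4))
  expect_equal(m["stable", ], occupancy_at(coh4, 1), tolerance = 1e-14)
  expect_equal(unname(m["recurrence", ]), c(0, 0, 1))

  # any estimated matrix is row-stochastic to 1e-12 with death absorbing
  coh <- generate_cohort(cohort_params(n_per_arm = 80, seed = 14))
  mats <- estimate_transition_matrices(coh)
  for (m in mats) {
    expect_equal(unname(rowSums(unclass(m))), c(1, 1, 1), tolerance = 1e-12)
    expect_equal(unname(unclass(m)[3, ]), c(0, 0, 1))
    expect_equal(unclass(m)[2, 1], 0)
  }

  # beyond follow-up the last informative matrix is carried forward
  fit <- aalen_johansen(coh[coh$arm == "C-TACE", ])
  w <- capture_warnings(
    mats_tv <- annual_matrix(fit, time_varying = TRUE, max_cycles = 20))
  expect_true(any(grepl("carrying previous annual matrix forward", w)))
  expect_identical(mats_tv[[20]], mats_tv[[16]])
})

test_that("transition_matrix validates its invariants", {
  expect_error(transition_matrix(matrix(1, 2, 2)), "3x3")
  bad_sum <- rbind(c(0.5, 0.4, 0.2), c(0, 0.5, 0.5), c(0, 0, 1))
  expect_error(transition_matrix(bad_sum), "sum to 1")
  bad_abs <- rbind(c(0.5, 0.4, 0.1), c(0, 0.5, 0.5), c(0.1, 0, 0.9))
  expect_error(transition_matrix(bad_abs), "absorbing")
  bad_back <- rbind(c(0.5, 0.4, 0.1), c(0.2, 0.3, 0.5), c(0, 0, 1))
  expect_error(transition_matrix(bad_back), "not allowed")
})

test_that("transition matrices survive the long-format CSV round trip", {
  coh <- generate_cohort(cohort_params(n_per_arm = 60, seed = 2))
  mats <- estimate_transition_matrices(coh)
  f <- tempfile(fileext = ".csv")
  write_transition_long(mats, f)
  d <- read.csv(f)
  expect_equal(nrow(d), 2 * 9)
  for (a in names(mats)) {
    da <- d[d$arm == a, ]
    back <- matrix(da$probability[order(match(da$to_state, tacecua:::.states),
                                        match(da$from_state, tacecua:::.states))], 3, 3)
    expect_equal(back, unclass(mats[[a]]), tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})
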