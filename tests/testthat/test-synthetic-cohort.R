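test_that("parameter validation rejects impossible inputs", {
  expect_error(cohort_params(n_per_arm = 0), "n_per_arm")
  expect_error(cohort_params(hazards = list(A = c(-0.1, 0.1, 0.1))), "non-negative")
  expect_error(cohort_params(p_transplant = c("C-TACE" = 1.2, "DEM-TACE" = 0.2)),
               "probability")
  expect_error(cohort_params(accrual_years = 14), "accrual_years")
})

test_that("zero hazards give a fully censored-alive cohort", {
  p <- cohort_params(n_per_arm = 30,
                     hazards = list("C-TACE" = c(0, 0, 0), "DEM-TACE" = c(0, 0, 0)),
                     accrual_years = 0, seed = 3)
  coh <- generate_cohort(p)
  expect_equal(sum(coh$event_recurrence), 0)
  expect_equal(sum(coh$event_death), 0)
  expect_true(all(coh$t_censor == 13.5))
  expect_true(all(is.na(coh$t_death)))
})

test_that("the same seed reproduces the cohort byte for byte", {
  p <- cohort_params(n_per_arm = 40, seed = 77)
  c1 <- generate_cohort(p)
  c2 <- generate_cohort(p)
  expect_identical(c1, c2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(c1, f1); write_cohort(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed does not
  c3 <- generate_cohort(cohort_params(n_per_arm = 40, seed = 78))
  expect_false(identical(c1$t_death, c3$t_death))
})

test_that("default hazards reproduce the study event fractions at large n", {
  coh <- generate_cohort(cohort_params(n_per_arm = 10000, seed = 42))
  s <- summarize_cohort(coh)$events
  targets <- data.frame(arm = c("C-TACE", "DEM-TACE"),
                        rec = c(61.4, 48.5), death = c(76.2, 57.4))
  for (i in 1:2) {
    row <- s[s$arm == targets$arm[i], ]
    expect_lt(abs(row$pct_recurrence - targets$rec[i]), 2)
    expect_lt(abs(row$pct_death - targets$death[i]), 2)
  }
})

test_that("empirical event fractions converge to the analytic competing-risks solution", {
  h <- c(h_sr = 0.2, h_sd = 0.1, h_rd = 0.5)
  p <- cohort_params(n_per_arm = 10000,
                     hazards = list("C-TACE" = h, "DEM-TACE" = h), seed = 9)
  coh <- generate_cohort(p)
  d <- coh[coh$arm == "C-TACE", ]
  # closed-form oracle: observed fractions averaged over Unif(5.5, 13.5)
  # administrative censoring
  truth <- tacecua:::expected_event_fractions(h[1], h[2], h[3], 5.5, 13.5)
  expect_lt(abs(mean(d$event_recurrence) - truth["recurrence"]), 0.02)
  expect_lt(abs(mean(d$event_death) - truth["death"]), 0.02)
})

test_that("with equal stable and recurrence death hazards the marginal death time is exponential", {
  h <- c(h_sr = 0.3, h_sd = 0.25, h_rd = 0.25)
  p <- cohort_params(n_per_arm = 10000, admin_censor_years = 500,
                     accrual_years = 0,
                     hazards = list("C-TACE" = h, "DEM-TACE" = h), seed = 12)
  coh <- generate_cohort(p)
  d <- coh[coh$arm == "C-TACE", ]
  expect_true(all(d$event_death == 1))
  ks <- stats::ks.test(d$t_death, "pexp", rate = 0.25)
  expect_gt(ks$p.value, 0.01)
})

test_that("two-part cost draws have the configured moments and zero median", {
  coh <- generate_cohort(cohort_params(n_per_arm = 10000, seed = 8))
  d <- coh[coh$arm == "C-TACE", ]
  expect_equal(median(d$cost_stable), 0)
  expect_lt(abs(mean(d$cost_stable) - 2463) / 2463, 0.10)
  # log-normal right skew: mean exceeds the median of the positive part
  pos <- d$cost_stable[d$cost_stable > 0]
  expect_gt(mean(pos), median(pos))
  rec <- d$cost_recurrence[d$event_recurrence == 1]
  expect_gt(mean(rec), median(rec))
  expect_lt(abs(mean(rec) - 12406) / 12406, 0.10)
})

test_that("two_part_cost_params inverts the mixture moments", {
  pars <- two_part_cost_params(2463, 6626, p_zero = 0.6)
  m <- exp(pars$meanlog + pars$sdlog^2 / 2) * (1 - pars$p_zero)
  v <- (1 - pars$p_zero) * exp(2 * pars$meanlog + 2 * pars$sdlog^2) - m^2
  expect_equal(m, 2463, tolerance = 1e-10)
  expect_equal(sqrt(v), 6626, tolerance = 1e-10)
  expect_error(two_part_cost_params(100, 1, p_zero = 0.9), "infeasible")
})

test_that("calibrate_hazards recovers rates whose expected fractions hit the targets", {
  h <- calibrate_hazards(0.614, 0.762, h_rd = 0.4)
  f <- tacecua:::expected_event_fractions(h["h_sr"], h["h_sd"], 0.4, 5.5, 13.5)
  expect_equal(unname(f), c(0.614, 0.762), tolerance = 1e-4)
  # and matches the package defaults
  expect_equal(unname(h[1:2]), c(0.1556074, 0.0613557), tolerance = 1e-4)
})

test_that("summarize_cohort reports exact percentages to one decimal", {
  coh <- study_counts_cohort()
  s <- summarize_cohort(coh)
  ev <- s$events
  expect_equal(ev$pct_recurrence[ev$arm == "C-TACE"], 61.4)
  expect_equal(ev$pct_recurrence[ev$arm == "DEM-TACE"], 48.5)
  # no events at all
  quiet <- make_cohort("q", t_rec = rep(NA_real_, 5), t_death = rep(NA_real_, 5),
                       t_cens = rep(2, 5))
  expect_equal(summarize_cohort(quiet)$events$pct_recurrence, 0)
})

test_that("cohort CSV round-trips and malformed files are rejected", {
  coh <- generate_cohort(cohort_params(n_per_arm = 25, seed = 5))
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- read_cohort(f)
  expect_equal(back$event_death, coh$event_death)
  expect_equal(back$t_death, coh$t_death, tolerance = 1e-5)
  expect_equal(names(back), tacecua:::cohort_columns)

  # missing column
  d <- read.csv(f)
  d$t_censor <- NULL
  f2 <- tempfile(fileext = ".csv")
  write.csv(d, f2, row.names = FALSE, na = "")
  expect_error(read_cohort(f2), "t_censor")

  # non-binary event flag, error names column and row
  d <- read.csv(f)
  d$event_death[3] <- 7
  write.csv(d, f2, row.names = FALSE, na = "")
  expect_error(read_cohort(f2), "event_death")

  # recurrence after death is inconsistent
  bad <- make_cohort("b", t_rec = 3, t_death = 2, t_cens = 10)
  expect_error(summarize_cohort(bad), "recurrence after death")
})
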