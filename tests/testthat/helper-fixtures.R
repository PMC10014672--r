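# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# one-arm cohort assembled from explicit per-patient paths
make_cohort <- function(arm, t_rec, t_death, t_cens, transplant = NULL,
                        cost_stable = 0, cost_rec = 0) {
  n <- length(t_cens)
  if (is.null(transplant)) transplant <- rep(0L, n)
  data.frame(
    id = paste0(arm, seq_len(n)),
    arm = arm,
    t_recurrence = t_rec,
    event_recurrence = as.integer(!is.na(t_rec)),
    t_death = t_death,
    event_death = as.integer(!is.na(t_death)),
    t_censor = t_cens,
    transplant = as.integer(transplant),
    cost_stable = rep_len(cost_stable, n),
    cost_recurrence = ifelse(is.na(t_rec), 0, rep_len(cost_rec, n)),
    stringsAsFactors = FALSE)
}

# arm with exact event counts: r recurrences, d deaths, tx transplants.
# Deaths are assigned first to recurrence patients (recurrence at 1y,
# death at 2y), then as direct stable->death at 2y; survivors censored
# alive at 10y.
count_cohort_arm <- function(arm, n, r, d, tx) {
  stopifnot(n >= max(r, d, tx))
  rec_id <- seq_len(r)
  death_id <- seq_len(d)
  t_rec <- ifelse(seq_len(n) %in% rec_id, 1, NA_real_)
  t_death <- ifelse(seq_len(n) %in% death_id, 2, NA_real_)
  make_cohort(arm, t_rec, t_death, t_cens = rep(10, n),
              transplant = as.integer(seq_len(n) <= tx))
}

# the matched two-arm study structure with its published event counts
study_counts_cohort <- function() {
  rbind(count_cohort_arm("C-TACE", 101, r = 62, d = 77, tx = 14),
        count_cohort_arm("DEM-TACE", 101, r = 49, d = 58, tx = 23))
}

# random censoring-free illness-death cohort of <= 20 subjects: every
# subject's full path is observed well past t_eval
random_uncensored_cohort <- function(n, t_horizon = 100) {
  path <- sample(c("stay", "die", "rec_die", "rec_stay"), n, replace = TRUE)
  t1 <- round(runif(n, 0.05, 3), 3)          # time of first transition
  gap <- round(runif(n, 0.05, 2), 3)         # recurrence sojourn
  t_rec <- ifelse(path %in% c("rec_die", "rec_stay"), t1, NA_real_)
  t_death <- ifelse(path == "die", t1,
                    ifelse(path == "rec_die", t1 + gap, NA_real_))
  make_cohort("sim", t_rec, t_death, t_cens = rep(t_horizon, n))
}

# enumeration oracle: empirical state-occupancy fractions at time t from
# the raw records (valid when no subject is censored before t)
occupancy_at <- function(cohort, t) {
  state <- ifelse(cohort$event_death == 1 & cohort$t_death <= t, "death",
                  ifelse(cohort$event_recurrence == 1 & cohort$t_recurrence <= t,
                         "recurrence", "stable"))
  c(stable = mean(state == "stable"),
    recurrence = mean(state == "recurrence"),
    death = mean(state == "death"))
}

# small valid transition matrix used across Markov tests
toy_matrix <- function() {
  transition_matrix(rbind(c(0.70, 0.20, 0.10),
                          c(0.00, 0.60, 0.40),
                          c(0.00, 0.00, 1.00)))
}

toy_inputs <- function(...) {
  defaults <- list(cost_stable = 1000, cost_recurrence = 4000,
                   cost_procedure = 3500, utility_stable = 0.72,
                   utility_recurrence = 0.50, utility_transplant = 0.82,
                   p_transplant = 0.18)
  args <- utils::modifyList(defaults, list(...))
  do.call(state_inputs, args)
}

# degenerate PSA spec (all SEs 0, infinite Dirichlet concentration): every
# draw must equal the deterministic base case
degenerate_psa_spec <- function(n_sims = 25) {
  P1 <- toy_matrix()
  P2 <- transition_matrix(rbind(c(0.80, 0.12, 0.08),
                                c(0.00, 0.67, 0.33),
                                c(0.00, 0.00, 1.00)))
  psa_spec(
    arms = list(
      "C-TACE" = list(cost_stable = c(0, 0), cost_recurrence = c(4415, 0),
                      cost_procedure = c(3500, 0), p_transplant = 0.139, P = P1),
      "DEM-TACE" = list(cost_stable = c(0, 0), cost_recurrence = c(4085, 0),
                        cost_procedure = c(3500, 0), p_transplant = 0.228, P = P2)),
    utilities = list(stable = c(0.72, 0), recurrence = c(0.50, 0),
                     transplant = c(0.82, 0)),
    ess = Inf, n_sims = n_sims)
}
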