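#' Kaplan-Meier product-limit survival estimate
#'
#' Thin wrapper around [survival::survfit()] returning a plain
#' `survival_curve` structure. At tied event and censoring times, events
#' precede censorings (the standard counting-process convention).
#'
#' @param times follow-up times (years, non-negative).
#' @param events event indicators (1/TRUE = event, 0/FALSE = censored).
#' @return An object of class `survival_curve` with components `times`
#'   (sorted distinct follow-up times), `survival`, `at_risk` and `n_event`.
#' @examples
#' km <- kaplan_meier(c(1, 1, 2), c(1, 0, 1))
#' km$survival  # 2/3 at t=1, 1/3 at t=2
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) != length(events)) stop_param("times and events must have equal length")
  if (anyNA(times) || any(times < 0)) stop_param("times must be non-negative and non-missing")
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(times = fit$time, survival = fit$surv,
                 at_risk = fit$n.risk, n_event = fit$n.event, n = length(times)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$n, "subjects,", sum(x$n_event), "events\n")
  show <- data.frame(time = x$times, at_risk = x$at_risk,
                     events = x$n_event, survival = signif(x$survival, 6))
  print(utils::head(show, 20), row.names = FALSE)
  if (length(x$times) > 20) cat("...\n")
  invisible(x)
}

#' Survival probability at given times
#' @param curve a `survival_curve`.
#' @param t times at which to evaluate (step function, right-continuous).
#' @return Survival probabilities; 1 before the first observed time.
#' @export
survival_at <- function(curve, t) {
  vapply(t, function(ti) {
    k <- findInterval(ti, curve$times)
    if (k == 0) 1 else curve$survival[k]
  }, 0)
}

# per-patient transition history -> counting-process summaries at each
# distinct transition time (vectorised; scales to tens of thousands of
# subjects)
transition_counts <- function(cohort) {
  validate_cohort(cohort)
  rec <- cohort$event_recurrence == 1
  die <- cohort$event_death == 1
  # exit time from stable: recurrence, direct death, or censoring
  exit1 <- ifelse(rec, cohort$t_recurrence, ifelse(die, cohort$t_death, cohort$t_censor))
  # recurrence-state interval (patients with observed recurrence only)
  entry2 <- cohort$t_recurrence[rec]
  exit2 <- ifelse(die[rec], cohort$t_death[rec], cohort$t_censor[rec])

  t_sr <- cohort$t_recurrence[rec]
  t_sd <- cohort$t_death[!rec & die]
  t_rd <- cohort$t_death[rec & die]
  entry_rd <- cohort$t_recurrence[rec & die]
  times <- sort(unique(c(t_sr, t_sd, t_rd)))
  if (!length(times))
    return(data.frame(time = numeric(), d_sr = integer(), d_sd = integer(),
                      d_rd = integer(), Y1 = integer(), Y2 = integer()))
  count_at <- function(x) tabulate(match(x, times), nbins = length(times))
  n_before <- function(x) findInterval(times, sort(x), left.open = TRUE)
  # censorings at t count as at risk at t (events precede censorings);
  # a patient whose recurrence and death coincide passes through the
  # recurrence state instantaneously and is at risk for its own death
  data.frame(
    time = times,
    d_sr = count_at(t_sr),
    d_sd = count_at(t_sd),
    d_rd = count_at(t_rd),
    Y1 = length(exit1) - n_before(exit1),
    Y2 = n_before(entry2) - n_before(exit2) + count_at(t_rd[entry_rd == t_rd]))
}

#' Aalen-Johansen estimator for the illness-death model
#'
#' Nonparametric estimate of the transition probability matrix P(0, t) over
#' the states stable, recurrence and death under right censoring: the
#' product-integral, over ordered transition times, of I + dA(t), where dA
#' holds the Nelson-Aalen increments (observed transitions divided by the
#' at-risk count in the source state). Death is absorbing and there is no
#' recurrence-to-stable transition, so each factor — and hence every P(0, t)
#' — is row-stochastic by construction.
#'
#' @param cohort a cohort `data.frame` (a single arm; subset before calling
#'   for multi-arm data).
#' @return An object of class `aj_fit`: `times` (distinct transition times),
#'   `P` (3 x 3 x length(times) array of cumulative transition probability
#'   matrices), `counts` (per-time transition and at-risk counts), `n`.
#' @seealso [aj_prob()], [annual_matrix()]
#' @examples
#' coh <- generate_cohort(cohort_params(n_per_arm = 60, seed = 4))
#' fit <- aalen_johansen(coh[coh$arm == "C-TACE", ])
#' aj_prob(fit, 1)
#' @export
aalen_johansen <- function(cohort) {
  counts <- transition_counts(cohort)
  K <- nrow(counts)
  P <- array(0, dim = c(3, 3, max(K, 1)), dimnames = list(.states, .states, NULL))
  cur <- diag(3)
  if (K == 0) {
    P[, , 1] <- cur
    return(structure(list(times = numeric(), P = P[, , 0, drop = FALSE],
                          counts = counts, n = nrow(cohort)), class = "aj_fit"))
  }
  d_sr <- counts$d_sr; d_sd <- counts$d_sd; d_rd <- counts$d_rd
  Y1 <- counts$Y1; Y2 <- counts$Y2
  for (k in seq_len(K)) {
    cur <- cur %*% aj_factor(d_sr[k], d_sd[k], d_rd[k], Y1[k], Y2[k])
    P[, , k] <- cur
  }
  structure(list(times = counts$time, P = P, counts = counts,
                 sojourn = recurrence_sojourns(cohort), n = nrow(cohort)),
            class = "aj_fit")
}

# time from recurrence entry to death or censoring (clock reset at entry)
recurrence_sojourns <- function(cohort) {
  rec <- cohort$event_recurrence == 1
  die <- cohort$event_death == 1
  exit2 <- ifelse(die[rec], cohort$t_death[rec], cohort$t_censor[rec])
  data.frame(time = exit2 - cohort$t_recurrence[rec], event = as.integer(die[rec]))
}

# product-limit survival of the recurrence sojourn at duration tmax
# (events precede censorings at ties)
sojourn_survival <- function(sojourn, tmax = 1) {
  ev <- sort(unique(sojourn$time[sojourn$event == 1 & sojourn$time <= tmax]))
  if (!length(ev)) return(1)
  d <- tabulate(match(sojourn$time[sojourn$event == 1], ev), nbins = length(ev))
  Y <- length(sojourn$time) - findInterval(ev, sort(sojourn$time), left.open = TRUE)
  prod(1 - d / Y)
}

# one product-integral factor I + dA(t)
aj_factor <- function(d_sr, d_sd, d_rd, Y1, Y2) {
  Fk <- diag(3)
  if (Y1 > 0) {
    Fk[1, 2] <- d_sr / Y1
    Fk[1, 3] <- d_sd / Y1
    Fk[1, 1] <- 1 - Fk[1, 2] - Fk[1, 3]
  }
  if (Y2 > 0) {
    Fk[2, 3] <- d_rd / Y2
    Fk[2, 2] <- 1 - Fk[2, 3]
  }
  Fk
}

#' @export
print.aj_fit <- function(x, ...) {
  cat("Aalen-Johansen fit:", x$n, "subjects,", length(x$times), "transition times\n")
  if (length(x$times)) {
    cat("P(0, t_max =", signif(max(x$times), 4), "):\n")
    print(signif(x$P[, , length(x$times)], 6))
  }
  invisible(x)
}

#' Transition probability matrix P(0, t) from an Aalen-Johansen fit
#' @param fit an `aj_fit`.
#' @param t a single time (years).
#' @return 3x3 matrix; identity for t before the first transition time.
#' @export
aj_prob <- function(fit, t) {
  k <- findInterval(t, fit$times)
  if (k == 0) {
    m <- diag(3)
    dimnames(m) <- list(.states, .states)
    m
  } else fit$P[, , k]
}

#' Annual transition matrix for the Markov model
#'
#' Converts an Aalen-Johansen fit into per-cycle (1-year) transition
#' matrices. The stable row of cycle k is the conditional product-integral
#' of the estimated increments restricted to calendar interval (k, k+1].
#' The recurrence row is estimated on the time-since-recurrence clock (a
#' product-limit over all observed sojourns, evaluated at one year): almost
#' nobody occupies the recurrence state in the earliest calendar intervals,
#' so the calendar-conditional version of that row would rest on a nearly
#' empty risk set, while pooled sojourns identify the homogeneous annual
#' exit probability the Markov model needs. The base case
#' (`time_varying = FALSE`) returns the single time-homogeneous matrix for
#' the first cycle; the time-varying mode returns one matrix per cycle,
#' carrying the last informative matrix forward (with a warning) once no
#' subjects remain under observation.
#'
#' @param fit an `aj_fit`.
#' @param cycle_index 0-based cycle to extract (base case uses 0).
#' @param time_varying if TRUE return a list of matrices for cycles
#'   `0:(max_cycles - 1)`.
#' @param max_cycles number of cycles in time-varying mode.
#' @return A `transition_matrix` (or list of them when `time_varying`).
#' @export
annual_matrix <- function(fit, cycle_index = 0, time_varying = FALSE, max_cycles = 40) {
  if (!inherits(fit, "aj_fit")) stop_param("fit must be an aj_fit")
  if (!time_varying) return(interval_matrix(fit, cycle_index))
  last_obs <- if (length(fit$times)) max(fit$counts$time[fit$counts$Y1 + fit$counts$Y2 > 0]) else 0
  mats <- vector("list", max_cycles)
  prev <- NULL
  for (k in seq_len(max_cycles) - 1) {
    if (k >= last_obs && !is.null(prev)) {
      warning("no subjects under observation in cycle ", k,
              "; carrying previous annual matrix forward", call. = FALSE)
      mats[[k + 1]] <- prev
    } else {
      prev <- interval_matrix(fit, k)
      mats[[k + 1]] <- prev
    }
  }
  mats
}

interval_matrix <- function(fit, k) {
  ct <- fit$counts
  sel <- which(ct$time > k & ct$time <= k + 1)
  P <- diag(3)
  for (i in sel)
    P <- P %*% aj_factor(ct$d_sr[i], ct$d_sd[i], ct$d_rd[i], ct$Y1[i], ct$Y2[i])
  # stable row: conditional calendar-time product over (k, k+1].
  # recurrence row: estimated on the time-since-recurrence clock instead —
  # the calendar product conditions on presence in the recurrence state at
  # the interval start, where the risk set is nearly empty in early cycles
  # (its variance diverges), whereas pooling all sojourns identifies the
  # homogeneous annual exit probability the Markov model needs.
  p22 <- sojourn_survival(fit$sojourn, tmax = 1)
  P[2, ] <- c(0, p22, 1 - p22)
  # row sums are exactly 1 in exact arithmetic; strip accumulated
  # floating-point drift from long products before validation
  transition_matrix(P / rowSums(P))
}

#' Construct and validate a per-cycle transition matrix
#'
#' @param P 3x3 matrix over states stable, recurrence, death. Rows must sum
#'   to 1 (tolerance 1e-12 after renormalisation guard), death must be
#'   absorbing, and the recurrence-to-stable entry must be 0.
#' @param cycle_length cycle length in years (informational; the model uses
#'   1-year cycles).
#' @return An object of class `transition_matrix` (a 3x3 matrix with
#'   attributes).
#' @export
transition_matrix <- function(P, cycle_length = 1) {
  P <- as.matrix(P)
  if (!identical(dim(P), c(3L, 3L))) stop_param("P must be 3x3")
  if (anyNA(P) || any(P < -1e-12) || any(P > 1 + 1e-12)) stop_param("entries must be probabilities")
  if (any(abs(rowSums(P) - 1) > 1e-12)) stop_param("rows must sum to 1 (tolerance 1e-12)")
  if (any(abs(P[3, ] - c(0, 0, 1)) > 1e-12)) stop_param("death must be absorbing: row 3 = (0,0,1)")
  if (abs(P[2, 1]) > 1e-12) stop_param("recurrence-to-stable transitions are not allowed")
  dimnames(P) <- list(.states, .states)
  structure(P, class = c("transition_matrix", "matrix"), cycle_length = cycle_length)
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Annual transition matrix (cycle length", attr(x, "cycle_length"), "y):\n")
  print(signif(unclass(x)[, , drop = FALSE], 6))
  invisible(x)
}

#' Estimate per-arm annual transition matrices from a cohort
#'
#' Runs [aalen_johansen()] within each arm and extracts the annual matrix
#' (or per-cycle matrices).
#'
#' @inheritParams annual_matrix
#' @param cohort a multi-arm cohort `data.frame`.
#' @return Named list (per arm) of `transition_matrix` objects (or lists of
#'   them when `time_varying`).
#' @export
estimate_transition_matrices <- function(cohort, time_varying = FALSE, max_cycles = 40) {
  validate_cohort(cohort)
  arms <- unique(cohort$arm)
  setNames(lapply(arms, function(a) {
    annual_matrix(aalen_johansen(cohort[cohort$arm == a, ]),
                  cycle_index = 0, time_varying = time_varying, max_cycles = max_cycles)
  }), arms)
}

#' Write transition matrices in long format
#'
#' One row per entry: `arm, cycle, from_state, to_state, probability`
#' (6 significant digits).
#'
#' @param matrices output of [estimate_transition_matrices()].
#' @param path CSV path.
#' @export
write_transition_long <- function(matrices, path) {
  rows <- list()
  for (a in names(matrices)) {
    m <- matrices[[a]]
    mats <- if (inherits(m, "transition_matrix")) list(m) else m
    for (k in seq_along(mats)) {
      g <- expand.grid(from_state = .states, to_state = .states, stringsAsFactors = FALSE)
      g$arm <- a; g$cycle <- k - 1
      g$probability <- signif(as.vector(unclass(mats[[k]])), 6)
      rows[[length(rows) + 1]] <- g[c("arm", "cycle", "from_state", "to_state", "probability")]
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
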