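#' Per-arm cost and utility inputs for the Markov model
#'
#' Cycle costs (Euro/year) for the stable and recurrence states, a one-off
#' procedure cost applied at cycle 0, per-state utilities weighted for the
#' transplant proportion via [effective_utility()], and the transplant
#' proportion itself. Death carries zero cost and zero utility.
#'
#' @param cost_stable,cost_recurrence per-cycle state costs (Euro, >= 0).
#' @param cost_procedure one-off initial procedure cost (Euro, >= 0).
#' @param utility_stable,utility_recurrence,utility_transplant per-year
#'   utilities in \[0, 1\].
#' @param p_transplant proportion of the arm undergoing transplant, in
#'   \[0, 1\].
#' @return An object of class `state_inputs`.
#' @export
state_inputs <- function(cost_stable, cost_recurrence, cost_procedure,
                         utility_stable, utility_recurrence,
                         utility_transplant, p_transplant) {
  costs <- c(cost_stable, cost_recurrence, cost_procedure)
  if (anyNA(costs) || any(costs < 0)) stop_param("costs must be non-negative")
  check_prob(c(utility_stable, utility_recurrence, utility_transplant), "utilities")
  check_prob(p_transplant, "p_transplant")
  structure(list(cost_stable = cost_stable, cost_recurrence = cost_recurrence,
                 cost_procedure = cost_procedure,
                 utility_stable = utility_stable,
                 utility_recurrence = utility_recurrence,
                 utility_transplant = utility_transplant,
                 p_transplant = p_transplant),
            class = "state_inputs")
}

#' Transplant-weighted state utility
#'
#' Utilities attached to the alive states are a mixture over the transplanted
#' and non-transplanted fractions of the cohort (transplant is not a separate
#' health state): `(1 - p_tx) * u_state + p_tx * u_transplant`.
#'
#' @param u_state utility of the health state in \[0, 1\].
#' @param u_transplant utility after transplant in \[0, 1\].
#' @param p_tx transplanted proportion in \[0, 1\].
#' @return The weighted utility (vectorised over its arguments).
#' @examples
#' effective_utility(0.70, 0.80, 0.183)  # 0.7183
#' @export
effective_utility <- function(u_state, u_transplant, p_tx) {
  check_prob(u_state, "u_state"); check_prob(u_transplant, "u_transplant")
  check_prob(p_tx, "p_tx")
  (1 - p_tx) * u_state + p_tx * u_transplant
}

# reward vectors over (stable, recurrence, death)
reward_vectors <- function(inputs) {
  u <- effective_utility(c(inputs$utility_stable, inputs$utility_recurrence),
                         inputs$utility_transplant, inputs$p_transplant)
  list(cost = c(inputs$cost_stable, inputs$cost_recurrence, 0),
       qaly = c(u, 0))
}

# lean engine shared by run_markov and the PSA loop; P is a plain 3x3 matrix
# or a list of them (one per cycle, last carried forward)
markov_core <- function(P, cost_vec, qaly_vec, cost_procedure,
                        horizon_cycles, discount_rate, half_cycle,
                        alive_tol = 1e-9) {
  plist <- if (is.list(P)) P else list(P)
  occ <- matrix(0, nrow = horizon_cycles + 1, ncol = 3)
  occ[1, ] <- c(1, 0, 0)
  cycle_cost <- cycle_qaly <- numeric(horizon_cycles)
  k <- 0L
  while (k < horizon_cycles) {
    start <- occ[k + 1, ]
    if (start[1] + start[2] < alive_tol) break
    Pk <- plist[[min(k + 1, length(plist))]]
    nxt <- as.vector(start %*% Pk)
    occ[k + 2, ] <- nxt
    w <- if (half_cycle) (start + nxt) / 2 else start
    disc <- (1 + discount_rate)^(-k)
    cycle_cost[k + 1] <- disc * sum(w * cost_vec)
    cycle_qaly[k + 1] <- disc * sum(w * qaly_vec)
    k <- k + 1L
  }
  cycle_cost[1] <- cycle_cost[1] + cost_procedure
  list(occupancy = occ[seq_len(k + 1), , drop = FALSE],
       cycle_cost = cycle_cost[seq_len(max(k, 1))],
       cycle_qaly = cycle_qaly[seq_len(max(k, 1))],
       cycles_run = k)
}

#' Run the three-state Markov cohort model
#'
#' Evolves the cohort occupancy vector from (1, 0, 0) under a row-stochastic
#' annual transition matrix (or one matrix per cycle), accumulating
#' discounted cycle costs and QALYs. The payoff convention is
#' state-membership at the start of each cycle (optionally the half-cycle
#' average of start and end occupancy); cycle k payoffs are discounted by
#' (1 + r)^-k; the procedure cost enters once at cycle 0. The run stops at
#' `horizon_cycles` or as soon as the alive fraction falls below 1e-9,
#' whichever comes first.
#'
#' @param P a [transition_matrix()] (or plain 3x3 row-stochastic matrix), or
#'   a list of them, one per cycle (last carried forward).
#' @param inputs a [state_inputs()] object.
#' @param horizon_cycles maximum number of 1-year cycles (default 40,
#'   operationalising a lifetime horizon).
#' @param discount_rate annual discount rate (fraction/year, default 0).
#' @param half_cycle apply a half-cycle correction (default FALSE).
#' @return An object of class `markov_trace`: `occupancy` (cycles+1 x 3),
#'   per-cycle `cycle_cost`/`cycle_qaly`, cumulative `cum_cost`/`cum_qaly`
#'   and `cycles_run`.
#' @examples
#' P <- transition_matrix(rbind(c(.7, .2, .1), c(0, .6, .4), c(0, 0, 1)))
#' si <- state_inputs(1000, 4000, 3500, 0.72, 0.50, 0.82, 0.18)
#' run_markov(P, si)
#' @export
run_markov <- function(P, inputs, horizon_cycles = 40, discount_rate = 0,
                       half_cycle = FALSE) {
  if (!inherits(inputs, "state_inputs")) stop_param("inputs must be a state_inputs object")
  if (horizon_cycles < 1) stop_param("horizon_cycles must be >= 1")
  if (discount_rate < 0) stop_param("discount_rate must be non-negative")
  plist <- if (is.list(P)) P else list(P)
  plist <- lapply(plist, function(p) {
    p <- unclass(as.matrix(p))
    if (!identical(dim(p), c(3L, 3L)) || anyNA(p) || any(p < 0) ||
        any(abs(rowSums(p) - 1) > 1e-8))
      stop_param("P must be 3x3 row-stochastic with non-negative entries")
    p
  })
  rw <- reward_vectors(inputs)
  res <- markov_core(plist, rw$cost, rw$qaly, inputs$cost_procedure,
                     horizon_cycles, discount_rate, half_cycle)
  colnames(res$occupancy) <- .states
  res$cum_cost <- sum(res$cycle_cost)
  res$cum_qaly <- sum(res$cycle_qaly)
  res$discount_rate <- discount_rate
  structure(res, class = "markov_trace")
}

#' @export
print.markov_trace <- function(x, ...) {
  cat("Markov trace:", x$cycles_run, "cycles run, discount",
      sprintf("%.1f%%", 100 * x$discount_rate), "\n")
  cat(sprintf("  total cost: %.2f Euro, total QALY: %.4f\n", x$cum_cost, x$cum_qaly))
  cat("  final occupancy:",
      paste(sprintf("%s=%.4g", .states, x$occupancy[nrow(x$occupancy), ]), collapse = ", "), "\n")
  invisible(x)
}

#' Expected discounted QALY/cost via the fundamental matrix
#'
#' Closed-form check for a time-homogeneous chain at discount rate 0: the
#' expected number of cycles spent in each transient state starting from
#' stable is the first row of N = (I - Q)^-1, with Q the transient block of
#' P, so the undiscounted total payoff is the dot product of that row with
#' the per-cycle state payoffs (start-of-cycle convention).
#'
#' @param P 3x3 row-stochastic matrix with death absorbing.
#' @param payoff length-2 per-cycle payoffs for (stable, recurrence).
#' @return Expected total payoff until absorption.
#' @export
expected_total_payoff <- function(P, payoff) {
  Q <- unclass(as.matrix(P))[1:2, 1:2]
  N <- solve(diag(2) - Q)
  sum(N[1, ] * payoff)
}
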