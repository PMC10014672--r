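#' Draw cost parameters from a truncated normal
#'
#' Normal(mean, se) draws, resampled until non-negative (costs are tariffs
#' and cannot be negative). A zero standard error returns the mean exactly.
#'
#' @param mean mean cost (Euro).
#' @param se standard error (Euro, >= 0).
#' @param n number of draws.
#' @return Numeric vector of n non-negative draws.
#' @export
sample_cost <- function(mean, se, n = 1) {
  if (se < 0) stop_param("se must be non-negative")
  if (se == 0) return(rep(mean, n))
  out <- rnorm(n, mean, se)
  bad <- which(out < 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, se)
    bad <- bad[out[bad] < 0]
  }
  out
}

#' Beta shape parameters from mean and standard error
#'
#' Method-of-moments matching: `alpha = mean * (mean(1-mean)/se^2 - 1)`,
#' `beta = alpha * (1 - mean)/mean`. Feasibility requires
#' `se^2 < mean * (1 - mean)`.
#'
#' @param mean mean utility in (0, 1).
#' @param se standard error (> 0).
#' @return Named vector c(alpha, beta).
#' @examples
#' beta_moments(0.5, 0.1)  # alpha = beta = 12
#' @export
beta_moments <- function(mean, se) {
  if (mean <= 0 || mean >= 1) stop_param("mean must be in (0, 1)")
  if (se <= 0) stop_param("se must be positive")
  v <- se^2
  if (v >= mean * (1 - mean))
    stop_param("infeasible moments: need se^2 < mean*(1-mean) = ",
               signif(mean * (1 - mean), 6), " (got ", signif(v, 6), ")")
  alpha <- mean * (mean * (1 - mean) / v - 1)
  c(alpha = alpha, beta = alpha * (1 - mean) / mean)
}

#' Draw utilities from a moment-matched beta distribution
#'
#' @inheritParams beta_moments
#' @param n number of draws.
#' @return n draws in (0, 1); `se = 0` returns the mean exactly.
#' @export
sample_utility <- function(mean, se, n = 1) {
  if (se < 0) stop_param("se must be non-negative")
  if (se == 0) return(rep(mean, n))
  ab <- beta_moments(mean, se)
  rbeta(n, ab["alpha"], ab["beta"])
}

# Dirichlet draws via normalised gammas
rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Draw a transition matrix row from a Dirichlet distribution
#'
#' Concentration is `ess * base_row`; entries that are structurally zero in
#' the base row (impossible transitions such as recurrence-to-stable) are
#' excluded from sampling and stay exactly zero. `ess = Inf` returns the
#' base row (degenerate draw).
#'
#' @param base_row probabilities summing to 1.
#' @param ess effective sample size (> 0) controlling concentration.
#' @param n number of draws.
#' @return n x length(base_row) matrix of rows summing to 1.
#' @export
sample_transition_row <- function(base_row, ess, n = 1) {
  if (all(base_row == 0)) stop_param("base_row must have a positive entry")
  if (abs(sum(base_row) - 1) > 1e-8 || any(base_row < 0))
    stop_param("base_row must be non-negative and sum to 1")
  if (ess <= 0) stop_param("ess must be positive")
  out <- matrix(0, nrow = n, ncol = length(base_row))
  pos <- base_row > 0
  if (sum(pos) == 1 || is.infinite(ess)) {
    out[, pos] <- matrix(base_row[pos], nrow = n, ncol = sum(pos), byrow = TRUE)
  } else {
    out[, pos] <- rdirichlet(n, ess * base_row[pos])
  }
  out
}

#' Specification of a probabilistic sensitivity analysis
#'
#' Distributional assumptions for every model input: normal distributions
#' for costs (mean, se), beta distributions for utilities (moment-matched
#' mean, se) and Dirichlet distributions for the rows of each arm's annual
#' transition matrix (base row scaled by an effective sample size).
#'
#' @param arms named list, one element per arm, each a list with elements
#'   `cost_stable`, `cost_recurrence`, `cost_procedure` (each c(mean, se)),
#'   `p_transplant` (fixed proportion) and `P` (base
#'   [transition_matrix()]).
#' @param utilities list with elements `stable`, `recurrence`, `transplant`,
#'   each c(mean, se); utilities are shared across arms.
#' @param ess Dirichlet effective sample size (default 101, the arm size).
#' @param n_sims number of simulations (default 10000).
#' @param wtp willingness-to-pay threshold (Euro/QALY, default 25000).
#' @param horizon_cycles,discount_rate,half_cycle Markov engine settings.
#' @return An object of class `psa_spec`.
#' @export
psa_spec <- function(arms, utilities, ess = 101, n_sims = 10000, wtp = 25000,
                     horizon_cycles = 40, discount_rate = 0, half_cycle = FALSE) {
  if (length(arms) != 2 || is.null(names(arms))) stop_param("arms must be a named list of two arms")
  if (n_sims < 1) stop_param("n_sims must be >= 1")
  for (a in names(arms)) {
    for (f in c("cost_stable", "cost_recurrence", "cost_procedure")) {
      v <- arms[[a]][[f]]
      if (length(v) != 2 || anyNA(v) || v[2] < 0)
        stop_param("arm '", a, "' field '", f, "' must be c(mean, se) with se >= 0")
    }
    check_prob(arms[[a]]$p_transplant, "p_transplant")
    arms[[a]]$P <- transition_matrix(arms[[a]]$P)
  }
  for (f in c("stable", "recurrence", "transplant")) {
    v <- utilities[[f]]
    if (length(v) != 2 || anyNA(v) || v[1] < 0 || v[1] > 1 || v[2] < 0)
      stop_param("utility '", f, "' must be c(mean in [0,1], se >= 0)")
  }
  if (ess <= 0) stop_param("ess must be positive")
  structure(list(arms = arms, utilities = utilities, ess = ess,
                 n_sims = as.integer(n_sims), wtp = wtp,
                 horizon_cycles = horizon_cycles, discount_rate = discount_rate,
                 half_cycle = half_cycle),
            class = "psa_spec")
}

draw_state_inputs <- function(arm_spec, u_draw) {
  list(cost = c(sample_cost(arm_spec$cost_stable[1], arm_spec$cost_stable[2]),
                sample_cost(arm_spec$cost_recurrence[1], arm_spec$cost_recurrence[2]),
                0),
       qaly = c(effective_utility(c(u_draw["stable"], u_draw["recurrence"]),
                                  u_draw["transplant"], arm_spec$p_transplant), 0),
       proc = sample_cost(arm_spec$cost_procedure[1], arm_spec$cost_procedure[2]))
}

draw_matrix <- function(P, ess) {
  rbind(sample_transition_row(P[1, ], ess),
        sample_transition_row(P[2, ], ess),
        c(0, 0, 1))
}

sample_one_utility <- function(u) sample_utility(u[1], u[2])

#' Run a probabilistic sensitivity analysis
#'
#' For each simulation, all parameters are drawn simultaneously from their
#' distributions (normal costs, beta utilities, Dirichlet transition rows),
#' the Markov model is re-run for both arms, and the incremental
#' (delta QALY, delta cost) pair of the second arm versus the first is
#' recorded. Cost-effectiveness is judged by positive incremental net
#' monetary benefit at the willingness-to-pay threshold, and an
#' acceptability curve is evaluated on a WTP grid from 0 to 100,000 in
#' steps of 1,000. Fully reproducible for a fixed seed.
#'
#' @param spec a [psa_spec()].
#' @param seed integer seed.
#' @param wtp_grid WTP grid (Euro/QALY) for the acceptability curve.
#' @return An object of class `psa_result`: `points` (sim_id, delta_qaly,
#'   delta_cost, ce_at_wtp), `fraction_ce`, `ceac` (wtp, probability),
#'   `quadrant_counts` (NE, NW, SW, SE), `base_case` deltas, `wtp`,
#'   `n_sims`, `labels`.
#' @export
run_psa <- function(spec, seed = 1, wtp_grid = seq(0, 100000, by = 1000)) {
  if (!inherits(spec, "psa_spec")) stop_param("spec must be a psa_spec")
  set.seed(as.integer(seed))
  arms <- names(spec$arms)
  n <- spec$n_sims
  dq <- dc <- numeric(n)
  run_arm <- function(P, si) {
    r <- markov_core(P, si$cost, si$qaly, si$proc, spec$horizon_cycles,
                     spec$discount_rate, spec$half_cycle)
    c(cost = sum(r$cycle_cost), qaly = sum(r$cycle_qaly))
  }
  for (i in seq_len(n)) {
    u <- c(stable = sample_one_utility(spec$utilities$stable),
           recurrence = sample_one_utility(spec$utilities$recurrence),
           transplant = sample_one_utility(spec$utilities$transplant))
    ref <- spec$arms[[1]]; new <- spec$arms[[2]]
    out_ref <- run_arm(draw_matrix(ref$P, spec$ess), draw_state_inputs(ref, u))
    out_new <- run_arm(draw_matrix(new$P, spec$ess), draw_state_inputs(new, u))
    dq[i] <- out_new["qaly"] - out_ref["qaly"]
    dc[i] <- out_new["cost"] - out_ref["cost"]
  }
  # deterministic base case with the same spec means
  base <- lapply(spec$arms, function(a) {
    u0 <- c(stable = spec$utilities$stable[1], recurrence = spec$utilities$recurrence[1],
            transplant = spec$utilities$transplant[1])
    si <- list(cost = c(a$cost_stable[1], a$cost_recurrence[1], 0),
               qaly = c(effective_utility(u0[c("stable", "recurrence")],
                                          u0[["transplant"]], a$p_transplant), 0),
               proc = a$cost_procedure[1])
    run_arm(unclass(a$P), si)
  })
  inmb <- spec$wtp * dq - dc
  ceac <- data.frame(wtp = wtp_grid,
                     probability = vapply(wtp_grid, function(w) mean(w * dq - dc > 0), 0))
  quad <- c(NE = sum(dq >= 0 & dc >= 0), NW = sum(dq < 0 & dc >= 0),
            SW = sum(dq < 0 & dc < 0), SE = sum(dq >= 0 & dc < 0))
  structure(list(
    points = data.frame(sim_id = seq_len(n), delta_qaly = dq, delta_cost = dc,
                        ce_at_wtp = as.integer(inmb > 0)),
    fraction_ce = mean(inmb > 0),
    ceac = ceac,
    quadrant_counts = quad,
    base_case = c(delta_qaly = unname(base[[2]]["qaly"] - base[[1]]["qaly"]),
                  delta_cost = unname(base[[2]]["cost"] - base[[1]]["cost"])),
    wtp = spec$wtp, n_sims = n, seed = as.integer(seed),
    labels = c(reference = arms[1], new = arms[2])), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("PSA:", x$n_sims, "simulations,", x$labels["new"], "vs", x$labels["reference"], "\n")
  cat(sprintf("  cost-effective at WTP %s: %.1f%% of draws\n",
              format(x$wtp, big.mark = ","), 100 * x$fraction_ce))
  cat("  quadrants (NE/NW/SW/SE):", paste(x$quadrant_counts, collapse = "/"), "\n")
  cat(sprintf("  mean delta QALY: %.4f, mean delta cost: %.2f\n",
              mean(x$points$delta_qaly), mean(x$points$delta_cost)))
  invisible(x)
}

#' Plot the cost-effectiveness plane
#'
#' Scatter of the PSA draws in the (delta QALY, delta cost) plane with the
#' willingness-to-pay line through the origin.
#'
#' @param x a `psa_result`.
#' @param ... passed to [plot()].
#' @export
plot.psa_result <- function(x, ...) {
  plot(x$points$delta_qaly, x$points$delta_cost,
       xlab = expression(Delta ~ "QALY"), ylab = expression(Delta ~ "cost (Euro)"),
       main = sprintf("Cost-effectiveness plane (%s vs %s)",
                      x$labels["new"], x$labels["reference"]),
       pch = 16, cex = 0.3, col = "#00000055", ...)
  abline(h = 0, v = 0, col = "grey")
  abline(a = 0, b = x$wtp, col = "red")
  legend("topleft", legend = sprintf("WTP = %s Euro/QALY", format(x$wtp, big.mark = ",")),
         col = "red", lty = 1, bty = "n")
  invisible(x)
}

#' Plot the cost-effectiveness acceptability curve
#' @param x a `psa_result`.
#' @param ... passed to [plot()].
#' @export
plot_ceac <- function(x, ...) {
  plot(x$ceac$wtp, x$ceac$probability, type = "l",
       xlab = "Willingness to pay (Euro/QALY)",
       ylab = sprintf("P(%s cost-effective)", x$labels["new"]),
       ylim = c(0, 1), main = "Cost-effectiveness acceptability curve", ...)
  abline(v = x$wtp, col = "red", lty = 2)
  invisible(x)
}

#' Write PSA outputs as CSV
#' @param x a `psa_result`.
#' @param points_path,ceac_path output CSV paths (either may be NULL).
#' @export
write_psa <- function(x, points_path = NULL, ceac_path = NULL) {
  if (!inherits(x, "psa_result")) stop_param("x must be a psa_result")
  if (!is.null(points_path)) {
    p <- x$points
    p$delta_qaly <- signif(p$delta_qaly, 6)
    p$delta_cost <- signif(p$delta_cost, 6)
    write.csv(p, points_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(ceac_path)) {
    cc <- x$ceac
    cc$probability <- signif(cc$probability, 6)
    write.csv(cc, ceac_path, row.names = FALSE, quote = FALSE)
  }
  invisible(x)
}
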