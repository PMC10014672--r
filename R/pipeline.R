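#' Run the full cost-utility analysis on a cohort
#'
#' Ties the stages together: per-arm Aalen-Johansen estimation of annual
#' transition matrices, the Markov cohort model for each arm under the
#' configured cost scenario, and the incremental cost-utility comparison of
#' the non-reference arm against the reference arm.
#'
#' @param cohort a two-arm cohort `data.frame` (see [generate_cohort()]).
#' @param config a `model_config` (see [read_model_config()]).
#' @param scenario override the configured cost scenario ("median" or
#'   "mean").
#' @return An object of class `cua_result`: `scenario`, `matrices` (per
#'   arm), `traces` (per arm [run_markov()] output), `ce` (a
#'   [icur()] result, non-reference vs reference arm) and `config`.
#' @examples
#' coh <- generate_cohort(cohort_params(n_per_arm = 80, seed = 11))
#' res <- run_cua(coh, default_model_config())
#' res$ce
#' @export
run_cua <- function(cohort, config = default_model_config(),
                    scenario = config$scenario) {
  if (!inherits(config, "model_config")) stop_param("config must be a model_config")
  if (!scenario %in% c("median", "mean")) stop_param("scenario must be 'median' or 'mean'")
  validate_cohort(cohort)
  arms_cfg <- names(config$arms)
  missing_arms <- setdiff(arms_cfg, unique(cohort$arm))
  if (length(missing_arms))
    stop_param("cohort lacks configured arm(s): ", paste(missing_arms, collapse = ", "))
  matrices <- estimate_transition_matrices(cohort,
                                           time_varying = isTRUE(config$time_varying),
                                           max_cycles = config$horizon_cycles)[arms_cfg]
  traces <- lapply(arms_cfg, function(a)
    run_markov(matrices[[a]], config_state_inputs(config, a, scenario),
               horizon_cycles = config$horizon_cycles,
               discount_rate = config$discount_rate,
               half_cycle = isTRUE(config$half_cycle)))
  names(traces) <- arms_cfg
  ref <- reference_arm(config)
  new <- comparator_arm(config)
  ce <- icur(traces[[new]]$cum_cost, traces[[new]]$cum_qaly,
             traces[[ref]]$cum_cost, traces[[ref]]$cum_qaly,
             wtp = config$wtp, labels = c(new, ref))
  structure(list(scenario = scenario, matrices = matrices, traces = traces,
                 ce = ce, config = config), class = "cua_result")
}

#' @export
print.cua_result <- function(x, ...) {
  cat("Cost-utility analysis (", x$scenario, "-cost scenario)\n\n", sep = "")
  print(x$ce)
  invisible(x)
}

#' Build a PSA specification from a configuration and estimated matrices
#'
#' Uses the configured scenario's state costs with their standard errors
#' (normal), the configured utilities (beta via moment matching) and the
#' estimated annual transition matrices as Dirichlet base rows with the
#' configured effective sample size. The reference arm comes first so that
#' incremental results are comparator-versus-reference.
#'
#' @param config a `model_config`.
#' @param matrices per-arm base-case `transition_matrix` objects, as
#'   produced by [estimate_transition_matrices()] or found in a
#'   `cua_result`.
#' @param scenario override the configured cost scenario.
#' @return A [psa_spec()].
#' @export
build_psa_spec <- function(config, matrices, scenario = config$scenario) {
  if (!inherits(config, "model_config")) stop_param("config must be a model_config")
  ref <- reference_arm(config)
  new <- comparator_arm(config)
  mk_arm <- function(a) {
    cfg <- config$arms[[a]]
    m <- matrices[[a]]
    if (is.list(m) && !inherits(m, "transition_matrix")) m <- m[[1]]
    list(cost_stable = c(cfg$cost_stable[[scenario]], cfg$cost_stable$se),
         cost_recurrence = c(cfg$cost_recurrence[[scenario]], cfg$cost_recurrence$se),
         cost_procedure = c(cfg$cost_procedure$mean, cfg$cost_procedure$se),
         p_transplant = cfg$p_transplant,
         P = m)
  }
  arms <- setNames(lapply(c(ref, new), mk_arm), c(ref, new))
  utilities <- lapply(config$utilities[c("stable", "recurrence", "transplant")],
                      function(u) c(u$mean, u$se))
  psa_spec(arms = arms, utilities = utilities, ess = config$psa$ess,
           n_sims = config$psa$n_sims, wtp = config$wtp,
           horizon_cycles = config$horizon_cycles,
           discount_rate = config$discount_rate,
           half_cycle = isTRUE(config$half_cycle))
}

#' Summary report for a cohort and cost-utility results
#'
#' Produces the two summary tables of a standard cost-utility write-up: the
#' per-arm event/cost summary of the source cohort and the cost, QALY,
#' cost/QALY and ICUR table for the analysed scenarios.
#'
#' @param cohort a cohort `data.frame`.
#' @param results named list of `cua_result` objects (e.g. median and mean
#'   scenarios); may be empty.
#' @return A list of class `cua_report` with elements `cohort_summary` and
#'   `ce_table` (a `data.frame`, one block of rows per scenario).
#' @export
cua_report <- function(cohort, results = list()) {
  summ <- summarize_cohort(cohort)
  ce_table <- NULL
  if (length(results)) {
    ce_table <- do.call(rbind, lapply(names(results), function(nm) {
      d <- as.data.frame(results[[nm]]$ce)
      cbind(scenario = nm, d)
    }))
  }
  structure(list(cohort_summary = summ, ce_table = ce_table), class = "cua_report")
}

#' @export
print.cua_report <- function(x, ...) {
  print(x$cohort_summary)
  if (!is.null(x$ce_table)) {
    cat("\nCost-utility results:\n")
    d <- x$ce_table
    num <- vapply(d, is.numeric, TRUE)
    d[num] <- lapply(d[num], signif, 6)
    print(d, row.names = FALSE)
  }
  invisible(x)
}

#' Log a pipeline run's provenance
#'
#' Writes seed, configuration file hash (MD5) and package/R versions to a
#' connection, so every artifact can be traced to its inputs.
#'
#' @param seed integer seed of the run.
#' @param config_path path of the configuration file used (NULL if none).
#' @param con connection (default [stderr()]).
#' @export
log_run <- function(seed, config_path = NULL, con = stderr()) {
  hash <- if (!is.null(config_path) && file.exists(config_path))
    unname(tools::md5sum(config_path)) else NA_character_
  writeLines(sprintf("[tacecua %s | R %s] seed=%s config_md5=%s",
                     as.character(packageVersion("tacecua")),
                     paste(R.version$major, R.version$minor, sep = "."),
                     seed, hash), con)
  invisible(NULL)
}
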