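#' Read and validate a model configuration file
#'
#' The configuration is a YAML file holding the decision-model inputs that
#' are not estimated from patient-level data: per-state utilities (mean and
#' standard error for the PSA), per-arm state costs for the median-cost and
#' mean-cost scenarios with their standard errors, procedure costs,
#' transplant proportions, the willingness-to-pay threshold, discounting and
#' horizon settings, and PSA sizes. A commented template is shipped at
#' `system.file("extdata", "config-default.yaml", package = "tacecua")`.
#'
#' @param path YAML file path; the default reads the shipped template.
#' @return A validated configuration list of class `model_config`.
#' @export
read_model_config <- function(path = system.file("extdata", "config-default.yaml",
                                                 package = "tacecua")) {
  if (!file.exists(path)) stop_param("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname read_model_config
#' @export
default_model_config <- function() read_model_config()

validate_config <- function(cfg) {
  req <- c("scenario", "wtp", "discount_rate", "horizon_cycles", "half_cycle",
           "time_varying", "utilities", "arms", "psa")
  missing_keys <- setdiff(req, names(cfg))
  if (length(missing_keys))
    stop_param("config is missing key(s): ", paste(missing_keys, collapse = ", "))
  if (!cfg$scenario %in% c("median", "mean"))
    stop_param("scenario must be 'median' or 'mean'")
  if (cfg$wtp < 0 || cfg$discount_rate < 0 || cfg$horizon_cycles < 1)
    stop_param("wtp and discount_rate must be >= 0 and horizon_cycles >= 1")
  for (u in c("stable", "recurrence", "transplant")) {
    v <- cfg$utilities[[u]]
    if (is.null(v$mean) || v$mean < 0 || v$mean > 1 || v$se < 0)
      stop_param("utilities$", u, " needs mean in [0,1] and se >= 0")
  }
  if (length(cfg$arms) != 2) stop_param("exactly two arms are required")
  refs <- vapply(cfg$arms, function(a) isTRUE(a$reference), TRUE)
  if (sum(refs) != 1) stop_param("exactly one arm must set reference: true")
  for (a in names(cfg$arms)) {
    arm <- cfg$arms[[a]]
    for (f in c("cost_stable", "cost_recurrence")) {
      v <- arm[[f]]
      if (is.null(v$median) || is.null(v$mean) || is.null(v$se) ||
          v$median < 0 || v$mean < 0 || v$se < 0)
        stop_param("arm '", a, "' ", f, " needs median, mean, se (all >= 0)")
    }
    if (is.null(arm$cost_procedure$mean) || arm$cost_procedure$mean < 0 ||
        arm$cost_procedure$se < 0)
      stop_param("arm '", a, "' cost_procedure needs mean, se")
    check_prob(arm$p_transplant, paste0("arm '", a, "' p_transplant"))
  }
  if (is.null(cfg$psa$n_sims) || cfg$psa$n_sims < 1 || is.null(cfg$psa$ess) ||
      cfg$psa$ess <= 0)
    stop_param("psa needs n_sims >= 1 and ess > 0")
  structure(cfg, class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("Model configuration: scenario =", x$scenario,
      "| WTP =", x$wtp, "Euro/QALY | discount =", x$discount_rate,
      "| horizon =", x$horizon_cycles, "cycles\n")
  cat("  arms:", paste(names(x$arms), collapse = ", "),
      "(reference:", reference_arm(x), ")\n")
  invisible(x)
}

reference_arm <- function(cfg) {
  names(cfg$arms)[vapply(cfg$arms, function(a) isTRUE(a$reference), TRUE)]
}

comparator_arm <- function(cfg) setdiff(names(cfg$arms), reference_arm(cfg))

#' Copy the commented configuration template
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_config_template <- function(path) {
  src <- system.file("extdata", "config-default.yaml", package = "tacecua")
  file.copy(src, path, overwrite = TRUE)
  invisible(path)
}

# state_inputs for one arm under the configured scenario
config_state_inputs <- function(cfg, arm, scenario = cfg$scenario) {
  a <- cfg$arms[[arm]]
  state_inputs(
    cost_stable = a$cost_stable[[scenario]],
    cost_recurrence = a$cost_recurrence[[scenario]],
    cost_procedure = a$cost_procedure$mean,
    utility_stable = cfg$utilities$stable$mean,
    utility_recurrence = cfg$utilities$recurrence$mean,
    utility_transplant = cfg$utilities$transplant$mean,
    p_transplant = a$p_transplant)
}
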