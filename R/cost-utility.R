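#' Incremental cost-utility ratio with dominance handling
#'
#' Computes the ICUR (incremental cost per QALY gained) of a new strategy
#' against a reference, together with per-arm cost/QALY ratios and net
#' monetary benefit at a willingness-to-pay threshold. Strict quadrant cases
#' are labelled rather than reported as (ambiguous) signed ratios:
#' `"dominant"` (cheaper and more effective), `"dominated"` (costlier and
#' less effective), `"undefined"` (equal QALYs, unequal costs) and
#' `"equivalent"` (both deltas zero).
#'
#' @param cost_new,qaly_new discounted total cost (Euro) and QALYs of the
#'   new strategy.
#' @param cost_ref,qaly_ref the same for the reference strategy.
#' @param wtp willingness-to-pay threshold (Euro/QALY) used for the net
#'   monetary benefit fields (default 25000).
#' @param labels length-2 character vector naming the two strategies.
#' @return An object of class `ce_result` with fields `cost_new`, `cost_ref`,
#'   `qaly_new`, `qaly_ref`, `delta_cost`, `delta_qaly`, `icur` (numeric, or
#'   `NA` when a dominance label applies), `dominance`, `ratio_new`,
#'   `ratio_ref`, `nmb_new`, `nmb_ref`, `wtp`, `labels`.
#' @examples
#' icur(3145.14, 0.523, 2158.32, 0.371)
#' @export
icur <- function(cost_new, qaly_new, cost_ref, qaly_ref, wtp = 25000,
                 labels = c("new", "reference")) {
  vals <- c(cost_new, qaly_new, cost_ref, qaly_ref, wtp)
  if (anyNA(vals) || any(!is.finite(vals))) stop_param("all inputs must be finite")
  if (qaly_new < 0 || qaly_ref < 0) stop_param("QALYs must be non-negative")
  dc <- cost_new - cost_ref
  dq <- qaly_new - qaly_ref
  dominance <- "none"
  ratio <- NA_real_
  if (dq > 0 && dc < 0) dominance <- "dominant"
  else if (dq < 0 && dc > 0) dominance <- "dominated"
  else if (dq == 0 && dc != 0) dominance <- "undefined"
  else if (dq == 0 && dc == 0) dominance <- "equivalent"
  else ratio <- dc / dq
  structure(list(
    cost_new = cost_new, cost_ref = cost_ref,
    qaly_new = qaly_new, qaly_ref = qaly_ref,
    delta_cost = dc, delta_qaly = dq,
    icur = ratio, dominance = dominance,
    ratio_new = if (qaly_new > 0) cost_new / qaly_new else NA_real_,
    ratio_ref = if (qaly_ref > 0) cost_ref / qaly_ref else NA_real_,
    nmb_new = net_monetary_benefit(cost_new, qaly_new, wtp),
    nmb_ref = net_monetary_benefit(cost_ref, qaly_ref, wtp),
    wtp = wtp, labels = labels), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  tab <- data.frame(
    strategy = x$labels,
    cost = sprintf("%.2f", c(x$cost_new, x$cost_ref)),
    QALY = sprintf("%.4f", c(x$qaly_new, x$qaly_ref)),
    cost_per_QALY = sprintf("%.2f", c(x$ratio_new, x$ratio_ref)),
    NMB = sprintf("%.2f", c(x$nmb_new, x$nmb_ref)))
  cat("Cost-utility result (WTP =", x$wtp, "Euro/QALY)\n")
  print(tab, row.names = FALSE)
  cat(sprintf("  delta cost: %.2f Euro, delta QALY: %.4f\n", x$delta_cost, x$delta_qaly))
  if (x$dominance == "none")
    cat(sprintf("  ICUR: %.2f Euro/QALY\n", x$icur))
  else cat("  ICUR:", x$dominance, "\n")
  invisible(x)
}

#' @export
as.data.frame.ce_result <- function(x, ...) {
  data.frame(strategy = x$labels,
             cost = c(x$cost_new, x$cost_ref),
             qaly = c(x$qaly_new, x$qaly_ref),
             cost_per_qaly = c(x$ratio_new, x$ratio_ref),
             nmb = c(x$nmb_new, x$nmb_ref),
             delta_cost = c(x$delta_cost, NA),
             delta_qaly = c(x$delta_qaly, NA),
             icur = c(x$icur, NA),
             dominance = c(x$dominance, NA))
}

#' Cost per QALY ratio
#' @param cost total cost (Euro).
#' @param qaly total QALYs; must be positive (zero cost gives ratio 0).
#' @return cost / qaly in Euro/QALY.
#' @examples
#' cost_per_qaly(3145.14, 0.523)
#' @export
cost_per_qaly <- function(cost, qaly) {
  if (any(!is.finite(c(cost, qaly)))) stop_param("inputs must be finite")
  if (any(qaly <= 0)) stop_param("cost per QALY is undefined for qaly <= 0")
  cost / qaly
}

#' Net monetary benefit
#'
#' `wtp * qaly - cost`; a strategy with higher NMB is preferred at that
#' willingness-to-pay, and for a positive QALY gain the incremental NMB is
#' positive exactly when the ICUR lies below the threshold.
#'
#' @param cost total cost (Euro).
#' @param qaly total QALYs.
#' @param wtp willingness-to-pay threshold (Euro/QALY, >= 0).
#' @return NMB in Euro (vectorised).
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) stop_param("wtp must be non-negative")
  wtp * qaly - cost
}

#' Write a cost-utility result as JSON and CSV
#' @param x a `ce_result`.
#' @param json_path,csv_path output paths (either may be NULL to skip).
#' @export
write_ce_result <- function(x, json_path = NULL, csv_path = NULL) {
  if (!inherits(x, "ce_result")) stop_param("x must be a ce_result")
  if (!is.null(json_path))
    jsonlite::write_json(unclass(x), json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(csv_path)) {
    d <- as.data.frame(x)
    num <- vapply(d, is.numeric, TRUE)
    d[num] <- lapply(d[num], signif, 6)
    write.csv(d, csv_path, row.names = FALSE, na = "", quote = FALSE)
  }
  invisible(x)
}
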