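# Incremental cost-effectiveness arithmetic and dominance classification.

#' Compare two strategies
#'
#' Computes incremental outcomes oriented intervention-minus-comparator
#' (`a - b`), classifies the cost-effectiveness quadrant and reports the
#' incremental cost-effectiveness ratio (ICER, EUR per life-year without DFU
#' gained) and cost-utility ratio (ICUR, EUR per QALY gained) only where they
#' are meaningful, i.e. in the trade-off quadrants. When the intervention is
#' both more effective and cheaper it is labelled `intervention-dominant`
#' and no ratio is reported (and conversely for `comparator-dominant`).
#'
#' @param a Intervention `dfu_cohort` (or any list with `mean` and `n`).
#' @param b Comparator `dfu_cohort`, run with the same `n`, horizon and
#'   discounting.
#' @return Object of class `dfu_comparison`: deltas (`d_ly_wo_dfu`,
#'   `d_qaly`, `d_cost`), `icer`, `icur` (NA where not reported),
#'   `dominance` label, and per-arm amputation counts per 100 patients.
#' @export
compare_strategies <- function(a, b) {
  if (!is.null(a$n) && !is.null(b$n) && a$n != b$n) {
    stop("cohorts must have the same n", call. = FALSE)
  }
  if (!is.null(a$horizon) && !is.null(b$horizon) && a$horizon != b$horizon) {
    stop("cohorts must share the horizon", call. = FALSE)
  }
  d_ly <- a$mean[["ly_wo_dfu"]] - b$mean[["ly_wo_dfu"]]
  d_q <- a$mean[["qaly"]] - b$mean[["qaly"]]
  d_c <- a$mean[["cost"]] - b$mean[["cost"]]
  dominance <-
    if (d_q == 0 && d_c == 0) "indeterminate"
    else if (d_q >= 0 && d_c <= 0) "intervention-dominant"
    else if (d_q <= 0 && d_c >= 0) "comparator-dominant"
    else if (d_q > 0 && d_c > 0) "trade-off-NE"
    else "trade-off-SW"
  tradeoff <- dominance %in% c("trade-off-NE", "trade-off-SW")
  icer <- if (tradeoff && d_ly != 0) d_c / d_ly else NA_real_
  icur <- if (tradeoff) d_c / d_q else NA_real_
  structure(
    list(
      d_ly_wo_dfu = d_ly, d_qaly = d_q, d_cost = d_c,
      icer = icer, icur = icur, dominance = dominance,
      ratio_undefined = tradeoff && d_ly == 0,
      amputations_per_100 = c(
        intervention = if (!is.null(a$amputation_count)) amputations_per_100(a) else NA,
        comparator = if (!is.null(b$amputation_count)) amputations_per_100(b) else NA
      ),
      intervention = a$strategy, comparator = b$strategy, n = a$n
    ),
    class = "dfu_comparison"
  )
}

#' @export
print.dfu_comparison <- function(x, ...) {
  cat("Incremental comparison (", x$intervention, " - ", x$comparator,
      "), n = ", x$n, " per arm\n", sep = "")
  cat(sprintf("  delta LY w/o DFU : %+0.2f years\n", x$d_ly_wo_dfu))
  cat(sprintf("  delta QALY       : %+0.2f years\n", x$d_qaly))
  cat(sprintf("  delta cost       : %+0.0f EUR\n", x$d_cost))
  cat("  dominance        :", x$dominance, "\n")
  if (!is.na(x$icer)) cat(sprintf("  ICER             : %0.0f EUR/LY w/o DFU\n", x$icer))
  if (!is.na(x$icur)) cat(sprintf("  ICUR             : %0.0f EUR/QALY\n", x$icur))
  invisible(x)
}

#' Net monetary benefit
#'
#' `lambda * qaly - cost`, for willingness-to-pay `lambda` (EUR per QALY).
#'
#' @param lambda Willingness-to-pay, EUR per QALY (>= 0).
#' @param qaly QALYs.
#' @param cost Cost in EUR.
#' @return Net monetary benefit in EUR.
#' @export
nmb <- function(lambda, qaly, cost) {
  stopifnot(all(lambda >= 0))
  lambda * qaly - cost
}

#' Amputations per 100 patients
#'
#' Each patient counts at most once (first entry into the amputation state).
#'
#' @param r A `dfu_cohort`.
#' @return `round(100 * amputation count / n)`.
#' @export
amputations_per_100 <- function(r) {
  stopifnot(r$n >= 1)
  round(100 * r$amputation_count / r$n)
}
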