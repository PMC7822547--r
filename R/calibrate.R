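#' Calibrate the inpatient-mix probabilities to target lifetime costs
#'
#' The monthly probability that an uninfected or infected ulcer cycle is
#' managed as an inpatient is not published at the cycle level; the packaged
#' defaults are an explicit assumption. This helper fits the two
#' probabilities, bounded to [0,1], so that the deterministic
#' cohort-expectation oracle's discounted lifetime cost per arm comes as
#' close as possible (least squares on relative error) to supplied target
#' totals. If a target exceeds what the configured monthly state costs can
#' generate, the fit ends on the boundary and is reported as such rather
#' than hidden.
#'
#' @param params A `dfu_params` object.
#' @param targets Named vector `c(tlc_nosf = ..., control = ...)` of target
#'   discounted lifetime costs (EUR).
#' @param lt Life table.
#' @param profiles Patient profiles to average over (default: a 200-patient
#'   synthetic cohort from the configured profile, fixed internal seed).
#' @param horizon Cycles.
#' @return List with `p_hospital` (fitted values), `achieved` (oracle costs
#'   at the fit), `targets`, `at_boundary` (logical), and `params` (the input
#'   with the fitted probabilities substituted).
#' @export
calibrate_hospital_mix <- function(params,
                                   targets = c(tlc_nosf = 281360, control = 316849),
                                   lt = make_life_table(),
                                   profiles = NULL,
                                   horizon = params$horizon_cycles) {
  stopifnot(all(c("tlc_nosf", "control") %in% names(targets)))
  if (is.null(profiles)) profiles <- sample_cohort(params$cohort, 200, seed = 987654)
  costs_at <- function(p) {
    p2 <- params
    p2$p_hospital$uninfected <- p[1]
    p2$p_hospital$infected <- p[2]
    c(tlc_nosf = cohort_expectation(p2, "tlc_nosf", lt, horizon, profiles)$mean[["cost"]],
      control = cohort_expectation(p2, "control", lt, horizon, profiles)$mean[["cost"]])
  }
  obj <- function(p) {
    a <- costs_at(p)
    sum(((a - targets[names(a)]) / targets[names(a)])^2)
  }
  fit <- optim(c(params$p_hospital$uninfected, params$p_hospital$infected),
               obj, method = "L-BFGS-B", lower = 0, upper = 1)
  achieved <- costs_at(fit$par)
  out_params <- params
  out_params$p_hospital$uninfected <- fit$par[1]
  out_params$p_hospital$infected <- fit$par[2]
  list(
    p_hospital = c(uninfected = fit$par[1], infected = fit$par[2]),
    achieved = achieved,
    targets = targets,
    at_boundary = any(fit$par < 1e-6 | fit$par > 1 - 1e-6),
    params = out_params
  )
}
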