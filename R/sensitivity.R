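# One-way deterministic sensitivity analysis (tornado), uniform probabilistic
# sensitivity analysis with acceptability curves, and subgroup runs.

#' Default one-way sensitivity-analysis ranges
#'
#' The published deterministic sensitivity analysis varies demographics and
#' efficacy over trial-based ranges, dressing unit prices over [-50%, +20%],
#' and all other parameters over [-30%, +30%]. Cost items are unit
#' prices/counts that the mapping in [apply_dsa_param()] translates into
#' perturbations of the aggregated monthly state costs. The two alternative
#' healing-probability rows (`*_alt`) reflect a second published healing
#' parameterisation; they drive the same engine parameter as the main rows
#' and are excluded from the probabilistic set (`psa = FALSE`), as are
#' demographics and utilities (the probabilistic analysis covers transition
#' probabilities, healing and costs).
#'
#' @param params A `dfu_params` object (supplies the cost-component bases).
#' @return Data.frame with columns `parameter`, `base`, `lower`, `upper`,
#'   `psa` (logical: part of the default probabilistic set).
#' @export
default_dsa_ranges <- function(params = builtin_basecase()) {
  cc <- params$cost_components
  rows <- rbind(
    data.frame(parameter = "mean_age", base = params$cohort$mean_age_years,
               lower = 58, upper = 70, psa = FALSE),
    data.frame(parameter = "prop_men", base = params$cohort$proportion_men,
               lower = 0.81, upper = 0.90, psa = FALSE),
    data.frame(parameter = "p_heal_tlc", base = params$strategies$tlc_nosf$p_heal,
               lower = 0.064, upper = 0.118, psa = TRUE),
    data.frame(parameter = "p_heal_control", base = params$strategies$control$p_heal,
               lower = 0.041, upper = 0.075, psa = TRUE),
    data.frame(parameter = "p_heal_tlc_alt", base = 0.068,
               lower = 0.048, upper = 0.089, psa = FALSE),
    data.frame(parameter = "p_heal_control_alt", base = 0.044,
               lower = 0.031, upper = 0.057, psa = FALSE),
    data.frame(parameter = "p_recur", base = params$transitions$p_recur,
               lower = 0.010, upper = 0.018, psa = TRUE),
    data.frame(parameter = "p_infect", base = params$transitions$p_infect,
               lower = 0.025, upper = 0.047, psa = TRUE),
    data.frame(parameter = "p_resolve", base = params$transitions$p_resolve,
               lower = 0.057, upper = 0.107, psa = TRUE),
    data.frame(parameter = "p_amp", base = params$transitions$p_amp,
               lower = 0.008, upper = 0.014, psa = TRUE),
    data.frame(parameter = "p_death_uninf", base = params$transitions$p_death_uninf,
               lower = 0.006, upper = 0.012, psa = TRUE),
    data.frame(parameter = "p_death_closed", base = params$transitions$p_death_closed,
               lower = 0.006, upper = 0.012, psa = TRUE),
    data.frame(parameter = "p_death_inf", base = params$transitions$p_death_inf,
               lower = 0.006, upper = 0.012, psa = TRUE),
    data.frame(parameter = "p_death_amp", base = params$transitions$p_death_amp,
               lower = 0.084, upper = 0.156, psa = TRUE),
    data.frame(parameter = "biological_tests", base = cc$biological_tests_eur_per_month,
               lower = 96, upper = 178, psa = TRUE),
    data.frame(parameter = "antibiotics", base = cc$antibiotics_eur_per_month,
               lower = 321, upper = 596, psa = TRUE),
    data.frame(parameter = "hosp_stay_days", base = cc$hospital_stay_days_infected,
               lower = 4.27, upper = 7.93, psa = TRUE),
    data.frame(parameter = "hosp_day_cost", base = cc$hospital_day_cost_infected_eur,
               lower = 629, upper = 1169, psa = TRUE),
    data.frame(parameter = "amputation_surgery", base = cc$amputation_surgery_eur,
               lower = 5215, upper = 9685, psa = TRUE),
    data.frame(parameter = "nurse_visit", base = cc$nurse_visit_eur,
               lower = 9.80, upper = 18.20, psa = TRUE),
    data.frame(parameter = "unit_price_control", base = cc$unit_price_control_eur,
               lower = 1.52, upper = 3.65, psa = TRUE),
    data.frame(parameter = "unit_price_tlc", base = cc$unit_price_tlc_eur,
               lower = 4.00, upper = 9.59, psa = TRUE),
    data.frame(parameter = "util_uninfected", base = params$utilities$uninfected,
               lower = 0.675, upper = 0.825, psa = FALSE),
    data.frame(parameter = "util_closed", base = params$utilities$closed,
               lower = 0.756, upper = 0.924, psa = FALSE),
    data.frame(parameter = "util_infected", base = params$utilities$infected,
               lower = 0.630, upper = 0.770, psa = FALSE),
    data.frame(parameter = "util_amputation", base = params$utilities$amputation,
               lower = 0.576, upper = 0.704, psa = FALSE)
  )
  bad <- rows$lower > rows$base | rows$base > rows$upper
  if (any(bad)) stop("invalid range for ", paste(rows$parameter[bad], collapse = ", "))
  rows
}

# add `delta` to the given monthly cost cells of one arm, floored at zero
.bump_costs <- function(params, arm, states, settings, delta) {
  for (s in states) for (w in settings) {
    v <- params$strategies[[arm]]$costs_eur_per_month[[s]][[w]] + delta
    params$strategies[[arm]]$costs_eur_per_month[[s]][[w]] <- max(v, 0)
  }
  params
}

#' Set one sensitivity-analysis parameter
#'
#' Applies one parameter of the sensitivity analysis to a parameter object.
#' Engine-level parameters (transition probabilities, utilities, cohort
#' demographics) are set directly. Cost items are mapped onto the aggregated
#' monthly state costs additively: a change in a unit price/count shifts the
#' affected cost cells by the change times the item's monthly multiplicity
#' (`cost_components` in the configuration). Dressing unit prices perturb
#' only the corresponding arm's ulcer-state cells, using the per-state
#' dressings-per-month derived from the arm cost differences.
#'
#' @param params A `dfu_params` object.
#' @param id Parameter id (a `parameter` value of [default_dsa_ranges()]).
#' @param value New value.
#' @return Modified `dfu_params` object.
#' @export
apply_dsa_param <- function(params, id, value) {
  cc <- params$cost_components
  both <- c("tlc_nosf", "control")
  set_heal <- function(p, arm, v) { p$strategies[[arm]]$p_heal <- v; p }
  params <- switch(
    id,
    mean_age = { params$cohort$mean_age_years <- value; params },
    prop_men = { params$cohort$proportion_men <- value; params },
    p_heal_tlc = , p_heal_tlc_alt = set_heal(params, "tlc_nosf", value),
    p_heal_control = , p_heal_control_alt = set_heal(params, "control", value),
    p_recur = , p_infect = , p_resolve = , p_amp = ,
    p_death_uninf = , p_death_closed = , p_death_inf = , p_death_amp = {
      params$transitions[[id]] <- value; params
    },
    util_uninfected = { params$utilities$uninfected <- value; params },
    util_closed = { params$utilities$closed <- value; params },
    util_infected = { params$utilities$infected <- value; params },
    util_amputation = { params$utilities$amputation <- value; params },
    biological_tests = {
      d <- value - cc$biological_tests_eur_per_month
      for (a in both) params <- .bump_costs(params, a, "infected", c("outpatient", "inpatient"), d)
      params
    },
    antibiotics = {
      d <- value - cc$antibiotics_eur_per_month
      for (a in both) params <- .bump_costs(params, a, "infected", c("outpatient", "inpatient"), d)
      params
    },
    nurse_visit = {
      d <- (value - cc$nurse_visit_eur) * cc$nurse_visits_per_month
      for (a in both) params <- .bump_costs(params, a, c("uninfected", "infected"), "outpatient", d)
      params
    },
    hosp_stay_days = {
      d <- (value - cc$hospital_stay_days_infected) * cc$hospital_day_cost_infected_eur
      for (a in both) params <- .bump_costs(params, a, "infected", "inpatient", d)
      params
    },
    hosp_day_cost = {
      d <- cc$hospital_stay_days_infected * (value - cc$hospital_day_cost_infected_eur)
      for (a in both) params <- .bump_costs(params, a, "infected", "inpatient", d)
      params
    },
    amputation_surgery = {
      d <- value - cc$amputation_surgery_eur
      for (a in both) params <- .bump_costs(params, a, "amputation", "inpatient", d)
      params
    },
    unit_price_tlc = , unit_price_control = {
      arm <- if (id == "unit_price_tlc") "tlc_nosf" else "control"
      base <- if (id == "unit_price_tlc") cc$unit_price_tlc_eur else cc$unit_price_control_eur
      d <- value - base
      params <- .bump_costs(params, arm, "uninfected", c("outpatient", "inpatient"),
                            d * cc$dressings_per_month$uninfected)
      params <- .bump_costs(params, arm, "infected", c("outpatient", "inpatient"),
                            d * cc$dressings_per_month$infected)
      params$strategies[[arm]]$dressing_unit_price_eur <- value
      params
    },
    stop("unknown sensitivity parameter id: ", id, call. = FALSE)
  )
  params
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' For each parameter, runs the full two-arm comparison at the lower and at
#' the upper bound, all other parameters at base, under common random numbers
#' (one shared stream object across every branch). The swing is the absolute
#' difference of the selected incremental outcome between the two bounds.
#' Rows are sorted by decreasing swing (stable for ties).
#'
#' @param params Base `dfu_params`.
#' @param ranges Data.frame as from [default_dsa_ranges()].
#' @param n Patients per arm and branch.
#' @param seed Master seed (one stream set shared by all branches).
#' @param lt Life table.
#' @param horizon Cycles.
#' @param outcome Incremental outcome for the swing: `"cost"`, `"qaly"` or
#'   `"ly"`.
#' @return Object of class `dfu_dsa`: data.frame with per-parameter bounds,
#'   incremental outcome at each bound, `swing`, plus the base-case
#'   comparison as attribute `base`.
#' @export
run_dsa <- function(params, ranges = default_dsa_ranges(params), n = 1000,
                    seed = params$seed, lt = make_life_table(),
                    horizon = params$horizon_cycles,
                    outcome = c("cost", "qaly", "ly")) {
  outcome <- match.arg(outcome)
  field <- switch(outcome, cost = "d_cost", qaly = "d_qaly", ly = "d_ly_wo_dfu")
  streams <- make_model_streams(n, horizon, seed)
  base_run <- run_two_arm(params, n, seed, lt, horizon, streams = streams)
  one <- function(id, value) {
    p2 <- apply_dsa_param(params, id, value)
    run_two_arm(p2, n, seed, lt, horizon, streams = streams)$comparison[[field]]
  }
  res <- ranges
  res$outcome_low <- NA_real_
  res$outcome_high <- NA_real_
  res$d_cost_low <- res$d_cost_high <- NA_real_
  res$d_qaly_low <- res$d_qaly_high <- NA_real_
  for (i in seq_len(nrow(ranges))) {
    p_lo <- apply_dsa_param(params, ranges$parameter[i], ranges$lower[i])
    p_hi <- apply_dsa_param(params, ranges$parameter[i], ranges$upper[i])
    cmp_lo <- run_two_arm(p_lo, n, seed, lt, horizon, streams = streams)$comparison
    cmp_hi <- run_two_arm(p_hi, n, seed, lt, horizon, streams = streams)$comparison
    res$outcome_low[i] <- cmp_lo[[field]]
    res$outcome_high[i] <- cmp_hi[[field]]
    res$d_cost_low[i] <- cmp_lo$d_cost; res$d_cost_high[i] <- cmp_hi$d_cost
    res$d_qaly_low[i] <- cmp_lo$d_qaly; res$d_qaly_high[i] <- cmp_hi$d_qaly
  }
  res$swing <- abs(res$outcome_high - res$outcome_low)
  ord <- order(-res$swing)            # order() is stable: ties keep input order
  res <- res[ord, ]
  rownames(res) <- NULL
  structure(res, class = c("dfu_dsa", "data.frame"),
            outcome = outcome, base = base_run$comparison)
}

#' Sample one probabilistic-sensitivity parameter vector
#'
#' Each parameter is drawn independently from a uniform distribution over its
#' deterministic range (the published analysis specifies a non-informative
#' uniform distribution).
#'
#' @param ranges Data.frame with `parameter`, `lower`, `upper`.
#' @return Named numeric vector of sampled values.
#' @export
sample_psa_params <- function(ranges) {
  setNames(ranges$lower + runif(nrow(ranges)) * (ranges$upper - ranges$lower),
           ranges$parameter)
}

#' Inner-loop seeds of a probabilistic sensitivity analysis
#'
#' Deterministic derivation of the per-replicate microsimulation seeds from
#' the master seed, exposed so a single replicate can be reproduced exactly.
#'
#' @param seed Master seed.
#' @param n_outer Number of outer replicates.
#' @return Integer vector of length `n_outer`.
#' @export
psa_inner_seeds <- function(seed, n_outer) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n_outer)
}

#' Probabilistic sensitivity analysis
#'
#' Outer loop: sample a parameter vector from the uniform ranges (parameter
#' uncertainty). Inner loop: simulate both arms with `n_inner` patients under
#' common random numbers (patient-level uncertainty) and record the
#' incremental pair (delta QALY, delta cost).
#'
#' @param params Base `dfu_params`.
#' @param ranges Uniform ranges; default: the `psa = TRUE` subset of
#'   [default_dsa_ranges()].
#' @param n_outer Number of parameter samples.
#' @param n_inner Patients per arm per sample.
#' @param seed Master seed (drives both parameter sampling and the derived
#'   inner seeds, see [psa_inner_seeds()]).
#' @param lt Life table.
#' @param horizon Cycles.
#' @return Object of class `dfu_psa`: data.frame with one row per outer
#'   sample (sampled parameter columns, `d_qaly`, `d_cost`, `d_ly_wo_dfu`,
#'   `dominant`), suitable for a cost-utility plane export.
#' @export
run_psa <- function(params, ranges = NULL, n_outer = 1000, n_inner = 1000,
                    seed = params$seed, lt = make_life_table(),
                    horizon = params$horizon_cycles) {
  stopifnot(n_outer >= 1, n_inner >= 1)
  if (is.null(ranges)) {
    r <- default_dsa_ranges(params)
    ranges <- r[r$psa, ]
  }
  inner_seeds <- psa_inner_seeds(seed, n_outer)   # also sets the RNG state
  draws <- matrix(runif(n_outer * nrow(ranges)), n_outer, nrow(ranges))
  values <- sweep(sweep(draws, 2, ranges$upper - ranges$lower, `*`),
                  2, ranges$lower, `+`)
  colnames(values) <- ranges$parameter
  out <- data.frame(sample = seq_len(n_outer))
  out <- cbind(out, as.data.frame(values))
  out$d_qaly <- out$d_cost <- out$d_ly_wo_dfu <- NA_real_
  for (k in seq_len(n_outer)) {
    pk <- params
    for (j in seq_len(nrow(ranges))) {
      pk <- apply_dsa_param(pk, ranges$parameter[j], values[k, j])
    }
    cmp <- run_two_arm(pk, n_inner, inner_seeds[k], lt, horizon)$comparison
    out$d_qaly[k] <- cmp$d_qaly
    out$d_cost[k] <- cmp$d_cost
    out$d_ly_wo_dfu[k] <- cmp$d_ly_wo_dfu
  }
  out$dominant <- out$d_qaly > 0 & out$d_cost < 0
  structure(out, class = c("dfu_psa", "data.frame"),
            n_inner = n_inner, seed = seed)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that each strategy
#' maximises the net monetary benefit across the probabilistic samples.
#' Ties are credited to the intervention (a measure-zero event under uniform
#' sampling). Probabilities sum to one at every grid point.
#'
#' @param psa A `dfu_psa` (needs columns `d_qaly`, `d_cost`).
#' @param lambda_grid Willingness-to-pay grid in EUR/QALY (default 0 to
#'   100,000 in steps of 1,000).
#' @return Object of class `dfu_ceac`: data.frame `lambda`, `p_tlc_nosf`,
#'   `p_control`.
#' @export
ceac <- function(psa, lambda_grid = seq(0, 100000, by = 1000)) {
  stopifnot(length(lambda_grid) > 0, all(lambda_grid >= 0))
  p_int <- vapply(lambda_grid, function(l) {
    mean(nmb(l, psa$d_qaly, psa$d_cost) >= 0)   # NMB difference; ties -> intervention
  }, numeric(1))
  structure(
    data.frame(lambda = lambda_grid, p_tlc_nosf = p_int, p_control = 1 - p_int),
    class = c("dfu_ceac", "data.frame")
  )
}

#' Subgroup analysis by wound duration at baseline
#'
#' Runs one two-arm comparison per wound-duration category, identical
#' settings apart from the two healing probabilities, under common random
#' numbers across categories. Wound duration affects only the healing
#' probability used (its only published effect).
#'
#' @param params Base `dfu_params`.
#' @param subgroup_p_heal Named list of the four categories (`le_2mo`,
#'   `3_5mo`, `6_11mo`, `gt_11mo`), each with `p_heal_tlc` and
#'   `p_heal_control`; defaults to the packaged (synthetic) block.
#' @param n Patients per arm and category.
#' @param seed Master seed.
#' @param lt Life table.
#' @param horizon Cycles.
#' @return Named list of `dfu_comparison` objects plus a `summary`
#'   data.frame attribute (per-category levels and gains).
#' @export
run_subgroups <- function(params, subgroup_p_heal = params$subgroups, n = 1000,
                          seed = params$seed, lt = make_life_table(),
                          horizon = params$horizon_cycles) {
  cats <- c("le_2mo", "3_5mo", "6_11mo", "gt_11mo")
  miss <- setdiff(cats, names(subgroup_p_heal))
  if (length(miss) > 0) {
    stop("missing subgroup healing probabilities for: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  streams <- make_model_streams(n, horizon, seed)
  res <- lapply(cats, function(cat) {
    ph <- subgroup_p_heal[[cat]]
    if (is.null(ph$p_heal_tlc) || is.null(ph$p_heal_control)) {
      stop("subgroup '", cat, "' must supply p_heal_tlc and p_heal_control",
           call. = FALSE)
    }
    p2 <- params
    p2$strategies$tlc_nosf$p_heal <- ph$p_heal_tlc
    p2$strategies$control$p_heal <- ph$p_heal_control
    run_two_arm(p2, n, seed, lt, horizon, streams = streams)
  })
  names(res) <- cats
  summary <- do.call(rbind, lapply(cats, function(cat) {
    cmp <- res[[cat]]$comparison
    data.frame(
      subgroup = cat,
      p_heal_tlc = subgroup_p_heal[[cat]]$p_heal_tlc,
      p_heal_control = subgroup_p_heal[[cat]]$p_heal_control,
      ly_tlc = res[[cat]]$tlc_nosf$mean[["ly_wo_dfu"]],
      ly_control = res[[cat]]$control$mean[["ly_wo_dfu"]],
      d_ly_wo_dfu = cmp$d_ly_wo_dfu,
      qaly_tlc = res[[cat]]$tlc_nosf$mean[["qaly"]],
      qaly_control = res[[cat]]$control$mean[["qaly"]],
      d_qaly = cmp$d_qaly,
      d_cost = cmp$d_cost,
      dominance = cmp$dominance
    )
  }))
  structure(lapply(res, `[[`, "comparison"),
            summary = summary, class = "dfu_subgroups")
}
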