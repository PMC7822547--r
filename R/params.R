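#' @importFrom stats optim pnorm qnorm runif setNames
#' @importFrom utils modifyList read.csv write.csv
NULL

# ---- schema -----------------------------------------------------------------

# Template of the configuration tree: names define the allowed keys at each
# level. Leaves are NA; the loader rejects unknown keys and missing sections.
.params_template <- function() {
  cost_block <- list(outpatient = NA, inpatient = NA)
  strategy <- list(
    name = NA, p_heal = NA, dressing_unit_price_eur = NA,
    costs_eur_per_month = list(
      uninfected = cost_block, closed = cost_block,
      infected = cost_block, amputation = cost_block
    )
  )
  list(
    horizon_cycles = NA,
    seed = NA,
    discount = list(annual_rate = NA),
    transitions = list(
      p_recur = NA, p_infect = NA, p_resolve = NA, p_amp = NA,
      p_death_uninf = NA, p_death_inf = NA, p_death_closed = NA,
      p_death_amp = NA
    ),
    strategies = list(tlc_nosf = strategy, control = strategy),
    p_hospital = list(uninfected = NA, infected = NA),
    utilities = list(
      uninfected = NA, closed = NA, infected = NA, amputation = NA, dead = NA
    ),
    cohort = list(
      mean_age_years = NA, sd_age_years = NA, proportion_men = NA,
      age_min_years = NA, age_max_years = NA,
      wound_duration_weights = list(
        le_2mo = NA, `3_5mo` = NA, `6_11mo` = NA, gt_11mo = NA
      )
    ),
    cost_components = list(
      dressings_per_month = list(uninfected = NA, infected = NA),
      nurse_visits_per_month = NA,
      hospital_stay_days_infected = NA,
      hospital_day_cost_infected_eur = NA,
      biological_tests_eur_per_month = NA,
      antibiotics_eur_per_month = NA,
      amputation_surgery_eur = NA,
      nurse_visit_eur = NA,
      unit_price_tlc_eur = NA,
      unit_price_control_eur = NA
    ),
    options = list(
      state_death_includes_background = NA,
      ly_wo_dfu_counts_amputation = NA
    ),
    subgroups = list(
      le_2mo = list(p_heal_tlc = NA, p_heal_control = NA),
      `3_5mo` = list(p_heal_tlc = NA, p_heal_control = NA),
      `6_11mo` = list(p_heal_tlc = NA, p_heal_control = NA),
      gt_11mo = list(p_heal_tlc = NA, p_heal_control = NA)
    )
  )
}

.check_keys <- function(cfg, tmpl, path = "") {
  if (!is.list(tmpl)) return(invisible(NULL))
  if (!is.list(cfg)) {
    stop("config section '", path, "' must be a mapping", call. = FALSE)
  }
  unknown <- setdiff(names(cfg), names(tmpl))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ",
         paste0(path, ifelse(nzchar(path), ".", ""), unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(names(tmpl), names(cfg))
  if (length(missing) > 0) {
    stop("missing required config key(s): ",
         paste0(path, ifelse(nzchar(path), ".", ""), missing, collapse = ", "),
         call. = FALSE)
  }
  for (k in names(tmpl)) {
    .check_keys(cfg[[k]], tmpl[[k]],
                paste0(path, ifelse(nzchar(path), ".", ""), k))
  }
  invisible(NULL)
}

.chk_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(what, ": probability out of [0,1] (got ", format(x), ")", call. = FALSE)
  }
}

.chk_nonneg <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
    stop(what, ": must be a non-negative number (got ", format(x), ")", call. = FALSE)
  }
}

# ---- loading ----------------------------------------------------------------

#' Load and validate a model-parameter configuration
#'
#' Reads the flat YAML configuration describing one full model
#' parameterisation: monthly transition probabilities per strategy, monthly
#' state costs by care setting, state utilities, discount rate, horizon,
#' baseline-cohort profile and the cost-component multiplicities used by the
#' sensitivity analyses. The schema is strict: unknown keys and missing
#' sections are rejected by name, every probability must lie in [0,1], costs
#' must be non-negative, and the closed-ulcer and death states must have zero
#' cost.
#'
#' @param source Path to a YAML file, or a single string containing YAML text.
#' @return A validated parameter object of class `dfu_params` (a named list
#'   mirroring the configuration tree).
#' @seealso [builtin_basecase()] for the packaged base case,
#'   [write_params()] for the inverse operation.
#' @export
load_params <- function(source) {
  cfg <- if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    yaml::read_yaml(source)
  } else {
    yaml::yaml.load(paste(source, collapse = "\n"))
  }
  .check_keys(cfg, .params_template())
  validate_params(cfg)
  structure(cfg, class = "dfu_params")
}

#' Validate a parameter object
#'
#' Checks all value-level invariants of a configuration tree (bounds,
#' zero-cost states, outgoing-probability mass, category weights summing
#' to one). Called by [load_params()]; exported so programmatically
#' modified parameter sets can be re-checked.
#'
#' @param cfg A parameter list with the `dfu_params` structure.
#' @return The input, invisibly; errors name the offending key and constraint.
#' @export
validate_params <- function(cfg) {
  if (!is.numeric(cfg$horizon_cycles) || cfg$horizon_cycles < 1 ||
      cfg$horizon_cycles != round(cfg$horizon_cycles)) {
    stop("horizon_cycles: must be a positive integer", call. = FALSE)
  }
  .chk_nonneg(cfg$discount$annual_rate, "discount.annual_rate")
  for (k in names(cfg$transitions)) .chk_prob(cfg$transitions[[k]], paste0("transitions.", k))
  for (s in names(cfg$strategies)) {
    st <- cfg$strategies[[s]]
    .chk_prob(st$p_heal, paste0("strategies.", s, ".p_heal"))
    .chk_nonneg(st$dressing_unit_price_eur, paste0("strategies.", s, ".dressing_unit_price_eur"))
    for (state in names(st$costs_eur_per_month)) {
      for (setting in c("outpatient", "inpatient")) {
        key <- paste0("strategies.", s, ".costs_eur_per_month.", state, ".", setting)
        .chk_nonneg(st$costs_eur_per_month[[state]][[setting]], key)
        if (state == "closed" && st$costs_eur_per_month[[state]][[setting]] != 0) {
          stop(key, ": closed-ulcer monthly cost must be exactly 0", call. = FALSE)
        }
      }
    }
    viol <- validate_transitions(strategy_transitions_list(cfg, s))
    if (length(viol) > 0) {
      stop("strategies.", s, ": ", paste(viol, collapse = "; "), call. = FALSE)
    }
  }
  for (k in names(cfg$p_hospital)) .chk_prob(cfg$p_hospital[[k]], paste0("p_hospital.", k))
  for (k in names(cfg$utilities)) .chk_prob(cfg$utilities[[k]], paste0("utilities.", k))
  if (cfg$utilities$dead != 0) stop("utilities.dead: must be exactly 0", call. = FALSE)
  ch <- cfg$cohort
  if (!is.numeric(ch$sd_age_years) || ch$sd_age_years <= 0) {
    stop("cohort.sd_age_years: must be > 0", call. = FALSE)
  }
  .chk_prob(ch$proportion_men, "cohort.proportion_men")
  if (ch$age_min_years >= ch$age_max_years) {
    stop("cohort.age_min_years must be < age_max_years", call. = FALSE)
  }
  w <- unlist(ch$wound_duration_weights)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("cohort.wound_duration_weights: weights must be non-negative and sum to 1",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Monthly transition set for one strategy
#'
#' Assembles the strategy-specific healing probability and the shared
#' transition probabilities into one flat list (the "transition set" of the
#' Markov diagram).
#'
#' @param params A `dfu_params` object.
#' @param strategy `"tlc_nosf"` or `"control"`.
#' @return Named list with `p_heal`, `p_recur`, `p_infect`, `p_resolve`,
#'   `p_amp` and the four state-specific death probabilities.
#' @export
strategy_transitions_list <- function(params, strategy) {
  st <- params$strategies[[strategy]]
  if (is.null(st)) stop("unknown strategy: ", strategy, call. = FALSE)
  c(list(p_heal = st$p_heal), params$transitions)
}

#' Check the invariants of a transition set
#'
#' For each transient state the outgoing monthly probabilities must sum to at
#' most one (the residual mass is "remain in state") and each probability must
#' lie in [0,1]. Death has no outgoing probability by construction.
#'
#' @param t Named list as returned by [strategy_transitions_list()].
#' @return Character vector of violations (empty when the set is valid); each
#'   entry names the state and the excess mass or offending probability.
#' @export
validate_transitions <- function(t) {
  need <- c("p_heal", "p_recur", "p_infect", "p_resolve", "p_amp",
            "p_death_uninf", "p_death_inf", "p_death_closed", "p_death_amp")
  miss <- setdiff(need, names(t))
  if (length(miss) > 0) {
    return(paste0("missing transition probability: ", miss))
  }
  viol <- character(0)
  for (k in need) {
    v <- t[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      viol <- c(viol, paste0(k, " probability out of [0,1] (", format(v), ")"))
    }
  }
  if (length(viol) > 0) return(viol)
  out <- c(
    uninfected = t$p_heal + t$p_infect + t$p_death_uninf,
    closed     = t$p_recur + t$p_death_closed,
    infected   = t$p_resolve + t$p_amp + t$p_death_inf,
    amputation = t$p_death_amp
  )
  bad <- out > 1 + 1e-12
  if (any(bad)) {
    viol <- c(viol, paste0(names(out)[bad], " outgoing mass ",
                           format(round(out[bad], 6)), " > 1"))
  }
  viol
}

#' Convert a multi-cycle probability to a per-cycle probability
#'
#' Standard constant-rate conversion: a probability `p_period` of an event
#' over `t_cycles` cycles corresponds to a per-cycle probability
#' `1 - (1 - p_period)^(1/t_cycles)` under a constant hazard.
#'
#' @param p_period Probability over the whole period, in [0, 1).
#' @param t_cycles Number of cycles in the period (positive, may be fractional).
#' @return Per-cycle probability.
#' @export
period_to_cycle_prob <- function(p_period, t_cycles) {
  if (any(t_cycles <= 0)) stop("t_cycles must be > 0", call. = FALSE)
  if (any(p_period < 0) || any(p_period >= 1)) {
    stop("p_period must be in [0, 1): a period probability of 1 implies an infinite rate",
         call. = FALSE)
  }
  1 - (1 - p_period)^(1 / t_cycles)
}

#' @rdname period_to_cycle_prob
#' @param p_cycle Per-cycle probability.
#' @export
cycle_to_period_prob <- function(p_cycle, t_cycles) {
  1 - (1 - p_cycle)^t_cycles
}

#' Packaged base-case parameter set
#'
#' Returns the parameter set shipped with the package: the published monthly
#' transition probabilities, monthly state costs by care setting (EUR 2019),
#' state utilities, 2.5% annual discount rate, 480-cycle (40-year) horizon and
#' the baseline cohort profile, together with the explicitly flagged
#' assumptions (inpatient mix, cost-component multiplicities, synthetic
#' subgroup healing probabilities).
#'
#' @return A validated `dfu_params` object.
#' @export
builtin_basecase <- function() {
  path <- system.file("extdata", "basecase_fr_2019.yaml", package = "dfusim")
  if (!nzchar(path)) stop("packaged base-case config not found", call. = FALSE)
  load_params(path)
}

#' Serialise a parameter object
#'
#' Writes a `dfu_params` object back to YAML (the loader's inverse, so
#' `load_params(write_params(p, f))` reproduces `p`), or exports the validated
#' tree as JSON for audit trails.
#'
#' @param params A `dfu_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_params
#' @export
export_params_json <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
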