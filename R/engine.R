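# Patient-level discrete-time simulation over monthly cycles, plus a
# deterministic cohort-expectation oracle used for validation.
#
# Conventions (all documented in the methods vignette):
#  * rewards accrue for the state occupied during a cycle, the transition
#    takes effect at cycle end; no half-cycle correction;
#  * each cycle resolves competing transitions with a single categorical
#    draw, interval order: death first, then the outgoing edges of the
#    Markov diagram, residual mass = remain in state;
#  * the first cycle spent in the amputation state bills the inpatient
#    amputation cost (the surgical admission), later amputation cycles the
#    outpatient cost;
#  * age advances by 1/12 year per cycle; background mortality is looked up
#    at floor(age), clamped to the life-table range.

#' Combine state-specific and background mortality
#'
#' Treats the disease-state-specific monthly death probability and the
#' all-cause background probability as independent competing hazards:
#' `1 - (1 - p_state) * (1 - p_background)`.
#'
#' @param p_state State-specific monthly death probability.
#' @param p_background Background monthly death probability.
#' @return Combined monthly death probability.
#' @export
combine_death_prob <- function(p_state, p_background) {
  stopifnot(all(p_state >= 0 & p_state <= 1), all(p_background >= 0 & p_background <= 1))
  1 - (1 - p_state) * (1 - p_background)
}

#' Per-cycle discount factor
#'
#' `(1 + annual_rate)^(-cycle/12)` for monthly cycles; cycle 0 is undiscounted.
#'
#' @param cycle_index Cycle number(s), starting at 0.
#' @param annual_rate Annual discount rate (e.g. 0.025).
#' @return Discount factor(s).
#' @export
discount_factor <- function(cycle_index, annual_rate) {
  stopifnot(all(cycle_index >= 0))
  (1 + annual_rate)^(-cycle_index / 12)
}

#' Draw the next health state
#'
#' Resolves one cycle's competing transitions for each patient with a single
#' uniform draw. The unit interval is partitioned, in order: combined death
#' probability, then the outgoing edges of the current state in diagram order
#' (uninfected: heal, infect; closed: recur; infected: resolve, amputate),
#' then the residual "remain in state" mass. Death is absorbing; amputation
#' can only be left through death.
#'
#' @param state Current state(s): labels from [dfu_states()] or integer codes.
#' @param t Transition set (see [strategy_transitions_list()]).
#' @param p_bg Background monthly death probability (vectorised over patients).
#' @param u Uniform(0,1) draw(s).
#' @return Next state(s), same mode as `state`.
#' @export
transition_draw <- function(state, t, p_bg, u) {
  chr <- is.character(state)
  s <- if (chr) .state_index(state) else as.integer(state)
  if (any(is.na(s)) || any(s < 1L) || any(s > 5L)) stop("unknown state code", call. = FALSE)
  n <- max(length(s), length(p_bg), length(u))
  s <- rep_len(s, n)
  p_bg <- rep_len(p_bg, n)
  u <- rep_len(u, n)
  pd <- numeric(n)
  sdeath <- c(t$p_death_uninf, t$p_death_closed, t$p_death_inf, t$p_death_amp, 0)
  pd <- combine_death_prob(sdeath[s], p_bg * (s != 5L))
  new <- s
  dead <- s == 5L
  dies <- !dead & u < pd
  new[dies] <- .S_DEAD
  live <- !dead & !dies
  i <- live & s == .S_UNINF
  new[i & u < pd + t$p_heal] <- .S_CLOSED
  new[i & u >= pd + t$p_heal & u < pd + t$p_heal + t$p_infect] <- .S_INFECTED
  i <- live & s == .S_CLOSED
  new[i & u < pd + t$p_recur] <- .S_UNINF
  i <- live & s == .S_INFECTED
  new[i & u < pd + t$p_resolve] <- .S_UNINF
  new[i & u >= pd + t$p_resolve & u < pd + t$p_resolve + t$p_amp] <- .S_AMP
  # amputation: no exits other than death; dead stays dead
  if (chr) dfu_states()[new] else new
}

#' Random-number streams for a cohort run
#'
#' Draws, from a single master seed, the per-patient uniform streams used by
#' the simulation: three cohort-profile streams and one `n x horizon` matrix
#' each for transition draws and hospitalisation draws. Row `i` is patient
#' `i`'s substream. Re-using one stream object across strategies, sensitivity
#' branches or horizons implements common random numbers.
#'
#' @param n Number of patients.
#' @param horizon Number of cycles.
#' @param seed Integer master seed.
#' @return List with `cohort` (list of uniforms `age`, `sex`, `cat`),
#'   `trans` and `hosp` (matrices `n x horizon`).
#' @export
make_model_streams <- function(n, horizon, seed) {
  set.seed(as.integer(seed))
  list(
    cohort = list(age = runif(n), sex = runif(n), cat = runif(n)),
    trans = matrix(runif(n * horizon), n, horizon),
    hosp = matrix(runif(n * horizon), n, horizon)
  )
}

# Per-strategy lookup tables used by the inner loop.
.strategy_tables <- function(params, strategy) {
  st <- params$strategies[[strategy]]
  if (is.null(st)) stop("unknown strategy: ", strategy, call. = FALSE)
  cost <- st$costs_eur_per_month
  list(
    label = strategy,
    name = st$name,
    trans = strategy_transitions_list(params, strategy),
    cost_out = c(cost$uninfected$outpatient, cost$closed$outpatient,
                 cost$infected$outpatient, cost$amputation$outpatient, 0),
    cost_in = c(cost$uninfected$inpatient, cost$closed$inpatient,
                cost$infected$inpatient, cost$amputation$inpatient, 0),
    p_hosp = c(params$p_hospital$uninfected, 0, params$p_hospital$infected, 0, 0),
    util = c(params$utilities$uninfected, params$utilities$closed,
             params$utilities$infected, params$utilities$amputation, 0),
    state_death = c(params$transitions$p_death_uninf, params$transitions$p_death_closed,
                    params$transitions$p_death_inf, params$transitions$p_death_amp, 0)
  )
}

.bg_lookup <- function(lt, age, male) {
  a <- pmin(floor(age), lt$max_age) + 1L
  q <- numeric(length(a))
  q[male] <- lt$table$male[a[male]]
  q[!male] <- lt$table$female[a[!male]]
  q
}

# Vectorised core: simulates all patients cycle by cycle.
.sim_core <- function(profiles, params, strategy, lt, horizon, streams,
                      keep_trace = FALSE) {
  tab <- .strategy_tables(params, strategy)
  tr <- tab$trans
  viol <- validate_transitions(tr)
  if (length(viol) > 0) stop(paste(viol, collapse = "; "), call. = FALSE)
  n <- nrow(profiles)
  H <- as.integer(horizon)
  r <- params$discount$annual_rate
  include_bg <- !isTRUE(params$options$state_death_includes_background)
  count_amp <- isTRUE(params$options$ly_wo_dfu_counts_amputation)
  dfac <- discount_factor(0:(H - 1), r)

  state <- rep(.S_UNINF, n)
  age <- profiles$age
  male <- profiles$sex == "M"
  ly <- qaly <- cost <- numeric(n)
  months <- integer(n)
  amp_entry <- rep(NA_integer_, n)
  death_cycle <- rep(NA_integer_, n)
  occ <- matrix(0L, H, 5L,
                dimnames = list(NULL, dfu_states()))
  trace <- if (keep_trace) matrix(NA_integer_, n, H) else NULL

  for (tt in seq_len(H)) {
    t0 <- tt - 1L                       # cycle index, 0-based
    occ[tt, ] <- tabulate(state, 5L)
    if (keep_trace) trace[, tt] <- state
    alive <- state != .S_DEAD
    if (!any(alive)) {
      if (tt < H) occ[(tt + 1L):H, 5L] <- n
      if (keep_trace && tt < H) trace[, (tt + 1L):H] <- .S_DEAD
      break
    }
    df <- dfac[tt]
    months <- months + as.integer(alive)
    qaly <- qaly + tab$util[state] * df
    in_wo_dfu <- state == .S_CLOSED
    if (count_amp) in_wo_dfu <- in_wo_dfu | state == .S_AMP
    ly <- ly + df * in_wo_dfu
    hosp <- streams$hosp[, tt] < tab$p_hosp[state]
    entry <- !is.na(amp_entry) & amp_entry == t0
    inpat <- hosp | (state == .S_AMP & entry)
    cost_t <- tab$cost_out[state]
    cost_t[inpat] <- tab$cost_in[state[inpat]]
    cost <- cost + cost_t * df
    # transition at cycle end
    p_bg <- if (include_bg) .bg_lookup(lt, age, male) else numeric(n)
    new <- transition_draw(state, tr, p_bg, streams$trans[, tt])
    newly_amp <- new == .S_AMP & state != .S_AMP
    amp_entry[newly_amp & is.na(amp_entry)] <- tt   # first cycle occupied in AMP
    newly_dead <- new == .S_DEAD & state != .S_DEAD
    death_cycle[newly_dead] <- tt
    state <- new
    age <- age + 1 / 12
  }

  patients <- data.frame(
    age0 = profiles$age, sex = profiles$sex,
    ly_wo_dfu = ly / 12, qaly = qaly / 12, cost = cost,
    months_alive = months,
    amputated = !is.na(amp_entry),
    amp_entry_cycle = amp_entry,
    death_cycle = death_cycle
  )
  list(patients = patients, occupancy = occ / n, trace = trace,
       strategy = strategy, horizon = H)
}

.summarise_cohort <- function(core, n, seed) {
  p <- core$patients
  num <- c("ly_wo_dfu", "qaly", "cost", "months_alive")
  means <- vapply(p[num], mean, numeric(1))
  ses <- vapply(p[num], function(x) stats::sd(x) / sqrt(length(x)), numeric(1))
  structure(
    list(
      n = n, seed = seed, strategy = core$strategy, horizon = core$horizon,
      mean = means, se = ses,
      amputation_count = sum(p$amputated),
      amputation_prob = mean(p$amputated),
      occupancy = core$occupancy,
      patients = p, trace = core$trace
    ),
    class = "dfu_cohort"
  )
}

#' Simulate one patient
#'
#' Runs a single patient through the model: starting with an uninfected
#' ulcer at cycle 0, each cycle accrues that cycle's discounted rewards
#' (a closed-ulcer month, utility-weighted month, monthly cost) and then
#' draws the next state, stopping at death or the horizon.
#'
#' @param profile One-row data.frame with `age` and `sex` (see
#'   [sample_cohort()]).
#' @param params A `dfu_params` object.
#' @param strategy `"tlc_nosf"` or `"control"`.
#' @param lt Background-mortality table ([make_life_table()]).
#' @param streams Streams from [make_model_streams()] with `n = 1`, or one
#'   patient's rows from a cohort's streams.
#' @param horizon Number of cycles (default: `params$horizon_cycles`).
#' @return List with `outcome` (one-row data.frame of discounted outcomes)
#'   and `trajectory` (data.frame of `cycle`, `state`).
#' @export
simulate_patient <- function(profile, params, strategy, lt, streams,
                             horizon = params$horizon_cycles) {
  stopifnot(nrow(profile) == 1)
  streams$trans <- matrix(streams$trans, nrow = 1)
  streams$hosp <- matrix(streams$hosp, nrow = 1)
  core <- .sim_core(profile, params, strategy, lt, horizon, streams,
                    keep_trace = TRUE)
  traj <- data.frame(cycle = 0:(horizon - 1), state = dfu_states()[core$trace[1, ]])
  list(outcome = core$patients, trajectory = traj)
}

#' Simulate a cohort under one strategy
#'
#' Microsimulation of `n` patients with per-patient random-number substreams
#' drawn from one master seed. Patients alive at the horizon are censored
#' there. Supply the same `streams`/`cohort` to several calls (different
#' strategies, perturbed parameters, shorter horizons) for common random
#' numbers.
#'
#' @inheritParams simulate_patient
#' @param n Number of patients.
#' @param seed Integer master seed (ignored when `streams` is supplied).
#' @param streams Optional pre-drawn streams from [make_model_streams()].
#' @param cohort Optional pre-sampled cohort data.frame; by default the
#'   cohort is derived from the stream's profile uniforms and
#'   `params$cohort`.
#' @param keep_trace Keep the full patient-by-cycle state matrix.
#' @return A `dfu_cohort` object: per-patient outcomes, cohort means and
#'   standard errors (discounted LY without DFU, QALY, cost, undiscounted
#'   months alive), amputation count, and the per-cycle state-occupancy
#'   fractions.
#' @export
run_cohort <- function(params, strategy, n = 1000, seed = params$seed,
                       lt = make_life_table(), horizon = params$horizon_cycles,
                       streams = NULL, cohort = NULL, keep_trace = FALSE) {
  stopifnot(n >= 1)
  if (is.null(streams)) streams <- make_model_streams(n, horizon, seed)
  if (is.null(cohort)) cohort <- cohort_from_uniforms(params$cohort, streams$cohort)
  core <- .sim_core(cohort, params, strategy, lt, horizon, streams, keep_trace)
  .summarise_cohort(core, n, seed)
}

#' Run both strategies under common random numbers
#'
#' Samples one cohort and one set of random streams, then simulates it under
#' the intervention (TLC-NOSF) and comparator (neutral dressing), so that
#' outcome differences reflect the parameters, not sampling noise. Returns
#' both cohort results and their incremental comparison.
#'
#' @inheritParams run_cohort
#' @return List with `tlc_nosf`, `control` (both `dfu_cohort`) and
#'   `comparison` ([compare_strategies()]).
#' @export
run_two_arm <- function(params, n = 1000, seed = params$seed,
                        lt = make_life_table(), horizon = params$horizon_cycles,
                        streams = NULL, cohort = NULL) {
  if (is.null(streams)) streams <- make_model_streams(n, horizon, seed)
  if (is.null(cohort)) cohort <- cohort_from_uniforms(params$cohort, streams$cohort)
  a <- run_cohort(params, "tlc_nosf", n, seed, lt, horizon, streams, cohort)
  b <- run_cohort(params, "control", n, seed, lt, horizon, streams, cohort)
  list(tlc_nosf = a, control = b, comparison = compare_strategies(a, b))
}

#' Deterministic cohort-expectation oracle
#'
#' Computes the exact expected outcomes of the model by forward propagation
#' of the state-occupancy distribution, independent of any random-number
#' generation: expected discounted LY without DFU, QALY and cost, expected
#' undiscounted months alive, cumulative amputation probability, and the
#' expected per-cycle occupancy. Hospitalisation is handled in expectation;
#' entry into the amputation state is tracked as an auxiliary flow so the
#' admission-cycle cost is timed as in the microsimulation. Used as the
#' independent validation oracle for [run_cohort()].
#'
#' @inheritParams run_cohort
#' @param profiles Data.frame of patient profiles (`age`, `sex`); the
#'   expectation is averaged over them. Use the same profiles as a
#'   simulation run for a like-for-like comparison.
#' @return List with `mean` (named vector: `ly_wo_dfu`, `qaly`, `cost`,
#'   `months_alive`), `amputation_prob` and `occupancy` (expected fractions
#'   per cycle).
#' @export
cohort_expectation <- function(params, strategy, lt = make_life_table(),
                               horizon = params$horizon_cycles, profiles) {
  tab <- .strategy_tables(params, strategy)
  tr <- tab$trans
  viol <- validate_transitions(tr)
  if (length(viol) > 0) stop(paste(viol, collapse = "; "), call. = FALSE)
  m <- nrow(profiles)
  H <- as.integer(horizon)
  r <- params$discount$annual_rate
  include_bg <- !isTRUE(params$options$state_death_includes_background)
  count_amp <- isTRUE(params$options$ly_wo_dfu_counts_amputation)
  dfac <- discount_factor(0:(H - 1), r)
  male <- profiles$sex == "M"
  age <- profiles$age

  # expected per-month cost in the uninfected/infected states
  ec <- tab$p_hosp * tab$cost_in + (1 - tab$p_hosp) * tab$cost_out

  occ <- matrix(0, m, 5)
  occ[, .S_UNINF] <- 1
  newA <- numeric(m)       # mass occupying amputation for the first time this cycle
  amp_cum <- numeric(m)
  ly <- qaly <- cost <- months <- numeric(m)
  occ_trace <- matrix(0, H, 5, dimnames = list(NULL, dfu_states()))

  for (tt in seq_len(H)) {
    df <- dfac[tt]
    occ_trace[tt, ] <- colMeans(occ)
    in_wo <- occ[, .S_CLOSED]
    if (count_amp) in_wo <- in_wo + occ[, .S_AMP]
    ly <- ly + df * in_wo
    qaly <- qaly + df * as.vector(occ %*% tab$util)
    cost <- cost + df * (occ[, .S_UNINF] * ec[.S_UNINF] +
                           occ[, .S_INFECTED] * ec[.S_INFECTED] +
                           (occ[, .S_AMP] - newA) * tab$cost_out[.S_AMP] +
                           newA * tab$cost_in[.S_AMP])
    months <- months + (1 - occ[, .S_DEAD])
    p_bg <- if (include_bg) .bg_lookup(lt, age, male) else numeric(m)
    # pd columns: uninfected, closed, infected, amputation
    pd <- cbind(combine_death_prob(tab$state_death[1], p_bg),
                combine_death_prob(tab$state_death[2], p_bg),
                combine_death_prob(tab$state_death[3], p_bg),
                combine_death_prob(tab$state_death[4], p_bg))
    inflowA <- occ[, .S_INFECTED] * tr$p_amp
    amp_cum <- amp_cum + inflowA
    u <- occ[, .S_UNINF]; cl <- occ[, .S_CLOSED]
    i <- occ[, .S_INFECTED]; a <- occ[, .S_AMP]; d <- occ[, .S_DEAD]
    occ <- cbind(
      u * (1 - tr$p_heal - tr$p_infect - pd[, 1]) + cl * tr$p_recur + i * tr$p_resolve,
      cl * (1 - tr$p_recur - pd[, 2]) + u * tr$p_heal,
      i * (1 - tr$p_resolve - tr$p_amp - pd[, 3]) + u * tr$p_infect,
      a * (1 - pd[, 4]) + inflowA,
      d + u * pd[, 1] + cl * pd[, 2] + i * pd[, 3] + a * pd[, 4]
    )
    newA <- inflowA
    age <- age + 1 / 12
  }
  list(
    mean = c(ly_wo_dfu = mean(ly) / 12, qaly = mean(qaly) / 12,
             cost = mean(cost), months_alive = mean(months)),
    amputation_prob = mean(amp_cum),
    occupancy = occ_trace
  )
}
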