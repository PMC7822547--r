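# Synthetic inputs: baseline cohort and background-mortality life table.
# These stand in for inputs the published analysis used but did not print
# (the national all-cause life table; individual patient profiles).

# ---- cohort -----------------------------------------------------------------

#' Sample a synthetic baseline cohort
#'
#' Draws `n` patient profiles matching a baseline cohort specification: age
#' from a normal distribution truncated to the configured bounds, sex from a
#' Bernoulli on the proportion of men, and a wound-duration category from the
#' configured weights. Sampling is deterministic given `seed`.
#'
#' Internally the profiles are an inverse-CDF transform of three uniform
#' streams, so a sensitivity analysis that shifts the mean age re-uses the
#' same underlying draws (common random numbers).
#'
#' @param spec Cohort specification: the `cohort` element of a `dfu_params`
#'   object (fields `mean_age_years`, `sd_age_years`, `proportion_men`,
#'   `age_min_years`, `age_max_years`, `wound_duration_weights`).
#' @param n Number of patients (>= 1).
#' @param seed Integer seed.
#' @return `data.frame` with columns `age` (years), `sex` (`"M"`/`"F"`) and
#'   `wound_duration` (factor with the four category labels).
#' @export
sample_cohort <- function(spec, n, seed) {
  stopifnot(n >= 1)
  if (!is.numeric(spec$sd_age_years) || spec$sd_age_years <= 0) {
    stop("cohort spec: sd_age_years must be > 0", call. = FALSE)
  }
  set.seed(as.integer(seed))
  u <- list(age = runif(n), sex = runif(n), cat = runif(n))
  cohort_from_uniforms(spec, u)
}

#' @rdname sample_cohort
#' @param u List of three uniform(0,1) vectors (`age`, `sex`, `cat`) of equal
#'   length, e.g. drawn once and shared across scenarios.
#' @export
cohort_from_uniforms <- function(spec, u) {
  mu <- spec$mean_age_years
  sd <- spec$sd_age_years
  plo <- pnorm((spec$age_min_years - mu) / sd)
  phi <- pnorm((spec$age_max_years - mu) / sd)
  age <- mu + sd * qnorm(plo + u$age * (phi - plo))
  sex <- ifelse(u$sex < spec$proportion_men, "M", "F")
  w <- unlist(spec$wound_duration_weights)
  labs <- names(w)
  cat <- labs[findInterval(u$cat, cumsum(w) / sum(w)) + 1L]
  data.frame(age = age, sex = sex,
             wound_duration = factor(cat, levels = labs))
}

#' Export or read a cohort as CSV
#' @param cohort Cohort `data.frame` from [sample_cohort()].
#' @param path File path.
#' @return `path` (write) or the cohort `data.frame` (read).
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

# ---- life table -------------------------------------------------------------

#' Default Gompertz--Makeham coefficients
#'
#' Annual all-cause mortality hazard is modelled as `a + b * exp(c * age)`
#' per sex. The defaults use a mortality-rate doubling time of about 8.2
#' years (`c = 0.085`) and are anchored so that annual all-cause mortality at
#' age 64 is 1.5% for men and 0.85% for women -- the order of magnitude of
#' French national statistics for the cohort's baseline age. A real life
#' table can be substituted via [read_life_table()].
#'
#' @return List with elements `male` and `female`, each `c(a, b, c)`.
#' @export
gm_defaults <- function() {
  c_slope <- 0.085
  anchor_age <- 64
  solve_b <- function(annual_q, a) (-log(1 - annual_q) - a) / exp(c_slope * anchor_age)
  list(
    male   = c(a = 2e-4, b = solve_b(0.0150, 2e-4), c = c_slope),
    female = c(a = 1e-4, b = solve_b(0.0085, 1e-4), c = c_slope)
  )
}

#' Build a synthetic background-mortality life table
#'
#' Tabulates the monthly all-cause death probability by integer age and sex
#' from Gompertz--Makeham hazards: `q_month(age) = 1 - exp(-(a + b e^{c age})/12)`.
#' The entry at `max_age` is forced to 1 (certain death), making the table a
#' proper terminating life table.
#'
#' @param gm Coefficients as returned by [gm_defaults()]: list with `male`
#'   and `female`, each `c(a, b, c)` with `a, b >= 0`.
#' @param max_age Maximum tabulated age (years).
#' @return Object of class `dfu_lifetable`: list with `table` (data.frame
#'   `age`, `male`, `female` of monthly probabilities), `max_age`, `gm`.
#' @export
make_life_table <- function(gm = gm_defaults(), max_age = 110) {
  ages <- 0:max_age
  q <- sapply(c("male", "female"), function(s) {
    co <- gm[[s]]
    if (any(co[c("a", "b")] < 0)) {
      stop("Gompertz-Makeham coefficients a, b must be >= 0", call. = FALSE)
    }
    haz <- co[["a"]] + co[["b"]] * exp(co[["c"]] * ages)
    1 - exp(-haz / 12)
  })
  if (any(q < 0) || any(q > 1)) stop("hazards yield probabilities outside [0,1]", call. = FALSE)
  if (any(diff(q[, "male"]) < -1e-15) || any(diff(q[, "female"]) < -1e-15)) {
    stop("monthly death probability must be non-decreasing in age", call. = FALSE)
  }
  q[length(ages), ] <- 1
  structure(
    list(table = data.frame(age = ages, male = q[, "male"], female = q[, "female"]),
         max_age = max_age, gm = gm),
    class = "dfu_lifetable"
  )
}

#' Zero background-mortality table
#'
#' All-zero table (except the forced terminal 1) used to isolate the printed
#' state-specific transition probabilities from the synthetic background
#' mortality assumption.
#'
#' @param max_age Maximum tabulated age.
#' @return A `dfu_lifetable`.
#' @export
zero_life_table <- function(max_age = 110) {
  ages <- 0:max_age
  q <- rep(0, length(ages))
  q[length(q)] <- 1
  structure(
    list(table = data.frame(age = ages, male = q, female = q),
         max_age = max_age, gm = NULL),
    class = "dfu_lifetable"
  )
}

#' Look up the monthly background death probability
#'
#' Uses the floor of the (possibly fractional) age: a patient aged 64.9 gets
#' the entry for age 64.
#'
#' @param lt A `dfu_lifetable`.
#' @param age Age(s) in years.
#' @param sex `"M"`/`"F"` (recycled as needed).
#' @return Monthly death probability/ies.
#' @export
background_monthly_prob <- function(lt, age, sex) {
  a <- floor(age)
  if (any(a < 0) || any(a > lt$max_age)) {
    stop("age outside life-table range [0, ", lt$max_age, "]", call. = FALSE)
  }
  n <- max(length(a), length(sex))
  a <- rep_len(a, n)
  sex <- rep_len(sex, n)
  out <- numeric(n)
  male <- sex == "M"
  out[male] <- lt$table$male[a[male] + 1L]
  out[!male] <- lt$table$female[a[!male] + 1L]
  out
}

#' Life-table CSV exchange
#'
#' Writes/reads the table as CSV with header `age,male,female` (monthly death
#' probabilities per sex), so a real national life table can be substituted
#' for the synthetic one.
#'
#' @param lt A `dfu_lifetable`.
#' @param path File path.
#' @return `path` (write) or a `dfu_lifetable` (read).
#' @export
write_life_table <- function(lt, path) {
  write.csv(lt$table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_life_table
#' @export
read_life_table <- function(path) {
  tab <- read.csv(path)
  stopifnot(all(c("age", "male", "female") == names(tab)))
  if (any(tab$age != seq(tab$age[1], by = 1, length.out = nrow(tab)))) {
    stop("life-table ages must be consecutive integers", call. = FALSE)
  }
  if (tab$age[1] != 0) stop("life table must start at age 0", call. = FALSE)
  q <- as.matrix(tab[, c("male", "female")])
  if (any(q < 0) || any(q > 1)) stop("life-table probabilities outside [0,1]", call. = FALSE)
  if (any(apply(q, 2, function(col) any(diff(col) < -1e-12)))) {
    stop("life-table probabilities must be non-decreasing in age", call. = FALSE)
  }
  structure(list(table = tab, max_age = max(tab$age), gm = NULL),
            class = "dfu_lifetable")
}
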