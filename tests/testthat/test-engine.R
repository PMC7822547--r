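test_that("death-probability combination is the independent-hazards product", {
  expect_equal(combine_death_prob(0.009, 0), 0.009)
  expect_equal(combine_death_prob(0.009, 0.0013), 1 - (1 - 0.009) * (1 - 0.0013))
  expect_equal(combine_death_prob(0.009, 0.0013), 0.0102883, tolerance = 1e-7)
  expect_equal(combine_death_prob(1, 0.5), 1)
  expect_equal(combine_death_prob(0, 0), 0)
  expect_error(combine_death_prob(1.2, 0))
})

test_that("discount factors follow the annual-rate convention on monthly cycles", {
  expect_equal(discount_factor(0, 0.025), 1)
  expect_equal(discount_factor(12, 0.025), 1 / 1.025)
  expect_equal(discount_factor(12, 0.025), 0.97561, tolerance = 1e-5)
  expect_equal(discount_factor(480, 0.025), 1.025^-40)
  expect_equal(discount_factor(480, 0.025), 0.37243, tolerance = 1e-5)
  expect_equal(discount_factor(7, 0), 1)
})

test_that("transition draws honour forced edges and absorbing states", {
  p <- base_params()
  tr <- strategy_transitions_list(p, "tlc_nosf")
  forced <- tr
  forced$p_heal <- 1
  forced$p_infect <- 0
  forced$p_death_uninf <- 0
  expect_equal(transition_draw("uninfected", forced, 0, 0.5), "closed")
  expect_equal(transition_draw("dead", tr, 0, runif(20)), rep("dead", 20))
  # amputation leaves only through death
  out <- transition_draw(rep("amputation", 1000), tr, 0, runif(1000))
  expect_true(all(out %in% c("amputation", "dead")))
  expect_error(transition_draw("limbo", tr, 0, 0.5), "unknown")
})

test_that("transition draws reproduce the input multinomial frequencies", {
  p <- base_params()
  tr <- strategy_transitions_list(p, "tlc_nosf")
  n <- 2e5
  set.seed(101)
  out <- transition_draw(rep("uninfected", n), tr, 0, runif(n))
  probs <- c(closed = 0.091, infected = 0.036, dead = 0.009, uninfected = 0.864)
  for (s in names(probs)) {
    se <- sqrt(probs[[s]] * (1 - probs[[s]]) / n)
    expect_lt(abs(mean(out == s) - probs[[s]]), 3 * se)
  }
})

test_that("immediate absorption yields exactly the first cycle's rewards", {
  p <- quiet_params()
  p$transitions$p_death_uninf <- 1
  p$transitions$p_death_inf <- 1
  p$transitions$p_death_closed <- 1
  p$transitions$p_death_amp <- 1
  p$strategies$tlc_nosf$p_heal <- 0
  p$strategies$control$p_heal <- 0
  p$transitions$p_infect <- 0
  p$transitions$p_recur <- 0
  p$transitions$p_resolve <- 0
  p$transitions$p_amp <- 0
  pr <- data.frame(age = 64, sex = "M")
  r <- simulate_patient(pr, p, "tlc_nosf", zero_life_table(),
                        make_model_streams(1, 48, 7), horizon = 48)
  expect_equal(r$outcome$months_alive, 1)
  expect_equal(r$outcome$qaly, 0.75 / 12)
  expect_equal(r$outcome$ly_wo_dfu, 0)
  expect_equal(r$outcome$cost, 1011)   # one outpatient uninfected month
  expect_equal(r$trajectory$state[1], "uninfected")
  expect_true(all(r$trajectory$state[-1] == "dead"))
})

test_that("a certain immediate heal with no deaths accrues horizon-1 closed months", {
  p <- quiet_params()
  p$strategies$tlc_nosf$p_heal <- 1
  p$transitions$p_infect <- 0
  p$transitions$p_recur <- 0
  p$discount$annual_rate <- 0
  H <- 120
  r <- run_cohort(p, "tlc_nosf", n = 20, seed = 5, lt = zero_life_table(),
                  horizon = H)
  expect_equal(unname(r$mean[["ly_wo_dfu"]]), (H - 1) / 12)
  expect_equal(unname(r$se[["ly_wo_dfu"]]), 0)
  expect_equal(unname(r$mean[["months_alive"]]), H)
})

test_that("runs are deterministic and n = 1 matches the patient-level path", {
  p <- base_params()
  lt <- test_lt()
  a <- run_cohort(p, "control", n = 150, seed = 11, lt = lt, horizon = 120)
  b <- run_cohort(p, "control", n = 150, seed = 11, lt = lt, horizon = 120)
  expect_identical(a$patients, b$patients)
  # one patient's substream replayed through simulate_patient
  streams <- make_model_streams(150, 120, 11)
  cohort <- cohort_from_uniforms(p$cohort, streams$cohort)
  i <- 37
  sp <- simulate_patient(cohort[i, , drop = FALSE], p, "control", lt,
                         list(trans = streams$trans[i, ], hosp = streams$hosp[i, ]),
                         horizon = 120)
  expect_equal(sp$outcome$qaly, a$patients$qaly[i])
  expect_equal(sp$outcome$cost, a$patients$cost[i])
  expect_equal(sp$outcome$months_alive, a$patients$months_alive[i])
})

test_that("state occupancy is conserved at every cycle", {
  r <- run_cohort(base_params(), "tlc_nosf", n = 250, seed = 2, lt = test_lt(),
                  horizon = 200)
  expect_true(all(abs(rowSums(r$occupancy) - 1) < 1e-9))
  expect_lte(r$amputation_count, r$n)
})

test_that("per-patient outcomes satisfy their structural bounds", {
  p <- base_params()
  r <- run_cohort(p, "tlc_nosf", n = 300, seed = 6, lt = test_lt(), horizon = 480)
  pt <- r$patients
  expect_true(all(pt$ly_wo_dfu >= 0 & pt$qaly >= 0 & pt$cost >= 0))
  umax <- max(unlist(p$utilities))
  expect_true(all(pt$qaly <= pt$months_alive / 12 * umax + 1e-12))
  expect_true(all(pt$ly_wo_dfu <= pt$months_alive / 12 + 1e-12))
  # discounted closed time cannot exceed undiscounted lifetime
  expect_true(all(pt$months_alive <= 480))
})

test_that("equal healing efficacy gives exactly zero incremental effectiveness", {
  p <- base_params()
  p$strategies$control$p_heal <- p$strategies$tlc_nosf$p_heal
  r <- run_two_arm(p, n = 300, seed = 8, lt = test_lt(), horizon = 240)
  expect_identical(r$comparison$d_ly_wo_dfu, 0)
  expect_identical(r$comparison$d_qaly, 0)
})

test_that("mean effectiveness responds monotonically under common random numbers", {
  p <- base_params()
  lt <- test_lt()
  streams <- make_model_streams(1500, 240, 13)
  ly_at <- function(ph) {
    p2 <- p
    p2$strategies$tlc_nosf$p_heal <- ph
    run_cohort(p2, "tlc_nosf", 1500, lt = lt, horizon = 240,
               streams = streams)$mean[["ly_wo_dfu"]]
  }
  lys <- vapply(c(0.03, 0.06, 0.09, 0.12), ly_at, numeric(1))
  expect_true(all(diff(lys) > 0))
  # discounting: higher rate never increases any discounted outcome (pathwise)
  out_at <- function(rate) {
    p2 <- p
    p2$discount$annual_rate <- rate
    run_cohort(p2, "tlc_nosf", 400, lt = lt, horizon = 240,
               streams = streams_sub)$mean[c("ly_wo_dfu", "qaly", "cost")]
  }
  streams_sub <- make_model_streams(400, 240, 14)
  o <- sapply(c(0, 0.025, 0.05), out_at)
  expect_true(all(o[, 2] <= o[, 1] & o[, 3] <= o[, 2]))
})

test_that("microsimulation agrees with the deterministic expectation oracle", {
  p <- base_params()
  lt <- test_lt()
  n <- 4000
  r <- run_cohort(p, "tlc_nosf", n = n, seed = 21, lt = lt)
  ex <- cohort_expectation(p, "tlc_nosf", lt, p$horizon_cycles, profiles = r$patients |>
                             (\(d) data.frame(age = d$age0, sex = d$sex))())
  for (k in c("ly_wo_dfu", "qaly", "cost")) {
    expect_lt(abs(r$mean[[k]] - ex$mean[[k]]), 3 * r$se[[k]])
  }
  se_amp <- sqrt(r$amputation_prob * (1 - r$amputation_prob) / n)
  expect_lt(abs(r$amputation_prob - ex$amputation_prob), 3 * se_amp)
  # oracle occupancy is conserved too
  expect_true(all(abs(rowSums(ex$occupancy) - 1) < 1e-9))
})

test_that("oracle symmetry: equal healing gives identical per-arm effectiveness", {
  p <- base_params()
  p$strategies$control$p_heal <- p$strategies$tlc_nosf$p_heal
  prof <- data.frame(age = c(60, 70), sex = c("M", "F"))
  a <- cohort_expectation(p, "tlc_nosf", test_lt(), 120, prof)
  b <- cohort_expectation(p, "control", test_lt(), 120, prof)
  expect_equal(a$mean[["ly_wo_dfu"]], b$mean[["ly_wo_dfu"]])
  expect_equal(a$mean[["qaly"]], b$mean[["qaly"]])
  # horizon 1: occupancy is the initial distribution, rewards the first cycle's
  h1 <- cohort_expectation(p, "tlc_nosf", test_lt(), 1, prof)
  expect_equal(unname(h1$occupancy[1, ]), c(1, 0, 0, 0, 0))
  expect_equal(h1$mean[["qaly"]], 0.75 / 12)
})
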