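test_that("sensitivity ranges are valid and parameters apply to the model", {
  p <- base_params()
  rg <- default_dsa_ranges(p)
  expect_true(all(rg$lower <= rg$base & rg$base <= rg$upper))
  expect_error(apply_dsa_param(p, "no_such_param", 1), "unknown sensitivity parameter")
  # engine-level parameter
  p2 <- apply_dsa_param(p, "p_amp", 0.014)
  expect_equal(p2$transitions$p_amp, 0.014)
  # dressing price maps through the per-state multiplicities, one arm only
  p3 <- apply_dsa_param(p, "unit_price_tlc", 9.59)
  d <- 9.59 - 7.99
  expect_equal(p3$strategies$tlc_nosf$costs_eur_per_month$uninfected$outpatient,
               1011 + d * p$cost_components$dressings_per_month$uninfected)
  expect_equal(p3$strategies$tlc_nosf$costs_eur_per_month$infected$inpatient,
               6516 + d * p$cost_components$dressings_per_month$infected)
  expect_equal(p3$strategies$control$costs_eur_per_month$uninfected$outpatient, 875)
  # amputation surgery maps to the inpatient amputation cell of both arms
  p4 <- apply_dsa_param(p, "amputation_surgery", 9685)
  expect_equal(p4$strategies$tlc_nosf$costs_eur_per_month$amputation$inpatient,
               23560 + (9685 - 7450))
  # costs never go negative
  p5 <- apply_dsa_param(p, "nurse_visit", 0)
  expect_true(p5$strategies$control$costs_eur_per_month$uninfected$outpatient >= 0)
})

test_that("tornado swings vanish for degenerate ranges and inert parameters", {
  p <- base_params()
  rg <- data.frame(parameter = c("p_amp", "nurse_visit", "amputation_surgery"),
                   base = c(0.011, 14, 7450),
                   lower = c(0.011, 9.8, 5215),
                   upper = c(0.011, 18.2, 9685),
                   psa = TRUE)
  d <- run_dsa(p, rg, n = 120, seed = 19, lt = test_lt(), horizon = 120,
               outcome = "qaly")
  expect_equal(nrow(d), 3)
  # degenerate range: zero swing
  expect_equal(d$swing[d$parameter == "p_amp"], 0)
  # cost-only parameters cannot move QALYs under common random numbers
  expect_equal(d$swing[d$parameter == "nurse_visit"], 0)
  expect_equal(d$swing[d$parameter == "amputation_surgery"], 0)
  # on the cost outcome the nurse-visit row does move
  d2 <- run_dsa(p, rg, n = 120, seed = 19, lt = test_lt(), horizon = 120,
                outcome = "cost")
  expect_gt(d2$swing[d2$parameter == "nurse_visit"], 0)
  # sorted by decreasing swing
  expect_true(all(diff(d2$swing) <= 0))
})

test_that("probabilistic parameter sampling is uniform over its bounds", {
  rg <- data.frame(parameter = c("a", "b"), base = c(1, 5),
                   lower = c(0, 5), upper = c(2, 5))
  set.seed(33)
  one <- sample_psa_params(rg)
  expect_equal(unname(one["b"]), 5)          # degenerate range
  set.seed(34)
  draws <- t(replicate(2000, sample_psa_params(rg)))
  expect_true(all(draws[, "a"] >= 0 & draws[, "a"] <= 2))
  se <- (2 - 0) / sqrt(12) / sqrt(2000)
  expect_lt(abs(mean(draws[, "a"]) - 1), 3 * se)
})

test_that("a degenerate PSA reproduces the base-case comparison exactly", {
  p <- base_params()
  rg <- default_dsa_ranges(p)
  rg <- rg[rg$psa, ]
  rg$lower <- rg$upper <- rg$base
  ps <- run_psa(p, rg, n_outer = 1, n_inner = 80, seed = 11, lt = test_lt(),
                horizon = 120)
  base <- run_two_arm(p, n = 80, seed = psa_inner_seeds(11, 1)[1],
                      lt = test_lt(), horizon = 120)
  expect_identical(ps$d_qaly[1], base$comparison$d_qaly)
  expect_identical(ps$d_cost[1], base$comparison$d_cost)
})

test_that("PSA output has one bounded sample per replicate", {
  p <- base_params()
  rg <- default_dsa_ranges(p)
  rg <- rg[rg$psa, ][1:4, ]
  ps <- run_psa(p, rg, n_outer = 5, n_inner = 40, seed = 77, lt = test_lt(),
                horizon = 60)
  expect_equal(nrow(ps), 5)
  for (j in seq_len(nrow(rg))) {
    expect_true(all(ps[[rg$parameter[j]]] >= rg$lower[j] &
                      ps[[rg$parameter[j]]] <= rg$upper[j]))
  }
  expect_true(all(c("d_qaly", "d_cost", "dominant") %in% names(ps)))
})

test_that("acceptability curves partition probability across the strategies", {
  fake <- structure(data.frame(d_qaly = c(1, -1), d_cost = c(0, 0)),
                    class = c("dfu_psa", "data.frame"))
  ce <- ceac(fake, lambda_grid = c(0, 1000))
  expect_equal(ce$p_tlc_nosf + ce$p_control, rep(1, 2))
  expect_equal(ce$p_tlc_nosf[ce$lambda == 0], 1)      # ties go to the intervention
  expect_equal(ce$p_tlc_nosf[ce$lambda == 1000], 0.5) # split sample
  # monotone in lambda when all samples share the sign of the QALY delta
  pos <- structure(data.frame(d_qaly = c(0.1, 0.2, 0.3),
                              d_cost = c(500, -200, 100)),
                   class = c("dfu_psa", "data.frame"))
  cm <- ceac(pos, lambda_grid = seq(0, 10000, 500))
  expect_true(all(diff(cm$p_tlc_nosf) >= 0))
  expect_error(ceac(fake, lambda_grid = numeric(0)))
})

test_that("subgroup runner preserves settings and reacts to healing gaps", {
  p <- base_params()
  same <- list(p_heal_tlc = p$strategies$tlc_nosf$p_heal,
               p_heal_control = p$strategies$control$p_heal)
  sg_same <- run_subgroups(p, list(le_2mo = same, `3_5mo` = same,
                                   `6_11mo` = same, gt_11mo = same),
                           n = 150, seed = 9, lt = test_lt(), horizon = 120)
  s <- attr(sg_same, "summary")
  expect_equal(length(unique(s$d_ly_wo_dfu)), 1)   # identical comparisons
  expect_equal(length(unique(s$d_cost)), 1)
  expect_error(run_subgroups(p, list(le_2mo = same), n = 50, seed = 1,
                             lt = test_lt(), horizon = 12),
               "missing subgroup")
})

test_that("wider healing gaps in earlier subgroups give larger effect gains", {
  p <- base_params()
  sg <- run_subgroups(p, n = 800, seed = 15, lt = test_lt(), horizon = 360)
  s <- attr(sg, "summary")
  expect_equal(s$subgroup, c("le_2mo", "3_5mo", "6_11mo", "gt_11mo"))
  # packaged gaps decrease with duration; LY gains must follow
  expect_true(all(diff(s$p_heal_tlc - s$p_heal_control) < 0))
  expect_true(all(diff(s$d_ly_wo_dfu) < 0))
  # TLC heals at least as fast and costs map proportionally: dominance everywhere
  expect_true(all(s$dominance == "intervention-dominant"))
})
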