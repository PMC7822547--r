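test_that("sampled cohorts match the baseline profile", {
  spec <- builtin_basecase()$cohort
  co <- sample_cohort(spec, 10000, seed = 42)
  expect_equal(nrow(co), 10000)
  expect_lt(abs(mean(co$age) - 64.2), 0.4)
  expect_lt(abs(mean(co$sex == "M") - 0.86), 0.01 + 3 * sqrt(0.86 * 0.14 / 10000))
  expect_true(all(co$age >= 18 & co$age <= 100))
  expect_identical(co, sample_cohort(spec, 10000, seed = 42))  # determinism
  expect_false(identical(co$age, sample_cohort(spec, 10000, seed = 43)$age))
})

test_that("cohort statistics converge to the closed-form truncated moments", {
  spec <- builtin_basecase()$cohort
  n <- 1e5
  co <- sample_cohort(spec, n, seed = 9)
  # closed-form truncated-normal mean as the independent oracle
  mu <- spec$mean_age_years; s <- spec$sd_age_years
  a <- (spec$age_min_years - mu) / s; b <- (spec$age_max_years - mu) / s
  m_true <- mu + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_lt(abs(mean(co$age) - m_true), 3 * s / sqrt(n))
  w <- unlist(spec$wound_duration_weights)
  freq <- as.numeric(table(co$wound_duration)[names(w)]) / n
  expect_true(all(abs(freq - w) < 3 * sqrt(w * (1 - w) / n)))
})

test_that("degenerate cohort specs behave at the limit or error", {
  spec <- builtin_basecase()$cohort
  spec$sd_age_years <- 1e-9
  co <- sample_cohort(spec, 5, seed = 1)
  expect_equal(co$age, rep(spec$mean_age_years, 5), tolerance = 1e-6)
  spec$sd_age_years <- 0
  expect_error(sample_cohort(spec, 5, seed = 1), "sd_age")
})

test_that("Gompertz-Makeham life table is monotone, bounded and terminating", {
  lt <- make_life_table()
  q <- lt$table
  expect_true(all(q$male >= 0 & q$male <= 1 & q$female >= 0 & q$female <= 1))
  expect_true(all(diff(q$male) >= 0) && all(diff(q$female) >= 0))
  expect_equal(q$male[q$age == lt$max_age], 1)
  expect_equal(q$female[q$age == lt$max_age], 1)
  # magnitude anchor: mid-sixties male monthly mortality
  q64 <- background_monthly_prob(lt, 64, "M")
  expect_gt(q64, 0.0005)
  expect_lt(q64, 0.003)
  # women lighter mortality than men at the anchor
  expect_lt(background_monthly_prob(lt, 64, "F"), q64)
})

test_that("pure Makeham hazard gives a constant table", {
  gm <- list(male = c(a = 0.001, b = 0, c = 0), female = c(a = 0.001, b = 0, c = 0))
  lt <- make_life_table(gm, max_age = 50)
  body <- lt$table$male[1:50]              # all but the forced terminal 1
  expect_equal(body, rep(body[1], 50))
  expect_equal(lt$table$male[51], 1)
})

test_that("life-table lookup uses floor(age) and guards its range", {
  lt <- make_life_table()
  expect_equal(background_monthly_prob(lt, 64.9, "M"),
               background_monthly_prob(lt, 64.0, "M"))
  expect_equal(background_monthly_prob(lt, lt$max_age, "F"), 1)
  ages <- 30:100
  qs <- background_monthly_prob(lt, ages, rep("M", length(ages)))
  expect_true(all(diff(qs) >= 0))
  expect_error(background_monthly_prob(lt, lt$max_age + 1, "M"), "range")
  expect_error(background_monthly_prob(lt, -1, "M"), "range")
})

test_that("life-table CSV round-trips and rejects malformed tables", {
  lt <- make_life_table()
  f <- tempfile(fileext = ".csv")
  write_life_table(lt, f)
  lt2 <- read_life_table(f)
  expect_equal(lt2$table, lt$table)
  bad <- lt$table
  bad$male[5] <- 2
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_life_table(f), "outside \\[0,1\\]")
})

test_that("disabling background mortality isolates the printed transition inputs", {
  p <- base_params()
  p_toggle <- p
  p_toggle$options$state_death_includes_background <- TRUE
  a <- run_cohort(p, "tlc_nosf", n = 200, seed = 3, lt = zero_life_table(),
                  horizon = 120)
  b <- run_cohort(p_toggle, "tlc_nosf", n = 200, seed = 3, lt = make_life_table(),
                  horizon = 120)
  expect_identical(a$mean, b$mean)
  expect_identical(a$patients$amputated, b$patients$amputated)
})
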