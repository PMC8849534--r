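test_that("incidence counts onsets up to the query day", {
  expect_equal(incidence(make_result(rep(NA_integer_, 50))), 0)
  expect_equal(incidence(make_result(rep(10L, 50)), day = 199), 1)

  onsets <- rep(NA_integer_, 5000)
  onsets[1:120] <- 30L
  onsets[121:200] <- 150L
  expect_equal(incidence(make_result(onsets), day = 100), 120 / 5000)
  expect_error(incidence(make_result(integer(0))), "empty")
  # non-decreasing in day
  r <- make_result(onsets)
  inc <- vapply(c(0, 50, 100, 150, 199), incidence, numeric(1), result = r)
  expect_false(is.unsorted(inc))
})

test_that("odds ratio per SD recovers a known logistic coefficient", {
  set.seed(701)
  z <- rnorm(20000)
  y <- runif(20000) < plogis(-1 + 0.7 * z)
  or <- or_per_sd(z, y)
  expect_lt(abs(or - exp(0.7)) / exp(0.7), 0.10)
  expect_false(attr(or, "capped"))
})

test_that("odds ratio is null when exposure is unrelated to disease", {
  set.seed(702)
  or <- or_per_sd(rnorm(5000), runif(5000) < 0.3)
  expect_gt(or, 0.9); expect_lt(or, 1.1)
})

test_that("separated exposures report the cap and degenerate outcomes are undefined", {
  x <- c(rnorm(200, 0), rnorm(200, 10))
  y <- rep(c(FALSE, TRUE), each = 200)
  or <- or_per_sd(x, y)
  expect_equal(as.numeric(or), 100)
  expect_true(attr(or, "capped"))

  expect_error(or_per_sd(rep(1, 100), rep(c(TRUE, FALSE), 50)), "variance")
  expect_true(is.na(or_per_sd(rnorm(100), rep(TRUE, 100))))
  nd <- or_per_sd(rnorm(100), rep(FALSE, 100))
  expect_true(is.na(nd))
  expect_match(attr(nd, "reason"), "variation")
})

test_that("odds_ratio_per_sd reads exposure and outcome from a population result", {
  onsets <- c(rep(5L, 40), rep(NA_integer_, 60))
  expos <- c(rnorm(40, 30, 2), rnorm(60, 10, 2))
  r <- make_result(onsets, exposure = expos)
  expect_equal(as.numeric(odds_ratio_per_sd(r)), 100)  # separated
  expect_true(is.na(odds_ratio_per_sd(r, day = 1)))    # nobody diseased yet
})

test_that("relative risk is a ratio of incidences with an undefined benchmark flagged", {
  a <- make_result(c(rep(10L, 20), rep(NA_integer_, 80)))
  b <- make_result(c(rep(10L, 10), rep(NA_integer_, 90)))
  expect_equal(relative_risk(a, b, day = 100), 2)
  expect_equal(relative_risk(a, a, day = 100), 1)
  none <- make_result(rep(NA_integer_, 100))
  expect_true(is.na(relative_risk(a, none, day = 100)))
})

test_that("the sweep grid enumerates 27 combinations exactly once", {
  g <- sweep_grid()
  expect_equal(nrow(g), 27)
  expect_equal(nrow(unique(g)), 27)
  expect_error(sweep_grid(rho_r = c(0.3, 0.3, 0.6)))
})

test_that("a single-cell sweep reduces to one simulate-and-OR run", {
  g1 <- sweep_grid(rho_r = 0.6, eps_l = 20, eps_d = 400)
  expect_equal(nrow(g1), 1)
  sw <- run_sweep(g1, table3_scenario(), n_people = 120, days = 40,
                  checkpoint_days = 40, seed = 703)
  expect_equal(nrow(sw), 1)

  pop <- build_population(120, table3_scenario(), seed = 703)
  res <- simulate_population(pop, standard_week(), dynamics_params(),
                             days = 40, seed = 704)
  or <- odds_ratio_per_sd(res, day = 40)
  expect_equal(sw$odds_ratio, as.numeric(or), tolerance = 1e-12)
  expect_equal(sw$n_diseased, sum(!is.na(res$people$onset_day)))
})

test_that("workweek comparison is exactly 1 against itself under common random numbers", {
  cfgs <- workweek_presets(40)[c("#1", "#2")]
  cfgs[["#2"]] <- cfgs[["#1"]]   # same configuration twice
  tab <- compare_workweeks(40, n_people = 60, days = 30, seed = 705,
                           configs = cfgs)
  expect_equal(tab$rr_vs_benchmark[tab$config_name == "#2"], 1)
  expect_equal(nrow(tab), 2)
})
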