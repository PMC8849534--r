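test_that("Euler cortisol integration matches a hand-unrolled recurrence", {
  # fixture impulse raster, 10 steps, checked step by step to 1e-12
  u <- c(0, 1, 0, 2, 0, 0, 3, 0, 0, 0)
  params <- dynamics_params(kappa_hpa = 2.2, tau = 0.5, dt = 0.5)
  C <- integrate_cortisol(u, rho_c = 0.52, params)

  expected <- numeric(10)
  for (k in 1:9) {
    lagged <- if (k - 1 >= 1) u[k - 1] else 0
    expected[k + 1] <- expected[k] +
      0.5 * (-0.52 * expected[k] + 2.2 * lagged)
  }
  expect_equal(C, expected, tolerance = 1e-12)
})

test_that("a single unit impulse produces the worked step values", {
  u <- rep(0, 12); u[5] <- 1   # impulse in step 5 (0-based step 4)
  C <- integrate_cortisol(u, 0.52, dynamics_params())
  expect_equal(C[1:6], rep(0, 6))          # zero through the step after onset
  expect_equal(C[7], 1.1)                  # dt * kappa = 0.5 * 2.2
  expect_equal(C[8], 1.1 * 0.74)           # one Euler decay factor
  expect_true(all(integrate_cortisol(rep(0, 20), 0.52, dynamics_params()) == 0))
})

test_that("exact decay mode preserves the analytic cortisol half-life", {
  u <- rep(0, 400); u[5] <- 1
  params <- dynamics_params(decay_mode = "exact")
  C <- integrate_cortisol(u, 0.52, params)
  # after forcing ends the series is a pure exponential: per-step ratio
  expect_equal(C[20] / C[19], exp(-0.52 * 0.5), tolerance = 1e-12)
  # time to halve from any post-forcing level
  hl_min <- 60 * log(2) / 0.52
  expect_gt(hl_min, 60); expect_lt(hl_min, 90)
  k0 <- 10
  expect_equal(C[k0] * 0.5,
               C[k0] * exp(-0.52 * hl_min / 60), tolerance = 1e-12)

  expect_error(integrate_cortisol(u, 2.5, dynamics_params(dt = 0.5)),
               "unstable")
})

test_that("strain relaxes to the fixed point c/rho_R and is linear in cortisol", {
  expect_true(all(integrate_strain(rep(0, 50), 0.6) == 0))

  S <- integrate_strain(rep(3, 4000), rho_r = 0.6, dt = 0.5)
  expect_equal(S[4000], 3 / 0.6, tolerance = 1e-9)

  set.seed(401)
  C <- rexp(200)
  expect_equal(integrate_strain(2 * C, 0.6), 2 * integrate_strain(C, 0.6),
               tolerance = 1e-12)
  expect_error(integrate_strain(C, rho_r = 3, dt = 0.5), "unstable")
})

test_that("load accrues only from strict strain excess", {
  expect_true(all(accumulate_load(rep(19.9, 100), eps_l = 20) == 0))

  # S = eps_L + 10 held for 2 h: rectangle integral adds 20
  S <- rep(30, 5)   # 4 intervals of 0.5 h
  L <- accumulate_load(S, eps_l = 20, dt = 0.5)
  expect_equal(L[5], 20)
  expect_false(is.unsorted(L))

  # exactly at the threshold: zero increment
  expect_true(all(accumulate_load(rep(20, 10), eps_l = 20) == 0))
})

test_that("disease state is inclusive at the threshold and monotone", {
  expect_false(any(disease_state(rep(0, 10), 400)))

  L <- c(0, 100, 399.999, 400, 450)
  D <- disease_state(L, 400)
  expect_equal(as.logical(D), c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(attr(D, "onset_index"), 4L)

  set.seed(402)
  Lr <- cumsum(runif(100))
  Dr <- as.logical(disease_state(Lr, 20))
  expect_false(is.unsorted(Dr))   # FALSE -> TRUE at most once
})

test_that("scaling kappa_HPA scales cortisol and strain pointwise", {
  set.seed(403)
  tr <- build_train(make_person(), standard_week(), days = 3)
  g <- rasterize(tr, horizon = 72)
  C1 <- integrate_cortisol(g, 0.52, dynamics_params(kappa_hpa = 2.2))
  C3 <- integrate_cortisol(g, 0.52, dynamics_params(kappa_hpa = 6.6))
  expect_equal(C3, 3 * C1, tolerance = 1e-12)
  expect_equal(integrate_strain(C3, 0.6), 3 * integrate_strain(C1, 0.6),
               tolerance = 1e-12)
})

test_that("simulated trajectories satisfy the model invariants", {
  pop <- build_population(8, table3_scenario(), seed = 404)
  for (i in seq_len(nrow(pop))) {
    set.seed(500 + i)
    tr <- build_train(pop[i, ], standard_week(), days = 14)
    tc <- simulate_person(pop[i, ], tr, dynamics_params(), horizon = 14 * 24)
    expect_true(all(tc$cortisol >= 0))
    expect_true(all(tc$strain >= 0))
    expect_false(is.unsorted(tc$load))
    expect_false(is.unsorted(tc$diseased))
    expect_equal(nrow(tc), 14 * 48)
    expect_equal(tc$t[1], 0)
  }
})

test_that("simulate_person is deterministic and zero without impulses", {
  p <- make_person(lambda_work = 0, lambda_night = 1e-9)
  empty <- data.frame(onset = numeric(0), kind = character(0))
  tc <- simulate_person(p, empty, dynamics_params(), horizon = 48)
  expect_true(all(tc$cortisol == 0) && all(tc$load == 0))
  expect_true(is.na(attr(tc, "onset_day")))

  pop <- build_population(2, table3_scenario(), seed = 405)
  run <- function() {
    set.seed(406)
    tr <- build_train(pop[1, ], standard_week(), days = 10)
    simulate_person(pop[1, ], tr, dynamics_params(), horizon = 240)
  }
  expect_identical(run(), run())
})

test_that("population simulation summarizes exposure and onsets reproducibly", {
  pop <- build_population(60, table3_scenario(), seed = 407)
  res1 <- simulate_population(pop, standard_week(), dynamics_params(),
                              days = 60, seed = 408)
  res2 <- simulate_population(pop, standard_week(), dynamics_params(),
                              days = 60, seed = 408)
  expect_identical(res1$people, res2$people)
  expect_true(all(res1$people$final_load >= 0))
  ok <- !is.na(res1$people$onset_day)
  expect_true(all(res1$people$onset_day[ok] <= 59))
  # more work stressors, more load (correlated scenario)
  expect_gt(cor(res1$people$lambda_work, res1$people$final_load,
                method = "spearman"), 0)
  # realized exposure tracks the latent rate
  expect_gt(cor(res1$people$lambda_work, res1$people$mean_work_impulses), 0.9)
})
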