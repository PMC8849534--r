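test_that("AUC with respect to ground matches closed-form areas", {
  t16 <- seq(0, 16, by = 0.5)
  expect_equal(auc_g(rep(3, length(t16)), t16), 48)          # rectangle
  expect_equal(auc_g(10 * t16 / 16, t16), 80)                # triangle
  expect_error(auc_g(5, 0), "length")
  expect_error(auc_g(c(1, 2), c(1, 1)))
})

test_that("AUC with respect to increase subtracts the waking rectangle", {
  t16 <- seq(0, 16, by = 0.5)
  expect_equal(auc_i(rep(7, length(t16)), t16), 0)
  expect_equal(auc_i(10 * (1 - t16 / 16), t16), 80 - 160)    # may be negative

  set.seed(601)
  y <- rexp(33)
  expect_equal(auc_i(y, t16), auc_g(y, t16) - y[1] * 16)     # identity
  expect_lte(auc_i(y, t16), auc_g(y, t16))
})

test_that("wake-to-bed slope uses the endpoint samples", {
  t16 <- seq(0, 16, by = 0.5)
  expect_equal(wake_bed_slope(rep(4, 33), t16, wake_t = 0), 0)
  expect_equal(wake_bed_slope(seq(16, 0, length.out = 33), t16, wake_t = 0), -1)
  expect_error(wake_bed_slope(1:5, 1:5, wake_t = 4, bed_t = 3), "after")
  # regression mode agrees on an exactly linear curve
  expect_equal(wake_bed_slope(2 - 0.5 * t16, t16, 0, method = "regression"),
               -0.5, tolerance = 1e-9)
})

test_that("day curves aggregate persons and reduce to a single person's curve", {
  pop <- build_population(1, table3_scenario(), seed = 602)
  res <- simulate_population(pop, standard_week(), dynamics_params(),
                             days = 2, seed = 603, keep_cortisol = TRUE)
  dc <- day_curve(res)
  expect_equal(dc$t_since_wake, seq(0, 16, by = 0.5))
  sel <- res$t >= 7 & res$t <= 23
  expect_equal(dc$mean, res$cortisol[sel, 1])

  res0 <- simulate_population(pop, standard_week(), dynamics_params(),
                              days = 2, seed = 603)
  expect_error(day_curve(res0), "keep_cortisol")
  expect_error(day_curve(res, day = 5))
})

test_that("group day curves are stable across independent seeds", {
  pop1 <- build_population(400, scenario_spec("I"), seed = 604)
  pop2 <- build_population(400, scenario_spec("I"), seed = 605)
  m1 <- day_curve(simulate_population(pop1, standard_week(), dynamics_params(),
                                      days = 1, seed = 606,
                                      keep_cortisol = TRUE))
  m2 <- day_curve(simulate_population(pop2, standard_week(), dynamics_params(),
                                      days = 1, seed = 607,
                                      keep_cortisol = TRUE))
  z <- (m1$mean - m2$mean) / sqrt(m1$se^2 + m2$se^2)
  expect_lt(max(abs(z)), 4)
})

test_that("diurnal indices carry the definitional identity and a declining profile", {
  pop <- build_population(150, scenario_spec("I"), seed = 608)
  res <- simulate_population(pop, standard_week(), dynamics_params(),
                             days = 1, seed = 609, keep_cortisol = TRUE)
  idx <- diurnal_indices(res)
  expect_equal(nrow(idx), 150)
  expect_equal(idx$auc_i, idx$auc_g - res$cortisol[res$t == 7, ] * 16,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(idx$auc_i <= idx$auc_g))
  expect_lt(mean(idx$slope), 0)   # cortisol declines from wake to bed
})

test_that("morning load fraction isolates the post-wake window", {
  # synthetic time course: load rises 10 within [7,9) and 5 elsewhere
  t <- seq(0, 47.5, by = 0.5)
  dL <- numeric(length(t)); tod <- t %% 24
  dL[tod >= 7 & tod < 9] <- 10 / sum(tod >= 7 & tod < 9)
  dL[tod >= 12 & tod < 14] <- 5 / sum(tod >= 12 & tod < 14)
  tc <- data.frame(t = t, load = cumsum(c(0, dL[-length(dL)])))
  expect_equal(morning_load_fraction(tc), 10 / 15, tolerance = 1e-9)
  expect_true(is.na(morning_load_fraction(data.frame(t = t, load = 0 * t))))
})
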