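test_that("daily counts are Poisson with the requested mean and variance", {
  expect_equal(daily_count(0), 0L)
  expect_error(daily_count(-1))

  set.seed(301)
  x <- daily_count(rep(42, 10000))
  expect_lt(abs(mean(x) - 42), 0.2)   # ~3 SE
  expect_lt(abs(var(x) - 42), 2)
})

test_that("night impulses cluster exponentially before waking", {
  expect_length(draw_night_times(0, 7), 0)
  set.seed(302)
  on <- draw_night_times(10000, 7)
  expect_true(all(on < 7))
  expect_lt(abs(mean(7 - on) - 1), 0.03)   # Exp(1) mean offset
})

test_that("work impulses are uniform over the work window", {
  expect_length(draw_work_times(0, c(8.5, 16.5)), 0)
  expect_error(draw_work_times(3, NULL), "window")
  set.seed(303)
  on <- draw_work_times(10000, c(8.5, 16.5))
  expect_true(all(on >= 8.5 & on < 16.5))
  expect_lt(abs(mean(on) - 12.5), 5 / 60)
})

test_that("impulse trains respect the workweek and the person's rates", {
  quiet <- make_person(lambda_work = 0)
  set.seed(304)
  tr0 <- build_train(quiet, standard_week(), days = 14)
  expect_true(all(tr0$kind == "night"))

  set.seed(305)
  tr <- build_train(make_person(), standard_week(), days = 200)
  expect_false(is.unsorted(tr$onset))
  # weekends are free of work impulses
  work <- tr[tr$kind == "work", ]
  weekday <- floor(work$onset / 24) %% 7
  expect_true(all(weekday <= 4))
  # work impulses only inside the 08:30-16:30 window
  tod <- work$onset %% 24
  expect_true(all(tod >= 8.5 & tod < 16.5))
  # night onsets precede that day's wake time (offsets can reach back
  # across midnight, so compare against the wake they were drawn for)
  night <- tr[tr$kind == "night", ]
  wake_for <- 24 * round((night$onset - 7) / 24) + 7
  expect_true(all(night$onset < wake_for + 1e-9))
  # Poisson totals: 200 days at lambda_N = 42
  expect_lt(abs(nrow(night) - 8400), 3 * sqrt(8400))
})

test_that("night realizations are common random numbers across configurations", {
  p <- make_person(lambda_work = 30, lambda_night = 38, anticipation = 0)
  cfgs <- workweek_presets(40)
  set.seed(306); a <- build_train(p, cfgs[["#1"]], days = 28)
  set.seed(306); b <- build_train(p, cfgs[["#2"]], days = 28)
  expect_identical(a$onset[a$kind == "night"], b$onset[b$kind == "night"])
})

test_that("expected weekly work impulses are invariant across equal-hour configurations", {
  p <- make_person(lambda_work = 16)
  totals <- vapply(workweek_presets(40), function(cfg) {
    set.seed(307)
    sum(build_train(p, cfg, days = 420)$kind == "work")
  }, numeric(1))
  # 60 weeks at 16 impulses per 8-h day, 40 h/week: expect 4800 +- 4 SD
  expect_true(all(abs(totals - 4800) < 4 * sqrt(4800)))
})

test_that("anticipation couples the night rate to the configured day length", {
  p <- make_person(lambda_work = 40, lambda_night = 48, anticipation = 40)
  compressed <- workweek_config("#4", c(0, 1, 3), hours_per_day = 40 / 3)
  set.seed(308)
  nights <- vapply(1:200, function(i)
    sum(build_train(p, compressed, days = 7)$kind == "night"), numeric(1))
  # effective nightly rate 48 + 40*(40/24/8 - 1) = 74.67 -> 522.7/week
  expected <- 7 * (48 + 40 * (40 / 3 / 8 - 1))
  expect_lt(abs(mean(nights) - expected), 4 * sqrt(expected / 200))
})

test_that("rasterization conserves impulse counts and snaps onsets to their step", {
  empty <- data.frame(onset = numeric(0), kind = character(0))
  expect_true(all(rasterize(empty, horizon = 24) == 0))

  two <- data.frame(onset = c(10.2, 10.4), kind = "work")
  g <- rasterize(two, dt = 0.5, horizon = 24, preroll = 0)
  expect_equal(as.numeric(g[21]), 2)      # both in step [10, 10.5)
  expect_equal(sum(g), 2)

  one <- data.frame(onset = 10.2, kind = "work")
  g1 <- rasterize(one, dt = 0.5, horizon = 24, preroll = 0)
  expect_equal(which(g1 == 1), 21L)       # 0-based step floor(10.2/0.5) = 20
  expect_equal(sum(g1), 1)

  # out-of-horizon onsets are dropped with a warning, conservation holds
  stray <- data.frame(onset = c(-30, 5, 200), kind = "night")
  expect_warning(g2 <- rasterize(stray, dt = 0.5, horizon = 24), "dropped")
  expect_equal(sum(g2), 1)

  set.seed(309)
  tr <- build_train(make_person(), standard_week(), days = 7)
  g3 <- rasterize(tr, dt = 0.5, horizon = 7 * 24)
  expect_equal(sum(g3), sum(tr$onset >= -24 & tr$onset < 7 * 24))
  expect_equal(attr(g3, "t")[1], -24)
})
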