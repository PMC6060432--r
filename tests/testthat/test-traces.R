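bl <- c(0, 10) # baseline window used throughout: first 10 minutes

test_that("linear baseline drift is removed while the level is preserved", {
  t_min <- (0:120) * 0.25
  r0 <- 1.5
  s <- 0.01
  pure_drift <- make_trace(r0 + s * t_min)
  out <- correct_drift(pure_drift, bl)
  expect_equal(out$R, rep(r0 + s * 5, 121), tolerance = 1e-12) # baseline mean kept

  flat <- make_trace(rep(r0, 121))
  expect_equal(correct_drift(flat, bl)$R, flat$R, tolerance = 1e-12)

  # drift plus a post-event step: the step must survive untouched
  h <- 0.2
  stepped <- make_trace(r0 + s * t_min + h * (t_min > 10))
  corr <- correct_drift(stepped, bl)
  level <- mean(corr$R[t_min <= 10])
  expect_lt(abs(diff(range(corr$R[t_min <= 10]))), 1e-9)
  expect_equal(corr$R[t_min > 10] - level, rep(h, sum(t_min > 10)),
    tolerance = 1e-9
  )

  expect_error(correct_drift(flat, c(40, 50)), "outside")
  expect_error(correct_drift(make_trace(rep(1, 4), dt_min = 0.5), c(0, 1)), "5 baseline")
})

test_that("relative ratio is the percent change from the baseline mean", {
  t_min <- (0:80) * 0.25
  r0 <- 1.25
  tr <- make_trace(ifelse(t_min <= 10, r0, 1.1 * r0))
  rel <- relative_ratio(tr, bl)
  expect_equal(rel$value[t_min > 10], rep(10, sum(t_min > 10)), tolerance = 1e-9)

  const <- make_trace(rep(2, 50))
  expect_equal(relative_ratio(const, c(0, 5))$value, rep(0, 50))

  # normalization identity: baseline mean of the output is 0 for any input
  set.seed(11)
  noisy <- make_trace(1.5 + cumsum(rnorm(100, sd = 0.01)))
  out <- relative_ratio(noisy, bl)
  expect_equal(mean(out$value[noisy$time_min <= 10]), 0, tolerance = 1e-9)

  expect_error(relative_ratio(make_trace(rep(-1, 50)), bl), "R0 must be > 0")
})

test_that("the five-point median filter kills single-frame spikes", {
  const <- make_rel_trace(rep(3, 20))
  expect_equal(median_filter5(const)$value, const$value)

  spiked <- make_rel_trace(c(rep(0, 9), 1e6, rep(0, 10)))
  expect_equal(median_filter5(spiked)$value, rep(0, 20))

  # edge behaviour against a brute-force shrinking-window median
  x <- c(0, 0, 10, 0, 0, 0)
  brute <- vapply(seq_along(x), function(i) {
    half <- min(2, i - 1, length(x) - i)
    median(x[(i - half):(i + half)])
  }, numeric(1))
  expect_equal(median_filter5(make_rel_trace(x))$value, brute)

  # a spike at every interior position is removed
  for (pos in 2:19) {
    z <- rep(1, 20)
    z[pos] <- -500
    expect_equal(median_filter5(make_rel_trace(z))$value, rep(1, 20),
      info = paste("spike at", pos)
    )
  }
})

test_that("filtering preserves the baseline mean of a constant baseline", {
  tr <- make_rel_trace(c(rep(0, 30), seq(0, 5, length.out = 20)))
  out <- median_filter5(tr)
  expect_equal(mean(out$value[1:30]), 0)
})

test_that("timepoint values use the nearest sample with earlier-wins ties", {
  const <- make_rel_trace(rep(7, 80))
  expect_equal(timepoint_value(const, 5, event_time = 10)$value, 7)

  # samples every 0.25 min; a target at +0.125 sits exactly between two
  ramp <- make_rel_trace(seq_along(1:60)) # value = sample index
  got <- timepoint_value(ramp, 0.125, event_time = 1)
  lo <- ramp$value[ramp$time_min == 1]
  hi <- ramp$value[ramp$time_min == 1.25]
  expect_equal(got$value, lo)
  expect_false(got$value == hi)

  # linear 1 %/min ramp read 10 min after the event
  t_min <- (0:200) * 0.25
  lin <- tibble::tibble(cell_id = "c1", time_min = t_min, value = t_min - 10)
  expect_equal(timepoint_value(lin, 10, event_time = 10)$value, 10,
    tolerance = 0.25 / 2 # at worst half a sample interval off
  )
  expect_error(timepoint_value(lin, 100, event_time = 10), "outside")
})

test_that("slope estimation is OLS on the unfiltered window", {
  t_min <- (0:140) * 0.25
  line <- tibble::tibble(
    cell_id = "c1", time_min = t_min,
    value = ifelse(t_min <= 10, 0, -2 * (t_min - 10))
  )
  est <- estimate_slope(line, c(2, 7), event_time = 10)
  expect_equal(est$slope, -2, tolerance = 1e-12)
  expect_equal(est$n_points, sum(t_min >= 12 & t_min <= 17))

  flat <- make_rel_trace(rep(1, 141))
  expect_equal(estimate_slope(flat, c(2, 7), 10)$slope, 0)

  # seeded noisy line: recovered slope within 3 standard errors of truth
  set.seed(21)
  noisy <- tibble::tibble(
    cell_id = "c1", time_min = 12 + 0:20 * 0.25,
    value = -2 * (0:20 * 0.25) + rnorm(21, sd = 0.3)
  )
  est2 <- estimate_slope(noisy, c(2, 7), event_time = 10)
  se <- est2$rse / sqrt(sum((noisy$time_min - mean(noisy$time_min))^2))
  expect_lt(abs(est2$slope - (-2)), 3 * se)

  expect_error(
    estimate_slope(make_rel_trace(rep(1, 5)), c(2, 7), 10),
    "at least 3"
  )
})

test_that("group summaries compute per-timepoint mean and SEM over cells", {
  t_min <- 0:9
  two <- dplyr::bind_rows(
    tibble::tibble(cell_id = "a", time_min = t_min, value = 0),
    tibble::tibble(cell_id = "b", time_min = t_min, value = 2)
  )
  gs <- group_summary(two)
  expect_equal(gs$mean, rep(1, 10))
  expect_equal(gs$sem, rep(1, 10))
  expect_equal(gs$n, rep(2L, 10))

  same <- dplyr::bind_rows(
    tibble::tibble(cell_id = "a", time_min = t_min, value = 5),
    tibble::tibble(cell_id = "b", time_min = t_min, value = 5)
  )
  expect_equal(group_summary(same)$sem, rep(0, 10))

  bad <- dplyr::bind_rows(
    tibble::tibble(cell_id = "a", time_min = t_min, value = 1),
    tibble::tibble(cell_id = "b", time_min = t_min + 0.5, value = 1)
  )
  expect_error(group_summary(bad), "common time grid")
  expect_error(group_summary(two[two$cell_id == "a", ]), "at least 2")
})

test_that("missing samples are dropped from summaries, never interpolated", {
  t_min <- 0:9
  tr <- dplyr::bind_rows(
    tibble::tibble(cell_id = "a", time_min = t_min, value = c(NA, rep(1, 9))),
    tibble::tibble(cell_id = "b", time_min = t_min, value = 3)
  )
  gs <- group_summary(tr)
  expect_equal(gs$n[1], 1L)
  expect_equal(gs$mean[1], 3)
  expect_equal(gs$n[2], 2L)
})

test_that("drift-correct then normalize reproduces the analytic composite", {
  # analytic composite: R = R0 + s t + h 1(t > ev). The pipeline order
  # drift-correct -> relative-ratio gives exactly 100 h / mean(baseline R)
  # after the event with a perfectly flat baseline; normalizing without
  # correcting leaves the drift slope in percent units.
  t_min <- (0:160) * 0.25
  r0 <- 1.4
  s <- 0.006
  h <- 0.21
  ev <- 10
  tr <- make_trace(r0 + s * t_min + h * (t_min > ev))
  base_mean <- r0 + s * 5 # drift correction preserves the baseline mean

  correct_then_rel <- relative_ratio(correct_drift(tr, bl), bl)
  expected <- 100 * h / base_mean
  post <- correct_then_rel$value[t_min > ev]
  expect_equal(post, rep(expected, length(post)), tolerance = 1e-9)
  pre <- correct_then_rel$value[t_min <= ev]
  expect_lt(diff(range(pre)), 1e-9)

  uncorrected <- relative_ratio(tr, bl)
  expect_gt(diff(range(uncorrected$value[t_min > ev])), 1) # slope survives
})
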