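# In-vivo speed estimators: worked arithmetic, units, and recovery of a
# configured engine speed.

test_that("endpoint, increment, gap-closure and spiral estimates match the
          in-vivo arithmetic", {
  # condensin II: 400 kb loops after 5 minutes of extrusion
  expect_equal(speed_endpoint(400, 5)$value_kb_s, 400 / 300,
               tolerance = 1e-12)
  # 200-300 kb after 2.5 min spans 1.3-2 kb/s
  expect_equal(speed_endpoint(200, 2.5)$value_kb_s, 4 / 3, tolerance = 1e-3)
  expect_equal(speed_endpoint(300, 2.5)$value_kb_s, 2, tolerance = 1e-12)
  expect_equal(speed_endpoint(0, 5)$value_kb_s, 0)

  # loop-size increment 200 -> 400 kb between t = 2.5 and 5 min
  ts <- time_series(c(2.5, 5), c(200, 400))
  expect_equal(speed_increment(ts)$value_kb_s, 200 / 150, tolerance = 1e-12)
  expect_equal(speed_increment(time_series(c(2.5, 5), c(300, 400)))$value_kb_s,
               100 / 150, tolerance = 1e-12)
  expect_equal(speed_increment(time_series(c(0, 10), c(250, 250)))$value_kb_s,
               0)

  # gap closure: 400 kb x (4-5) / 600 s
  expect_equal(speed_gap_closure(400, 600, 4)$value_kb_s, 400 * 4 / 600,
               tolerance = 1e-12)
  expect_equal(speed_gap_closure(400, 600, 5)$value_kb_s, 10 / 3,
               tolerance = 1e-3)
  expect_equal(speed_gap_closure(400, 300, 1)$value_kb_s,
               speed_endpoint(400, 5)$value_kb_s)

  # spiral period growth: 4.0 -> 6.1 Mb in 15 min; 6.6 -> 16.4 Mb in 15 min
  expect_equal(
    spiral_growth_rate(time_series(c(15, 30), c(4.0, 6.1),
                                   "period_mb"))$value_kb_s,
    2100 / 900, tolerance = 1e-12)
  expect_equal(
    spiral_growth_rate(time_series(c(15, 30), c(6.6, 16.4),
                                   "period_mb"))$value_kb_s,
    9800 / 900, tolerance = 1e-12)
  expect_equal(
    spiral_growth_rate(time_series(c(0, 5), c(3, 3),
                                   "period_mb"))$value_kb_s, 0)
})

test_that("projected-area fold converts to volume fold isotropically", {
  expect_equal(volume_fold_from_area_fold(2), 2^1.5, tolerance = 1e-12)
  expect_equal(volume_fold_from_area_fold(1), 1)
  expect_equal(volume_fold_from_area_fold(4), 8)
  expect_error(volume_fold_from_area_fold(0.5))
})

test_that("estimator edge cases and unit handling are sound", {
  expect_error(speed_endpoint(400, 0), "positive")
  expect_equal(speed_endpoint(300, elapsed_s = 150)$value_kb_s, 2)
  expect_equal(speed_endpoint(400, 7, t0_offset_min = 2)$value_kb_s,
               400 / 300)
  expect_warning(speed_increment(time_series(c(0, 5), c(400, 300))),
                 "non-monotone")
  expect_error(speed_gap_closure(400, 600, 12))
  expect_error(time_series(c(5, 2.5), c(1, 2)))
})

test_that("increment estimate is a lower bound on concave (saturating)
          loop growth", {
  set.seed(7)
  for (k in 1:20) {
    t <- sort(runif(5, 1, 30))
    v0 <- runif(1, 0.5, 3)
    tau <- runif(1, 5, 20)
    loops <- 60 * v0 * tau * (1 - exp(-t / tau))  # saturating growth
    ser <- time_series(t, loops)
    inc <- speed_increment(ser, from = 2, to = length(t))$value_kb_s
    end <- speed_endpoint(loops[length(t)], t[length(t)])$value_kb_s
    expect_lte(inc, end + 1e-9)
  }
})

test_that("gyre-size consistency check compares pairwise ratios", {
  r <- gyre_size_check(edu_mb = 17, model_pitch_mb = 17, hic_period_mb = 17)
  expect_true(all(r$pass))
  r2 <- gyre_size_check(model_pitch_mb = 8, hic_period_mb = 16)
  expect_false(any(r2$pass))
  r3 <- gyre_size_check(edu_um = 0.4, model_pitch_mb = 17,
                        linear_density = 42.5)
  expect_true(all(r3$pass))
  expect_error(gyre_size_check(edu_um = 0.4, model_pitch_mb = 17),
               "incomparable units")
  expect_error(gyre_size_check(edu_mb = 17))
})

test_that("estimators recover the speed configured in the lattice engine", {
  # sparse condensins so loops grow freely: loop growth = complex speed
  st <- lattice_state(2e7)
  set.seed(3)
  st <- mitobrush:::.load_burst(st, "condensin_II", 0.4)
  sp <- species_config("condensin_II", speed = 1.5)
  res <- mitobrush:::.run_engine(st, list(sp), collision_policy(),
                                 n_steps = 150, stats_every = 30L)
  stats <- res$stats
  loop_kb <- stats$mean_loop_sites  # 1 kb sites
  est_end <- speed_endpoint(loop_kb[nrow(stats)],
                            elapsed_s = stats$time[nrow(stats)])$value_kb_s
  ser <- time_series(stats$time / 60, loop_kb)
  est_inc <- speed_increment(ser, from = 1, to = nrow(stats))$value_kb_s
  expect_lt(abs(est_end - 1.5) / 1.5, 0.2)
  expect_lt(abs(est_inc - 1.5) / 1.5, 0.2)
})
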