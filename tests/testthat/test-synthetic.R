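# Seeded generators: statistical structure and determinism.

test_that("G2 fixture places convergent-pair dots, covers all bins with
          labels, and is deterministic given seed", {
  fx <- g2_small()
  expect_gt(nrow(fx$ctcf), 10)
  d <- fx$expected_dots
  expect_true(all(d$pos2 > d$pos1))
  expect_true(all(d$pos2 - d$pos1 <= 1e6))
  # every dot is a +/- convergent pair
  site <- fx$site_bp
  for (k in seq_len(nrow(d))) {
    s1 <- fx$ctcf$strand[fx$ctcf$pos == d$pos1[k] / site]
    s2 <- fx$ctcf$strand[fx$ctcf$pos == d$pos2[k] / site]
    expect_equal(c(s1, s2), c("+", "-"))
  }
  expect_equal(length(fx$ab_labels), 200)
  expect_identical(fx, make_g2_fixture(length_mb = 20, seed = 42))
  expect_warning(make_g2_fixture(length_mb = 5, ctcf_spacing_kb = 500,
                                 cohesin_density = 10, seed = 1),
                 "density high")
})

test_that("cohesin-only extrusion on the fixture makes ~100 kb loops with a
          P(s) shoulder that vanishes without cohesin", {
  st <- g2_small_state()
  ls <- loop_statistics(st)
  expect_gt(ls$mean_loop_kb, 60)
  expect_lt(ls$mean_loop_kb, 180)
  # P(s) of the G2 loop array via the 3D bridge: a shoulder (derivative
  # bump) at the 100 kb loop scale, absent for a loop-free fiber
  loops <- st$extruders[st$extruders$r > st$extruders$l, ]
  loops <- loops[order(loops$l), ]
  # keep outermost loops only (engine loading can nest cohesin loops)
  keep <- rep(TRUE, nrow(loops))
  hi <- -1
  for (i in seq_len(nrow(loops))) {
    if (loops$r[i] <= hi) keep[i] <- FALSE else hi <- loops$r[i]
  }
  loops <- loops[keep, ]
  arr <- data.frame(start = loops$l * st$site_bp,
                    end = loops$r * st$site_bp,
                    species = "cohesin_extrusive")
  length_bp <- st$lattice_length * st$site_bp
  p <- chromatid_params(loop_kb = 100, gap_nm = 40,
                        turn_mb = Inf, volume_density = 44,
                        bead_bp = 5000)
  confs <- lapply(1:8, function(s) build_bottlebrush(arr, p, length_bp,
                                                     seed = s))
  est <- estimate_loop_size(ps_curve(confs, bins_per_decade = 20),
                            s_range = c(2e4, 1e6))
  expect_false(is.na(est))
  # shoulder at the ~100 kb scale (the G2 array is sparser than the dense
  # mitotic arrays the estimator is calibrated on, so the band is wide)
  expect_gt(est, 50)
  expect_lt(est, 300)
  # loop-free control: no shoulder
  bare <- lapply(1:4, function(s) build_bottlebrush(NULL, p, length_bp,
                                                    seed = s))
  est0 <- estimate_loop_size(ps_curve(bare, bins_per_decade = 20),
                             s_range = c(2e4, 1e6))
  expect_true(is.na(est0) || est0 > 400)
})

test_that("zero cohesin density leaves no loops and no anchored dots", {
  fx <- make_g2_fixture(length_mb = 5, cohesin_density = 0, seed = 3)
  st <- g2_equilibrate(fx, seed = 1, burnin_s = 500)
  expect_equal(nrow(st$extruders), 0L)
})

test_that("compartment label blocks have the requested mean length and
          balanced A/B fractions", {
  set.seed(2)
  counts <- replicate(30, {
    labs <- make_compartment_labels(500, 25)
    sum(rle(labs)$lengths > 0)
  })
  # expected block count n/domain = 20, binomial-ish spread
  expect_lt(abs(mean(counts) - 20), 3 * sd(counts) / sqrt(30) + 1)
  labs <- make_compartment_labels(5000, 50, seed = 8)
  expect_lt(abs(mean(labs == "A") - 0.5), 0.1)
  # single-domain edge
  expect_error(make_compartment_labels(10, 20))
})

test_that("cohesive links are Poisson-placed, symmetric and sorted", {
  set.seed(1)
  n <- replicate(40, nrow(make_cohesive_links(50, 2,
                                              seed = sample.int(1e6, 1))))
  expect_lt(abs(mean(n) - 100), 3 * sqrt(100) / sqrt(40) + 1)
  l <- make_cohesive_links(50, 2, seed = 5)
  expect_identical(l$pos_bp1, l$pos_bp2)
  expect_false(is.unsorted(l$pos_bp1))
  expect_true(all(l$pos_bp1 >= 0 & l$pos_bp1 <= 5e7))
  expect_equal(nrow(make_cohesive_links(50, 1e-9, seed = 2)), 0L)
})

test_that("noisy target P(s) has the requested noise level and reduces to
          the clean curve at zero noise", {
  p <- chromatid_params(preset = "condensin_II")
  clean <- simulate_ps(p, replicates = 2, seed0 = 7000, length_mb = 20)
  t0 <- make_target_ps(p, noise_cv = 0, seed = 7, replicates = 2,
                       length_mb = 20)
  expect_equal(t0$p, clean$p, tolerance = 1e-12)
  # realized noise dispersion matches the requested CV
  cv <- 0.2
  ratios <- unlist(lapply(1:6, function(s) {
    tn <- make_target_ps(p, noise_cv = cv, seed = s, replicates = 2,
                         length_mb = 20)
    base <- simulate_ps(p, replicates = 2, seed0 = s * 1000,
                        length_mb = 20)  # same simulation, no noise
    keep <- tn$p > 0 & base$p > 0
    log(tn$p[keep] / base$p[keep])
  }))
  expect_lt(abs(sd(ratios) - sqrt(log(1 + cv^2))), 0.05)
})

test_that("planted maps are symmetric with recorded ground truth", {
  m <- make_planted_map(100, dots = data.frame(bin1 = 20, bin2 = 60),
                        dot_fold = 3, seed = 1)
  expect_equal(m$matrix, t(m$matrix))
  expect_equal(attr(m, "truth")$dot_fold, 3)
  expect_error(make_planted_map(100, dot_fold = 0.5))
})
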