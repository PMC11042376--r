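# Prophase scenarios, loop statistics, gap closure, nested loops.

test_that("loop_statistics handles empty lattices and recovers the
          analytic 1/density loop size at full coverage", {
  st <- lattice_state(1e6)
  ls0 <- loop_statistics(st)
  expect_equal(ls0$coverage_fraction, 0)
  expect_true(is.na(ls0$mean_loop_kb))

  # steady state of 2.5 condensins II per Mb with stalling: consecutive
  # loops, coverage -> 1, mean loop -> 1/density = 400 kb
  set.seed(21)
  st <- lattice_state(4e7)
  st <- mitobrush:::.load_burst(st, "condensin_II", 2.5)
  sp <- species_config("condensin_II", speed = 2)
  st2 <- step_lattice(st, list(sp), collision_policy(), seed = 2,
                      n_steps = 2500)
  ls2 <- loop_statistics(st2)
  expect_gt(ls2$coverage_fraction, 0.97)
  expect_lt(abs(ls2$mean_loop_kb - 400) / 400, 0.15)
  # consecutive non-overlapping loops: covered + gaps = lattice
  lattice_kb <- st2$lattice_length * st2$site_bp / 1000
  expect_equal(ls2$coverage_fraction +
                 sum(ls2$gap_lengths_kb) / lattice_kb, 1,
               tolerance = 0.01)
})

test_that("gap closure requires extruding several loop lengths, matching
          the log(1/(1-c)) theory", {
  gc1 <- gap_closure_experiment(length_mb = 50, density_per_mb = 2.5,
                                speed_kb_s = 1.5, seed = 1,
                                coverage_target = 0.98)
  theory <- log(1 / (1 - 0.98))
  expect_lt(abs(gc1$ratio - theory) / theory, 0.25)
  # lower coverage target needs proportionally less extrusion
  gc2 <- gap_closure_experiment(length_mb = 50, density_per_mb = 2.5,
                                speed_kb_s = 1.5, seed = 1,
                                coverage_target = 0.9)
  expect_lt(gc2$ratio, gc1$ratio)
  expect_lt(abs(gc2$ratio - log(10)) / log(10), 0.3)
})

test_that("anchored cohesins decay exponentially at the background rate in
          a condensin-free control", {
  # no condensin, stabilization off: every bound cohesin unloads at rate k
  fx <- g2_small()
  k <- 2e-3
  st <- g2_equilibrate(fx, seed = 9)
  st$time <- 0L
  coh <- species_config("cohesin_extrusive", speed = 1, loading_rate = 0,
                        unloading_rate = k, ctcf_stabilized = FALSE)
  n0 <- nrow(st$extruders)
  times <- c(300, 600, 1200)
  counts <- sapply(seq_along(times), function(i) {
    set.seed(31)
    res <- mitobrush:::.run_engine(st, list(coh), collision_policy(),
                                   n_steps = times[i])
    nrow(res$state$extruders)
  })
  expected <- n0 * exp(-k * times)
  for (i in seq_along(times)) {
    tol <- 3 * sqrt(expected[i] * (1 - exp(-k * times[i])))
    expect_lt(abs(counts[i] - expected[i]), tol + 3)
  }
})

test_that("cohesin fate in prophase depends on the scenario: unload and
          push clear CTCF anchors much faster than bypass and stall", {
  fx <- g2_small()
  late <- list()
  for (sc in c("unload", "push", "bypass", "stall")) {
    tr <- run_prophase_scenario(sc, fx, duration_s = 900, seed = 7,
                                sample_times_s = c(450, 900),
                                fixture_seed = 9)
    af <- anchored_cohesin_fraction(tr, fx$ctcf)
    late[[sc]] <- af$n_anchored[nrow(af)]
  }
  expect_lt(late$unload, late$bypass)
  expect_lt(late$unload, late$stall)
  expect_lt(late$push, late$bypass)
  expect_lt(late$push, late$stall)
})

test_that("bypass scenario with zero unloading keeps all anchored cohesins
          anchored", {
  fx <- g2_small()
  tr <- run_prophase_scenario("bypass", fx, duration_s = 600, seed = 3,
                              sample_times_s = c(1, 600),
                              cohesin_background_unloading_s = 0,
                              ctcf_loss_s = 0, fixture_seed = 9)
  af <- anchored_cohesin_fraction(tr, fx$ctcf)
  expect_gte(af$n_anchored[2], af$n_anchored[1])
})

test_that("condensin I loops nest inside condensin II loops and shrink the
          combined loop size severalfold", {
  ne <- nested_loop_experiment(phase1_s = 900, phase2_s = 600, seed = 3,
                               length_mb = 30)
  f1 <- ne$frames[[1]]
  f2 <- ne$frames[[2]]
  # before condensin I loads: only large condensin II loops
  expect_true(all(f1$extruders$species == "condensin_II"))
  s1 <- loop_statistics(f1)
  s2 <- loop_statistics(f2)
  expect_gt(s1$mean_loop_kb / s2$mean_loop_kb, 2)
  # condensin I-only loops are ~100 kb scale
  li <- f2$extruders[f2$extruders$species == "condensin_I" &
                       f2$extruders$r > f2$extruders$l, ]
  expect_lt(mean(li$r - li$l), 200)
  # nesting under the stalling rule, scored against a direct
  # interval-containment check
  nf_stall <- nesting_fraction(f2)
  expect_gt(nf_stall, 0.6)
  # independent containment computation
  lo <- f2$extruders[f2$extruders$species == "condensin_II" &
                       f2$extruders$r > f2$extruders$l, ]
  contained <- sapply(seq_len(nrow(li)), function(i) {
    sum(lo$l <= li$l[i] & lo$r >= li$r[i]) > 0
  })
  expect_equal(nf_stall, mean(contained))
})

test_that("allowing condensin I to bypass condensin II reduces nesting", {
  pol_bypass <- collision_policy(
    rules = list("condensin_I|condensin_II" = "bypass",
                 "condensin_II|condensin_I" = "bypass"))
  ne_b <- nested_loop_experiment(phase1_s = 900, phase2_s = 600, seed = 3,
                                 length_mb = 30, policy = pol_bypass)
  ne_s <- nested_loop_experiment(phase1_s = 900, phase2_s = 600, seed = 3,
                                 length_mb = 30)
  nb <- nesting_fraction(ne_b$frames[[2]])
  ns <- nesting_fraction(ne_s$frames[[2]])
  expect_lt(nb, 1)
  expect_lt(nb, ns)
})

test_that("normalized dot strength decays faster along unload/push
          trajectories than bypass/stall (map-level check)", {
  fx <- g2_small()
  st <- g2_small_state()
  g2f <- list(time = 0, extruders = st$extruders, obstacles = st$obstacles,
              ctcf = st$ctcf, site_bp = st$site_bp,
              lattice_length = st$lattice_length)
  ref <- dot_strength(frame_to_contact_map(g2f, bin_bp = 20000),
                      fx$expected_dots, window_bins = 5)$value
  expect_gt(ref, 1.2)  # G2 reference has real dots
  norm_late <- sapply(c("unload", "push", "bypass", "stall"), function(sc) {
    tr <- run_prophase_scenario(sc, fx, duration_s = 900, seed = 7,
                                sample_times_s = 900, fixture_seed = 9)
    m <- frame_to_contact_map(tr$frames[[1]], bin_bp = 20000)
    dot_strength(m, fx$expected_dots, reference = ref,
                 window_bins = 5)$normalized
  })
  expect_lt(max(norm_late["unload"], norm_late["push"]),
            min(norm_late["bypass"], norm_late["stall"]))
})

test_that("condensin-free scenario leaves the G2 dot pattern largely
          intact over prophase", {
  fx <- g2_small()
  tr <- run_prophase_scenario("unload", fx, duration_s = 900, seed = 5,
                              sample_times_s = c(1, 900),
                              condensin = species_config("condensin_II",
                                                         density = 0),
                              fixture_seed = 9)
  af <- anchored_cohesin_fraction(tr, fx$ctcf)
  expect_gt(af$n_anchored[2], 0.5 * af$n_anchored[1])
})
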