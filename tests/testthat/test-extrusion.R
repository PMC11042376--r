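# Lattice engine: single encounters, stepping semantics, invariants.

basic_state <- function(extruders, L = 100, obstacles = NULL, ctcf = NULL) {
  lattice_state(L * 1000, extruders = extruders, obstacles = obstacles,
                ctcf = ctcf)
}

test_that("resolve_encounter implements the four rules of engagement", {
  pol <- collision_policy()
  # condensin leg meets cohesive cohesin -> bypass: condensin advances past,
  # cohesin stays put
  st <- basic_state(data.frame(species = "condensin_II", l = 40L, r = 50L),
                    obstacles = data.frame(species = "cohesin_cohesive",
                                           pos = 51L))
  r <- resolve_encounter(st, 1, +1L, pol)
  expect_equal(r$outcome, "bypass")
  expect_equal(r$state$extruders$r, 52L)
  expect_equal(r$state$obstacles$pos, 51L)

  # condensin meets CTCF-stalled cohesin, unload_obstacle -> cohesin gone,
  # condensin advances
  st <- basic_state(data.frame(species = c("condensin_II",
                                           "cohesin_extrusive"),
                               l = c(40L, 51L), r = c(50L, 60L)))
  r <- resolve_encounter(st, 1, +1L, pol)
  expect_equal(r$outcome, "unload_obstacle")
  expect_equal(nrow(r$state$extruders), 1L)
  expect_equal(r$state$extruders$r, 51L)

  # stall: condensin vs condensin
  st <- basic_state(data.frame(species = c("condensin_II", "condensin_I"),
                               l = c(40L, 51L), r = c(50L, 60L)))
  r <- resolve_encounter(st, 1, +1L, pol)
  expect_equal(r$outcome, "stall")
  expect_true(r$state$extruders$stalled_r[1])
  expect_equal(r$state$extruders$r[1], 50L)

  # push: cohesin displaced one site, chain resolved
  pol_push <- collision_policy(cohesin_fate = "push")
  st <- basic_state(data.frame(species = c("condensin_II",
                                           "cohesin_extrusive"),
                               l = c(40L, 51L), r = c(50L, 60L)))
  r <- resolve_encounter(st, 1, +1L, pol_push)
  expect_equal(r$outcome, "push_obstacle")
  expect_equal(r$state$extruders$l[2], 52L)
  expect_equal(r$state$extruders$r[1], 51L)

  # any leg at the chromosome end -> stall, position unchanged
  st <- basic_state(data.frame(species = "condensin_II", l = 0L, r = 10L))
  r <- resolve_encounter(st, 1, -1L, pol)
  expect_equal(r$outcome, "stall")
  expect_equal(r$state$extruders$l, 0L)

  # push against the chromosome end converts to stall
  st <- basic_state(data.frame(species = c("condensin_II",
                                           "cohesin_extrusive"),
                               l = c(90L, 98L), r = c(97L, 99L)))
  r <- resolve_encounter(st, 1, +1L, pol_push)
  expect_equal(r$outcome, "stall")

  # cohesive cohesin is not pushable by default (it tethers the sister)
  pol_all_push <- collision_policy(
    rules = list("condensin_II|cohesin_cohesive" = "push_obstacle"))
  st <- basic_state(data.frame(species = "condensin_II", l = 40L, r = 50L),
                    obstacles = data.frame(species = "cohesin_cohesive",
                                           pos = 51L))
  r <- resolve_encounter(st, 1, +1L, pol_all_push)
  expect_equal(r$outcome, "stall")
  r2 <- resolve_encounter(st, 1, +1L, pol_all_push, push_cohesive = TRUE)
  expect_equal(r2$outcome, "push_obstacle")
})

test_that("one-step engine moves agree with resolve_encounter on single
          encounters", {
  pol <- collision_policy()
  cases <- list(
    list(fate = NULL, obstacle = "cohesin_cohesive", outcome = "bypass"),
    list(fate = "unload", obstacle = "cohesin_extrusive",
         outcome = "unload_obstacle"),
    list(fate = "stall", obstacle = "cohesin_extrusive", outcome = "stall"),
    list(fate = "push", obstacle = "cohesin_extrusive",
         outcome = "push_obstacle"))
  for (cs in cases) {
    p <- if (is.null(cs$fate)) pol else collision_policy(cohesin_fate =
                                                           cs$fate)
    if (cs$obstacle == "cohesin_cohesive") {
      st <- basic_state(data.frame(species = "condensin_II", l = 40L,
                                   r = 50L),
                        obstacles = data.frame(species = cs$obstacle,
                                               pos = 51L))
    } else {
      st <- basic_state(data.frame(species = c("condensin_II", cs$obstacle),
                                   l = c(40L, 51L), r = c(50L, 60L)))
    }
    # R-level single-encounter resolution
    rr <- resolve_encounter(st, 1, +1L, p)
    # engine: one deterministic step of the condensin only (speed 2 kb/s
    # two-sided -> 1 site per leg per second)
    sp <- species_config("condensin_II", speed = 2)
    eng <- step_lattice(st, list(sp), p, seed = 1, n_steps = 1)
    cond_r <- eng$extruders$r[eng$extruders$species == "condensin_II"]
    rr_cond <- rr$state$extruders$r[
      rr$state$extruders$species == "condensin_II"]
    expect_equal(cond_r, rr_cond, info = cs$outcome)
    if (cs$outcome == "unload_obstacle") {
      expect_false("cohesin_extrusive" %in% eng$extruders$species)
    }
    if (cs$outcome == "push_obstacle") {
      expect_equal(eng$extruders$l[eng$extruders$species ==
                                     "cohesin_extrusive"], 52L)
    }
  }
})

test_that("an undefined species pair is a configuration error", {
  expect_error(collision_policy(rules = list("ctcf_barrier|condensin_I" =
                                               "stall")), "malformed")
  expect_error(collision_policy(rules = list(bad = "stall")), "malformed")
})

test_that("a free two-sided extruder grows its loop by 2 sites per step and
          growth is linear at slope 2 x leg speed", {
  st <- lattice_state(1e6, extruders = data.frame(species = "condensin_II",
                                                  l = 500L, r = 500L))
  sp <- species_config("condensin_II", speed = 2)  # 1 site/s per leg
  for (n in c(10, 50, 100)) {
    st2 <- step_lattice(st, list(sp), collision_policy(), seed = 1,
                        n_steps = n)
    expect_equal(st2$extruders$r - st2$extruders$l, 2L * n)
  }
})

test_that("extruder count is conserved exactly without loading/unloading", {
  set.seed(5)
  st <- lattice_state(2e6)
  st <- mitobrush:::.load_burst(st, "condensin_II", 5)
  n0 <- nrow(st$extruders)
  st2 <- step_lattice(st, list(species_config("condensin_II")),
                      collision_policy(), seed = 2, n_steps = 200)
  expect_equal(nrow(st2$extruders), n0)
})

test_that("leg ordering and bounds hold after every step across random
          configurations (property)", {
  pol <- collision_policy(cohesin_fate = "push")
  for (seed in 1:8) {
    set.seed(seed)
    st <- lattice_state(5e5)
    st <- mitobrush:::.load_burst(st, "condensin_II", 6)
    st <- mitobrush:::.load_burst(st, "cohesin_extrusive", 8)
    sp <- list(species_config("condensin_II", speed = 2),
               species_config("cohesin_extrusive", speed = 1,
                              unloading_rate = 0.005,
                              loading_rate = 2e-5))
    for (chunk in 1:4) {
      st <- step_lattice(st, sp, pol, seed = seed * 100 + chunk,
                        n_steps = 25)
      expect_silent(validate_lattice_state(st))
    }
  }
})

test_that("identical seed and state give identical trajectories", {
  set.seed(11)
  st <- lattice_state(1e6)
  st <- mitobrush:::.load_burst(st, "condensin_II", 4)
  sp <- list(species_config("condensin_II", unloading_rate = 0.002,
                            loading_rate = 1e-5))
  a <- step_lattice(st, sp, collision_policy(), seed = 42, n_steps = 100)
  b <- step_lattice(st, sp, collision_policy(), seed = 42, n_steps = 100)
  expect_identical(a, b)
  c <- step_lattice(st, sp, collision_policy(), seed = 43, n_steps = 100)
  expect_false(identical(a$extruders, c$extruders))
})

test_that("extrusive cohesin anchors at orientation-matched CTCF sites and
          condensins ignore them", {
  # '+' site blocks leftward legs, '-' blocks rightward
  ctcf <- data.frame(pos = c(30L, 70L), strand = c("+", "-"))
  st <- lattice_state(1e5, extruders = data.frame(
    species = "cohesin_extrusive", l = 50L, r = 50L), ctcf = ctcf)
  sp <- species_config("cohesin_extrusive", speed = 2)
  st2 <- step_lattice(st, list(sp), collision_policy(), seed = 1,
                      n_steps = 60)
  expect_equal(st2$extruders$l, 30L)
  expect_equal(st2$extruders$r, 70L)
  # condensin passes straight through
  stc <- lattice_state(1e5, extruders = data.frame(
    species = "condensin_II", l = 50L, r = 50L), ctcf = ctcf)
  st3 <- step_lattice(stc, list(species_config("condensin_II", speed = 2)),
                      collision_policy(), seed = 1, n_steps = 60)
  expect_lt(st3$extruders$l, 30L)
  expect_gt(st3$extruders$r, 70L)
})

test_that("a time step implying per-step move probability above 1 is a
          configuration error naming the remedy", {
  st <- lattice_state(1e5, extruders = data.frame(species = "condensin_II",
                                                  l = 10L, r = 10L))
  expect_error(step_lattice(st, list(species_config("condensin_II",
                                                    speed = 10)),
                            collision_policy(), seed = 1, dt = 1),
               "smaller time step")
})
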