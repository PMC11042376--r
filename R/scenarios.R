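# Prophase collision scenarios, nested loops and gap-closure experiments.

#' Summary statistics of a loop array frame
#'
#' @param frame one frame of a [run_prophase_scenario()] trajectory, or a
#'   [lattice_state()].
#' @return list with `mean_loop_kb`, `median_loop_kb`, `coverage_fraction`
#'   (union of loop intervals over lattice length), `gap_lengths_kb`,
#'   `loops_per_mb`, and `extruded_length_per_extruder_kb` (cumulative sites
#'   translocated per currently bound extruder). An empty lattice yields
#'   coverage 0 and `NA` loop sizes.
#' @export
loop_statistics <- function(frame) {
  if (inherits(frame, "lattice_state")) {
    frame <- list(extruders = frame$extruders, site_bp = frame$site_bp,
                  lattice_length = frame$lattice_length)
  }
  ex <- frame$extruders
  site_kb <- frame$site_bp / 1000
  L <- frame$lattice_length
  loops <- ex[ex$r > ex$l, , drop = FALSE]
  if (!nrow(ex)) {
    return(list(mean_loop_kb = NA_real_, median_loop_kb = NA_real_,
                coverage_fraction = 0, gap_lengths_kb = numeric(0),
                loops_per_mb = 0, extruded_length_per_extruder_kb = NA_real_))
  }
  sizes <- (loops$r - loops$l) * site_kb
  # union of intervals
  cov_sites <- 0L
  gaps <- numeric(0)
  if (nrow(loops)) {
    o <- order(loops$l)
    ll <- loops$l[o]; rr <- loops$r[o]
    cl <- ll[1]; cr <- rr[1]
    last_end <- 0L
    for (i in seq_len(nrow(loops))[-1]) {
      if (ll[i] <= cr) cr <- max(cr, rr[i])
      else {
        cov_sites <- cov_sites + (cr - cl)
        gaps <- c(gaps, ll[i] - cr)
        cl <- ll[i]; cr <- rr[i]
      }
    }
    cov_sites <- cov_sites + (cr - cl)
    gaps <- c(if (ll[1] > 0) ll[1], gaps, if (rr[nrow(loops)] < L - 1)
      L - 1 - rr[nrow(loops)])
  } else {
    gaps <- L
  }
  list(mean_loop_kb = if (nrow(loops)) mean(sizes) else NA_real_,
       median_loop_kb = if (nrow(loops)) median(sizes) else NA_real_,
       coverage_fraction = cov_sites / L,
       gap_lengths_kb = gaps * site_kb,
       loops_per_mb = nrow(loops) / (L * site_kb / 1000),
       extruded_length_per_extruder_kb =
         sum(ex$translocated) * site_kb / nrow(ex))
}

# place a burst of extruders of one species at random free sites
.load_burst <- function(state, species_name, density_per_mb, rng_offset = 0) {
  L <- state$lattice_length
  n <- round(density_per_mb * L * state$site_bp / 1e6)
  if (n <= 0) return(state)
  occupied <- c(state$extruders$l, state$extruders$r, state$obstacles$pos)
  free <- setdiff(seq_len(L) - 1L, occupied)
  pos <- sample(free, min(n, length(free)))
  add <- data.frame(species = species_name, l = pos, r = pos,
                    stalled_l = FALSE, stalled_r = FALSE, translocated = 0)
  state$extruders <- rbind(state$extruders, add)
  state
}

#' Equilibrate a G2-like cohesin/CTCF configuration
#'
#' Runs the engine with extrusive cohesin only (loading, unloading and CTCF
#' stalling active) on a fixture from [make_g2_fixture()], long enough for
#' binding/unbinding to reach steady state. The result is the initial
#' condition for the prophase scenarios: CTCF-anchored cohesin loops
#' producing TADs and dots.
#'
#' @param fixture a [make_g2_fixture()] object.
#' @param seed integer seed.
#' @param burnin_s equilibration time in seconds (default 4000, many
#'   cohesin residence times, long enough for CTCF-stabilized dots to
#'   accumulate at most convergent pairs).
#' @return a [lattice_state()].
#' @export
g2_equilibrate <- function(fixture, seed, burnin_s = 4000) {
  stopifnot(inherits(fixture, "g2_fixture"))
  st <- lattice_state(fixture$length_bp, fixture$site_bp,
                      ctcf = fixture$ctcf)
  set.seed(seed)
  st <- .load_burst(st, "cohesin_extrusive", fixture$cohesin$density)
  res <- .run_engine(st, list(fixture$cohesin), fixture$policy,
                     n_steps = burnin_s)
  res$state
}

#' Simulate one prophase collision scenario
#'
#' Starting from a G2-like configuration of CTCF-anchored extrusive
#' cohesins, condensins load as a burst at t = 0 and the chosen rule of
#' engagement decides the cohesins' fate when condensin runs into them:
#' `"unload"` (cohesin removed), `"push"` (displaced ahead of condensin),
#' `"bypass"` (stepped over) or `"stall"` (both wait). Cohesin does not
#' rebind once lost, a slow background unloading acts in all scenarios, and
#' CTCF sites decay at a configurable background rate.
#'
#' @param scenario one of `"unload"`, `"push"`, `"bypass"`, `"stall"`.
#' @param g2_fixture a [make_g2_fixture()], or a pre-equilibrated
#'   [lattice_state()] carrying cohesins (then `fixture_seed` is unused).
#' @param duration_s simulated prophase duration in seconds.
#' @param seed integer seed.
#' @param sample_times_s times (s) at which frames are recorded.
#' @param condensin a [species_config()] for the loading condensin
#'   (default condensin II at its prometaphase density).
#' @param cohesin_background_unloading_s per-second background unloading
#'   rate of cohesin (condensin-independent pathway).
#' @param ctcf_loss_s per-second background CTCF site loss rate.
#' @param fixture_seed seed for G2 equilibration when a fixture is given.
#' @return a `loop_trajectory`: list of frames (time, loop intervals with
#'   species labels, obstacle and CTCF positions) plus metadata.
#' @export
run_prophase_scenario <- function(scenario = c("unload", "push", "bypass",
                                               "stall"),
                                  g2_fixture, duration_s = 1800, seed = 1,
                                  sample_times_s = seq(0, duration_s,
                                                       by = 150),
                                  condensin = species_config("condensin_II"),
                                  cohesin_background_unloading_s = 2e-4,
                                  ctcf_loss_s = 2e-4,
                                  fixture_seed = seed + 1000) {
  scenario <- match.arg(scenario)
  if (inherits(g2_fixture, "g2_fixture")) {
    st <- g2_equilibrate(g2_fixture, fixture_seed)
    cohesin_speed <- g2_fixture$cohesin$speed
  } else {
    st <- g2_fixture
    cohesin_speed <- 1.0
  }
  st$time <- 0L
  policy <- collision_policy(cohesin_fate = scenario)
  # prophase cohesin: keeps extruding while anchored states allow, but does
  # not reload; background unloading only
  cohesin <- species_config("cohesin_extrusive", speed = cohesin_speed,
                            loading_rate = 0,
                            unloading_rate = cohesin_background_unloading_s)
  ctcf <- species_config("ctcf_barrier", unloading_rate = ctcf_loss_s)
  set.seed(seed)
  if (condensin$density > 0) st <- .load_burst(st, condensin$name,
                                               condensin$density)
  res <- .run_engine(st, list(cohesin, condensin, ctcf), policy,
                     n_steps = duration_s,
                     record_at = unique(pmax(1, round(sample_times_s))),
                     stats_every = max(1, round(duration_s / 200)))
  structure(list(frames = res$frames,
                 times = vapply(res$frames, `[[`, 0, "time"),
                 stats = res$stats, scenario = scenario, seed = seed,
                 site_bp = st$site_bp, lattice_length = st$lattice_length),
            class = "loop_trajectory")
}

#' @export
print.loop_trajectory <- function(x, ...) {
  cat(sprintf("<loop_trajectory> %d frames, t in [%g, %g] s%s\n",
              length(x$frames), min(x$times), max(x$times),
              if (!is.null(x$scenario)) paste0(", scenario=", x$scenario)
              else ""))
  invisible(x)
}

#' Fraction of extrusive cohesins anchored at CTCF sites, per frame
#'
#' @param traj a `loop_trajectory`.
#' @param fixture_ctcf data.frame of the original CTCF sites (anchoring is
#'   scored against the original positions, so pushed-away cohesins count
#'   as de-anchored even if their barrier site later decays).
#' @return data.frame with `time`, `n_cohesin`, `n_anchored`, `fraction`.
#' @export
anchored_cohesin_fraction <- function(traj, fixture_ctcf) {
  out <- lapply(traj$frames, function(f) {
    coh <- f$extruders[f$extruders$species == "cohesin_extrusive", ,
                       drop = FALSE]
    anch <- coh$l %in% fixture_ctcf$pos | coh$r %in% fixture_ctcf$pos
    data.frame(time = f$time, n_cohesin = nrow(coh),
               n_anchored = sum(anch),
               fraction = if (nrow(coh)) mean(anch) else 0)
  })
  do.call(rbind, out)
}

#' Nested-loop experiment: condensin II first, then condensin I
#'
#' Condensin II loads at t = 0 and extrudes to steady state (the prophase
#' mimic); condensin I then loads (the NEB mimic) and subdivides the large
#' loops. With the default stalling rule between condensins, condensin I
#' loops end up nested inside condensin II loops and the combined mean loop
#' size drops roughly by the density ratio.
#'
#' @param phase1_s duration of the condensin II-only phase (s).
#' @param phase2_s duration after condensin I loads (s).
#' @param seed integer seed.
#' @param length_mb lattice length (Mb).
#' @param condensin_II,condensin_I [species_config()]s.
#' @param policy a [collision_policy()]; default has all condensin-condensin
#'   encounters stall.
#' @return `loop_trajectory` with frames at the end of each phase and
#'   `phase_times` metadata.
#' @export
nested_loop_experiment <- function(phase1_s = 900, phase2_s = 600, seed = 1,
                                   length_mb = 40,
                                   condensin_II =
                                     species_config("condensin_II"),
                                   condensin_I =
                                     species_config("condensin_I"),
                                   policy = collision_policy()) {
  st <- lattice_state(length_mb * 1e6)
  set.seed(seed)
  st <- .load_burst(st, "condensin_II", condensin_II$density)
  res1 <- .run_engine(st, list(condensin_II), policy, n_steps = phase1_s,
                      record_at = phase1_s)
  st2 <- res1$state
  st2 <- .load_burst(st2, "condensin_I", condensin_I$density)
  res2 <- .run_engine(st2, list(condensin_II, condensin_I), policy,
                      n_steps = phase2_s, record_at = phase2_s)
  frames <- c(res1$frames, res2$frames)
  structure(list(frames = frames,
                 times = vapply(frames, `[[`, 0, "time"),
                 phase_times = c(phase1_s, phase1_s + phase2_s),
                 seed = seed, site_bp = st$site_bp,
                 lattice_length = st$lattice_length),
            class = "loop_trajectory")
}

#' Fraction of inner-species loops nested inside outer-species loops
#'
#' A condensin I loop is nested when its interval lies inside some condensin
#' II loop interval.
#'
#' @param frame a trajectory frame.
#' @param inner,outer species names.
#' @return fraction in `[0, 1]` (NA if no inner loops).
#' @export
nesting_fraction <- function(frame, inner = "condensin_I",
                             outer = "condensin_II") {
  ex <- frame$extruders
  li <- ex[ex$species == inner & ex$r > ex$l, , drop = FALSE]
  lo <- ex[ex$species == outer & ex$r > ex$l, , drop = FALSE]
  if (!nrow(li)) return(NA_real_)
  if (!nrow(lo)) return(0)
  nested <- vapply(seq_len(nrow(li)), function(i) {
    any(lo$l <= li$l[i] & lo$r >= li$r[i])
  }, logical(1))
  mean(nested)
}

#' Gap-closure experiment: extrusion needed to solidify a loop array
#'
#' A fixed cohort of condensins loads simultaneously on an empty lattice
#' (no exchange) and extrudes with stalling at neighbours. The experiment
#' records when the loop array first covers `coverage_target` of the
#' chromosome and reports the per-condensin extrusion capacity at that time
#' (speed x time, the chromatin one unobstructed complex reels in) as a
#' multiple of the steady-state mean loop size (lattice length / cohort
#' size). For random loading the multiple is close to log(1/(1-c)) at
#' coverage c, which is how extruding ~4-5 loop lengths closes most gaps.
#'
#' @param length_mb lattice length (Mb).
#' @param density_per_mb condensins per Mb.
#' @param speed_kb_s extrusion speed per complex (kb/s).
#' @param seed integer seed.
#' @param coverage_target coverage fraction defining "most gaps closed"
#'   (default 0.98).
#' @param max_s simulation cap in seconds.
#' @return list with `time_s`, `capacity_kb`, `steady_loop_kb`, `ratio`,
#'   and the coverage trace.
#' @export
gap_closure_experiment <- function(length_mb = 50, density_per_mb = 2.5,
                                   speed_kb_s = 1.5, seed = 1,
                                   coverage_target = 0.98, max_s = NULL) {
  st <- lattice_state(length_mb * 1e6)
  sp <- species_config("condensin_II", density = density_per_mb,
                       speed = speed_kb_s)
  set.seed(seed)
  st <- .load_burst(st, "condensin_II", density_per_mb)
  n <- nrow(st$extruders)
  steady_loop_kb <- length_mb * 1000 / n
  if (is.null(max_s)) {
    max_s <- ceiling(12 * steady_loop_kb / speed_kb_s)
  }
  res <- .run_engine(st, list(sp), collision_policy(), n_steps = max_s,
                     stats_every = 1L, coverage_target = coverage_target)
  t_s <- res$coverage_time
  capacity_kb <- speed_kb_s * t_s
  list(time_s = t_s, capacity_kb = capacity_kb,
       steady_loop_kb = steady_loop_kb,
       ratio = capacity_kb / steady_loop_kb,
       n_extruders = n,
       coverage = res$stats[, c("time", "coverage")])
}
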