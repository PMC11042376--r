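# Lattice state container and the engine driver.

#' Construct a 1D lattice state for the extrusion engine
#'
#' The genomic substrate is a 1D lattice of `length_bp / site_bp` sites
#' (default resolution 1 kb/site, which keeps 100 Mb runs tractable while
#' resolving the >= 100 kb loop scales of interest). Extruders occupy one
#' site per leg; cohesive cohesins occupy one site; CTCF barriers annotate
#' sites without occupying them.
#'
#' @param length_bp chromosome length in bp.
#' @param site_bp bp per lattice site (default 1000).
#' @param extruders data.frame with columns `species` (name), `l`, `r`
#'   (0-based site indices, `l <= r`), optional `stalled_l`, `stalled_r`,
#'   `translocated`.
#' @param obstacles data.frame with columns `species`, `pos` (cohesive
#'   cohesins).
#' @param ctcf data.frame with columns `pos` and either `strand`
#'   (`"+"`/`"-"`) or `blocks_dir` (+1 blocks rightward-moving legs, -1
#'   leftward). A `'+'` site is a left loop anchor: it blocks legs moving
#'   left, so convergent `'+'...'-'` pairs trap extrusive cohesin.
#' @param time simulation time already elapsed, seconds.
#' @return object of class `lattice_state`.
#' @examples
#' st <- lattice_state(1e6, extruders = data.frame(
#'   species = "condensin_II", l = 400L, r = 420L))
#' @export
lattice_state <- function(length_bp, site_bp = 1000,
                          extruders = NULL, obstacles = NULL, ctcf = NULL,
                          time = 0L) {
  L <- as.integer(round(length_bp / site_bp))
  stopifnot(L > 1)
  empty_ex <- data.frame(species = character(0), l = integer(0),
                         r = integer(0), stalled_l = logical(0),
                         stalled_r = logical(0), translocated = numeric(0))
  if (is.null(extruders) || !nrow(extruders)) {
    extruders <- empty_ex
  } else {
    extruders <- as.data.frame(extruders)
    if (is.null(extruders$stalled_l)) extruders$stalled_l <- FALSE
    if (is.null(extruders$stalled_r)) extruders$stalled_r <- FALSE
    if (is.null(extruders$translocated)) extruders$translocated <- 0
    extruders <- extruders[, names(empty_ex)]
  }
  if (is.null(obstacles) || !NROW(obstacles)) {
    obstacles <- data.frame(species = character(0), pos = integer(0))
  } else {
    obstacles <- as.data.frame(obstacles)[, c("species", "pos")]
  }
  if (is.null(ctcf) || !NROW(ctcf)) {
    ctcf <- data.frame(pos = integer(0), blocks_dir = integer(0))
  } else {
    ctcf <- as.data.frame(ctcf)
    if (is.null(ctcf$blocks_dir)) {
      stopifnot(!is.null(ctcf$strand))
      ctcf$blocks_dir <- ifelse(ctcf$strand == "+", -1L, 1L)
    }
    ctcf <- ctcf[, c("pos", "blocks_dir")]
  }
  st <- structure(list(lattice_length = L, site_bp = site_bp,
                       extruders = extruders, obstacles = obstacles,
                       ctcf = ctcf, time = as.numeric(time)),
                  class = "lattice_state")
  validate_lattice_state(st)
  st
}

#' Validate lattice-state invariants
#'
#' Checks leg ordering (`l <= r`), position bounds, and single occupancy of
#' every site. Called by the constructor and useful in property tests.
#'
#' @param state a [lattice_state()].
#' @return `state`, invisibly; errors on violation.
#' @export
validate_lattice_state <- function(state) {
  ex <- state$extruders
  L <- state$lattice_length
  if (nrow(ex)) {
    if (any(ex$l > ex$r)) stop("leg ordering violated: l > r")
    if (any(ex$l < 0 | ex$r >= L)) stop("extruder leg out of bounds")
  }
  if (nrow(state$obstacles) &&
      any(state$obstacles$pos < 0 | state$obstacles$pos >= L)) {
    stop("obstacle out of bounds")
  }
  occ <- c(ex$l[ex$l == ex$r], ex$l[ex$l != ex$r], ex$r[ex$l != ex$r],
           state$obstacles$pos)
  if (anyDuplicated(occ)) stop("double site occupancy")
  invisible(state)
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf(paste0("<lattice_state> %d sites x %d bp, %d extruders, ",
                     "%d obstacles, %d CTCF, t=%g s\n"),
              x$lattice_length, x$site_bp, nrow(x$extruders),
              nrow(x$obstacles), nrow(x$ctcf), x$time))
  invisible(x)
}

# Convert species configs to per-step engine probabilities.
# dt is chosen so the fastest leg moves at most ~1 site per step unless the
# caller overrides it; per-step leg probability must stay <= 1.
.engine_config <- function(species, dt = NULL, site_bp = 1000) {
  if (inherits(species, "species_config")) species <- list(species)
  cfg <- list(move_prob = numeric(4), move_sites = integer(4),
              unload_prob = numeric(5), load_prob = numeric(3),
              ctcf_loss_prob = 0)
  site_kb <- site_bp / 1000
  leg_rate <- numeric(4)  # sites per second
  for (s in species) {
    code <- .species_code(s$name)
    if (code <= 4 && s$mobile) {
      per_leg <- s$speed * (if (s$two_sided) 0.5 else 1)
      leg_rate[code] <- per_leg / site_kb
    }
  }
  if (is.null(dt)) {
    mx <- max(leg_rate)
    dt <- if (mx > 0) min(1, 1 / mx) else 1
  }
  for (s in species) {
    code <- .species_code(s$name)
    if (code <= 4) {
      v <- leg_rate[code] * dt
      if (v > 1 + 1e-9) {
        stop("per-step move probability ", signif(v, 3), " exceeds 1 for ",
             s$name, ": use a smaller time step dt")
      }
      cfg$move_sites[code] <- floor(v + 1e-12)
      cfg$move_prob[code] <- v - cfg$move_sites[code]
      u <- s$unloading_rate * dt
      if (u > 1) stop("per-step unloading probability > 1: smaller dt needed")
      cfg$unload_prob[code] <- u
    }
    if (code <= 3) {
      p <- s$loading_rate * dt
      if (p > 1) stop("per-step loading probability > 1: smaller dt needed")
      cfg$load_prob[code] <- p
    }
    if (s$name == "ctcf_barrier") {
      cfg$ctcf_loss_prob <- s$unloading_rate * dt
    }
  }
  cfg$dt <- dt
  cfg
}

# Durations and sampling times are in seconds; they are converted to
# engine steps with the configured dt (dt <= 1 s, smaller only when a leg
# would otherwise move more than one site per step).
.run_engine <- function(state, species, policy, n_steps, dt = NULL,
                        record_at = integer(0), stats_every = 0L,
                        coverage_target = 0, push_cohesive = FALSE) {
  cfg <- .engine_config(species, dt = dt, site_bp = state$site_bp)
  n_steps <- max(1L, as.integer(round(n_steps / cfg$dt)))
  record_at <- unique(pmax(1L, as.integer(round(record_at / cfg$dt))))
  stats_every <- max(0L, as.integer(round(stats_every / cfg$dt)))
  if (inherits(species, "species_config")) species <- list(species)
  protect <- any(vapply(species, function(s) {
    s$name == "cohesin_extrusive" && isTRUE(s$ctcf_stabilized)
  }, logical(1)))
  ex <- state$extruders
  ob <- state$obstacles
  ct <- state$ctcf
  res <- engine_run_cpp(
    L = state$lattice_length,
    ex_species = .species_code(ex$species), ex_l = as.integer(ex$l),
    ex_r = as.integer(ex$r), ex_stall_l = ex$stalled_l,
    ex_stall_r = ex$stalled_r, ex_transloc = ex$translocated,
    ob_species = .species_code(ob$species), ob_pos = as.integer(ob$pos),
    ctcf_pos = as.integer(ct$pos), ctcf_dir = as.integer(ct$blocks_dir),
    policy = matrix(as.integer(unclass(policy)), 4, 5),
    move_prob = cfg$move_prob, move_sites = cfg$move_sites,
    unload_prob = cfg$unload_prob, load_prob = cfg$load_prob,
    ctcf_loss_prob = cfg$ctcf_loss_prob, push_cohesive = push_cohesive,
    protect_anchored = protect,
    n_steps = n_steps, t0 = 0L,
    record_at = as.integer(sort(record_at)),
    stats_every = as.integer(stats_every),
    coverage_target = coverage_target)

  new_state <- state
  new_state$extruders <- data.frame(
    species = .species_name(res$species), l = res$l, r = res$r,
    stalled_l = res$stall_l, stalled_r = res$stall_r,
    translocated = res$translocated)
  new_state$obstacles <- data.frame(
    species = .species_name(res$obstacle_species), pos = res$obstacle_pos)
  new_state$ctcf <- data.frame(pos = res$ctcf_pos,
                               blocks_dir = res$ctcf_dir)
  new_state$time <- state$time + res$time * cfg$dt

  frames <- lapply(res$frames, function(f) {
    list(time = state$time + f$time * cfg$dt,
         extruders = data.frame(
           species = .species_name(f$extruders[, 1]),
           l = f$extruders[, 2], r = f$extruders[, 3],
           stalled_l = f$stalled[, 1], stalled_r = f$stalled[, 2],
           translocated = f$translocated),
         obstacles = data.frame(species = .species_name(f$obstacle_species),
                                pos = f$obstacle_pos),
         ctcf = data.frame(pos = f$ctcf_pos, blocks_dir = f$ctcf_dir),
         site_bp = state$site_bp,
         lattice_length = state$lattice_length)
  })
  stats <- as.data.frame(res$stats)
  if (nrow(stats)) stats$time <- state$time + stats$time * cfg$dt
  list(state = new_state, frames = frames, stats = stats,
       coverage_time = state$time + res$coverage_time * cfg$dt,
       audit = res$audit, dt = cfg$dt)
}

#' Advance the lattice by one (or more) time steps
#'
#' Every mobile leg attempts its per-step moves (in seeded random order,
#' which is how ties for a contested site are broken), each resolved by the
#' collision policy; then stochastic unloading and loading are applied.
#' Identical seed and state give identical results.
#'
#' @param state a [lattice_state()].
#' @param species list of [species_config()] objects.
#' @param policy a [collision_policy()].
#' @param seed integer seed.
#' @param n_steps simulated time in seconds (equal to the number of steps
#'   at the default time step).
#' @param dt seconds per step; default 1 s, shortened automatically so the
#'   fastest leg moves at most one site per step. An explicit `dt` implying
#'   a per-step move probability above 1 is a configuration error.
#' @param push_cohesive allow cohesive cohesin to be pushed.
#' @return the updated `lattice_state`.
#' @export
step_lattice <- function(state, species, policy, seed, n_steps = 1,
                         dt = NULL, push_cohesive = FALSE) {
  set.seed(seed)
  res <- .run_engine(state, species, policy, n_steps, dt = dt,
                     push_cohesive = push_cohesive)
  validate_lattice_state(res$state)
  res$state
}
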