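# Coarse-grained 3D chromatid builders: bottlebrush, helical cylinder,
# periodic random walk, nested loops and cohesed sister pairs.
#
# Construction is direct (anchored random walks / Brownian bridges with
# geometric confinement), not Brownian dynamics; ensembles over seeds stand
# in for time averaging.

#' Parameters of the coarse-grained chromatid model
#'
#' Three free parameters control the models: the average loop size (bp),
#' the spatial gap between adjacent loop anchors along the scaffold (nm)
#' and the linear density of chromatin along the chromatid axis (Mb/um).
#' Two parameters are fixed from experiment: the genomic length of one
#' helical turn (Mb, from the position of the second diagonal in Hi-C) and
#' the chromatin volume density (Mb/um^3, from electron microscopy).
#'
#' Presets: `"condensin_II"` is the best-fit helical-cylinder model of
#' chromatids formed by condensin II alone (400 kb loops, 80 nm gaps,
#' 17 Mb per turn, 400 nm pitch, 44 Mb/um^3); `"condensin_I"` is the
#' best-fit periodic-boundary stretched-random-walk model of condensin
#' I-only chromatids (100 kb loops, 20 nm gaps, 4 um end-to-end per 100 Mb,
#' 77 Mb/um^3, no helix).
#'
#' @param preset `"condensin_II"`, `"condensin_I"` or `NULL`.
#' @param loop_kb average loop size, kb.
#' @param gap_nm gap between adjacent loop anchors, nm.
#' @param linear_density Mb per um of chromatid axis. In periodic mode this
#'   sets the imposed end-to-end distance, `length_mb / linear_density`.
#' @param turn_mb Mb of chromatin per helical turn (helical mode).
#' @param volume_density chromatin density, Mb/um^3 (sanity band 10-200).
#' @param helix_mode `"helical_cylinder"` or `"periodic_random_walk"`.
#' @param bead_bp bp per bead (default 10 kb: a 100 Mb chromatid is 1e4
#'   beads; the P(s) features of interest are at >= 100 kb).
#' @param end_to_end_um explicit end-to-end distance (periodic mode);
#'   overrides `linear_density` at build time if given.
#' @param scaffold_frac scaffold (loop-anchor) radius as a fraction of the
#'   chromatid radius (helical mode).
#' @param angular_jitter_sd irregularity of the helix: stationary sd of the
#'   phase noise, radians.
#' @param axial_jitter_frac stationary sd of the scaffold's axial wander,
#'   as a fraction of the pitch (the helix is disordered: gyres
#'   interdigitate rather than stack as flat rings).
#' @param jitter_corr_mb correlation length of the scaffold wander, Mb
#'   (long relative to a loop, so the wander is smooth at the anchor scale
#'   and the gap size controls the fine-scale scaffold roughness).
#' @param bow_frac how far loop bellies bow outward from the scaffold
#'   towards the cylinder wall, fraction of the available annulus.
#' @return object of class `chromatid_params`.
#' @examples
#' chromatid_params(preset = "condensin_II")
#' @export
chromatid_params <- function(preset = NULL, loop_kb = 400, gap_nm = 80,
                             linear_density = NULL, turn_mb = 17,
                             volume_density = NULL,
                             helix_mode = c("helical_cylinder",
                                            "periodic_random_walk"),
                             bead_bp = 10000, end_to_end_um = NULL,
                             scaffold_frac = 0.45, angular_jitter_sd = 0.3,
                             axial_jitter_frac = 0.75, jitter_corr_mb = 8,
                             bow_frac = 0.6) {
  helix_mode <- match.arg(helix_mode)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("condensin_II", "condensin_I"))
    if (preset == "condensin_II") {
      loop_kb <- 400; gap_nm <- 80; turn_mb <- 17
      if (is.null(volume_density)) volume_density <- 44
      if (is.null(linear_density)) linear_density <- turn_mb / 0.4
      helix_mode <- "helical_cylinder"
    } else {
      loop_kb <- 100; gap_nm <- 20; turn_mb <- Inf
      if (is.null(volume_density)) volume_density <- 77
      if (is.null(linear_density)) linear_density <- 25  # 4 um per 100 Mb
      helix_mode <- "periodic_random_walk"
    }
  }
  if (is.null(volume_density)) volume_density <- 44
  if (is.null(linear_density)) {
    linear_density <- if (is.finite(turn_mb)) turn_mb / 0.4 else 25
  }
  stopifnot(loop_kb > 0, gap_nm > 0, linear_density > 0, turn_mb > 0,
            volume_density > 0, bead_bp > 0)
  if (volume_density < 10 || volume_density > 200) {
    stop("volume_density ", volume_density,
         " Mb/um^3 outside the plausible band [10, 200]")
  }
  pitch_nm <- if (is.finite(turn_mb)) 1000 * turn_mb / linear_density
              else Inf
  structure(list(loop_kb = loop_kb, gap_nm = gap_nm,
                 linear_density = linear_density, turn_mb = turn_mb,
                 volume_density = volume_density, pitch_nm = pitch_nm,
                 helix_mode = helix_mode, bead_bp = bead_bp,
                 end_to_end_um = end_to_end_um,
                 scaffold_frac = scaffold_frac,
                 angular_jitter_sd = angular_jitter_sd,
                 axial_jitter_frac = axial_jitter_frac,
                 jitter_corr_mb = jitter_corr_mb, bow_frac = bow_frac),
            class = "chromatid_params")
}

#' @export
print.chromatid_params <- function(x, ...) {
  cat(sprintf(paste0("<chromatid_params> %s: loops %g kb, gaps %g nm, ",
                     "%g Mb/um axis, %s, %g Mb/um^3\n"),
              x$helix_mode, x$loop_kb, x$gap_nm, x$linear_density,
              if (is.finite(x$turn_mb)) paste0(x$turn_mb, " Mb/turn")
              else "no helix", x$volume_density))
  invisible(x)
}

# derived geometry, all lengths in nm
.geometry <- function(params, length_bp) {
  g_mb <- length_bp / 1e6
  bead_um3 <- (params$bead_bp / 1e6) / params$volume_density
  b_nm <- 1000 * bead_um3^(1 / 3)          # bead step / effective diameter
  l_ax <- 1000 * g_mb / params$linear_density
  r_cyl <- 1000 * sqrt(g_mb / params$volume_density /
                         (pi * l_ax / 1000)) # um -> nm
  box <- 1000 * (g_mb / params$volume_density)^(1 / 3)
  e2e <- if (!is.null(params$end_to_end_um)) 1000 * params$end_to_end_um
         else l_ax
  list(g_mb = g_mb, b_nm = b_nm, l_ax_nm = l_ax, r_cyl_nm = r_cyl,
       box_nm = box, e2e_nm = e2e,
       winding = if (is.finite(params$turn_mb)) g_mb / params$turn_mb
                 else 0)
}

#' Generate a consecutive loop array
#'
#' Partitions a chromosome into consecutive loops with gamma-distributed
#' sizes (shape 4, i.e. coefficient of variation 0.5) around the requested
#' mean, the size heterogeneity a stalling loop array settles into.
#'
#' @param length_bp chromosome length.
#' @param loop_bp mean loop size.
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @param species species label for the anchors.
#' @param shape gamma shape of the size distribution.
#' @return data.frame with `start`, `end` (bp, 0-based half-open),
#'   `species`.
#' @export
make_loop_array <- function(length_bp, loop_bp, seed = NULL,
                            species = "condensin_II", shape = 4) {
  if (!is.null(seed)) set.seed(seed)
  n_guess <- ceiling(1.6 * length_bp / loop_bp) + 8
  sizes <- rgamma(n_guess, shape = shape, scale = loop_bp / shape)
  ends <- cumsum(sizes)
  ends <- ends[ends < length_bp]
  bounds <- c(0, ends, length_bp)
  data.frame(start = bounds[-length(bounds)], end = bounds[-1],
             species = species)
}

# stationary AR(1) noise
.ar1 <- function(n, sd, rho) {
  if (n == 0) return(numeric(0))
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  if (n > 1) {
    innov <- rnorm(n - 1, 0, sd * sqrt(1 - rho^2))
    for (i in 2:n) x[i] <- rho * x[i - 1] + innov[i - 1]
  }
  x
}

# triangle-wave fold of values into [lo, hi] (reflecting boundaries)
.reflect <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

# n interior points of a 3D Brownian bridge from p0 to p1
.bridge3 <- function(n, p0, p1, step_sd) {
  if (n <= 0) return(matrix(numeric(0), 0, 3))
  w <- apply(matrix(rnorm(3 * (n + 1), 0, step_sd), n + 1, 3), 2, cumsum)
  endv <- w[n + 1, ]
  tfrac <- seq_len(n) / (n + 1)
  sweep(w[seq_len(n), , drop = FALSE], 2, p0, "+") -
    tfrac %o% (endv - (p1 - p0))
}

# Scaffold anchor coordinates for all segment boundaries.
# g: boundary genomic positions (bp). Returns matrix (length(g) x 3), nm.
.scaffold_anchors <- function(g, params, geo, mode) {
  n <- length(g)
  g_mb <- g / 1e6
  mean_loop_mb <- mean(diff(g_mb))
  rho <- exp(-mean_loop_mb / params$jitter_corr_mb)
  if (mode == "periodic") {
    # random walk conditioned on the imposed end-to-end vector (along x)
    nper <- params$bead_bp / 1e6 * 0 + mean_loop_mb * 1e3 / params$bead_bp *
      1000 # beads per loop (kb/bead_kb)
    nper <- mean_loop_mb * 1e6 / params$bead_bp
    b_bb <- params$gap_nm + 0.5 * geo$b_nm * sqrt(max(nper, 1))
    steps <- matrix(rnorm(3 * (n - 1), 0, b_bb / sqrt(3)), n - 1, 3)
    w <- rbind(0, apply(steps, 2, cumsum))
    target <- c(geo$e2e_nm, 0, 0)
    tfrac <- (seq_len(n) - 1) / (n - 1)
    return(w + tfrac %o% (target - w[n, ]))
  }
  z_mean <- g_mb / params$linear_density * 1000
  build_smooth <- function(shrink) {
    if (mode == "helical") {
      phase <- 2 * pi * g_mb / params$turn_mb +
        .ar1(n, params$angular_jitter_sd, rho)
      r_s <- shrink * params$scaffold_frac * geo$r_cyl_nm
      rad <- r_s * pmax(0.2, 1 + .ar1(n, 0.15, rho))
      zj <- .ar1(n, shrink * params$axial_jitter_frac * params$pitch_nm,
                 rho)
    } else { # straight cylinder: scaffold hugs the axis
      phase <- runif(1, 0, 2 * pi) + .ar1(n, 1.5, rho)
      rad <- shrink * abs(.ar1(n, 0.1 * geo$r_cyl_nm, rho))
      zj <- .ar1(n, shrink * 0.05 * geo$l_ax_nm, rho)
    }
    # pin the ends to the cylinder caps
    zj <- zj - (1 - (seq_len(n) - 1) / (n - 1)) * zj[1] -
      ((seq_len(n) - 1) / (n - 1)) * zj[n]
    z <- .reflect(z_mean + zj, 0, geo$l_ax_nm)
    cbind(rad * cos(phase), rad * sin(phase), z)
  }
  # The scaffold contour is set by the gap between adjacent loop anchors:
  # a scaffold too short for the smooth helix path pulls taut (the helix
  # radius and axial wander shrink); surplus contour becomes fine-scale
  # roughness on top of the smooth path.
  seed_state <- .Random.seed
  xyz <- build_smooth(1)
  d_smooth <- mean(sqrt(rowSums(diff(xyz)^2)))
  if (params$gap_nm >= d_smooth) {
    delta <- sqrt((params$gap_nm^2 - d_smooth^2) / 6)
    xyz <- xyz + matrix(rnorm(3 * n, 0, delta), n, 3)
  } else {
    dz_mean <- mean(abs(diff(z_mean)))
    lateral2 <- max(d_smooth^2 - dz_mean^2, 1e-12)
    shrink <- sqrt(max(params$gap_nm^2 - dz_mean^2, 0.04 * lateral2) /
                     lateral2)
    .Random.seed <<- seed_state
    xyz <- build_smooth(shrink)
  }
  xyz
}

# Fill bead-level loops/linkers between consecutive anchors.
# segs: data.frame(start, end, is_loop, species); anchors: (nseg+1) x 3.
.fill_beads <- function(segs, anchors, params, geo, mode,
                        fixed = NULL) {
  bead_bp <- params$bead_bp
  idx <- round(c(segs$start, segs$end[nrow(segs)]) / bead_bp)
  rows <- vector("list", nrow(segs))
  for (k in seq_len(nrow(segs))) {
    m <- idx[k + 1] - idx[k] - 1
    p0 <- anchors[k, ]
    p1 <- anchors[k + 1, ]
    fx <- NULL
    if (!is.null(fixed)) {
      inside <- fixed$bead > idx[k] & fixed$bead < idx[k + 1]
      if (any(inside)) fx <- fixed[inside, , drop = FALSE]
    }
    if (is.null(fx) || !nrow(fx)) {
      pts <- .bridge3(m, p0, p1, geo$b_nm / sqrt(3))
    } else {
      # bridge through fixed interior points (cohesive-link beads)
      knots_bead <- c(idx[k], fx$bead, idx[k + 1])
      knots_xyz <- rbind(p0, as.matrix(fx[, c("x", "y", "z")]), p1)
      pts <- matrix(0, m, 3)
      for (q in seq_len(length(knots_bead) - 1)) {
        mm <- knots_bead[q + 1] - knots_bead[q] - 1
        sub <- .bridge3(mm, knots_xyz[q, ], knots_xyz[q + 1, ],
                        geo$b_nm / sqrt(3))
        if (mm > 0) {
          pts[(knots_bead[q] - idx[k]) + seq_len(mm), ] <- sub
        }
        if (q < length(knots_bead) - 1) {
          pts[knots_bead[q + 1] - idx[k], ] <- knots_xyz[q + 1, ]
        }
      }
    }
    if (segs$is_loop[k] && m > 0 && mode != "periodic" &&
        params$bow_frac > 0) {
      # bow the loop belly outward, towards the cylinder wall
      mid <- (p0 + p1) / 2
      rr <- sqrt(sum(mid[1:2]^2))
      u <- if (rr > 1e-6) c(mid[1:2] / rr, 0)
           else { th <- runif(1, 0, 2 * pi); c(cos(th), sin(th), 0) }
      # radial target drawn so loop bellies fill the cylinder cross-section
      amp <- params$bow_frac *
        max(1.5 * geo$r_cyl_nm * sqrt(runif(1)) - rr, 0)
      pts <- pts + (sin(pi * seq_len(m) / (m + 1)) * amp) %o% u
    }
    rows[[k]] <- pts
  }
  beads <- matrix(0, idx[length(idx)] + 1, 3)
  beads[idx + 1, ] <- anchors
  for (k in seq_len(nrow(segs))) {
    m <- idx[k + 1] - idx[k] - 1
    if (m > 0) beads[(idx[k] + 1) + seq_len(m), ] <- rows[[k]]
  }
  if (mode != "periodic") {
    # radial + axial confinement of the cylinder body
    rho <- sqrt(beads[, 1]^2 + beads[, 2]^2)
    rho_f <- .reflect(rho, 0, geo$r_cyl_nm)
    sc <- ifelse(rho > 1e-9, rho_f / rho, 1)
    beads[, 1] <- beads[, 1] * sc
    beads[, 2] <- beads[, 2] * sc
    beads[, 3] <- .reflect(beads[, 3], -2 * geo$b_nm,
                           geo$l_ax_nm + 2 * geo$b_nm)
  }
  anchor_flag <- logical(nrow(beads))
  anchor_flag[idx + 1] <- TRUE
  list(xyz = beads, anchor = anchor_flag, idx = idx)
}

.segments_from_loops <- function(loops, length_bp) {
  loops <- loops[order(loops$start), , drop = FALSE]
  bounds <- sort(unique(round(c(0, loops$start, loops$end, length_bp))))
  segs <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  segs$is_loop <- vapply(seq_len(nrow(segs)), function(k) {
    any(loops$start <= segs$start[k] + 1 & loops$end >= segs$end[k] - 1)
  }, logical(1))
  segs$species <- NA_character_
  hit <- findInterval(segs$start + 1, loops$start)
  ok <- hit >= 1 & hit <= nrow(loops)
  segs$species[ok] <- loops$species[hit[ok]]
  segs
}

.new_conformation <- function(xyz, anchor_flag, params, length_bp, mode,
                              loops, chromatid_id = 1L,
                              link_flag = NULL, species = NULL) {
  n <- nrow(xyz)
  beads <- data.frame(
    bead = seq_len(n) - 1L,
    chromatid_id = chromatid_id,
    genomic_bp = (seq_len(n) - 1L) * params$bead_bp,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    anchor = anchor_flag,
    link = if (is.null(link_flag)) FALSE else link_flag,
    species = if (is.null(species)) NA_character_ else species)
  structure(list(beads = beads, params = params, length_bp = length_bp,
                 mode = mode, loop_array = loops,
                 bead_bp = params$bead_bp),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation> %d beads x %g kb, %s, %d chromatid(s)\n",
              nrow(x$beads), x$bead_bp / 1000, x$mode,
              length(unique(x$beads$chromatid_id))))
  invisible(x)
}

.annotate_species <- function(segs, fill) {
  # per-bead species label from the segment table
  function(idx, n) {
    sp <- rep(NA_character_, n)
    for (k in seq_len(nrow(segs))) {
      if (!is.na(segs$species[k]) && segs$is_loop[k]) {
        sp[(idx[k] + 1):(idx[k + 1] + 1)] <- segs$species[k]
      }
    }
    sp
  }
}

#' Build a straight cylindrical bottlebrush chromatid
#'
#' Folds a consecutive loop array into a bottlebrush packed into a
#' cylindrical chromatid body: loop anchors form a noisy scaffold path near
#' the cylinder axis with inter-anchor spacing set by `gap_nm`, loop
#' interiors are Brownian-bridge excursions bowed towards the cylinder
#' wall, and the whole body is confined to the cylinder whose radius
#' follows from the linear and volume densities.
#'
#' @param loops loop array data.frame (`start`, `end`, bp; see
#'   [make_loop_array()]), or `NULL` for a loop-free fiber (the
#'   conformation reduces to a confined random walk).
#' @param params a [chromatid_params()].
#' @param length_bp chromosome length (default: end of the loop array).
#' @param seed integer seed.
#' @return a `conformation`: bead table (10 kb/bead by default) with
#'   genomic coordinate, nm positions, and anchor annotations.
#' @export
build_bottlebrush <- function(loops, params, length_bp = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(loops) || !NROW(loops)) {
    stopifnot(!is.null(length_bp))
    loops <- data.frame(start = numeric(0), end = numeric(0),
                        species = character(0))
    segs <- data.frame(start = 0, end = length_bp, is_loop = FALSE,
                       species = NA_character_)
  } else {
    if (is.null(length_bp)) length_bp <- max(loops$end)
    segs <- .segments_from_loops(loops, length_bp)
  }
  geo <- .geometry(params, length_bp)
  .check_loop_fit(params, geo)
  bounds <- c(segs$start, length_bp)
  anchors <- .scaffold_anchors(bounds, params, geo, mode = "straight")
  fb <- .fill_beads(segs, anchors, params, geo, mode = "straight")
  sp <- .annotate_species(segs)(fb$idx, nrow(fb$xyz))
  .new_conformation(fb$xyz, fb$anchor, params, length_bp, "straight",
                    loops, species = sp)
}

.check_loop_fit <- function(params, geo) {
  # a loop's unperturbed spatial extent must fit the cylinder diameter
  if (params$helix_mode == "periodic_random_walk") return(invisible())
  n_per <- params$loop_kb * 1000 / params$bead_bp
  extent <- sqrt(n_per) / 2 * geo$b_nm
  if (extent > geo$r_cyl_nm) {
    stop("loops of ", params$loop_kb, " kb are too large for a cylinder of",
         " radius ", round(geo$r_cyl_nm), " nm at linear density ",
         params$linear_density, " Mb/um (violated constraint: loop extent ",
         round(extent), " nm exceeds the cylinder radius)")
  }
  invisible()
}

#' Nudge a bottlebrush chromatid into an irregular helix
#'
#' Rebuilds the conformation with its loop-anchor scaffold following a
#' noisy helical path: the winding number is fixed at
#' `length_mb / turn_mb`, the two ends are pinned to opposite cylinder
#' caps, and angular and axial jitter make the helix irregular (gyres
#' interdigitate rather than stack). Because a rigid geometric twist of
#' existing bead coordinates would shear loops that span gyres, the loops
#' are re-grown around the helical scaffold instead (same generative model,
#' helical scaffold curve).
#'
#' @param conf a `conformation` from [build_bottlebrush()].
#' @param params a [chromatid_params()] with finite `turn_mb`.
#' @param seed integer seed.
#' @return a helical `conformation`.
#' @export
apply_helical_scaffold <- function(conf, params = conf$params, seed = 1) {
  stopifnot(inherits(conf, "conformation"))
  if (!is.finite(params$turn_mb)) {
    return(conf)  # infinite turn length: straight backbone, no periodicity
  }
  length_bp <- conf$length_bp
  if (params$turn_mb >= length_bp / 1e6) {
    warning("turn_mb >= chromatid length: fewer than one helical turn")
  }
  set.seed(seed)
  loops <- conf$loop_array
  segs <- if (NROW(loops)) .segments_from_loops(loops, length_bp)
          else data.frame(start = 0, end = length_bp, is_loop = FALSE,
                          species = NA_character_)
  geo <- .geometry(params, length_bp)
  bounds <- c(segs$start, length_bp)
  anchors <- .scaffold_anchors(bounds, params, geo, mode = "helical")
  fb <- .fill_beads(segs, anchors, params, geo, mode = "helical")
  sp <- .annotate_species(segs)(fb$idx, nrow(fb$xyz))
  .new_conformation(fb$xyz, fb$anchor, params, length_bp, "helical",
                    loops, species = sp)
}

#' Build a stretched random-walk bottlebrush (periodic-boundary mode)
#'
#' The model of chromatids without a defined cylindrical shape: the loop
#' array folds into a random walk with an imposed end-to-end distance, and
#' chromatin density is imposed through a periodic box rather than a
#' cylindrical wall, making no assumption about chromatid shape. At scales
#' of several loops the backbone is a (weakly stretched) random walk, so
#' contact frequency decays as s^-1.5.
#'
#' Contacts and P(s) are computed on unwrapped coordinates: minimum-image
#' contacts across box replicas model background (inter-chromatid)
#' interactions, which Hi-C analysis masks below the background floor.
#'
#' @param loops loop array data.frame.
#' @param params a [chromatid_params()] with
#'   `helix_mode = "periodic_random_walk"`.
#' @param length_bp chromosome length.
#' @param seed integer seed.
#' @param end_to_end_um override of the imposed end-to-end distance (um);
#'   default `length_mb / linear_density`. Zero gives the unstretched
#'   control. Must not exceed the backbone contour length.
#' @return a `conformation` (attribute `box_nm` records the periodic box).
#' @export
build_periodic_random_walk <- function(loops, params, length_bp = NULL,
                                       seed = 1, end_to_end_um = NULL) {
  set.seed(seed)
  if (is.null(length_bp)) length_bp <- max(loops$end)
  geo <- .geometry(params, length_bp)
  if (!is.null(end_to_end_um)) {
    geo$e2e_nm <- 1000 * end_to_end_um
  } else if (!is.null(params$end_to_end_um)) {
    geo$e2e_nm <- 1000 * params$end_to_end_um
  }
  segs <- .segments_from_loops(loops, length_bp)
  contour <- nrow(segs) * (params$gap_nm +
                             0.5 * geo$b_nm *
                             sqrt(params$loop_kb * 1000 / params$bead_bp))
  if (geo$e2e_nm > contour) {
    stop("imposed end-to-end distance ", round(geo$e2e_nm), " nm exceeds ",
         "the backbone contour length ", round(contour), " nm")
  }
  bounds <- c(segs$start, length_bp)
  anchors <- .scaffold_anchors(bounds, params, geo, mode = "periodic")
  fb <- .fill_beads(segs, anchors, params, geo, mode = "periodic")
  sp <- .annotate_species(segs)(fb$idx, nrow(fb$xyz))
  out <- .new_conformation(fb$xyz, fb$anchor, params, length_bp,
                           "periodic", loops, species = sp)
  out$box_nm <- geo$box_nm
  out
}

#' Realized chromatin volume density of a conformation
#'
#' Estimated as chromatin content over occupied volume on an occupancy grid
#' with cells of 2.5 bead diameters (a compromise between resolving the
#' body outline and not counting internal voids; periodic mode: beads are
#' wrapped into the density box first).
#'
#' @param conf a `conformation`.
#' @return Mb per um^3.
#' @export
realized_volume_density <- function(conf) {
  geo <- .geometry(conf$params, conf$length_bp)
  h <- 2.5 * geo$b_nm
  xyz <- as.matrix(conf$beads[, c("x", "y", "z")])
  if (conf$mode == "periodic") {
    xyz <- xyz %% conf$box_nm
  }
  cells <- unique(floor(sweep(xyz, 2, apply(xyz, 2, min)) / h))
  occupied_um3 <- nrow(cells) * (h / 1000)^3
  (nrow(conf$beads) * conf$bead_bp / 1e6) / occupied_um3
}

#' Build a cohesed sister-chromatid pair
#'
#' Two modes of condensin engagement with cohesive cohesin:
#' `"bypass"` - condensins step over cohesive links, each sister
#' individualizes into its own bottlebrush with its own condensin axis, and
#' the links (which end up inside loops, distal from anchors) concentrate
#' at the inter-sister interface; `"stall"` - condensins cannot pass the
#' links, loop arrays are truncated at link positions so links sit at loop
#' bases, and the two sisters share a single merged axis where condensin
#' and cohesin colocalize.
#'
#' @param loops1,loops2 loop arrays of the two sisters.
#' @param links a [make_cohesive_links()] data.frame (`pos_bp1`,
#'   `pos_bp2`).
#' @param mode `"bypass"` or `"stall"`.
#' @param params a [chromatid_params()].
#' @param length_bp chromosome length.
#' @param seed integer seed.
#' @param axis_sep_nm separation of the sister axes in bypass mode
#'   (default 1.1 chromatid radii; in stall mode the axes coincide).
#' @return a `conformation` with `chromatid_id` 1/2 and `link` flags on the
#'   cohesive-link beads.
#' @export
build_sister_pair <- function(loops1, loops2, links,
                              mode = c("bypass", "stall"), params,
                              length_bp = NULL, seed = 1,
                              axis_sep_nm = NULL) {
  mode <- match.arg(mode)
  set.seed(seed)
  if (is.null(length_bp)) length_bp <- max(loops1$end, loops2$end)
  if (NROW(links) && (any(links$pos_bp1 < 0) ||
                      any(links$pos_bp1 > length_bp))) {
    stop("cohesive links outside chromatid range")
  }
  geo <- .geometry(params, length_bp)
  if (is.null(axis_sep_nm)) {
    axis_sep_nm <- if (mode == "bypass") 1.1 * geo$r_cyl_nm else 0
  }
  link_beads <- if (NROW(links)) {
    sort(unique(pmin(round(links$pos_bp1 / params$bead_bp),
                     round(length_bp / params$bead_bp) - 1)))
  } else integer(0)

  if (mode == "stall" && length(link_beads)) {
    cut_at <- function(loops) {
      pos <- link_beads * params$bead_bp
      for (p in pos) {
        k <- which(loops$start < p & loops$end > p)
        if (length(k)) {
          row <- loops[k, ]
          loops <- rbind(loops[-k, ],
                         data.frame(start = row$start, end = p,
                                    species = row$species),
                         data.frame(start = p, end = row$end,
                                    species = row$species))
        }
      }
      loops[order(loops$start), ]
    }
    loops1 <- cut_at(loops1)
    loops2 <- cut_at(loops2)
  }

  build_one <- function(loops, x_off, sgn, fixed) {
    segs <- .segments_from_loops(loops, length_bp)
    bounds <- c(segs$start, length_bp)
    anchors <- .scaffold_anchors(bounds, params, geo, mode = "straight")
    anchors[, 1] <- anchors[, 1] + x_off
    fb <- .fill_beads(segs, anchors, params, geo, mode = "straight",
                      fixed = fixed)
    sp <- .annotate_species(segs)(fb$idx, nrow(fb$xyz))
    list(fb = fb, sp = sp)
  }

  # shared interface positions for the linked beads
  fixed1 <- fixed2 <- NULL
  if (length(link_beads)) {
    zlink <- link_beads * params$bead_bp / 1e6 / params$linear_density *
      1000 + rnorm(length(link_beads), 0, 0.1 * geo$r_cyl_nm)
    ylink <- rnorm(length(link_beads), 0, 0.3 * geo$r_cyl_nm)
    xlink <- rnorm(length(link_beads), 0, 0.1 * geo$r_cyl_nm)
    fixed1 <- data.frame(bead = link_beads, x = xlink, y = ylink,
                         z = zlink)
    fixed2 <- fixed1
    fixed2$x <- fixed2$x + rnorm(length(link_beads), 0, geo$b_nm / 2)
  }
  off <- axis_sep_nm / 2
  if (mode == "stall") {
    # links sit at loop bases on the shared axis: fix them near x = 0 but
    # they are anchors already (arrays truncated), so no interior fixing
    fixed1 <- fixed2 <- NULL
  }
  s1 <- build_one(loops1, -off, -1, fixed1)
  s2 <- build_one(loops2, +off, +1, fixed2)

  confine_x <- function(fb, x_off) {
    # each sister confined to its own cylinder around its axis
    rho <- sqrt((fb$xyz[, 1] - x_off)^2 + fb$xyz[, 2]^2)
    rho_f <- .reflect(rho, 0, geo$r_cyl_nm)
    sc <- ifelse(rho > 1e-9, rho_f / rho, 1)
    fb$xyz[, 1] <- x_off + (fb$xyz[, 1] - x_off) * sc
    fb$xyz[, 2] <- fb$xyz[, 2] * sc
    fb
  }
  if (mode == "bypass") {
    keep1 <- s1$fb$xyz[link_beads + 1, , drop = FALSE]
    keep2 <- s2$fb$xyz[link_beads + 1, , drop = FALSE]
    s1$fb <- confine_x(s1$fb, -off)
    s2$fb <- confine_x(s2$fb, +off)
    # linked beads stay at the interface
    if (length(link_beads)) {
      s1$fb$xyz[link_beads + 1, ] <- keep1
      s2$fb$xyz[link_beads + 1, ] <- keep2
    }
  }

  n1 <- nrow(s1$fb$xyz)
  n2 <- nrow(s2$fb$xyz)
  xyz <- rbind(s1$fb$xyz, s2$fb$xyz)
  link_flag <- c(seq_len(n1) - 1L, seq_len(n2) - 1L) %in% link_beads
  conf <- .new_conformation(
    xyz, c(s1$fb$anchor, s2$fb$anchor), params, length_bp, "sister_pair",
    loops1, chromatid_id = rep(c(1L, 2L), c(n1, n2)),
    link_flag = link_flag, species = c(s1$sp, s2$sp))
  conf$beads$genomic_bp <- c(seq_len(n1) - 1L, seq_len(n2) - 1L) *
    params$bead_bp
  conf$sister_mode <- mode
  conf
}

#' Cross-section intensity profiles across the chromatid axis
#'
#' The in-silico analogue of a fluorescence line scan: beads are projected
#' onto the plane perpendicular to the longitudinal axis (first principal
#' component of the bead cloud) and histogrammed along the in-plane
#' direction of maximal spread (for sister pairs, the direction separating
#' the two chromatid centroids). Profiles are normalized to unit area;
#' widths are reported as full width at half maximum of the binned profile,
#' the convention used for chromatid width measurements.
#'
#' @param conf a `conformation`.
#' @param markers named list of logical bead masks; default `dna` (all
#'   beads), `condensin` (loop-anchor beads), and `cohesin` (link beads,
#'   when present).
#' @param axis optional unit 3-vector overriding the PCA axis.
#' @param nbins histogram bins (widened with a warning when fewer than 100
#'   annotated beads are available).
#' @return data.frame of bin centers (nm) and one normalized intensity
#'   column per marker; attributes `peaks` and `fwhm` (nm) per marker.
#' @export
cross_section_profile <- function(conf, markers = NULL, axis = NULL,
                                  nbins = 41) {
  xyz <- as.matrix(conf$beads[, c("x", "y", "z")])
  if (is.null(markers)) {
    markers <- list(dna = rep(TRUE, nrow(xyz)), condensin = conf$beads$anchor)
    if (any(conf$beads$link)) markers$cohesin <- conf$beads$link
  }
  if (is.null(axis)) {
    ctr <- sweep(xyz, 2, colMeans(xyz))
    axis <- svd(ctr, nu = 0, nv = 3)$v[, 1]
  }
  axis <- axis / sqrt(sum(axis^2))
  perp <- sweep(xyz, 2, colMeans(xyz))
  perp <- perp - (perp %*% axis) %*% t(axis)
  two_chrom <- length(unique(conf$beads$chromatid_id)) > 1
  if (two_chrom) {
    c1 <- colMeans(perp[conf$beads$chromatid_id == 1, , drop = FALSE])
    c2 <- colMeans(perp[conf$beads$chromatid_id == 2, , drop = FALSE])
    dirv <- c1 - c2
    if (sqrt(sum(dirv^2)) < 1e-6) dirv <- svd(perp, nu = 0, nv = 1)$v[, 1]
  } else {
    dirv <- svd(perp, nu = 0, nv = 1)$v[, 1]
  }
  dirv <- dirv / sqrt(sum(dirv^2))
  u <- drop(perp %*% dirv)
  nmin <- min(vapply(markers, sum, 0))
  if (nmin < 100) {
    warning("fewer than 100 annotated beads for some marker: wide bins used")
    nbins <- max(9, nbins %/% 3)
  }
  br <- seq(min(u), max(u), length.out = nbins + 1)
  mid <- (br[-1] + br[-length(br)]) / 2
  wd <- diff(br)[1]
  out <- data.frame(position_nm = mid)
  peaks <- fwhm <- numeric(0)
  for (nm in names(markers)) {
    h <- tabulate(findInterval(u[markers[[nm]]], br, all.inside = TRUE),
                  nbins)
    dens <- h / sum(h) / wd
    out[[nm]] <- dens
    pk <- mid[which.max(dens)]
    half <- max(dens) / 2
    above <- which(dens >= half)
    fw <- if (length(above)) (max(above) - min(above) + 1) * wd else NA
    peaks[nm] <- pk
    fwhm[nm] <- fw
  }
  attr(out, "peaks") <- peaks
  attr(out, "fwhm") <- fwhm
  attr(out, "axis") <- axis
  attr(out, "direction") <- dirv
  out
}
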