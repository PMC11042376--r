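# Grid-search fitting of the three free chromatid-model parameters to a
# target P(s) curve.

#' Ensemble-averaged model P(s) for a parameter set
#'
#' Builds `replicates` chromatid conformations for `params` (helical
#' cylinder or periodic random walk, or a nested two-condensin model from
#' [combine_nested_model()]) and returns the pooled P(s).
#'
#' @param params a [chromatid_params()] or nested model.
#' @param replicates ensemble size.
#' @param seed0 base seed; replicate k uses `seed0 + k`.
#' @param length_mb chromosome length (default 100, the reference
#'   chromatid).
#' @param bins_per_decade P(s) binning (default 20 for sharp diagonal
#'   localization).
#' @param bin... passed through to [ps_curve()].
#' @param ... passed to [ps_curve()].
#' @return a [ps_curve()].
#' @export
simulate_ps <- function(params, replicates = 10, seed0 = 1,
                        length_mb = 100, bins_per_decade = 20, ...) {
  confs <- simulate_ensemble(params, replicates, seed0, length_mb)
  ps_curve(confs, bins_per_decade = bins_per_decade, ...)
}

#' Build an ensemble of chromatid conformations for a parameter set
#'
#' @inheritParams simulate_ps
#' @return list of `conformation`s.
#' @export
simulate_ensemble <- function(params, replicates = 10, seed0 = 1,
                              length_mb = 100) {
  length_bp <- length_mb * 1e6
  lapply(seq_len(replicates), function(k) {
    sd <- seed0 + k
    if (inherits(params, "nested_chromatid_params")) {
      build_nested_chromatid(params, length_bp = length_bp, seed = sd)
    } else if (params$helix_mode == "periodic_random_walk") {
      loops <- make_loop_array(length_bp, params$loop_kb * 1000, seed = sd,
                               species = "condensin_I")
      build_periodic_random_walk(loops, params, length_bp, seed = sd)
    } else {
      loops <- make_loop_array(length_bp, params$loop_kb * 1000, seed = sd,
                               species = "condensin_II")
      conf <- build_bottlebrush(loops, params, length_bp, seed = sd)
      if (is.finite(params$turn_mb)) {
        conf <- apply_helical_scaffold(conf, params, seed = sd)
      }
      conf
    }
  })
}

#' Goodness of fit between a model and a target P(s)
#'
#' Root-mean-square of `log10(model / target)` over the log-spaced bins of
#' the target inside `fit_range`, after masking bins below the background
#' floor. The model curve is interpolated onto the target grid in log-log
#' space. Zero for identical curves; symmetric in its two arguments.
#'
#' @param model_ps,target_ps [ps_curve()] objects with overlapping support.
#' @param fit_range bp range used (default 30 kb to 0.6 x the largest
#'   target separation).
#' @param floor background floor; target bins below it are masked (default
#'   `1e-6 * max(target)`, standing in for the inter-chromosomal background
#'   level when none is supplied).
#' @param min_counts when the target carries per-bin contact counts,
#'   bins with fewer contacts are masked as below the sampling floor
#'   (default 10); the deep inter-gyre dips of helical models otherwise
#'   contribute pure counting noise.
#' @return non-negative scalar; smaller is better.
#' @export
goodness_of_fit <- function(model_ps, target_ps, fit_range = NULL,
                            floor = NULL, min_counts = 10) {
  if (is.null(fit_range)) fit_range <- c(3e4, 0.6 * max(target_ps$s_bp))
  if (is.null(floor)) floor <- 1e-6 * max(target_ps$p)
  keep_t <- target_ps$p > floor & target_ps$s_bp >= fit_range[1] &
    target_ps$s_bp <= fit_range[2]
  if (!is.null(target_ps$counts) && any(target_ps$counts > 0)) {
    keep_t <- keep_t & target_ps$counts >= min_counts
  }
  if (!is.null(model_ps$counts) && any(model_ps$counts > 0)) {
    mkeep <- model_ps$counts >= min_counts & model_ps$p > 0
    mfit <- approx(log10(model_ps$s_bp[model_ps$p > 0]),
                   as.numeric(model_ps$counts[model_ps$p > 0] >=
                                min_counts),
                   xout = log10(target_ps$s_bp), rule = 2)$y
    keep_t <- keep_t & mfit > 0.5
  }
  keep_m <- model_ps$p > 0
  if (!any(keep_t)) stop("no target bins inside the fit range")
  lo <- max(min(model_ps$s_bp[keep_m]), min(target_ps$s_bp[keep_t]))
  hi <- min(max(model_ps$s_bp[keep_m]), max(target_ps$s_bp[keep_t]))
  if (lo >= hi) stop("disjoint s ranges between model and target")
  use <- keep_t & target_ps$s_bp >= lo & target_ps$s_bp <= hi
  my <- approx(log10(model_ps$s_bp[keep_m]), log10(model_ps$p[keep_m]),
               xout = log10(target_ps$s_bp[use]), rule = 2)$y
  sqrt(mean((my - log10(target_ps$p[use]))^2))
}

#' Specification of a parameter-grid fit
#'
#' @param grid named list of grid values for `loop_kb`, `gap_nm`,
#'   `linear_density` (any subset; missing entries use the template's
#'   value).
#' @param fixed a template [chromatid_params()] carrying the fixed
#'   parameters (turn length, volume density, mode).
#' @param replicates simulated replicates per grid point.
#' @param seed0 base seed.
#' @param fit_range s range for [goodness_of_fit()].
#' @param length_mb simulated chromosome length per replicate.
#' @return object of class `fit_spec`.
#' @export
fit_spec <- function(grid, fixed, replicates = 3, seed0 = 1,
                     fit_range = NULL, length_mb = 50) {
  stopifnot(inherits(fixed, "chromatid_params"), length(grid) >= 1,
            all(names(grid) %in% c("loop_kb", "gap_nm", "linear_density")),
            all(lengths(grid) >= 1))
  structure(list(grid = grid, fixed = fixed, replicates = replicates,
                 seed0 = seed0, fit_range = fit_range,
                 length_mb = length_mb),
            class = "fit_spec")
}

#' Exhaustive grid search of the free chromatid-model parameters
#'
#' Evaluates every grid point by simulating `replicates` conformations,
#' computing the ensemble P(s) and its goodness of fit to the target, and
#' returns the best point with the full goodness-of-fit surface (grid
#' points whose simulation fails are recorded and skipped). A near-tied
#' surface (degenerate fit) is flagged.
#'
#' @param target_ps target [ps_curve()].
#' @param spec a [fit_spec()].
#' @param verbose print progress.
#' @return object of class `fit_result`: `best_params`, `gof`, `surface`
#'   (data.frame over the grid with `gof` and replicate `gof_sem`),
#'   `degenerate` flag.
#' @export
fit_grid <- function(target_ps, spec, verbose = FALSE) {
  g <- spec$grid
  tmpl <- spec$fixed
  vals <- list(loop_kb = g$loop_kb %||% tmpl$loop_kb,
               gap_nm = g$gap_nm %||% tmpl$gap_nm,
               linear_density = g$linear_density %||% tmpl$linear_density)
  surface <- expand.grid(loop_kb = vals$loop_kb, gap_nm = vals$gap_nm,
                         linear_density = vals$linear_density)
  surface$gof <- NA_real_
  surface$gof_sem <- NA_real_
  surface$failed <- FALSE
  for (i in seq_len(nrow(surface))) {
    p <- chromatid_params(
      loop_kb = surface$loop_kb[i], gap_nm = surface$gap_nm[i],
      linear_density = surface$linear_density[i], turn_mb = tmpl$turn_mb,
      volume_density = tmpl$volume_density, helix_mode = tmpl$helix_mode,
      bead_bp = tmpl$bead_bp, scaffold_frac = tmpl$scaffold_frac,
      angular_jitter_sd = tmpl$angular_jitter_sd,
      axial_jitter_frac = tmpl$axial_jitter_frac,
      jitter_corr_mb = tmpl$jitter_corr_mb, bow_frac = tmpl$bow_frac)
    # gof on the pooled ensemble (ranking); half-split for the SEM
    res <- tryCatch({
      confs <- simulate_ensemble(p, replicates = spec$replicates,
                                 seed0 = spec$seed0 +
                                   (i - 1) * spec$replicates,
                                 length_mb = spec$length_mb)
      pooled <- ps_curve(confs, bins_per_decade = 20)
      g <- goodness_of_fit(pooled, target_ps, fit_range = spec$fit_range)
      sem <- 0
      if (spec$replicates >= 2) {
        half <- seq_len(spec$replicates) <= spec$replicates / 2
        g1 <- goodness_of_fit(ps_curve(confs[half], bins_per_decade = 20),
                              target_ps, fit_range = spec$fit_range)
        g2 <- goodness_of_fit(ps_curve(confs[!half], bins_per_decade = 20),
                              target_ps, fit_range = spec$fit_range)
        sem <- abs(g1 - g2) / 2
      }
      list(g = g, sem = sem)
    }, error = function(e) NULL)
    if (is.null(res)) {
      surface$failed[i] <- TRUE
      next
    }
    surface$gof[i] <- res$g
    surface$gof_sem[i] <- res$sem
    if (verbose) {
      message(sprintf("grid %d/%d: loop %g kb gap %g nm lambda %g -> %.4f",
                      i, nrow(surface), surface$loop_kb[i],
                      surface$gap_nm[i], surface$linear_density[i],
                      surface$gof[i]))
    }
  }
  ok <- which(!surface$failed & is.finite(surface$gof))
  if (!length(ok)) stop("all grid points failed")
  best <- ok[which.min(surface$gof[ok])]
  best_params <- chromatid_params(
    loop_kb = surface$loop_kb[best], gap_nm = surface$gap_nm[best],
    linear_density = surface$linear_density[best], turn_mb = tmpl$turn_mb,
    volume_density = tmpl$volume_density, helix_mode = tmpl$helix_mode,
    bead_bp = tmpl$bead_bp)
  spread <- diff(range(surface$gof[ok]))
  structure(list(best_params = best_params, gof = surface$gof[best],
                 surface = surface,
                 degenerate = spread < 2 * median(surface$gof_sem[ok])),
            class = "fit_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(paste0("<fit_result> best: loop %g kb, gap %g nm, ",
                     "%g Mb/um (gof %.4f)%s\n"),
              x$best_params$loop_kb, x$best_params$gap_nm,
              x$best_params$linear_density, x$gof,
              if (isTRUE(x$degenerate)) " [degenerate: near-tied surface]"
              else ""))
  invisible(x)
}

#' Combine condensin II and condensin I models into a nested model
#'
#' The two condensins act additively: condensin II defines the outer loop
#' array and overall (helical) scaffold; condensin I subdivides each outer
#' loop into several inner loops whose anchors form a secondary scaffold
#' along the outer loop's path. Only the inner gap size may need a minor
#' adjustment when combining independently fitted models.
#'
#' @param params_II outer (condensin II) [chromatid_params()].
#' @param params_I inner (condensin I) [chromatid_params()].
#' @param gap_adjustment multiplier on the inner gap size (default 1).
#' @return object of class `nested_chromatid_params`.
#' @export
combine_nested_model <- function(params_II, params_I, gap_adjustment = 1) {
  if (params_I$loop_kb >= params_II$loop_kb) {
    warning("inner loop size >= outer loop size: nesting is degenerate")
  }
  inner <- params_I
  inner$gap_nm <- inner$gap_nm * gap_adjustment
  structure(list(outer = params_II, inner = inner,
                 gap_adjustment = gap_adjustment),
            class = "nested_chromatid_params")
}

#' @export
print.nested_chromatid_params <- function(x, ...) {
  cat(sprintf(paste0("<nested_chromatid_params> outer %g kb / inner %g kb",
                     " (~%.1f nested loops per outer loop)\n"),
              x$outer$loop_kb, x$inner$loop_kb,
              x$outer$loop_kb / x$inner$loop_kb))
  invisible(x)
}

#' Build a nested two-condensin chromatid conformation
#'
#' Outer (condensin II) anchors follow the scaffold path of the outer
#' model; each outer loop is spanned by a secondary random-walk path of
#' inner (condensin I) anchors, and beads bridge between inner anchors.
#' When the inner density is zero (no inner loops) the model reduces to
#' the pure outer model.
#'
#' @param nested a [combine_nested_model()] object.
#' @param length_bp chromosome length.
#' @param seed integer seed.
#' @return a `conformation`.
#' @export
build_nested_chromatid <- function(nested, length_bp, seed = 1) {
  outer <- nested$outer
  inner <- nested$inner
  set.seed(seed)
  loops_o <- make_loop_array(length_bp, outer$loop_kb * 1000,
                             species = "condensin_II")
  # inner loops partition each outer loop
  inner_rows <- lapply(seq_len(nrow(loops_o)), function(k) {
    seg <- loops_o[k, ]
    len <- seg$end - seg$start
    nin <- max(1, round(len / (inner$loop_kb * 1000)))
    bounds <- seg$start + len * seq(0, 1, length.out = nin + 1)
    jit <- c(0, rnorm(max(nin - 1, 0), 0, 0.1 * len / max(nin, 1)), 0)
    bounds <- sort(bounds + jit)
    data.frame(start = bounds[-length(bounds)], end = bounds[-1],
               species = "condensin_I")
  })
  loops_i <- do.call(rbind, inner_rows)
  geo <- .geometry(outer, length_bp)
  segs_o <- .segments_from_loops(loops_o, length_bp)
  bounds_o <- c(segs_o$start, length_bp)
  mode <- if (is.finite(outer$turn_mb)) "helical" else "straight"
  anchors_o <- .scaffold_anchors(bounds_o, outer, geo, mode = mode)
  # secondary scaffold: inner anchors bridge along each outer loop
  bead_bp <- outer$bead_bp
  bounds_i <- sort(unique(round(c(loops_i$start, loops_i$end) / bead_bp)))
  n_per_inner <- inner$loop_kb * 1000 / bead_bp
  b_sub <- inner$gap_nm + 0.5 * geo$b_nm * sqrt(max(n_per_inner, 1))
  anchor_i_xyz <- matrix(NA_real_, length(bounds_i), 3)
  idx_o <- round(bounds_o / bead_bp)
  for (k in seq_len(nrow(segs_o))) {
    inside <- which(bounds_i * bead_bp >= segs_o$start[k] &
                      bounds_i * bead_bp <= segs_o$end[k])
    if (!length(inside)) next
    m <- length(inside)
    first <- bounds_i[inside[1]] == idx_o[k]
    last <- bounds_i[inside[m]] == idx_o[k + 1]
    interior <- inside[!(bounds_i[inside] %in% idx_o[c(k, k + 1)])]
    if (first) anchor_i_xyz[inside[1], ] <- anchors_o[k, ]
    if (last) anchor_i_xyz[inside[m], ] <- anchors_o[k + 1, ]
    if (length(interior)) {
      pts <- .bridge3(length(interior), anchors_o[k, ], anchors_o[k + 1, ],
                      b_sub / sqrt(3))
      anchor_i_xyz[interior, ] <- pts
    }
  }
  segs_i <- data.frame(start = bounds_i[-length(bounds_i)] * bead_bp,
                       end = bounds_i[-1] * bead_bp, is_loop = TRUE,
                       species = "condensin_I")
  fb <- .fill_beads(segs_i, anchor_i_xyz, inner2 <- {
    tmp <- inner; tmp$bow_frac <- outer$bow_frac; tmp
  }, geo, mode = mode)
  sp <- rep("condensin_I", nrow(fb$xyz))
  sp[idx_o + 1] <- "condensin_II"
  conf <- .new_conformation(fb$xyz, fb$anchor, outer, length_bp,
                            paste0("nested_", mode), loops_o, species = sp)
  conf$inner_loops <- loops_i
  conf
}
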