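# Seeded generators for every input the pipeline needs.

#' G2-like cohesin/CTCF fixture
#'
#' Generates the substrate of a G2-arrested nucleus for the lattice engine:
#' CTCF sites with exponential spacing and random orientations, an
#' extrusive-cohesin species parameterized so its loops produce the
#' characteristic ~100 kb shoulder in P(s), the list of expected dots
#' (convergent CTCF pairs within a maximum separation), and an A/B
#' compartment label track. Running the engine with cohesin only on this
#' fixture yields CTCF-anchored loops, i.e. TADs and dots.
#'
#' @param length_mb chromosome length (Mb).
#' @param ctcf_spacing_kb mean CTCF spacing (kb).
#' @param cohesin_density extrusive cohesins per Mb (default 12: the G2
#'   level, about 3-fold the residual prometaphase density, consistent
#'   with the ~3-fold prophase loss of chromatin-bound cohesin).
#' @param seed integer seed.
#' @param site_bp lattice resolution.
#' @param cohesin_speed_kb_s extrusion speed (kb/s).
#' @param cohesin_processivity_kb mean chromatin extruded per binding event
#'   (sets the unloading rate, speed/processivity, and with it the ~100 kb
#'   loop scale).
#' @param max_dot_sep_mb maximum anchor separation of an expected dot.
#' @param label_bin_bp bin size of the A/B label track.
#' @param domain_mb mean compartment domain length.
#' @return object of class `g2_fixture`.
#' @export
make_g2_fixture <- function(length_mb = 20, ctcf_spacing_kb = 250,
                            cohesin_density = 12, seed = 1, site_bp = 1000,
                            cohesin_speed_kb_s = 1,
                            cohesin_processivity_kb = 150,
                            max_dot_sep_mb = 1, label_bin_bp = 1e5,
                            domain_mb = 2) {
  stopifnot(ctcf_spacing_kb * 1000 > site_bp)
  if (cohesin_density * ctcf_spacing_kb / 1000 > 4) {
    warning("cohesin density high for the CTCF spacing: ",
            "many unanchored cohesins expected")
  }
  set.seed(seed)
  length_bp <- length_mb * 1e6
  L <- length_bp / site_bp
  # CTCF sites: exponential spacing, random orientation
  pos <- cumsum(rexp(ceiling(2.5 * length_mb * 1000 / ctcf_spacing_kb),
                     1 / (ctcf_spacing_kb * 1000 / site_bp)))
  pos <- floor(pos[pos < L - 1])
  pos <- unique(pmax(pos, 1))
  strand <- sample(c("+", "-"), length(pos), replace = TRUE)
  ctcf <- data.frame(pos = pos, strand = strand,
                     blocks_dir = ifelse(strand == "+", -1L, 1L))
  # expected dots: consecutive convergent (+ ... -) pairs within range
  dots <- NULL
  if (length(pos) > 1) {
    i <- seq_len(length(pos) - 1)
    conv <- strand[i] == "+" & strand[i + 1] == "-" &
      (pos[i + 1] - pos[i]) * site_bp <= max_dot_sep_mb * 1e6
    dots <- data.frame(pos1 = pos[i][conv] * site_bp,
                       pos2 = pos[i + 1][conv] * site_bp)
  }
  unload <- cohesin_speed_kb_s / cohesin_processivity_kb
  cohesin <- species_config(
    "cohesin_extrusive", density = cohesin_density,
    speed = cohesin_speed_kb_s,
    loading_rate = cohesin_density / 1000 * unload / (site_bp / 1000),
    unloading_rate = unload)
  labels <- make_compartment_labels(ceiling(length_bp / label_bin_bp),
                                    domain_mb * 1e6 / label_bin_bp)
  structure(list(length_bp = length_bp, site_bp = site_bp, ctcf = ctcf,
                 cohesin = cohesin, expected_dots = dots,
                 ab_labels = labels, label_bin_bp = label_bin_bp,
                 policy = collision_policy(), seed = seed),
            class = "g2_fixture")
}

#' @export
print.g2_fixture <- function(x, ...) {
  cat(sprintf(paste0("<g2_fixture> %.0f Mb, %d CTCF sites, %d expected ",
                     "dots, cohesin %.3g/Mb\n"),
              x$length_bp / 1e6, nrow(x$ctcf), NROW(x$expected_dots),
              x$cohesin$density))
  invisible(x)
}

#' A/B compartment label track
#'
#' Alternating A/B blocks with geometric block lengths (mean
#' `domain_length_bins`); alternation keeps the A and B fractions near
#' one half.
#'
#' @param n_bins number of bins.
#' @param domain_length_bins mean domain length in bins.
#' @param seed integer seed (`NULL`: current RNG state).
#' @return character vector of `"A"`/`"B"` labels, length `n_bins`.
#' @export
make_compartment_labels <- function(n_bins, domain_length_bins, seed = NULL) {
  stopifnot(domain_length_bins < n_bins)
  if (!is.null(seed)) set.seed(seed)
  labels <- character(0)
  cur <- sample(c("A", "B"), 1)
  while (length(labels) < n_bins) {
    len <- rgeom(1, 1 / domain_length_bins) + 1
    labels <- c(labels, rep(cur, len))
    cur <- if (cur == "A") "B" else "A"
  }
  labels[seq_len(n_bins)]
}

#' Cohesive-cohesin link set for sister-pair models
#'
#' Poisson-placed, symmetric (same locus on both sisters) cohesive links.
#'
#' @param length_mb chromosome length (Mb).
#' @param links_per_mb link density (default 2, i.e. one per 500 kb).
#' @param seed integer seed.
#' @return data.frame with `pos_bp1`, `pos_bp2` (sorted; equal by
#'   symmetry).
#' @export
make_cohesive_links <- function(length_mb, links_per_mb = 2, seed = 1) {
  stopifnot(links_per_mb >= 0)
  set.seed(seed)
  n <- rpois(1, length_mb * links_per_mb)
  pos <- sort(runif(n, 0, length_mb * 1e6))
  data.frame(pos_bp1 = pos, pos_bp2 = pos)
}

#' Noisy target P(s) curve for fitting tests
#'
#' [simulate_ps()] output with multiplicative lognormal noise of the given
#' coefficient of variation (mean-one noise, so the expectation is the
#' clean curve).
#'
#' @param params a [chromatid_params()].
#' @param noise_cv coefficient of variation of the noise (0 = clean).
#' @param seed integer seed (used for both the simulation and the noise).
#' @param ... passed to [simulate_ps()].
#' @return a [ps_curve()] with attribute `true_params`.
#' @export
make_target_ps <- function(params, noise_cv = 0.1, seed = 1, ...) {
  stopifnot(noise_cv >= 0)
  ps <- simulate_ps(params, seed0 = seed * 1000, ...)
  if (noise_cv > 0) {
    set.seed(seed)
    sdl <- sqrt(log(1 + noise_cv^2))
    ps$p <- ps$p * rlnorm(length(ps$p), -sdl^2 / 2, sdl)
    ps$p <- ps$p / sum(ps$p)
  }
  attr(ps, "true_params") <- params
  ps
}

#' Contact map with planted compartment and dot signal
#'
#' Power-law background times planted enrichments with known ground-truth
#' folds: within-compartment pairs are enriched (and between-type pairs
#' depleted) so the compartment strength equals `compartment_fold`, and
#' 3x3 windows at dot positions are multiplied by `dot_fold`. Used as
#' positive and null controls for the feature scorers.
#'
#' @param n_bins map size.
#' @param bin_bp bin size.
#' @param dots data.frame with `bin1`, `bin2` (1-based), or `NULL`.
#' @param dot_fold planted dot enrichment (>= 1).
#' @param ab_labels compartment labels (length `n_bins`), or `NULL`.
#' @param compartment_fold planted compartment strength (>= 1).
#' @param alpha background decay exponent.
#' @param noise_cv multiplicative lognormal noise.
#' @param seed integer seed.
#' @return a [contact_map()] with attribute `truth` recording the folds.
#' @export
make_planted_map <- function(n_bins = 200, bin_bp = 1e5, dots = NULL,
                             dot_fold = 1, ab_labels = NULL,
                             compartment_fold = 1, alpha = 1,
                             noise_cv = 0.05, seed = 1) {
  stopifnot(dot_fold >= 1, compartment_fold >= 1)
  set.seed(seed)
  d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  m <- (d + 1)^(-alpha)
  if (!is.null(ab_labels) && compartment_fold > 1) {
    stopifnot(length(ab_labels) == n_bins)
    same <- outer(ab_labels, ab_labels, "==")
    m <- m * ifelse(same, sqrt(compartment_fold), 1 / sqrt(compartment_fold))
  }
  if (!is.null(dots) && dot_fold > 1) {
    for (k in seq_len(nrow(dots))) {
      i <- dots$bin1[k]; j <- dots$bin2[k]
      ii <- intersect(seq_len(n_bins), (i - 1):(i + 1))
      jj <- intersect(seq_len(n_bins), (j - 1):(j + 1))
      m[ii, jj] <- m[ii, jj] * dot_fold
      m[jj, ii] <- t(m[ii, jj])
    }
  }
  if (noise_cv > 0) {
    sdl <- sqrt(log(1 + noise_cv^2))
    noise <- matrix(rlnorm(n_bins^2, -sdl^2 / 2, sdl), n_bins)
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    m <- m * noise
  }
  out <- contact_map(m, bin_bp)
  attr(out, "truth") <- list(dot_fold = dot_fold,
                             compartment_fold = compartment_fold)
  out
}
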