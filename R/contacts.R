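# Contact maps and P(s) contact-scaling curves.

#' Contact map container
#'
#' @param matrix symmetric, non-negative, finite numeric matrix of contact
#'   counts or frequencies.
#' @param bin_bp genomic bin size (bp).
#' @param length_bp chromosome length (bp).
#' @param balanced whether the matrix has been balanced.
#' @return object of class `contact_map`.
#' @export
contact_map <- function(matrix, bin_bp, length_bp = nrow(matrix) * bin_bp,
                        balanced = FALSE) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (any(!is.finite(matrix))) stop("contact map entries must be finite")
  if (any(matrix < 0)) stop("contact map entries must be non-negative")
  if (max(abs(matrix - t(matrix))) > 1e-8 * max(1, max(matrix))) {
    stop("contact map must be symmetric")
  }
  structure(list(matrix = matrix, bin_bp = bin_bp, length_bp = length_bp,
                 balanced = balanced),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d x %d bins of %g kb (%.1f Mb)\n",
              nrow(x$matrix), ncol(x$matrix), x$bin_bp / 1000,
              x$length_bp / 1e6))
  invisible(x)
}

.default_capture_radius <- function(conf) {
  2 * .geometry(conf$params, conf$length_bp)$b_nm
}

.contact_pairs <- function(conf, capture_radius_nm = NULL) {
  if (is.null(capture_radius_nm)) {
    capture_radius_nm <- .default_capture_radius(conf)
  }
  xyz <- as.matrix(conf$beads[, c("x", "y", "z")])
  contact_pairs_cpp(xyz, capture_radius_nm)
}

#' Contact map from an ensemble of conformations
#'
#' Counts a contact whenever two beads lie within the capture radius
#' (default twice the bead diameter), bins pairs by genomic position and
#' sums over the ensemble. Sister-pair conformations contribute both intra-
#' and inter-chromatid contacts at their genomic coordinates, as Hi-C
#' would.
#'
#' @param confs a `conformation` or list of them.
#' @param capture_radius_nm contact capture radius (nm).
#' @param bin_bp genomic bin size (bp).
#' @return a [contact_map()].
#' @export
contact_map_from_conformations <- function(confs, capture_radius_nm = NULL,
                                           bin_bp = 1e5) {
  if (inherits(confs, "conformation")) confs <- list(confs)
  if (!length(confs)) stop("empty conformation ensemble")
  length_bp <- confs[[1]]$length_bp
  n_bins <- ceiling(length_bp / bin_bp)
  m <- matrix(0, n_bins, n_bins)
  for (conf in confs) {
    pr <- .contact_pairs(conf, capture_radius_nm)
    if (!nrow(pr)) next
    gi <- pmin(conf$beads$genomic_bp[pr[, 1]] %/% bin_bp + 1, n_bins)
    gj <- pmin(conf$beads$genomic_bp[pr[, 2]] %/% bin_bp + 1, n_bins)
    for (k in seq_along(gi)) {
      m[gi[k], gj[k]] <- m[gi[k], gj[k]] + 1
      if (gi[k] != gj[k]) m[gj[k], gi[k]] <- m[gj[k], gi[k]] + 1
    }
  }
  contact_map(m, bin_bp, length_bp)
}

.s_bins <- function(s_min, s_max, bins_per_decade = 10) {
  n <- ceiling(log10(s_max / s_min) * bins_per_decade) + 1
  10^(seq(log10(s_min), log10(s_max), length.out = max(n, 2)))
}

.new_ps_curve <- function(s, p, counts, possible, bins_per_decade,
                          normalization = "unit_sum") {
  keep <- possible > 0
  df <- data.frame(s_bp = s[keep], p = p[keep], counts = counts[keep],
                   possible = possible[keep])
  structure(list(s_bp = df$s_bp, p = df$p, counts = df$counts,
                 possible = df$possible,
                 bins_per_decade = bins_per_decade,
                 normalization = normalization),
            class = "ps_curve")
}

#' @export
print.ps_curve <- function(x, ...) {
  cat(sprintf("<ps_curve> %d bins, s in [%.3g, %.3g] bp (%d bins/decade)\n",
              length(x$s_bp), min(x$s_bp), max(x$s_bp), x$bins_per_decade))
  invisible(x)
}

#' @export
as.data.frame.ps_curve <- function(x, ...) {
  data.frame(s_bp = x$s_bp, p = x$p, counts = x$counts,
             possible = x$possible)
}

#' Contact frequency versus genomic separation, P(s)
#'
#' Computes the average contact frequency per log-spaced genomic-separation
#' bin, either from a binned [contact_map()] or directly from (an ensemble
#' of) bead conformations. Frequencies are the contact count divided by the
#' number of locus pairs at that separation, then normalized to unit sum
#' over bins (the convention used throughout; ratios and log-derivatives
#' are insensitive to it).
#'
#' @param x a `contact_map`, `conformation`, or list of conformations.
#' @param bins_per_decade log-bin resolution (>= 8; default 10, use more
#'   for sharp periodic-diagonal localization).
#' @param capture_radius_nm capture radius for conformation input.
#' @param s_min minimum separation (default one bead / one bin).
#' @param ... unused.
#' @return object of class `ps_curve` with fields `s_bp` (geometric bin
#'   centers), `p`, `counts`, `possible`.
#' @export
ps_curve <- function(x, ...) UseMethod("ps_curve")

#' @rdname ps_curve
#' @export
ps_curve.contact_map <- function(x, bins_per_decade = 10, s_min = NULL,
                                 ...) {
  m <- x$matrix
  n <- nrow(m)
  if (all(m == 0)) stop("all-zero contact map")
  d_counts <- vapply(seq_len(n - 1), function(d) {
    sum(m[cbind(seq_len(n - d), seq_len(n - d) + d)])
  }, 0)
  d_possible <- (n - seq_len(n - 1))
  s_of_d <- seq_len(n - 1) * x$bin_bp
  if (is.null(s_min)) s_min <- x$bin_bp
  edges <- .s_bins(s_min * 0.999, n * x$bin_bp, bins_per_decade)
  bi <- findInterval(s_of_d, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1
  counts <- vapply(seq_len(nb), function(b) sum(d_counts[bi == b]), 0)
  poss <- vapply(seq_len(nb), function(b) sum(d_possible[bi == b]), 0)
  centers <- sqrt(edges[-1] * edges[-length(edges)])
  praw <- ifelse(poss > 0, counts / poss, 0)
  p <- praw / sum(praw)
  .new_ps_curve(centers, p, counts, poss, bins_per_decade)
}

#' @rdname ps_curve
#' @export
ps_curve.conformation <- function(x, bins_per_decade = 10,
                                  capture_radius_nm = NULL, s_min = NULL,
                                  ...) {
  ps_curve.list(list(x), bins_per_decade = bins_per_decade,
                capture_radius_nm = capture_radius_nm, s_min = s_min, ...)
}

#' @rdname ps_curve
#' @export
ps_curve.list <- function(x, bins_per_decade = 10,
                          capture_radius_nm = NULL, s_min = NULL, ...) {
  stopifnot(length(x) >= 1)
  bead_bp <- x[[1]]$bead_bp
  length_bp <- x[[1]]$length_bp
  if (is.null(s_min)) s_min <- bead_bp
  edges <- .s_bins(s_min * 0.999, length_bp, bins_per_decade)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  poss <- numeric(nb)
  max_conf <- numeric(nb)  # largest single-conformation contribution
  for (conf in x) {
    pr <- .contact_pairs(conf, capture_radius_nm)
    if (nrow(pr)) {
      s <- abs(conf$beads$genomic_bp[pr[, 1]] -
                 conf$beads$genomic_bp[pr[, 2]])
      s <- s[s > 0]
      bi <- findInterval(s, edges, rightmost.closed = TRUE)
      ok <- bi >= 1 & bi <= nb
      tb <- tabulate(bi[ok], nb)
      counts <- counts + tb
      max_conf <- pmax(max_conf, tb)
    }
    # possible pairs at each bead separation
    nb_beads <- sum(conf$beads$chromatid_id == conf$beads$chromatid_id[1])
    nchrom <- length(unique(conf$beads$chromatid_id))
    d <- seq_len(nb_beads - 1)
    npairs <- (nb_beads - d) * nchrom
    bi <- findInterval(d * bead_bp, edges, rightmost.closed = TRUE)
    ok <- bi >= 1 & bi <= nb
    for (b in unique(bi[ok])) {
      poss[b] <- poss[b] + sum(npairs[bi == b])
    }
  }
  centers <- sqrt(edges[-1] * edges[-length(edges)])
  praw <- ifelse(poss > 0, counts / poss, 0)
  if (sum(praw) == 0) stop("no contacts found: is the capture radius sane?")
  p <- praw / sum(praw)
  out <- .new_ps_curve(centers, p, counts, poss, bins_per_decade)
  keep <- poss > 0
  out$max_conf_frac <- ifelse(counts[keep] > 0,
                              max_conf[keep] / pmax(counts[keep], 1), 0)
  out$n_conf <- length(x)
  out
}

#' @export
plot.ps_curve <- function(x, ..., xlab = "s (bp)", ylab = "P(s)") {
  graphics::plot(x$s_bp, x$p, log = "xy", type = "l", xlab = xlab,
                 ylab = ylab, ...)
  invisible(x)
}

#' Synthetic contact map from a lattice loop-array frame
#'
#' Constructive 1D-to-map bridge used to score Hi-C features along an
#' extrusion trajectory without building 3D conformations: a power-law
#' background (the overall P(s) decay) plus a focal enrichment at loop
#' anchor pairs. The map stands for a cell-population average, so by
#' default only loops whose both legs sit at deterministic positional
#' cues - CTCF barrier sites - produce focal dots (`focal =
#' "ctcf_anchored"`); cell-to-cell variable anchors (e.g. condensin loops)
#' average into the distance background. CTCF-anchored cohesins therefore
#' give dots at convergent CTCF pairs, and once unloaded or pushed away
#' the enrichment leaves the annotated positions.
#'
#' @param frame one frame of a `loop_trajectory`.
#' @param bin_bp map bin size.
#' @param dot_fold enrichment factor at an anchor pair.
#' @param alpha background decay exponent.
#' @param noise_cv multiplicative lognormal noise CV (0 = deterministic).
#' @param seed seed used when `noise_cv > 0`.
#' @param focal `"ctcf_anchored"` (population semantics, default) or
#'   `"all"` (every bound loop is focal - single-cell semantics).
#' @return a [contact_map()].
#' @export
frame_to_contact_map <- function(frame, bin_bp = 50000, dot_fold = 3,
                                 alpha = 1, noise_cv = 0, seed = 1,
                                 focal = c("ctcf_anchored", "all")) {
  focal <- match.arg(focal)
  length_bp <- frame$lattice_length * frame$site_bp
  n <- ceiling(length_bp / bin_bp)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  m <- (d + 1)^(-alpha)
  ex <- frame$extruders
  ex <- ex[ex$r > ex$l, , drop = FALSE]
  if (focal == "ctcf_anchored" && nrow(ex)) {
    cpos <- frame$ctcf$pos
    anch <- function(x) {
      if (!length(cpos)) rep(FALSE, length(x))
      else vapply(x, function(p) any(abs(cpos - p) <= 1), logical(1))
    }
    ex <- ex[anch(ex$l) & anch(ex$r), , drop = FALSE]
  }
  if (nrow(ex)) {
    bl <- pmin((ex$l * frame$site_bp) %/% bin_bp + 1, n)
    br <- pmin((ex$r * frame$site_bp) %/% bin_bp + 1, n)
    for (k in seq_len(nrow(ex))) {
      if (br[k] - bl[k] < 2) next
      ii <- intersect(seq_len(n), (bl[k] - 1):(bl[k] + 1))
      jj <- intersect(seq_len(n), (br[k] - 1):(br[k] + 1))
      m[ii, jj] <- m[ii, jj] * dot_fold
      m[jj, ii] <- t(m[ii, jj])
    }
  }
  if (noise_cv > 0) {
    set.seed(seed)
    sdl <- sqrt(log(1 + noise_cv^2))
    noise <- matrix(rlnorm(n * n, -sdl^2 / 2, sdl), n, n)
    noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
    m <- m * noise
  }
  contact_map(m, bin_bp, length_bp)
}
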