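# Compartment and dot strength scoring on contact maps.

.observed_expected <- function(map) {
  m <- map$matrix
  n <- nrow(m)
  exp_d <- vapply(0:(n - 1), function(k) {
    i <- seq_len(n - k)
    mean(m[cbind(i, i + k)])
  }, 0)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  e <- matrix(exp_d[d + 1], n, n)
  ifelse(e > 0, m / e, NA)
}

.new_feature_score <- function(kind, value, reference) {
  structure(list(kind = kind, value = value, reference_value = reference,
                 normalized = value / reference),
            class = "feature_score")
}

#' @export
print.feature_score <- function(x, ...) {
  cat(sprintf("<feature_score> %s: %.3f (normalized %.3f vs reference %.3f)\n",
              x$kind, x$value, x$normalized, x$reference_value))
  invisible(x)
}

#' Compartment strength of a contact map
#'
#' Checkerboard (A/B) compartmentalization strength, distance-stratified:
#' at every bin separation with both pair types present, the ratio of the
#' mean contact frequency between same-type bins to that between
#' different-type bins is computed (the expected-at-distance cancels
#' within a stratum), and strata are averaged with weights proportional to
#' the rarer pair type's count. Scores are typically normalized to a
#' G2-arrested reference, set to 1.
#'
#' @param map a [contact_map()].
#' @param ab_labels per-bin labels, `"A"`/`"B"`.
#' @param reference G2 reference strength for normalization (default 1).
#' @param min_sep_bins minimum bin separation included (default 2).
#' @return a `feature_score` (kind `"compartment"`).
#' @export
compartment_strength <- function(map, ab_labels, reference = 1,
                                 min_sep_bins = 2) {
  m <- map$matrix
  n <- nrow(m)
  stopifnot(length(ab_labels) == n)
  if (length(unique(ab_labels)) < 2) {
    stop("compartment strength undefined for single-type labels")
  }
  ratios <- wts <- numeric(0)
  for (d in min_sep_bins:(n - 1)) {
    i <- seq_len(n - d)
    v <- m[cbind(i, i + d)]
    same <- ab_labels[i] == ab_labels[i + d]
    ns <- sum(same)
    nd <- sum(!same)
    if (ns == 0 || nd == 0) next
    ratios <- c(ratios, mean(v[same]) / mean(v[!same]))
    wts <- c(wts, min(ns, nd))
  }
  if (!length(ratios)) stop("no separations with both pair types")
  .new_feature_score("compartment",
                     sum(ratios * wts) / sum(wts), reference)
}

#' Dot (focal loop) strength of a contact map
#'
#' Distance-normalized pileup enrichment at a list of dot anchors: for
#' each dot, the mean observed/expected over the 3x3 center is divided by
#' the mean over a background ring (the outer `ring_bins` of a
#' `+/- window_bins` square). The score is the mean over scorable dots;
#' dots closer to the diagonal (or map edge) than the window are skipped
#' and counted in the `"skipped"` attribute.
#'
#' @param map a [contact_map()].
#' @param dots data.frame with bp midpoint columns `pos1`, `pos2` (or bin
#'   columns `bin1`, `bin2`, 1-based).
#' @param reference G2 reference strength (default 1).
#' @param window_bins half-width of the pileup window.
#' @param ring_bins thickness of the background ring.
#' @return a `feature_score` (kind `"dot"`) with attribute `skipped`.
#' @export
dot_strength <- function(map, dots, reference = 1, window_bins = 10,
                         ring_bins = 3) {
  n <- nrow(map$matrix)
  if (!NROW(dots)) stop("need at least one dot")
  if (is.null(dots$bin1)) {
    dots$bin1 <- pmin(dots$pos1 %/% map$bin_bp + 1, n)
    dots$bin2 <- pmin(dots$pos2 %/% map$bin_bp + 1, n)
  }
  oe <- .observed_expected(map)
  w <- window_bins
  off <- abs(outer(-w:w, -w:w, function(a, b) pmax(abs(a), abs(b))))
  center_mask <- off <= 1
  ring_mask <- off > w - ring_bins & off <= w
  scores <- numeric(0)
  skipped <- 0L
  for (k in seq_len(NROW(dots))) {
    i <- min(dots$bin1[k], dots$bin2[k])
    j <- max(dots$bin1[k], dots$bin2[k])
    if (j - i <= w || i - w < 1 || j + w > n) {
      skipped <- skipped + 1L
      next
    }
    sub <- oe[(i - w):(i + w), (j - w):(j + w)]
    ctr <- mean(sub[center_mask], na.rm = TRUE)
    bg <- mean(sub[ring_mask], na.rm = TRUE)
    if (is.finite(ctr) && is.finite(bg) && bg > 0) {
      scores <- c(scores, ctr / bg)
    }
  }
  if (!length(scores)) stop("no scorable dots (", skipped, " skipped)")
  structure(.new_feature_score("dot", mean(scores), reference),
            skipped = skipped)
}
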