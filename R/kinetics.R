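# In-vivo estimators of extrusion speed, spiral growth and compaction.
#
# Unit conventions are centralized here: times in the public interface are
# minutes (as reported for synchronized mitotic entry) unless a *_s suffix
# says seconds; all speeds are kb/s.

.MIN_S <- 60

#' Time series of a loop-size / spiral-period / area measurement
#'
#' @param times_min times in minutes since release from the G2 block.
#' @param values measured values (kb for loop sizes, Mb for spiral periods,
#'   fold for projected areas).
#' @param kind one of `"loop_kb"`, `"period_mb"`, `"area_fold"`.
#' @return object of class `time_series`.
#' @export
time_series <- function(times_min, values,
                        kind = c("loop_kb", "period_mb", "area_fold")) {
  kind <- match.arg(kind)
  stopifnot(length(times_min) == length(values),
            !is.unsorted(times_min, strictly = TRUE),
            all(values >= 0))
  structure(list(times_min = times_min, values = values, kind = kind),
            class = "time_series")
}

.new_speed <- function(value, method, inputs) {
  structure(list(value_kb_s = value, method = method, inputs = inputs),
            class = "speed_estimate")
}

#' @export
print.speed_estimate <- function(x, ...) {
  cat(sprintf("<speed_estimate> %s: %.2g kb/s\n", x$method,
              signif(x$value_kb_s, 2)))
  invisible(x)
}

#' Extrusion speed from a single loop size and elapsed time
#'
#' The endpoint estimate: a loop of `loop_kb` after `elapsed` of extrusion
#' implies a speed of `loop_kb / elapsed_s` (e.g. 400 kb after 5 min gives
#' ~1.3 kb/s). Because the exact activation time after release is unknown,
#' an optional `t0_offset_min` shifts the elapsed time.
#'
#' @param loop_kb loop size, kb.
#' @param elapsed_min elapsed time in minutes (or supply `elapsed_s`).
#' @param elapsed_s elapsed time in seconds (overrides `elapsed_min`).
#' @param t0_offset_min unknown activation delay subtracted from the
#'   elapsed time (default 0).
#' @return a `speed_estimate` (kb/s).
#' @examples
#' speed_endpoint(400, 5)   # ~1.3 kb/s
#' @export
speed_endpoint <- function(loop_kb, elapsed_min = NULL, elapsed_s = NULL,
                           t0_offset_min = 0) {
  if (is.null(elapsed_s)) elapsed_s <- (elapsed_min - t0_offset_min) * .MIN_S
  stopifnot(loop_kb >= 0)
  if (elapsed_s <= 0) stop("elapsed time must be positive")
  .new_speed(loop_kb / elapsed_s, "endpoint",
             list(loop_kb = loop_kb, elapsed_s = elapsed_s))
}

#' Extrusion speed from the increment of a loop-size time series
#'
#' Speed between two time points of one time course,
#' `(l2 - l1) / (t2 - t1)`. When loops may have saturated inside the
#' interval the estimate is a lower bound; the returned object carries a
#' `lower_bound` flag for that case (set by the caller via
#' `saturating = TRUE`).
#'
#' @param series a [time_series()] of kind `"loop_kb"` (>= 2 points).
#' @param from,to indices of the two points (default first and last).
#' @param saturating flag the estimate as a lower bound.
#' @return a `speed_estimate` (kb/s).
#' @examples
#' speed_increment(time_series(c(2.5, 5), c(200, 400)))  # 1.33 kb/s
#' @export
speed_increment <- function(series, from = 1, to = length(series$values),
                            saturating = FALSE) {
  stopifnot(inherits(series, "time_series"), length(series$values) >= 2)
  dv <- series$values[to] - series$values[from]
  dt <- (series$times_min[to] - series$times_min[from]) * .MIN_S
  if (dv < 0) warning("non-monotone interval: negative loop-size change")
  est <- .new_speed(max(dv, 0) / dt, "increment",
                    list(from = from, to = to, dv_kb = dv, dt_s = dt))
  est$lower_bound <- isTRUE(saturating)
  est
}

#' Extrusion speed from the gap-closure argument
#'
#' Forming a dense rod requires neighbouring condensins to meet: theory
#' says each must extrude about 4-5 times the average loop size to close
#' most gaps. Given the time at which the rod shape appears, the speed is
#' `mean_loop_kb * multiple / time_to_rod_s` (e.g. 400 kb x (4-5) / 600 s
#' = 2.5-3 kb/s).
#'
#' @param mean_loop_kb steady-state mean loop size, kb.
#' @param time_to_rod_s time to rod appearance, seconds.
#' @param multiple extrusion multiple (default 4.5; plausible range 4-5,
#'   accepted range `[1, 10]`; 1 reduces to the endpoint estimate).
#' @return a `speed_estimate` (kb/s).
#' @examples
#' speed_gap_closure(400, 600, 4)  # 2.67 kb/s
#' @export
speed_gap_closure <- function(mean_loop_kb, time_to_rod_s, multiple = 4.5) {
  stopifnot(multiple >= 1, multiple <= 10, time_to_rod_s > 0)
  .new_speed(mean_loop_kb * multiple / time_to_rod_s, "gap_closure",
             list(mean_loop_kb = mean_loop_kb,
                  time_to_rod_s = time_to_rod_s, multiple = multiple))
}

#' Growth rate of the chromatid spiral from the second-diagonal period
#'
#' The genomic period of the chromatid spiral is the position of the first
#' periodic peak of P(s); its growth rate between two time points,
#' converted to kb/s, characterizes spiraling dynamics (e.g. 4.0 to 6.1 Mb
#' between 15 and 30 min is ~2.3 kb/s).
#'
#' @param series a [time_series()] of kind `"period_mb"`.
#' @param from,to indices of the two points (default first and last).
#' @return a `speed_estimate` (kb/s).
#' @examples
#' spiral_growth_rate(time_series(c(15, 30), c(4.0, 6.1), "period_mb"))
#' @export
spiral_growth_rate <- function(series, from = 1,
                               to = length(series$values)) {
  stopifnot(inherits(series, "time_series"), length(series$values) >= 2)
  dv_kb <- (series$values[to] - series$values[from]) * 1000
  dt_s <- (series$times_min[to] - series$times_min[from]) * .MIN_S
  .new_speed(max(dv_kb, 0) / dt_s, "spiral",
             list(from = from, to = to, dv_mb = dv_kb / 1000, dt_s = dt_s))
}

#' Volume fold change from a projected-area fold change
#'
#' Under isotropic compaction a k-fold decrease of maximum-projection area
#' corresponds to a k^(3/2)-fold decrease of volume: a 2-fold area decrease
#' is a 2.83-fold (approximately 3-fold) volume decrease.
#'
#' @param area_fold area fold change (>= 1).
#' @return volume fold change.
#' @examples
#' volume_fold_from_area_fold(2)  # 2.83
#' @export
volume_fold_from_area_fold <- function(area_fold) {
  stopifnot(area_fold >= 1)
  area_fold^(3 / 2)
}

#' Consistency check of gyre-size estimates
#'
#' Compares up to three independent estimates of the genomic size of one
#' helical gyre: the EdU-labeled sister-chromatid-exchange height, the
#' model helix turn length, and the Hi-C second-diagonal period. EdU
#' heights measured in um are converted to Mb with the axial linear
#' density. Each pair passes when its ratio is within `tol` of 1.
#'
#' @param edu_mb gyre size from EdU exchange height, Mb (or give `edu_um`
#'   with `linear_density`).
#' @param model_pitch_mb helix turn length used in the model, Mb.
#' @param hic_period_mb second-diagonal position in Hi-C, Mb.
#' @param edu_um EdU height in um (requires `linear_density`).
#' @param linear_density Mb per um of chromatid axis.
#' @param tol pass tolerance on `|ratio - 1|` (default 0.2).
#' @return data.frame with one row per comparable pair: `pair`, `ratio`,
#'   `pass`.
#' @export
gyre_size_check <- function(edu_mb = NULL, model_pitch_mb = NULL,
                            hic_period_mb = NULL, edu_um = NULL,
                            linear_density = NULL, tol = 0.2) {
  if (is.null(edu_mb) && !is.null(edu_um)) {
    if (is.null(linear_density)) {
      stop("incomparable units: EdU height in um needs linear_density ",
           "(Mb/um) for conversion")
    }
    edu_mb <- edu_um * linear_density
  }
  vals <- c(edu = edu_mb, model = model_pitch_mb, hic = hic_period_mb)
  if (length(vals) < 2) {
    stop("need at least two of the three gyre-size estimates")
  }
  cmb <- utils::combn(names(vals), 2)
  out <- data.frame(pair = apply(cmb, 2, paste, collapse = " vs "),
                    ratio = vals[cmb[1, ]] / vals[cmb[2, ]])
  out$pass <- abs(out$ratio - 1) < tol
  rownames(out) <- NULL
  out
}
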