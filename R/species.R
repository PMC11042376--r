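#' @keywords internal
"_PACKAGE"

#' @useDynLib mitobrush, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois rbinom rgamma rexp rlnorm median
#'   approx optimize quantile sd setNames
#' @importFrom utils read.table write.table head tail
NULL

# internal species codes shared with the C++ engine
.SPECIES <- c(condensin_I = 1L, condensin_II = 2L, cohesin_extrusive = 3L,
              cohesin_cohesive = 4L, ctcf_barrier = 5L)

.species_code <- function(name) {
  code <- .SPECIES[match(name, names(.SPECIES))]
  if (anyNA(code)) {
    stop("unknown species: ", paste(name[is.na(code)], collapse = ", "),
         " (known: ", paste(names(.SPECIES), collapse = ", "), ")")
  }
  unname(code)
}

.species_name <- function(code) names(.SPECIES)[match(code, .SPECIES)]

#' Configure one SMC species for the lattice engine
#'
#' Describes one species of SMC complex (or the CTCF barrier) for the 1D
#' loop-extrusion engine: its chromatin-bound density, extrusion speed and
#' binding kinetics.
#'
#' `speed` is the extrusion speed of the whole complex, i.e. the rate at
#' which chromatin is reeled into its loop, in kb/s. For a two-sided
#' (symmetric) extruder each leg translocates at `speed / 2`; the loop of an
#' unobstructed complex therefore grows at `speed`, which is the quantity the
#' in-vivo estimators in [speed_endpoint()] and friends measure. Cohesive
#' cohesin and CTCF are immobile obstacles and must have `speed = 0`.
#'
#' Default densities follow the quantitative chromatin proteomics of
#' prometaphase DT40 cells: roughly 3-6 cohesins, ~10 condensins I and 2-3
#' condensins II per Mb.
#'
#' @param name one of `"condensin_I"`, `"condensin_II"`,
#'   `"cohesin_extrusive"`, `"cohesin_cohesive"`, `"ctcf_barrier"`.
#' @param density complexes per Mb (used when a scenario loads the species
#'   as a burst or places obstacles).
#' @param speed extrusion speed of the complex in kb/s (0 for obstacles).
#' @param loading_rate loading events per site per second.
#' @param unloading_rate unloading events per bound complex per second.
#' @param two_sided logical; both legs translocate (default).
#' @param ctcf_stabilized extrusive cohesin only: a loop whose both legs
#'   are anchored at matching CTCF barrier sites (a formed dot) is
#'   protected from stochastic unloading while the barriers persist, the
#'   stabilization that lets CTCF-CTCF dots accumulate in G2 (default
#'   `TRUE`).
#' @return an object of class `species_config`.
#' @examples
#' species_config("condensin_II", density = 2.5, speed = 1.5)
#' @export
species_config <- function(name, density = NULL, speed = NULL,
                           loading_rate = 0, unloading_rate = 0,
                           two_sided = TRUE, ctcf_stabilized = TRUE) {
  name <- match.arg(name, names(.SPECIES))
  defaults <- list(
    condensin_I = list(density = 10, speed = 1.0),
    condensin_II = list(density = 2.5, speed = 1.5),
    cohesin_extrusive = list(density = 5, speed = 1.0),
    cohesin_cohesive = list(density = 2, speed = 0),
    ctcf_barrier = list(density = 4, speed = 0)
  )[[name]]
  if (is.null(density)) density <- defaults$density
  if (is.null(speed)) speed <- defaults$speed
  mobile <- !(name %in% c("cohesin_cohesive", "ctcf_barrier"))
  if (!mobile && speed != 0) {
    stop("immobile species '", name, "' must have speed 0")
  }
  stopifnot(density >= 0, speed >= 0, loading_rate >= 0, unloading_rate >= 0)
  structure(list(name = name, density = density, speed = speed,
                 loading_rate = loading_rate,
                 unloading_rate = unloading_rate,
                 two_sided = isTRUE(two_sided), mobile = mobile,
                 ctcf_stabilized = isTRUE(ctcf_stabilized) &&
                   name == "cohesin_extrusive"),
            class = "species_config")
}

#' @export
print.species_config <- function(x, ...) {
  cat(sprintf("<species_config> %s: %.3g/Mb, %.3g kb/s%s\n", x$name,
              x$density, x$speed, if (x$mobile) "" else " (immobile)"))
  invisible(x)
}
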