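# Rules of engagement between SMC complexes on the lattice.

.OUTCOMES <- c(bypass = 0L, stall = 1L, unload_obstacle = 2L,
               push_obstacle = 3L, unload_self = 4L)

#' Collision policy: rules of engagement between SMC complexes
#'
#' A collision policy assigns exactly one outcome to every ordered pair
#' (moving species, obstacle species): the moving leg can `bypass` the
#' obstacle, `stall` against it, remove it (`unload_obstacle`), push it one
#' site ahead (`push_obstacle`, displacing chains of contiguous obstacles as
#' a unit), or fall off itself (`unload_self`). Chromosome ends always stall.
#'
#' The default policy encodes the rules of engagement inferred for mitotic
#' chromosome formation: condensins bypass cohesive cohesins, condensins
#' remove extrusive cohesins, and condensins stall when they encounter one
#' another (which makes their loops consecutive rather than overlapping).
#' Extrusive cohesin stalls at everything it meets.
#'
#' @param rules named list overriding individual entries, names of the form
#'   `"mover|obstacle"`, e.g. `list("condensin_II|cohesin_extrusive" =
#'   "push_obstacle")`. Values must be outcome names.
#' @param cohesin_fate convenience switch setting the outcome of
#'   condensin-vs-extrusive-cohesin encounters for the four prophase
#'   scenarios: `"unload"`, `"push"`, `"bypass"` or `"stall"` (applied to
#'   both condensin species; `NULL` leaves the default `unload_obstacle`).
#' @return a `collision_policy`: an integer matrix (movers x obstacles) of
#'   outcome codes with a `"collision_policy"` class attribute.
#' @examples
#' collision_policy(cohesin_fate = "bypass")
#' @export
collision_policy <- function(rules = list(), cohesin_fate = NULL) {
  movers <- names(.SPECIES)[1:4]
  obstacles <- names(.SPECIES)
  m <- matrix("stall", 4, 5, dimnames = list(movers, obstacles))
  # condensins bypass cohesive cohesin, remove extrusive cohesin,
  # stall at each other
  for (cnd in c("condensin_I", "condensin_II")) {
    m[cnd, "cohesin_cohesive"] <- "bypass"
    m[cnd, "cohesin_extrusive"] <- "unload_obstacle"
  }
  if (!is.null(cohesin_fate)) {
    fate <- match.arg(cohesin_fate, c("unload", "push", "bypass", "stall"))
    out <- c(unload = "unload_obstacle", push = "push_obstacle",
             bypass = "bypass", stall = "stall")[[fate]]
    m["condensin_I", "cohesin_extrusive"] <- out
    m["condensin_II", "cohesin_extrusive"] <- out
  }
  for (nm in names(rules)) {
    pair <- strsplit(nm, "|", fixed = TRUE)[[1]]
    if (length(pair) != 2 || !(pair[1] %in% movers) ||
        !(pair[2] %in% obstacles)) {
      stop("malformed policy rule name: ", nm)
    }
    m[pair[1], pair[2]] <- match.arg(rules[[nm]], names(.OUTCOMES))
  }
  codes <- matrix(.OUTCOMES[m], 4, 5, dimnames = dimnames(m))
  structure(codes, class = "collision_policy")
}

#' @export
print.collision_policy <- function(x, ...) {
  m <- matrix(names(.OUTCOMES)[unclass(x) + 1L], nrow(x), ncol(x),
              dimnames = dimnames(x))
  cat("<collision_policy>\n")
  print(m, quote = FALSE)
  invisible(x)
}

.policy_lookup <- function(policy, mover, obstacle) {
  code <- unclass(policy)[mover, obstacle]
  names(.OUTCOMES)[code + 1L]
}

#' Resolve a single encounter between a moving leg and an obstacle
#'
#' Applies the collision policy to one encounter: a leg of extruder
#' `extruder` in `state` attempting a unit move in direction `dir` into an
#' occupied (or boundary) site. This is the single-encounter view of the
#' same rules the lattice engine applies at every step; it is implemented
#' independently in R so engine behaviour can be cross-checked against it.
#'
#' @param state a [lattice_state()].
#' @param extruder row index of the moving extruder in `state$extruders`.
#' @param dir -1 (left leg moves left) or +1 (right leg moves right).
#' @param policy a [collision_policy()].
#' @param push_cohesive allow cohesive cohesin to be pushed (default FALSE:
#'   it tethers the sister chromatid).
#' @return list with `outcome` (one of bypass/stall/unload_obstacle/
#'   push_obstacle/unload_self, or `"move"` if the target site is free) and
#'   the updated `state`.
#' @export
resolve_encounter <- function(state, extruder, dir, policy,
                              push_cohesive = FALSE) {
  stopifnot(inherits(state, "lattice_state"), dir %in% c(-1L, 1L))
  ex <- state$extruders
  ob <- state$obstacles
  L <- state$lattice_length
  mover_sp <- ex$species[extruder]
  cur <- if (dir < 0) ex$l[extruder] else ex$r[extruder]

  occupant_at <- function(site) {
    ei <- which(ex$l == site | ex$r == site)
    ei <- setdiff(ei, extruder)
    if (length(ei)) return(list(kind = "extruder", id = ei[1],
                                species = ex$species[ei[1]]))
    oi <- which(ob$pos == site)
    if (length(oi)) return(list(kind = "obstacle", id = oi[1],
                                species = ob$species[oi[1]]))
    NULL
  }
  set_pos <- function(e, site) {
    if (dir < 0) ex$l[e] <<- site else ex$r[e] <<- site
  }
  set_stall <- function(e) {
    if (dir < 0) ex$stalled_l[e] <<- TRUE else ex$stalled_r[e] <<- TRUE
  }
  finish <- function(outcome) {
    state$extruders <- ex
    state$obstacles <- ob
    list(outcome = outcome, state = state)
  }

  # anchored at a matching CTCF barrier
  ct <- state$ctcf
  if (mover_sp == "cohesin_extrusive" && nrow(ct) &&
      any(ct$pos == cur & ct$blocks_dir == dir)) {
    set_stall(extruder)
    return(finish("stall"))
  }
  tgt <- cur + dir
  if (tgt < 0 || tgt >= L) {
    set_stall(extruder)
    return(finish("stall"))
  }
  occ <- occupant_at(tgt)
  if (is.null(occ)) {
    set_pos(extruder, tgt)
    return(finish("move"))
  }
  out <- .policy_lookup(policy, mover_sp, occ$species)
  if (out == "stall") {
    set_stall(extruder)
    return(finish("stall"))
  }
  if (out == "unload_self") {
    ex <- ex[-extruder, , drop = FALSE]
    state$extruders <- ex
    state$obstacles <- ob
    return(list(outcome = "unload_self", state = state))
  }
  if (out == "unload_obstacle") {
    if (occ$kind == "extruder") ex <- ex[-occ$id, , drop = FALSE]
    else ob <- ob[-occ$id, , drop = FALSE]
    # careful: row index of mover may have shifted
    if (occ$kind == "extruder" && occ$id < extruder) extruder <- extruder - 1L
    set_pos(extruder, tgt)
    return(finish("unload_obstacle"))
  }
  if (out == "push_obstacle") {
    # collect contiguous chain, then displace as a unit
    chain <- integer(0)
    j <- tgt
    ok <- TRUE
    while (j >= 0 && j < L) {
      o <- occupant_at(j)
      if (is.null(o)) break
      pushable <- .policy_lookup(policy, mover_sp, o$species) ==
        "push_obstacle" && (o$species != "cohesin_cohesive" || push_cohesive)
      if (!pushable) { ok <- FALSE; break }
      chain <- c(chain, j)
      j <- j + dir
    }
    if (!ok || j < 0 || j >= L) {
      set_stall(extruder)
      return(finish("stall"))
    }
    for (site in rev(chain)) {
      o <- occupant_at(site)
      if (o$kind == "obstacle") ob$pos[o$id] <- site + dir
      else {
        if (ex$l[o$id] == site && ex$r[o$id] == site) {
          ex$l[o$id] <- site + dir; ex$r[o$id] <- site + dir
        } else if (ex$l[o$id] == site) ex$l[o$id] <- site + dir
        else ex$r[o$id] <- site + dir
      }
    }
    set_pos(extruder, tgt)
    return(finish("push_obstacle"))
  }
  # bypass: land past the contiguous run of bypassable occupants
  j <- tgt
  while (j >= 0 && j < L) {
    o <- occupant_at(j)
    if (is.null(o)) break
    if (.policy_lookup(policy, mover_sp, o$species) != "bypass") {
      set_stall(extruder)
      return(finish("stall"))
    }
    j <- j + dir
  }
  if (j < 0 || j >= L) {
    set_stall(extruder)
    return(finish("stall"))
  }
  set_pos(extruder, j)
  finish("bypass")
}
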