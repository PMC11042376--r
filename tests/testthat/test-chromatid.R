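# 3D chromatid builders: parameters, geometry, invariants.

test_that("parameter validation enforces positivity, the pitch relation and
          the density sanity band", {
  p <- chromatid_params(preset = "condensin_II")
  expect_equal(p$pitch_nm, 1000 * p$turn_mb / p$linear_density)
  expect_equal(p$pitch_nm, 400)
  expect_error(chromatid_params(loop_kb = -1), "loop_kb")
  expect_error(chromatid_params(volume_density = 5), "plausible band")
  expect_error(chromatid_params(volume_density = 500), "plausible band")
  pI <- chromatid_params(preset = "condensin_I")
  expect_equal(pI$helix_mode, "periodic_random_walk")
  expect_equal(pI$volume_density, 77)
})

test_that("builders preserve genomic bead ordering and respect the volume
          density within 15%", {
  pII <- chromatid_params(preset = "condensin_II")
  loops <- make_loop_array(4e7, 4e5, seed = 2)
  for (conf in list(
    build_bottlebrush(loops, pII, 4e7, seed = 2),
    apply_helical_scaffold(build_bottlebrush(loops, pII, 4e7, seed = 3),
                           pII, seed = 3),
    build_periodic_random_walk(make_loop_array(4e7, 1e5, seed = 2),
                               chromatid_params(preset = "condensin_I"),
                               4e7, seed = 2))) {
    expect_true(!is.unsorted(conf$beads$genomic_bp, strictly = TRUE))
    target <- conf$params$volume_density
    expect_lt(abs(realized_volume_density(conf) - target) / target, 0.15)
  }
})

test_that("a loop-free fiber reduces to a confined random walk", {
  p <- chromatid_params(preset = "condensin_II")
  conf <- build_bottlebrush(NULL, p, length_bp = 2e7, seed = 1)
  expect_equal(nrow(conf$beads), 2001)
  geo <- mitobrush:::.geometry(p, 2e7)
  rho <- sqrt(conf$beads$x^2 + conf$beads$y^2)
  expect_lte(max(rho), geo$r_cyl_nm + 1e-6)
})

test_that("the helical scaffold has the imposed winding number and pinned
          ends; infinite turn length leaves no periodicity", {
  p <- chromatid_params(preset = "condensin_II")
  loops <- make_loop_array(1e8, 4e5, seed = 5)
  conf <- apply_helical_scaffold(build_bottlebrush(loops, p, 1e8, seed = 5),
                                 p, seed = 5)
  a <- conf$beads[conf$beads$anchor, ]
  ph <- atan2(a$y, a$x)
  dph <- diff(ph)
  dph <- ifelse(dph > pi, dph - 2 * pi, ifelse(dph < -pi, dph + 2 * pi,
                                               dph))
  winding <- sum(dph) / (2 * pi)
  expect_lt(abs(winding - 100 / 17), 0.6)
  geo <- mitobrush:::.geometry(p, 1e8)
  expect_lt(a$z[1], 0.1 * geo$l_ax_nm)
  expect_gt(a$z[nrow(a)], 0.9 * geo$l_ax_nm)
  # scaffold concentrated well inside the chromatid radius
  expect_lt(median(sqrt(a$x^2 + a$y^2)), 0.55 * geo$r_cyl_nm)
  # loop bulk reaches the wall: anchors are more central than loop beads
  rho_all <- sqrt(conf$beads$x^2 + conf$beads$y^2)
  expect_lt(median(sqrt(a$x^2 + a$y^2)), median(rho_all))

  expect_warning(apply_helical_scaffold(
    build_bottlebrush(loops[loops$end <= 1.2e7, ],
                      chromatid_params(preset = "condensin_II"), 1.2e7,
                      seed = 1),
    chromatid_params(preset = "condensin_II"), seed = 1),
    "fewer than one")
})

test_that("oversized loops for the cylinder geometry raise a clear error", {
  p <- chromatid_params(loop_kb = 20000, gap_nm = 80, turn_mb = 17,
                        volume_density = 44, linear_density = 200)
  expect_error(build_bottlebrush(make_loop_array(5e7, 2e7, seed = 1), p,
                                 5e7, seed = 1), "too large")
})

test_that("the periodic random walk has linear backbone MSD over 2-8 Mb and
          honours the imposed end-to-end distance", {
  pI <- chromatid_params(preset = "condensin_I")
  loops <- make_loop_array(1e8, 1e5, seed = 3)
  conf <- build_periodic_random_walk(loops, pI, 1e8, seed = 3)
  a <- as.matrix(conf$beads[conf$beads$anchor, c("x", "y", "z")])
  n <- nrow(a)
  msd <- sapply(c(20, 40, 80), function(k) {
    d <- a[(k + 1):n, ] - a[1:(n - k), ]
    mean(rowSums(d^2))
  })
  # MSD proportional to genomic distance (random walk): ratios ~ 2
  expect_lt(abs(msd[2] / msd[1] - 2), 0.5)
  expect_lt(abs(msd[3] / msd[2] - 2), 0.5)
  # imposed end-to-end: 4 um for 100 Mb
  e2e <- sqrt(sum((a[n, ] - a[1, ])^2))
  expect_lt(abs(e2e - 4000) / 4000, 0.05)
  # explicit override, zero-stretch control
  conf0 <- build_periodic_random_walk(loops, pI, 1e8, seed = 4,
                                      end_to_end_um = 0)
  a0 <- as.matrix(conf0$beads[conf0$beads$anchor, c("x", "y", "z")])
  expect_lt(sqrt(sum((a0[nrow(a0), ] - a0[1, ])^2)), 1500)
  # over-stretched walk is rejected
  expect_error(build_periodic_random_walk(loops, pI, 1e8, seed = 5,
                                          end_to_end_um = 500),
               "exceeds")
})

test_that("bypass sister pairs form two condensin axes with interfacial
          cohesin; stall pairs merge into one axis (over seeds)", {
  p <- chromatid_params(loop_kb = 400, gap_nm = 80, turn_mb = Inf,
                        volume_density = 44)
  links <- make_cohesive_links(30, 2, seed = 5)
  l1 <- make_loop_array(3e7, 4e5, seed = 11)
  l2 <- make_loop_array(3e7, 4e5, seed = 12)
  seps <- sapply(1:4, function(sd) {
    sapply(c("bypass", "stall"), function(mode) {
      conf <- build_sister_pair(l1, l2, links, mode, p, 3e7, seed = sd)
      pr <- cross_section_profile(conf)
      xyz <- as.matrix(conf$beads[, c("x", "y", "z")])
      ctr <- sweep(xyz, 2, colMeans(xyz))
      perp <- ctr - (ctr %*% attr(pr, "axis")) %*% t(attr(pr, "axis"))
      u <- drop(perp %*% attr(pr, "direction"))
      b <- conf$beads
      c1 <- median(u[b$anchor & b$chromatid_id == 1])
      c2 <- median(u[b$anchor & b$chromatid_id == 2])
      coh <- median(u[b$link])
      c(sep = abs(c1 - c2), coh_center = abs(coh - (c1 + c2) / 2),
        inner = min(abs(coh - c1), abs(coh - c2)))
    })
  })
  # seps rows 1-3: bypass sep/coh_center/inner; rows 4-6: stall
  for (i in 1:4) {
    sep_b <- seps[1, i]
    sep_s <- seps[4, i]
    expect_gt(sep_b, sep_s)      # bypass separates the axes
    expect_gt(sep_b, 200)
    expect_lt(sep_s, 100)
  }
  # cohesin sits between the two condensin axes in bypass mode
  conf <- build_sister_pair(l1, l2, links, "bypass", p, 3e7, seed = 1)
  pr <- cross_section_profile(conf)
  pk <- attr(pr, "peaks")
  expect_lt(abs(pk["cohesin"]), abs(pk["condensin"]) + 150)
  # zero links: two independent chromatids, no link beads
  conf0 <- build_sister_pair(l1, l2, links[0, ], "bypass", p, 3e7,
                             seed = 2)
  expect_false(any(conf0$beads$link))
  expect_error(build_sister_pair(l1, l2,
                                 data.frame(pos_bp1 = 4e7, pos_bp2 = 4e7),
                                 "bypass", p, 3e7, seed = 1),
               "outside")
})

test_that("cross-section of uniform beads in a cylinder matches the
          analytic chord-length projection", {
  # uniform density in a disk projects to f(x) proportional to
  # sqrt(R^2 - x^2)
  set.seed(9)
  R <- 500
  n <- 60000
  r <- R * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  beads <- data.frame(bead = seq_len(n) - 1L, chromatid_id = 1L,
                      genomic_bp = seq_len(n) * 100,
                      x = r * cos(th), y = r * sin(th),
                      z = runif(n, 0, 5000),
                      anchor = FALSE, link = FALSE,
                      species = NA_character_)
  conf <- structure(list(beads = beads,
                         params = chromatid_params(preset = "condensin_II"),
                         length_bp = n * 100, mode = "straight",
                         loop_array = NULL, bead_bp = 100),
                    class = "conformation")
  pr <- cross_section_profile(conf, markers = list(dna = rep(TRUE, n)),
                              axis = c(0, 0, 1), nbins = 31)
  x <- pr$position_nm
  expected <- sqrt(pmax(R^2 - x^2, 0))
  expected <- expected / sum(expected) / diff(x)[1]
  keep <- abs(x) < 0.9 * R
  expect_lt(max(abs(pr$dna[keep] - expected[keep])) /
              max(expected), 0.1)
})

test_that("condensin scaffold is narrower than the DNA cross-section in the
          condensin II-only model", {
  p <- chromatid_params(preset = "condensin_II")
  loops <- make_loop_array(5e7, 4e5, seed = 7)
  conf <- apply_helical_scaffold(build_bottlebrush(loops, p, 5e7, seed = 7),
                                 p, seed = 7)
  pr <- cross_section_profile(conf)
  fw <- attr(pr, "fwhm")
  expect_lt(fw["condensin"], fw["dna"])
})

test_that("profile warns and widens bins with few annotated beads", {
  p <- chromatid_params(preset = "condensin_II")
  loops <- make_loop_array(2e6, 4e5, seed = 1)
  conf <- build_bottlebrush(loops, p, 2e6, seed = 1)
  expect_warning(cross_section_profile(conf), "fewer than 100")
})
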