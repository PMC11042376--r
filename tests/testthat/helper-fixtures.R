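# Shared, lazily built simulation fixtures (cached across test files).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .fixture_cache)) {
    assign(name, force(expr), .fixture_cache)
  }
  get(name, .fixture_cache)
}

# condensin II-only best-fit ensemble P(s), 20 replicates of 100 Mb
condensin_II_ps <- function() {
  cached("condensin_II_ps", {
    simulate_ps(chromatid_params(preset = "condensin_II"),
                replicates = 20, seed0 = 1, length_mb = 100)
  })
}

# condensin I-only best-fit ensemble P(s), 60 replicates of 100 Mb
condensin_I_ps <- function() {
  cached("condensin_I_ps", {
    simulate_ps(chromatid_params(preset = "condensin_I"),
                replicates = 60, seed0 = 1, length_mb = 100)
  })
}

# small G2 fixture and its equilibrated lattice state
g2_small <- function() {
  cached("g2_small", make_g2_fixture(length_mb = 20, seed = 42))
}

g2_small_state <- function() {
  cached("g2_small_state", g2_equilibrate(g2_small(), seed = 9))
}

# analytic P(s) curve object for estimator unit tests
analytic_ps <- function(p_fun, s_min = 1e4, s_max = 1e8,
                        bins_per_decade = 20) {
  edges <- 10^(seq(log10(s_min), log10(s_max),
                   by = 1 / bins_per_decade))
  s <- sqrt(edges[-1] * edges[-length(edges)])
  p <- p_fun(s)
  p <- p / sum(p)
  structure(list(s_bp = s, p = p, counts = rep(1000, length(s)),
                 possible = rep(1e6, length(s)),
                 bins_per_decade = bins_per_decade,
                 normalization = "unit_sum"),
            class = "ps_curve")
}
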