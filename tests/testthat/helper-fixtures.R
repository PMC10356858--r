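# Shared fixtures. Everything is generated in code; solver fixtures use the
# coarse resolution unless a test is specifically about accuracy.

coarse_sim <- function(power, spot_radius, duration, ambient, ...) {
  simulate_treatment(default_skin_model(),
                     operating_point(power, spot_radius, duration, ambient),
                     spec = coarse_grid_spec(), dt = 5e-3, ...)
}

# the published nine-run orthogonal experiment: factor settings and the
# 20-um target-point temperatures
published_l9_responses <- function() {
  des <- orthogonal_l9()
  des$hpm <- c(44.190, 41.418, 40.320, 54.258, 44.122,
               39.628, 63.521, 44.511, 41.048)
  class(des) <- unique(c("response_table", class(des)))
  des
}

# a quick, accurate surrogate of the synthetic analytic indicators
synthetic_surrogate <- function(n = 40, seed = 7) {
  tab <- fixture_response_table(n = n, seed = seed)
  train_rbf(tab[c("power", "spot_radius", "duration", "ambient")],
            as.matrix(tab[c("hpm", "st")]), design_domain())
}

# cache expensive shared objects across test files
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}
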