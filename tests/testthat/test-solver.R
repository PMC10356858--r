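test_that("steady state respects its limiting cases", {
  m <- default_skin_model()
  g <- build_grid(m, 1.5, coarse_grid_spec())
  # insulated surface: uniform core temperature
  t0 <- steady_state(m, environment_spec(h_conv = 0, ambient = 25), g)
  expect_equal(max(abs(t0 - 37)), 0, tolerance = 1e-9)
  # no ambient gradient: uniform regardless of h
  t1 <- steady_state(m, environment_spec(h_conv = 50, ambient = 37), g)
  expect_equal(max(abs(t1 - 37)), 0, tolerance = 1e-9)
  # cool room: surface between ambient and core, monotone with depth
  t2 <- steady_state(m, environment_spec(ambient = 25), g)
  axis <- t2[1, ]
  expect_gt(axis[1], 25)
  expect_lt(axis[1], 37)
  expect_true(all(diff(axis) >= -1e-9))
})

test_that("a zero-power pulse leaves the steady field untouched", {
  m <- default_skin_model()
  g <- build_grid(m, 1.5, coarse_grid_spec())
  env <- environment_spec(ambient = 25)
  res <- simulate_treatment(m, operating_point(0, 1.5, 0.2, 25), env,
                            grid = g, dt = 5e-3)
  t0 <- steady_state(m, env, g)
  expect_lt(max(abs(res$field - t0)), 1e-6)
  expect_equal(unname(extract_indicators(res)["hpm"]), t0[1, g$probe_index],
               tolerance = 1e-8)
})

test_that("an insulated domain conserves the deposited energy", {
  m <- default_skin_model()
  res <- simulate_treatment(
    m, operating_point(5, 1.5, 0.2, 37),
    environment_spec(h_conv = 0),
    spec = coarse_grid_spec(), dt = 5e-3, bottom_bc = "insulated")
  gain <- res$energy$enthalpy_gain
  dep <- res$energy$deposited
  expect_gt(dep, 0)
  expect_lt(abs(gain - dep) / dep, 0.01)
})

test_that("the axisymmetric solver matches a 1-D Crank-Nicolson oracle", {
  rho <- 1100; cp <- 3400; k <- 0.45
  q0 <- 2e7; mu <- 500; h <- 10; ambient <- 25; core <- 37; dur <- 0.3
  uni <- skin_model(list(tissue_layer("uniform", 2000, rho, cp, k, 0, 0)),
                    core_temperature = core)
  g <- build_grid(uni, 1.5)
  src <- as_source_field(g, function(r, z) q0 * exp(-mu * z))
  res <- simulate_treatment(uni, operating_point(1, 1.5, dur, ambient),
                            environment_spec(h, ambient), grid = g,
                            dt = 1e-3, source = src)
  ora <- oracle_1d_cn(2000e-6, rho, cp, k, q0, mu, h, ambient, core, dur)
  # compare the full axial profile at pulse end (solution is r-independent)
  at <- function(zz, tt, z) approx(z, tt, zz)$y
  probe_z <- c(0, 20e-6, 100e-6, 500e-6, 1500e-6)
  pkg_prof <- at(probe_z, res$field[1, ], g$z)
  ora_prof <- at(probe_z, ora$t_final, ora$z)
  expect_lt(max(abs(pkg_prof - ora_prof)), 0.05)
  # and the initial steady state
  pkg_init <- at(probe_z, res$initial_field[1, ], g$z)
  ora_init <- at(probe_z, ora$t_init, ora$z)
  expect_lt(max(abs(pkg_init - ora_init)), 0.02)
  # radial uniformity of the response to a radially uniform source
  expect_lt(max(abs(res$field[1, ] - res$field[nrow(res$field), ])), 1e-6)
})

test_that("backward Euler and Crank-Nicolson agree at small steps", {
  m <- default_skin_model()
  op <- operating_point(7.5, 1.5, 0.4, 25)
  g <- build_grid(m, 1.5, coarse_grid_spec())
  be <- simulate_treatment(m, op, grid = g, dt = 1e-3,
                           scheme = "backward_euler")
  cn <- simulate_treatment(m, op, grid = g, dt = 1e-3,
                           scheme = "crank_nicolson")
  expect_lt(abs(be$hpm - cn$hpm), 0.05)
  expect_lt(abs(be$st - cn$st), 0.05)
})

test_that("indicators move monotonically with each operating parameter", {
  hpm_of <- function(...) coarse_sim(...)$hpm
  pw <- vapply(c(5, 7.5, 10), function(p) hpm_of(p, 1.5, 0.4, 25), 0)
  expect_true(all(diff(pw) > 0))
  sr <- vapply(c(1, 1.5, 2), function(s) hpm_of(7.5, s, 0.4, 25), 0)
  expect_true(all(diff(sr) < 0))
  du <- vapply(c(0.2, 0.4, 0.6), function(d) hpm_of(7.5, 1.5, d, 25), 0)
  expect_true(all(diff(du) > 0))
  am <- vapply(c(10, 25, 35), function(a) hpm_of(7.5, 1.5, 0.4, a), 0)
  expect_true(all(diff(am) > 0))
})

test_that("the lateral boundary is far enough not to matter", {
  m <- default_skin_model()
  op <- operating_point(10, 1.5, 0.4, 25)
  near <- simulate_treatment(m, op, spec = coarse_grid_spec(), dt = 5e-3)
  sp2 <- coarse_grid_spec(); sp2$r_extent <- 2 * max(near$grid$r)
  far <- simulate_treatment(m, op, spec = sp2, dt = 5e-3)
  expect_lt(abs(near$hpm - far$hpm), 0.05)
  expect_lt(abs(near$st - far$st), 0.05)
})

test_that("indicator extraction is a pure function of the stored traces", {
  res <- coarse_sim(7.5, 1.5, 0.2, 25)
  ind <- extract_indicators(res)
  expect_equal(unname(ind["st"]), res$surface_trace[length(res$surface_trace)])
  expect_equal(unname(ind["hpm"]), max(res$probe_trace))
  expect_equal(unname(ind["hpm"]), res$probe_trace[length(res$probe_trace)])
  expect_gte(ind["hpm"], min(res$field))
  expect_lte(ind["hpm"], max(res$field) + 1e-9)
})
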