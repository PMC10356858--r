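test_that("interval arithmetic ties bounds, midpoint and radius together", {
  a <- interval(1, 3)
  expect_equal(interval_mid(a), 2)
  expect_equal(interval_radius(a), 1)
  b <- interval_from_center(2, 1)
  expect_equal(unclass(b), unclass(a))
  expect_error(interval(3, 1), "lower")
  expect_error(interval_from_center(0, -1), "radius")
})

test_that("the possibility degree reproduces its worked value and features", {
  # direct substitution
  expect_equal(rpdi(interval(1, 3), interval(2, 6)), 5 / 6)
  set.seed(42)
  for (i in 1:1000) {
    lo <- runif(2, -10, 10); a <- interval(min(lo), max(lo))
    hi <- runif(2, -10, 10); b <- interval(min(hi), max(hi))
    q <- rpdi(a, b)
    # complement identity
    expect_equal(rpdi(b, a), 1 - q, tolerance = 1e-12)
    # separated intervals are fully ordered
    if (a$upper <= b$lower) expect_gte(q, 1)
    if (b$upper <= a$lower) expect_lte(q, 0)
  }
  # degenerate scalar pair convention
  expect_equal(rpdi(interval(1, 1), interval(2, 2)), 1)
  expect_equal(rpdi(interval(2, 2), interval(1, 1)), 0)
  expect_equal(rpdi(interval(2, 2), interval(2, 2)), 0.5)
})

test_that("the scalar-threshold degree matches the constraint algebra", {
  expect_equal(rpdi_scalar(interval(50, 52), 52), 1)
  expect_lt(rpdi_scalar(interval(53, 55), 52), 0)
  expect_equal(rpdi_scalar(interval(48.07, 52.00), 52), 1, tolerance = 1e-9)
  expect_equal(rpdi_scalar(interval(40, 40), 52), Inf)
  expect_equal(rpdi_scalar(interval(60, 60), 52), -Inf)
  set.seed(7)
  for (i in 1:500) {
    lo <- sort(runif(2, 30, 70))
    f <- interval(lo[1], lo[2] + 1e-9)
    b <- runif(1, 30, 70)
    p <- rpdi_scalar(f, b)
    expect_equal(p >= 1, f$upper <= b, tolerance = 0)
    expect_equal(p >= 0.5, interval_mid(f) <= b)
  }
})

test_that("design boxes must sit inside the design domain", {
  rad <- c(power = 0.25, spot_radius = 0.05, duration = 0.02, ambient = 1.25)
  mid <- c(power = 9, spot_radius = 1.5, duration = 0.4, ambient = 20)
  box <- design_box(mid, rad)
  expect_equal(unname(box$upper - box$lower), unname(2 * rad))
  bad <- mid; bad["power"] <- 9.9
  expect_error(design_box(bad, rad), "outside the design domain")
})

test_that("response intervals contain a dense grid oracle", {
  sur <- cached("syn_sur", synthetic_surrogate(n = 40, seed = 7))
  rad <- c(power = 0.25, spot_radius = 0.05, duration = 0.02, ambient = 1.25)
  mid <- c(power = 8.2, spot_radius = 1.3, duration = 0.45, ambient = 28)
  box <- design_box(mid, rad)
  for (resp in c("hpm", "st")) {
    got <- response_interval(sur, box, resp)
    # brute-force tensor grid oracle
    grids <- mapply(function(l, u) seq(l, u, length.out = 17),
                    box$lower, box$upper, SIMPLIFY = FALSE)
    g <- as.matrix(expand.grid(grids))
    y <- predict(sur, g)[, resp]
    expect_gte(min(y), got$lower - 1e-6)
    expect_lte(max(y), got$upper + 1e-6)
  }
})

test_that("monotone responses attain their bounds at opposite vertices", {
  lin <- function(x) {
    cbind(hpm = x[, 1], st = 4 * x[, 1] + 2 * x[, 2])
  }
  box <- design_box(c(power = 8, spot_radius = 1.5, duration = 0.4,
                      ambient = 25),
                    c(power = 0.25, spot_radius = 0.05, duration = 0.02,
                      ambient = 1.25))
  got <- response_interval(lin, box, "st")
  expect_equal(got$lower, 4 * 7.75 + 2 * 1.45, tolerance = 1e-8)
  expect_equal(got$upper, 4 * 8.25 + 2 * 1.55, tolerance = 1e-8)
  # a zero-radius box degenerates to the point prediction
  pt <- design_box(c(power = 8, spot_radius = 1.5, duration = 0.4,
                     ambient = 25), rep(0, 4))
  got0 <- response_interval(lin, pt, "st")
  expect_equal(got0$lower, got0$upper)
  expect_equal(got0$lower, 4 * 8 + 2 * 1.5)
})

test_that("the whole-domain sweep shows the surface can overheat", {
  sur <- cached("syn_sur", synthetic_surrogate(n = 40, seed = 7))
  sw <- uncertainty_sweep(sur)
  expect_gt(sw$st$upper, 52)
  expect_gte(sw$st$upper, sw$hpm$upper)
  expect_lt(sw$hpm$lower, 45)
})

test_that("the nested optimizer recovers a known constrained optimum", {
  lin <- function(x) cbind(hpm = x[, 1], st = 4 * x[, 1] + 2 * x[, 2])
  prob <- interval_problem(b = 40, lambda = 1)
  res <- optimize_treatment(prob, lin, ga_config(pop_size = 40,
                                                 generations = 60), seed = 5)
  # analytic optimum: spot radius at its lowest feasible midpoint, then
  # power midpoint from the active constraint 4 p + 2 s + 1.1 = 40
  expect_true(res$feasible)
  expect_equal(unname(res$midpoints["power"]), 9.2, tolerance = 0.01)
  expect_equal(unname(res$midpoints["spot_radius"]), 1.05, tolerance = 0.01)
  expect_lte(res$constraint_interval$upper, 40 + 1e-6)
  expect_equal(res$objective_interval$lower, res$midpoints[["power"]] - 0.25,
               tolerance = 1e-6)
})

test_that("raising the reliability level trades away thermal penetration", {
  sur <- cached("syn_sur", synthetic_surrogate(n = 40, seed = 7))
  mids <- vapply(c(0.9, 1.0, 1.1), function(lam) {
    res <- optimize_treatment(
      interval_problem(lambda = lam),
      sur, ga_config(pop_size = 40, generations = 60), seed = 11)
    if (lam >= 1) expect_lte(res$constraint_interval$upper, 52 + 1e-6)
    interval_mid(res$objective_interval)
  }, numeric(1))
  expect_true(all(diff(mids) <= 1e-6))
})

test_that("optimization runs are reproducible for a fixed seed", {
  lin <- function(x) cbind(hpm = x[, 1], st = 4 * x[, 1] + 2 * x[, 2])
  prob <- interval_problem(b = 40, lambda = 1)
  cfg <- ga_config(pop_size = 20, generations = 15)
  r1 <- optimize_treatment(prob, lin, cfg, seed = 3)
  r2 <- optimize_treatment(prob, lin, cfg, seed = 3)
  expect_identical(r1$midpoints, r2$midpoints)
  expect_identical(r1$history, r2$history)
})
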