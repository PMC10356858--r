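test_that("the L9 array matches the standard table and is orthogonal", {
  des <- orthogonal_l9()
  expect_equal(nrow(des), 9)
  expect_equal(unlist(des[1, ], use.names = FALSE), c(5, 1, 0.2, 10))
  expect_equal(unlist(des[7, ], use.names = FALSE), c(10, 1, 0.6, 25))
  expect_equal(unlist(des[4, ], use.names = FALSE), c(7.5, 1, 0.4, 35))
  lev <- attr(des, "levels")
  # every (factor, level) appears exactly three times
  for (f in colnames(lev)) {
    expect_equal(as.vector(table(lev[, f])), rep(3L, 3))
  }
  # every ordered level pair of any two factors appears exactly once
  for (a in 1:3) {
    for (b in setdiff(1:4, seq_len(a))) {
      combo <- table(lev[, a], lev[, b])
      expect_true(all(combo == 1))
    }
  }
  expect_error(orthogonal_l9(levels = list(power = 1:2)), "four factors")
})

test_that("latin hypercube designs stratify every dimension exactly once", {
  dom <- design_domain()
  for (n in c(12, 50)) {
    des <- optimal_lhs(dom, n, seed = 11)
    expect_equal(nrow(des), n)
    for (f in names(des)) {
      u <- (des[[f]] - dom["lower", f]) /
        (dom["upper", f] - dom["lower", f])
      expect_true(all(u >= 0 & u <= 1))
      strata <- floor(u * n)                  # one point per quantile band
      expect_equal(sort(strata), 0:(n - 1))
    }
  }
  expect_error(optimal_lhs(dom, 1), "at least 2")
})

test_that("the same seed reproduces the same design", {
  a <- optimal_lhs(n = 20, seed = 99)
  b <- optimal_lhs(n = 20, seed = 99)
  expect_identical(a, b)
  c <- optimal_lhs(n = 20, seed = 100)
  expect_false(isTRUE(all.equal(a, c)))
})

test_that("range analysis reproduces the published summary of the printed runs", {
  l9 <- published_l9_responses()
  ra <- range_analysis(l9, "hpm")
  # independent arithmetic straight from the printed responses
  y <- l9$hpm
  lev <- attr(orthogonal_l9(), "levels")
  for (f in colnames(lev)) {
    for (l in 1:3) {
      expect_equal(ra$K[l, f], sum(y[lev[, f] == l]), ignore_attr = TRUE)
    }
  }
  expect_equal(round(ra$level_means[, "spot_radius"], 2),
               c(53.99, 43.35, 40.33), ignore_attr = TRUE)
  expect_equal(round(ra$K[1, "spot_radius"], 2), 161.97, ignore_attr = TRUE)
  expect_equal(round(ra$kbar[1, "spot_radius"], 2), 18.00, ignore_attr = TRUE)
  expect_equal(round(unname(ra$R), 2), c(7.72, 13.66, 6.54, 5.07))
  expect_equal(ra$ranking,
               c("spot_radius", "power", "duration", "ambient"))
  # optimal levels follow the level means (the self-consistent reading)
  expect_equal(ra$optimal_labels, c("A3", "B1", "C3", "D2"),
               ignore_attr = TRUE)
})

test_that("range analysis is location invariant and handles ties", {
  l9 <- published_l9_responses()
  shifted <- l9; shifted$hpm <- shifted$hpm + 100
  expect_equal(range_analysis(shifted)$R, range_analysis(l9)$R)
  flat <- l9; flat$hpm <- rep(5, 9)
  ra <- range_analysis(flat)
  expect_equal(unname(ra$R), rep(0, 4))
  expect_equal(ra$ranking, c("power", "spot_radius", "duration", "ambient"))
})

test_that("variance analysis agrees with a reference ANOVA decomposition", {
  l9 <- published_l9_responses()
  va <- variance_analysis(l9, pooling = "none")
  ss <- setNames(va$table$ss, va$table$factor)
  # independent route: stats::aov on the same saturated design
  df <- data.frame(y = l9$hpm,
                   A = factor(l9$power), B = factor(l9$spot_radius),
                   C = factor(l9$duration), D = factor(l9$ambient))
  ref <- summary(stats::aov(y ~ A + B + C + D, data = df))[[1]][, "Sum Sq"]
  expect_equal(unname(ss), unname(ref[1:4]), tolerance = 1e-8)
  expect_equal(unname(ss["spot_radius"]), 308.8, tolerance = 1e-3)
  expect_equal(unname(ss["power"]), 89.4, tolerance = 1e-2)
  # saturated identity: factor SS sum to the total SS
  expect_equal(sum(ss), va$ss_total, tolerance = 1e-8)
  # influence ranking
  expect_equal(names(sort(-ss)),
               c("spot_radius", "power", "duration", "ambient"))
  # pooled F uses the smallest factor as error
  vp <- variance_analysis(l9)
  expect_equal(vp$pooled, "ambient")
  expect_true(all(is.na(vp$table$F[vp$table$factor == "ambient"])))
  flat <- l9; flat$hpm <- rep(5, 9)
  expect_equal(variance_analysis(flat, pooling = "none")$table$ss, rep(0, 4))
})

test_that("single-factor sweeps hold the base point and track monotone trends", {
  tab <- single_factor_sweep(factor = "power", values = c(5, 7.5, 10),
                             spec = coarse_grid_spec(), dt = 5e-3)
  expect_equal(tab$spot_radius, rep(1.5, 3))
  expect_equal(tab$ambient, rep(25, 3))
  expect_true(all(diff(tab$hpm) > 0))
  traces <- attr(tab, "traces")
  expect_length(traces, 3)
  expect_true(all(c("time", "probe", "surface") %in% names(traces[[1]])))

  down <- single_factor_sweep(factor = "spot_radius", values = c(1, 1.5, 2),
                              spec = coarse_grid_spec(), dt = 5e-3)
  expect_true(all(diff(down$hpm) < 0))

  empty <- single_factor_sweep(factor = "duration", values = numeric(0))
  expect_equal(nrow(empty), 0)
  expect_warning(
    single_factor_sweep(factor = "power", values = 12,
                        spec = coarse_grid_spec(), dt = 5e-3),
    "outside the design domain")
})

test_that("analysis functions reject malformed designs", {
  bad <- published_l9_responses()[1:8, ]
  expect_error(range_analysis(bad), "9-run")
  notlev <- published_l9_responses()
  notlev$power[1] <- 6
  expect_error(range_analysis(notlev), "3 levels")
  noresp <- orthogonal_l9()
  expect_error(range_analysis(noresp), "not found")
})
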