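test_that("the RBF network interpolates its training data as ridge -> 0", {
  tab <- fixture_response_table(n = 12, seed = 3)
  x <- tab[c("power", "spot_radius", "duration", "ambient")]
  y <- as.matrix(tab[c("hpm", "st")])
  sur <- train_rbf(x, y, design_domain(), ridge = 1e-12)
  pred <- predict(sur, x)
  expect_lt(max(abs(pred - y) / abs(y)), 1e-8)
})

test_that("error metrics follow their definitions on a hand-worked case", {
  em <- error_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(em$sse, 1)
  expect_equal(em$sst, 2)
  expect_equal(em$r2, 0.5)
  expect_equal(em$rmse, sqrt(1 / 3))
  expect_equal(em$re, c(0, 0, -1 / 3))     # positive = under-prediction
  expect_equal(em$k, 3)

  perfect <- error_metrics(c(2, 4), c(2, 4))
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)

  withzero <- error_metrics(c(0, 1, 2), c(0.1, 1, 2))
  expect_equal(withzero$excluded, 1L)
  expect_true(is.na(withzero$re[1]))
  expect_error(error_metrics(numeric(0), numeric(0)), "k must")
})

test_that("training is equivariant to affine input rescaling", {
  tab <- fixture_response_table(n = 15, seed = 5)
  x <- as.matrix(tab[c("power", "spot_radius", "duration", "ambient")])
  y <- tab$hpm
  dom <- design_domain()
  s1 <- train_rbf(x, y, dom)
  # rescale: power in kW, duration in ms
  scale <- c(1e-3, 1, 1e3, 1)
  x2 <- sweep(x, 2, scale, `*`)
  dom2 <- design_domain(power = c(5, 10) * 1e-3,
                        duration = c(0.2, 0.6) * 1e3)
  s2 <- train_rbf(x2, y, dom2)
  probe <- as.matrix(fixture_response_table(n = 8, seed = 9)[
    c("power", "spot_radius", "duration", "ambient")])
  p1 <- predict(s1, probe)
  p2 <- predict(s2, sweep(probe, 2, scale, `*`))
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("degenerate and malformed inputs are handled", {
  tab <- fixture_response_table(n = 10, seed = 2)
  x <- tab[c("power", "spot_radius", "duration", "ambient")]
  sur <- train_rbf(x, rep(41.5, 10), design_domain())
  expect_true(sur$constant)
  expect_equal(unname(predict(sur, x[3, ])[1, 1]), 41.5, tolerance = 1e-6)
  expect_true(is.na(error_metrics(rep(41.5, 10),
                                  predict(sur, x)[, 1])$r2))
  xdup <- rbind(x[1, ], x)
  expect_error(train_rbf(xdup, c(50, 40 + seq_len(10))), "conflicting")
  expect_error(train_rbf(x[1:4, ], 1:4), "at least 5")
  expect_warning(predict(sur, data.frame(power = 30, spot_radius = 1.5,
                                         duration = 0.4, ambient = 25)),
                 "outside the design domain")
})

test_that("surrogates survive a JSON round trip", {
  tab <- fixture_response_table(n = 12, seed = 4)
  sur <- train_rbf(tab[c("power", "spot_radius", "duration", "ambient")],
                   as.matrix(tab[c("hpm", "st")]), design_domain())
  path <- withr::local_tempfile(fileext = ".json")
  save_surrogate(sur, path)
  sur2 <- load_surrogate(path)
  probe <- fixture_response_table(n = 6, seed = 8)[
    c("power", "spot_radius", "duration", "ambient")]
  expect_equal(predict(sur, probe), predict(sur2, probe), tolerance = 1e-12)
})

test_that("the surrogate generalizes to held-out points of a smooth surface", {
  sur <- synthetic_surrogate(n = 40, seed = 7)
  held <- fixture_response_table(n = 10, seed = 21)
  pred <- predict(sur, held[c("power", "spot_radius", "duration", "ambient")])
  expect_lt(max(abs(pred[, "hpm"] - held$hpm)), 0.5)
  expect_lt(max(abs(pred[, "st"] - held$st)), 0.5)
})
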