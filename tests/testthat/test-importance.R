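test_that("VIF matches the closed form and flags exact collinearity", {
  set.seed(121)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  v <- vif(cbind(a = x1, b = x2))
  expect_equal(unname(v), c(1, 1), tolerance = 0.15)

  # construct a pair with sample correlation exactly 0.9
  x2r <- residuals(lm(x2 ~ x1))
  x2c <- 0.9 * scale(x1)[, 1] + sqrt(1 - 0.81) * scale(x2r)[, 1]
  x <- cbind(x1 = scale(x1)[, 1], x2 = x2c)
  expect_equal(cor(x)[1, 2], 0.9, tolerance = 1e-10)
  expect_equal(unname(vif(x)), rep(1 / (1 - 0.81), 2), tolerance = 1e-3)

  coll <- cbind(x1 = x1, x2 = 2 * x1)
  expect_true(all(is.infinite(vif(coll))))

  expect_error(vif(cbind(a = x1, b = rep(1, n))), "constant column.*b")
  expect_error(vif(matrix(rnorm(5), 5, 1)), "at least 2")
})

test_that("VIF equals the auxiliary-regression oracle on random designs", {
  set.seed(131)
  for (i in 1:25) {
    p <- sample(3:6, 1L)
    n <- 40
    x <- matrix(rnorm(n * p), n, p)
    x[, 1] <- x[, 1] + 0.8 * x[, 2]  # induce some collinearity
    expect_equal(unname(vif(x)), oracle_vif(x), tolerance = 1e-8)
  }
})

test_that("AIC stage discards pure noise and VIF stage breaks collinear pairs", {
  set.seed(141)
  n <- 200
  keeps <- 0L
  signal_kept <- 0L
  for (r in 1:100) {
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- x1 + rnorm(n)
    d <- data.frame(y = y, x1 = x1, x2 = x2)
    pr <- prune_predictors(d, model_spec("y", c("x1", "x2"), seed = r))
    signal_kept <- signal_kept + ("x1" %in% pr$retained)
    keeps <- keeps + ("x1" %in% pr$retained && !("x2" %in% pr$retained))
  }
  expect_equal(signal_kept, 100L)  # the true driver always survives
  # a pure-noise predictor survives AIC backward elimination only when its
  # t^2 exceeds 2 (~16% of draws), so ~84% of replicates drop it
  expect_gte(keeps, 70L)

  x1 <- rnorm(n)
  x3 <- x1 + rnorm(n, 0, 0.01)
  y <- x1 + rnorm(n)
  d <- data.frame(y = y, x1 = x1, x3 = x3)
  pr <- prune_predictors(d, model_spec("y", c("x1", "x3"), seed = 1))
  dropped_any <- nrow(pr$dropped) >= 1L
  expect_true(dropped_any)
  expect_equal(length(pr$retained), 1L)

  single <- prune_predictors(data.frame(y = y, x1 = x1),
                             model_spec("y", "x1", seed = 1))
  expect_equal(single$retained, "x1")
  expect_equal(nrow(single$dropped), 0L)
})

test_that("pruning is deterministic and validates its inputs", {
  set.seed(151)
  d <- data.frame(y = rnorm(30), a = rnorm(30), b = rnorm(30))
  s <- model_spec("y", c("a", "b"), seed = 5)
  expect_identical(prune_predictors(d, s), prune_predictors(d, s))
  tiny <- d[1:5, ]
  expect_error(prune_predictors(tiny, s), "at least 10")
})

test_that("forest importance is normalised to 1 and recovers the signal", {
  set.seed(161)
  n <- 300
  hits <- 0L
  for (r in 1:20) {
    x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
    y <- 3 * x1 + rnorm(n)
    d <- data.frame(y = y, x1 = x1, x2 = x2, x3 = x3)
    s <- model_spec("y", c("x1", "x2", "x3"), seed = r)
    imp <- rf_importance(d, c("x1", "x2", "x3"), s)$importance
    expect_equal(max(imp), 1)
    hits <- hits + (imp[["x1"]] == 1 && imp[["x2"]] < 0.3 && imp[["x3"]] < 0.3)
  }
  expect_equal(hits, 20L)

  # symmetric contributions share the importance
  x1 <- rnorm(n); x2 <- rnorm(n)
  d <- data.frame(y = x1 + x2, x1 = x1, x2 = x2)
  imp <- rf_importance(d, c("x1", "x2"),
                       model_spec("y", c("x1", "x2"), seed = 9))$importance
  expect_true(all(imp > 0.5))
})

test_that("forest importance is reproducible for a fixed seed", {
  set.seed(171)
  d <- data.frame(y = rnorm(50), a = rnorm(50), b = rnorm(50))
  s <- model_spec("y", c("a", "b"), seed = 7)
  r1 <- rf_importance(d, c("a", "b"), s)
  r2 <- rf_importance(d, c("a", "b"), s)
  expect_identical(r1$importance, r2$importance)
  expect_identical(r1$residuals, r2$residuals)
})

test_that("a response leaked as predictor is flagged and dominates", {
  set.seed(181)
  n <- 100
  y <- rnorm(n)
  d <- data.frame(y = y, leak = y, x = rnorm(n))
  s <- model_spec("y", c("leak", "x"), seed = 3)
  expect_warning(imp <- rf_importance(d, c("leak", "x"), s)$importance,
                 "identical to the response")
  expect_equal(imp[["leak"]], 1)
})

test_that("Moran's I matches the naive double-loop evaluation on fixtures", {
  # 1D transect, 12 points spaced ~0.1 degree apart along a meridian
  n <- 12
  lat <- 30 + 0.1 * (0:(n - 1))
  lon <- rep(100, n)
  set.seed(191)
  vals <- rnorm(n)
  res <- morans_i(vals, lon, lat, n_classes = 2, n_perm = 49, seed = 1)
  d <- geosphere::distm(cbind(lon, lat))
  for (k in seq_len(nrow(res))) {
    w <- (d > 0) & (d >= res$d_min[k] - 1e-9) & (d <= res$d_max[k] + 1e-9)
    expect_equal(res$I[k], oracle_morans_i(vals, w), tolerance = 1e-12)
  }
})

test_that("alternating transect values give I = -1 in the nearest class", {
  n <- 12
  lat <- 30 + 0.1 * (0:(n - 1))
  lon <- rep(100, n)
  vals <- rep(c(1, -1), n / 2)
  res <- morans_i(vals, lon, lat, n_classes = 6, n_perm = 19, seed = 1)
  # first equal-count class holds exactly the 11 nearest-neighbour pairs
  expect_equal(res$n_pairs[1], 11L)
  expect_equal(res$I[1], -1, tolerance = 1e-12)
})

test_that("a smooth gradient shows significant positive autocorrelation", {
  n <- 20
  lat <- 30 + 0.1 * (0:(n - 1))
  lon <- rep(100, n)
  res <- morans_i(seq_len(n), lon, lat, n_classes = 4, n_perm = 199, seed = 2)
  expect_gt(res$I[1], 0)
  expect_lte(res$p_value[1], 0.05)
})

test_that("permutation null of Moran's I centres on -1/(n-1)", {
  set.seed(201)
  n <- 30
  lon <- runif(n, 82, 130)
  lat <- runif(n, 19, 52)
  vals <- rnorm(n)
  d <- geosphere::distm(cbind(lon, lat))
  pair <- which(upper.tri(d), arr.ind = TRUE)
  dd <- d[pair]
  w <- (d >= min(dd)) & (d <= quantile(dd, 0.3)) & d > 0
  perm_i <- replicate(999, {
    p <- sample.int(n)
    oracle_morans_i(vals[p], w)
  })
  expect_lt(abs(mean(perm_i) - (-1 / (n - 1))), 0.02)
})

test_that("Moran's I rejects degenerate inputs", {
  lat <- 30 + 0.1 * (0:11); lon <- rep(100, 12)
  expect_error(morans_i(rep(1, 12), lon, lat), "constant")
  expect_error(morans_i(rnorm(5), lon[1:5], lat[1:5]), "n >= 10")
})

test_that("the composed importance stage records every decision", {
  set.seed(211)
  n <- 120
  lat <- runif(n, 19, 52); lon <- runif(n, 82, 130)
  x1 <- -lat + rnorm(n, 0, 2)   # the driver follows a latitudinal gradient
  x2 <- rnorm(n)
  x3 <- x1 + rnorm(n, 0, 0.05)  # collinear shadow of the driver
  y <- 2 * x1 + rnorm(n)
  d <- data.frame(y = y, x1 = x1, x2 = x2, x3 = x3, lon = lon, lat = lat)
  s <- model_spec("y", c("x1", "x2", "x3"), seed = 4, n_perm = 99)
  rep <- run_importance_stage(d, s)
  expect_setequal(c(rep$retained, rep$dropped$predictor),
                  c("x1", "x2", "x3"))
  expect_equal(max(rep$importance), 1)
  expect_true(all(rep$dropped$reason %in% c("AIC", "VIF")))
  expect_equal(rep$seed, 4L)

  # spatially unstructured residuals are declared independent in most seeds
  flags <- vapply(1:10, function(r) {
    yr <- rnorm(n)
    dr <- data.frame(y = yr, x1 = rnorm(n), x2 = rnorm(n),
                     lon = lon, lat = lat)
    sr <- model_spec("y", c("x1", "x2"), seed = r, n_perm = 999)
    suppressWarnings(run_importance_stage(dr, sr)$residuals_independent)
  }, logical(1L))
  expect_gte(sum(flags), 9L)
})
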