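make_stack <- function(..., nr = NULL) {
  vals <- list(...)
  n <- length(vals[[1]])
  if (is.null(nr)) nr <- n
  climate_stack(lapply(vals, function(v)
    grid_raster(matrix(v, nrow = nr))))
}

test_that("standardized PCA matches a direct eigendecomposition", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3)
  st <- make_stack(a = X[, 1], b = X[, 2], c = X[, 3])
  p <- fit_pca(st)
  ev <- eigen(cor(X))
  expect_equal(p$sdev^2, ev$values, tolerance = 1e-10)
  expect_equal(abs(p$loadings), abs(ev$vectors), tolerance = 1e-10,
               ignore_attr = TRUE)
  # orthonormal loadings; back-projection reproduces standardized inputs
  expect_equal(crossprod(p$loadings), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  sc <- pca_transform(p, st)
  S <- sapply(sc$layers, function(l) as.vector(l$values))
  Z <- scale(X)
  expect_lt(max(abs(S %*% t(p$loadings) - Z)), 1e-8)
  # scores are centred with variances equal to the eigenvalues
  expect_equal(colMeans(S), rep(0, 3), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(apply(S, 2, stats::var), ev$values, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("perfectly correlated layers put zero variance on the last PC", {
  v <- rnorm(12)
  st <- make_stack(a = v, b = 2 * v + 1)
  p <- fit_pca(st)
  expect_equal(p$sdev[2], 0, tolerance = 1e-10)
  st_const <- make_stack(a = v, b = rep(1, 12))
  expect_warning(fit_pca(st_const), "constant layer")
})

test_that("VIF filtering removes collinear layers worst-first", {
  set.seed(2)
  a <- rnorm(100); b <- rnorm(100); c_ <- rnorm(100)
  # orthogonal-ish layers: all retained
  st <- make_stack(a = a, b = b, c = c_)
  keep <- vif_filter(st, threshold = 3)
  expect_setequal(keep, c("a", "b", "c"))
  expect_true(all(attr(keep, "vif") < 3))
  # duplicate pair: exactly one of the pair removed
  st2 <- make_stack(a = a, a2 = a, b = b)
  keep2 <- vif_filter(st2, threshold = 3)
  expect_length(intersect(keep2, c("a", "a2")), 1)
  expect_true("b" %in% keep2)
  # VIF = 1/(1-R^2) matches a per-layer regression oracle
  d <- a + 0.5 * b + rnorm(100, sd = 0.6)
  st3 <- make_stack(a = a, b = b, d = d)
  v <- attr(vif_filter(st3, threshold = 100), "vif")
  r2 <- summary(lm(d ~ a + b))$r.squared
  expect_equal(unname(v["d"]), 1 / (1 - r2), tolerance = 1e-8)
})

test_that("MESS similarity follows the percentile definition", {
  ref <- data.frame(v = 1:10)
  tg <- make_stack(v = c(2, 5.5, 0.5, 11, 10))
  names(tg$layers) <- "v"
  m <- mess(ref, tg)
  vals <- as.vector(m$per_variable$v$values)
  # f = 10% below 2 -> 2f = 20; median -> 100; outside range -> negative
  expect_equal(vals[1], 20)
  expect_equal(vals[2], 100)
  expect_lt(vals[3], 0)
  expect_lt(vals[4], 0)
  # at the maximum: f = 90 -> 2(100-90) = 20
  expect_equal(vals[5], 20)
  # brute-force percentile oracle on random targets
  set.seed(3)
  t_rand <- runif(50, -2, 13)
  oracle <- vapply(t_rand, function(ti) {
    f <- 100 * sum(ref$v < ti) / 10
    if (f == 0) 100 * (ti - 1) / 9
    else if (f <= 50) 2 * f
    else if (f < 100) 2 * (100 - f)
    else 100 * (10 - ti) / 9
  }, numeric(1))
  tg2 <- make_stack(v = t_rand); names(tg2$layers) <- "v"
  expect_equal(as.vector(mess(ref, tg2)$per_variable$v$values), oracle)
})

test_that("MESS map is the per-cell minimum and never exceeds 100", {
  set.seed(4)
  ref <- data.frame(a = rnorm(30), b = runif(30))
  tg <- make_stack(a = rnorm(25), b = runif(25, -1, 2))
  names(tg$layers) <- c("a", "b")
  m <- mess(ref, tg)
  expect_equal(m$minimum$values,
               pmin(m$per_variable$a$values, m$per_variable$b$values))
  expect_true(all(m$minimum$values <= 100))
  neg <- m$minimum$values < 0
  out_a <- tg$layers$a$values < min(ref$a) | tg$layers$a$values > max(ref$a)
  out_b <- tg$layers$b$values < min(ref$b) | tg$layers$b$values > max(ref$b)
  expect_equal(neg, out_a | out_b)
})

test_that("MESS screening drops variables by mean out-of-range proportion", {
  ref <- data.frame(v = 1:10)
  bin1 <- make_stack(v = c(rep(5, 9), 20), nr = 2)   # 10% out of range
  bin2 <- make_stack(v = c(rep(5, 13), rep(20, 7)), nr = 4) # 35%
  names(bin1$layers) <- names(bin2$layers) <- "v"
  maps <- list(mess(ref, bin1), mess(ref, bin2))
  sc <- screen_variables_by_mess(maps, cutoff = 0.20)
  expect_equal(sc$mean_out_of_range, 0.225)
  expect_false(sc$retained)
  # in-range everywhere -> retained; fully out -> dropped
  all_in <- make_stack(v = rep(5, 8), nr = 2); names(all_in$layers) <- "v"
  all_out <- make_stack(v = rep(50, 8), nr = 2); names(all_out$layers) <- "v"
  expect_true(screen_variables_by_mess(list(mess(ref, all_in)))$retained)
  expect_false(screen_variables_by_mess(list(mess(ref, all_out)))$retained)
})

test_that("block aggregation averages blocks and respects missing cells", {
  r <- grid_raster(matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(aggregate_raster(r, 2)$values, matrix(2.5, 1, 1))
  expect_identical(aggregate_raster(r, 1), r)
  expect_equal(aggregate_raster(r, 2)$cell_size, 2)
  # randomized 6x6 vs a mean-pooling oracle
  set.seed(5)
  m <- matrix(rnorm(36), 6, 6)
  agg <- aggregate_raster(grid_raster(m), 3)$values
  oracle <- matrix(NA_real_, 2, 2)
  for (i in 1:2) for (j in 1:2)
    oracle[i, j] <- mean(m[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)])
  expect_equal(agg, oracle)
  # missing cells are ignored within blocks
  m[1, 1] <- NA
  agg2 <- aggregate_raster(grid_raster(m), 3)$values
  expect_equal(agg2[1, 1], mean(m[1:3, 1:3], na.rm = TRUE))
  expect_error(aggregate_raster(grid_raster(m), 10), "exceeds")
})
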