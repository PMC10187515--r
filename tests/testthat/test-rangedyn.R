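test_that("MUT equals the brute-force threshold-by-bin scan", {
  # spec toys
  mk <- function(...) grid_raster(matrix(c(...), 1))
  expect_equal(compute_mut(list(mk(0.1, 0.30), mk(0.2, 0.60),
                                mk(0.5, 0.90)))$mut, 0.30)
  expect_equal(compute_mut(list(mk(1, 1, 1)))$mut, 1)
  expect_error(compute_mut(list(mk(0.005), mk(0.9))), "null range")
  # randomized instances vs a double loop over thresholds x bins
  set.seed(1)
  ths <- seq(0.01, 1, by = 0.01)
  for (i in 1:50) {
    maps <- lapply(seq_len(sample(2:6, 1)), function(j)
      grid_raster(matrix(runif(12, 0.02, 1), 3, 4)))
    oracle <- 0
    for (t in ths) {
      ok <- TRUE
      for (m in maps) if (!any(m$values >= t)) { ok <- FALSE; break }
      if (ok) oracle <- max(oracle, t)
    }
    expect_equal(compute_mut(maps)$mut, oracle)
  }
})

test_that("binarized area is monotone in the threshold and counts cells", {
  m <- grid_raster(matrix(c(0.2, 0.6, 0.7, 0.4), 2, 2), cell_size = 2)
  b <- binarize_range(m, 0.5)
  expect_equal(sum(b$mask), 2)
  expect_equal(b$area, 2 * 4)          # cells x cell_size^2
  expect_equal(binarize_range(m, 0.71)$area, 0)
  set.seed(2)
  r <- random_hsi(6, 6, seed = 2)
  areas <- vapply(seq(0.05, 1, 0.05), function(t) binarize_range(r, t)$area,
                  numeric(1))
  expect_true(all(diff(areas) <= 0))
  expect_error(binarize_range(m, 0), "in \\(0, 1\\]")
})

test_that("GB/GW partition conserves the range and puts 0.5 in GW", {
  m <- grid_raster(matrix(c(0.4, 0.6, 0.5, 0.9), 2, 2))
  b <- binarize_range(m, 0.3)
  s <- gb_gw_split(m, b$mask)
  expect_equal(s$gb_area + s$gw_area, b$area)
  expect_equal(s$gb_area, 2)   # 0.6 and 0.9
  expect_equal(s$gw_area, 2)   # 0.4 and 0.5 (boundary cell is GW)
  r <- random_hsi(7, 7, seed = 3)
  br <- binarize_range(r, 0.2)
  sr <- gb_gw_split(r, br$mask)
  expect_equal(sr$gb_area + sr$gw_area, br$area)
  expect_equal(gb_gw_split(m, matrix(FALSE, 2, 2)),
               list(gb_area = 0, gw_area = 0, expansion = FALSE))
})

test_that("bin-vs-present comparison flags match exact rank-sum enumeration", {
  same <- compare_bin_to_present(c(0.3, 0.5, 0.7), c(0.3, 0.5, 0.7))
  expect_true(same$similar); expect_false(same$better)
  # disjoint samples, n1 = n2 = 4: one-sided exact p = 1 / choose(8, 4)
  hi <- c(0.9, 0.92, 0.94, 0.96); lo <- c(0.1, 0.12, 0.14, 0.16)
  cmp <- compare_bin_to_present(hi, lo)
  expect_true(cmp$better)
  expect_equal(cmp$p_greater, 1 / choose(8, 4))
  # exact-permutation oracle for n1 = n2 = 5
  set.seed(4)
  a <- round(runif(5), 3); b <- round(runif(5), 3) + 1e-4  # no ties
  obs <- sum(rank(c(a, b))[1:5])
  combs <- combn(10, 5)
  stats <- apply(combs, 2, function(idx) sum(rank(c(a, b))[idx]))
  p_oracle <- mean(stats >= obs)
  expect_equal(compare_bin_to_present(a, b)$p_greater, p_oracle)
  expect_equal(compare_bin_to_present(rep(1, 3), rep(1, 4))$p_greater, 1)
})

test_that("Brown-Forsythe equals ANOVA on absolute deviations from medians", {
  a <- c(1, 2, 1, 5, 5, 6); b <- c(3, 3, 4, 3, 3, 9)
  bf <- brown_forsythe(a, b)
  z <- c(abs(a - median(a)), abs(b - median(b)))
  g <- factor(rep(c("a", "b"), each = 6))
  oracle <- summary(aov(z ~ g))[[1]]
  expect_equal(bf$statistic, oracle$`F value`[1], tolerance = 1e-12)
  expect_equal(bf$p_value, oracle$`Pr(>F)`[1], tolerance = 1e-12)
  # larger spread in one group drives the statistic up (power check)
  set.seed(5)
  pow <- mean(replicate(200, {
    x <- rnorm(100); y <- rnorm(100, sd = 2)
    brown_forsythe(x, y)$p_value < 0.05
  }))
  expect_gt(pow, 0.9)
  expect_error(brown_forsythe(c(1, 1), c(2, 2)), "undefined")
  expect_error(brown_forsythe(1, c(1, 2)), "at least 2")
})

test_that("trend fitting keeps OLS for uncorrelated residuals", {
  set.seed(6)
  y <- rnorm(80); x <- rnorm(80)
  tf <- fit_trend(y, x)
  expect_equal(tf$family, "OLS")
  expect_equal(tf$slope, unname(coef(lm(y ~ x))[2]))
  expect_error(fit_trend(y[1:10], x[1:10]), "at least 20")
  expect_error(fit_trend(c(y[-1], Inf), x), "non-finite")
})

test_that("OLS slope confidence intervals cover zero under the null", {
  set.seed(7)
  cover <- replicate(200, {
    y <- rnorm(60); x <- rnorm(60)
    tf <- fit_trend(y, x)
    abs(tf$slope) < qt(0.975, 58) * tf$slope_se
  })
  expect_gte(mean(cover), 0.90)
})

test_that("ARIMA-error regression recovers the slope under AR(1) noise", {
  set.seed(8)
  n <- 600
  e <- as.numeric(arima.sim(list(ar = 0.7), n))
  x <- rnorm(n)
  y <- -0.1 * x + e
  tf <- suppressWarnings(fit_trend(y, x))
  expect_equal(tf$family, "ARIMA")
  expect_lt(abs(tf$slope + 0.1), 0.05)
  expect_true(all(c("residual-AR", "auto-grid") %in% tf$candidates$strategy))
  expect_equal(tf$aic, min(tf$candidates$aic))
})

test_that("the range series assembles per-bin accounting correctly", {
  mk_map <- function(v, t) structure(
    list(hsi = grid_raster(matrix(v, 2, 2)), time_label = t,
         scenario = NULL), class = "suitability_map")
  past <- list(mk_map(c(0.9, 0.6, 0.3, 0.2), 10),
               mk_map(c(0.8, 0.75, 0.7, 0.1), 20))
  present <- mk_map(c(0.85, 0.55, 0.4, 0.3), 0)
  alt <- grid_raster(matrix(c(4, 3, 2, 1), 2, 2))
  rs <- build_range_series(past, present, altitude = alt,
                           temperature = c(10, 8))
  expect_equal(nrow(rs), 2)
  mut <- attr(rs, "mut")
  expect_equal(mut, compute_mut(c(past, list(present)))$mut)
  expect_equal(rs$range_area[1],
               binarize_range(past[[1]], mut)$area)
  expect_equal(rs$gb_area + rs$gw_area, rs$range_area)
  expect_equal(rs$mean_temperature, c(10, 8))
  m1 <- binarize_range(past[[1]], mut)$mask
  expect_equal(rs$mean_altitude[1], mean(alt$values[m1]))
})
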