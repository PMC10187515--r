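# Independent recursive flood-fill oracle for patch labelling.
flood_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc); nxt <- 0L
  fill <- function(r, c, id) {
    if (r < 1 || r > nr || c < 1 || c > nc) return()
    if (!mask[r, c] || lab[r, c] != 0L) return()
    lab[r, c] <<- id
    fill(r - 1, c, id); fill(r + 1, c, id)
    fill(r, c - 1, id); fill(r, c + 1, id)
  }
  for (r in seq_len(nr)) for (c in seq_len(nc))
    if (mask[r, c] && lab[r, c] == 0L) { nxt <- nxt + 1L; fill(r, c, nxt) }
  lab
}

test_that("HSI classification uses the printed class boundaries", {
  g <- grid_raster(matrix(c(0.1, 0.25, 0.49, 0.5, 0.74, 0.75, 1, NA, 0), 3, 3))
  cm <- classify_hsi(g)
  expect_equal(as.vector(cm$classes)[1:7], c(1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_true(is.na(cm$classes[2, 3]))
  counts <- table(cm$classes)
  expect_equal(sum(counts), sum(!is.na(g$values)))
})

test_that("patch labelling equals the flood-fill oracle on random grids", {
  set.seed(1)
  for (i in 1:20) {
    mask <- matrix(runif(64) < 0.45, 8, 8)
    lab <- label_patches(mask)
    oracle <- flood_oracle(mask)
    # same partition: identical up to label permutation
    expect_equal(max(lab), max(oracle))
    if (max(lab) > 0) {
      key <- paste(lab[mask], oracle[mask])
      expect_equal(length(unique(key)), max(lab))
    }
  }
})

test_that("toy landscapes reproduce hand-computed metric values", {
  # one patch covering everything: np = 1, division = 0, cohesion = 100
  full <- patch_metrics(classify_hsi(grid_raster(matrix(0.9, 4, 4))), 4)
  expect_equal(full$np, 1)
  expect_equal(full$division, 0)
  expect_equal(full$ai, 100)
  expect_equal(full$cohesion, 100)
  # checkerboard: no like adjacencies -> ai = 0
  v <- matrix(0.1, 8, 8); v[(row(v) + col(v)) %% 2 == 0] <- 0.9
  chk <- patch_metrics(classify_hsi(grid_raster(v)), 4)
  expect_equal(chk$ai, 0)
  expect_equal(chk$np, 32)
  # 2x2 block in a 4x4 grid: np = 1, area_mn = 4 cells, ai = 100
  b <- matrix(0.1, 4, 4); b[2:3, 2:3] <- 0.9
  blk <- patch_metrics(classify_hsi(grid_raster(b)), 4)
  expect_equal(blk$np, 1)
  expect_equal(blk$area_mn, 4)
  expect_equal(blk$ai, 100)
  # absent class -> np = 0, other metrics flagged NA
  absent <- patch_metrics(classify_hsi(grid_raster(matrix(0.1, 3, 3))), 4)
  expect_equal(absent$np, 0)
  expect_true(is.na(absent$area_mn))
})

test_that("metric ranges hold on randomized class maps", {
  set.seed(2)
  for (i in 1:15) {
    cm <- classify_hsi(random_hsi(9, 9, seed = i))
    met <- landscape_metrics(cm)
    ok <- !is.na(met$ai)
    expect_true(all(met$ai[ok] >= 0 & met$ai[ok] <= 100))
    ok <- !is.na(met$clumpy)
    expect_true(all(met$clumpy[ok] >= -1 & met$clumpy[ok] <= 1))
    ok <- !is.na(met$cohesion)
    expect_true(all(met$cohesion[ok] >= 0 & met$cohesion[ok] <= 100))
    ok <- !is.na(met$division)
    expect_true(all(met$division[ok] >= 0 & met$division[ok] <= 1))
    expect_true(all(met$np >= 0))
  }
})

perm_records <- function(n_per_cell = 4, effect = 0, seed = 1) {
  set.seed(seed)
  grid <- tidyr::expand_grid(
    emulator = c("E1", "E2"), period = c("P1", "P2"),
    ssp = c("S1", "S2"), rep = seq_len(n_per_cell))
  n <- nrow(grid)
  dplyr::mutate(grid,
    class = rep(2:3, length.out = n),
    np = exp(rnorm(n) + effect * (emulator == "E2")),
    area_mn = exp(rnorm(n)), ai = runif(n, 40, 90),
    clumpy = runif(n, -0.2, 0.8), cohesion = runif(n, 50, 99),
    division = rep(0.5, n))
}

test_that("univariate single-factor PerMANOVA equals the classical ANOVA F", {
  set.seed(3)
  dat <- tibble::tibble(
    emulator = rep(c("A", "B", "C"), each = 8),
    period = rep(c("P1", "P2"), 12),
    ssp = "S1", class = 2,
    np = exp(rnorm(24, mean = rep(c(0, 0.8, 1.6), each = 8))),
    area_mn = 1, ai = 1, clumpy = 0.1, cohesion = 1, division = 0.5)
  res <- permanova_two_way(dat, metrics = "np", factors = "emulator",
                           strata = "ssp", n_perm = 99, seed = 1)
  f_perm <- res$table$pseudo_f[res$table$term == "emulator"]
  f_aov <- summary(aov(log10(np) ~ emulator, data = dat))[[1]]$`F value`[1]
  expect_equal(f_perm, f_aov, tolerance = 1e-10)
})

test_that("identical responses give a zero pseudo-F", {
  dat <- perm_records(seed = 4)
  dat$np <- 2; dat$area_mn <- 3; dat$ai <- 50
  dat$clumpy <- 0.5; dat$cohesion <- 80
  res <- permanova_two_way(dat, n_perm = 49, seed = 1)
  f <- res$table$pseudo_f[res$table$term %in% c("emulator", "period")]
  expect_true(all(abs(f) < 1e-10 | is.na(f)))
})

test_that("PerMANOVA permutation p-values are uniform under the null", {
  set.seed(5)
  ps <- vapply(1:300, function(i) {
    dat <- perm_records(n_per_cell = 2, effect = 0, seed = i + 1000)
    res <- permanova_two_way(dat, metrics = c("np", "area_mn"),
                             n_perm = 59, seed = i)
    res$table$p_value[res$table$term == "emulator"]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("class 1 and the division metric are excluded from PerMANOVA", {
  dat <- perm_records(seed = 6)
  dat1 <- dplyr::mutate(dat, class = 1)
  expect_error(permanova_two_way(dat1, n_perm = 49, seed = 1))
  # division has zero variance by construction and is not in the defaults
  expect_false("division" %in% c("np", "area_mn", "ai", "clumpy", "cohesion"))
})

test_that("patch-area trends recover constructed slopes", {
  periods <- c("P1", "P2", "P3", "P4")
  base <- tidyr::expand_grid(emulator = "E1", period = periods, class = 2:4)
  # constant area -> zero slope
  d0 <- dplyr::mutate(base, area_mn = 8)
  t0 <- suppressWarnings(patch_area_trend(d0))   # exact fit by construction
  expect_lt(abs(t0$estimate[t0$term == "period_index"]), 1e-12)
  # halving every period -> slope log10(0.5) per step
  d1 <- dplyr::mutate(base,
                      area_mn = 16 * 0.5^(match(period, periods) - 1))
  t1 <- suppressWarnings(patch_area_trend(d1))   # exact fit by construction
  expect_equal(t1$estimate[t1$term == "period_index"], log10(0.5),
               tolerance = 1e-10, ignore_attr = TRUE)
  # coefficients match the normal-equations oracle on a random design
  set.seed(7)
  d2 <- dplyr::mutate(base, area_mn = exp(rnorm(nrow(base), 2)))
  t2 <- patch_area_trend(d2)
  X <- model.matrix(~ match(period, periods) + factor(class), data = d2)
  beta <- solve(crossprod(X), crossprod(X, log10(d2$area_mn)))
  expect_equal(t2$estimate, as.vector(beta), tolerance = 1e-8,
               ignore_attr = TRUE)
  # zero-area rows dropped with a message
  d3 <- d2; d3$area_mn[1] <- 0
  expect_message(patch_area_trend(d3), "dropping")
})

test_that("ordinal class regression finds a constructed cohesion gradient", {
  set.seed(8)
  n <- 40
  base <- tibble::tibble(
    emulator = "E1", period = rep(c("P1", "P2"), n),
    class = rep(2:4, length.out = 2 * n))
  dat <- dplyr::mutate(base,
    np = exp(rnorm(2 * n)), area_mn = exp(rnorm(2 * n)),
    ai = runif(2 * n, 40, 90), clumpy = runif(2 * n, 0, 0.5),
    cohesion = 50 + 12 * (class - 2) + rnorm(2 * n, sd = 3))
  fit <- suppressWarnings(class_metric_glm(dat))
  expect_gt(fit$estimate[fit$term == "cohesion"][1], 0)
  expect_error(class_metric_glm(dplyr::mutate(dat, class = 2)),
               "at least 2 classes")
})
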