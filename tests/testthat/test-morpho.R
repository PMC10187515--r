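test_that("log-PCA matches a direct eigendecomposition on a toy sample", {
  set.seed(1)
  tab <- tibble::tibble(species = rep(c("x", "y"), each = 3))
  X <- matrix(exp(rnorm(6 * 19, 2, 0.3)), 6, 19,
              dimnames = list(NULL, morpho_variables()))
  tab <- dplyr::bind_cols(tab, tibble::as_tibble(X))
  p <- log_pca(tab)
  L <- log10(X)
  ev <- eigen(cov(L))
  expect_equal(p$sdev^2, pmax(ev$values, 0), tolerance = 1e-8)
  S <- as.matrix(p$scores[paste0("PC", 1:19)])
  expect_equal(abs(S[, 1]),
               abs(sweep(L, 2, colMeans(L)) %*% ev$vectors[, 1])[, 1],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("fossil projection is passive and order-invariant", {
  tab <- generate_morpho_table(seed = 2)
  p1 <- log_pca(tab)
  ord <- sample(nrow(tab))
  p2 <- log_pca(tab[ord, ])
  f1 <- p1$scores[p1$scores$species == "fossil", -1]
  f2 <- p2$scores[p2$scores$species == "fossil", -1]
  expect_equal(as.numeric(f1), as.numeric(f2), tolerance = 1e-10)
  # centring uses extant specimens only: dropping the fossil changes nothing
  p3 <- log_pca(tab[tab$species != "fossil", ])
  expect_equal(p1$loadings, p3$loadings, tolerance = 1e-10)
})

test_that("PC1 separates the hypercarnivorous from the mesocarnivorous guild", {
  tab <- generate_morpho_table(seed = 3, include_fossil = FALSE)
  p <- log_pca(tab)
  agg <- tapply(p$scores$PC1, p$scores$species, mean)
  hyper <- c("lupus", "pictus", "alpinus")
  meso <- c("simensis", "aureus", "adusta", "mesomelas", "latrans")
  expect_gt(min(agg[hyper]), max(agg[meso]))
})

test_that("degenerate morphometric inputs are handled", {
  tab <- tibble::tibble(species = rep("x", 4))
  X <- matrix(5, 4, 19, dimnames = list(NULL, morpho_variables()))
  tab <- dplyr::bind_cols(tab, tibble::as_tibble(X))
  p <- log_pca(tab)
  expect_equal(max(p$sdev), 0)
  tab$Lc[1] <- -1
  expect_error(log_pca(tab), "positive")
})

test_that("Wilks' lambda equals the determinant ratio |W|/|T|", {
  set.seed(4)
  X <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 1.5), 10, 2))
  g <- rep(c("a", "b"), each = 10)
  lam <- wilks_lambda(X, g)
  Tm <- crossprod(scale(X, scale = FALSE))
  W <- crossprod(scale(X[1:10, ], scale = FALSE)) +
    crossprod(scale(X[11:20, ], scale = FALSE))
  expect_equal(lam, det(W) / det(Tm), tolerance = 1e-12)
})

test_that("stepwise discriminant separates well-separated groups perfectly", {
  set.seed(5)
  n <- 30
  mk <- function(mu) {
    X <- matrix(exp(rnorm(n * 19, 2, 0.05)), n, 19,
                dimnames = list(NULL, morpho_variables()))
    X[, "Bp4"] <- X[, "Bp4"] + mu          # Mahalanobis-separated direction
    X
  }
  tab <- dplyr::bind_cols(
    tibble::tibble(species = rep(c("aureus", "simensis"), each = n)),
    tibble::as_tibble(rbind(mk(0), mk(3))))
  dm <- fit_lda_stepwise(tab, group_a = "aureus", group_b = "simensis")
  expect_equal(dm$loo_accuracy, 1)
  expect_true("Bp4" %in% dm$variables)
  expect_lt(dm$lambda_wilks, 0.5)
  expect_equal(sum(dm$loo_table), 2 * n)
  # group centroids score on opposite sides of the cut-point
  expect_lt(dm$centroid_scores["A"], dm$cut_point)
  expect_gt(dm$centroid_scores["B"], dm$cut_point)
})

test_that("identical group means admit no variables", {
  set.seed(6)
  X <- matrix(exp(rnorm(40 * 19, 2, 0.1)), 40, 19,
              dimnames = list(NULL, morpho_variables()))
  tab <- dplyr::bind_cols(
    tibble::tibble(species = rep(c("aureus", "simensis"), each = 20)),
    tibble::as_tibble(X))
  dm <- fit_lda_stepwise(tab, group_a = "aureus", group_b = "simensis")
  expect_length(dm$variables, 0)
  expect_equal(dm$lambda_wilks, 1)
})

test_that("LOO accuracy is invariant to positive rescaling of measurements", {
  tab <- generate_morpho_table(seed = 7)
  dm1 <- fit_lda_stepwise(tab, use_log = TRUE)
  tab2 <- tab
  for (v in morpho_variables()) tab2[[v]] <- tab2[[v]] * 3.7
  dm2 <- fit_lda_stepwise(tab2, use_log = TRUE)
  expect_equal(dm1$loo_accuracy, dm2$loo_accuracy)
  expect_equal(dm1$lambda_wilks, dm2$lambda_wilks, tolerance = 1e-8)
})

test_that("the published discriminant function evaluates as printed", {
  zero <- setNames(rep(0, 6), setdiff(names(phi_published), "(constant)"))
  s0 <- apply_discriminant(phi_published, zero)
  expect_equal(s0$score, -14.966)
  one_bp4 <- zero; one_bp4["Bp4"] <- 1
  s1 <- apply_discriminant(phi_published, one_bp4)
  expect_equal(s1$score - s0$score, 1.545)
  expect_error(apply_discriminant(phi_published, zero[-2]), "missing variable")
})

test_that("fitted discriminant scores and posteriors behave at the centroids", {
  tab <- generate_morpho_table(seed = 8)
  dm <- fit_lda_stepwise(tab)
  dat <- dplyr::filter(tab, species %in% c("aureus", "adusta", "mesomelas"))
  centroid <- as.data.frame(t(colMeans(dat[dm$variables])))
  sc <- apply_discriminant(dm, centroid)
  expect_equal(sc$score, unname(dm$centroid_scores["A"]), tolerance = 1e-8)
  # the fossil (drawn from the simensis model) classifies with the wolf
  fossil <- tab[tab$species == "fossil", ]
  cls <- apply_discriminant(dm, fossil)
  expect_equal(cls$class, "group_b")
  expect_gt(cls$posterior, 0.95)
})
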