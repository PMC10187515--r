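#' Published jackal-vs-Ethiopian-wolf discriminant function
#'
#' Coefficients and constant of the published two-group linear discriminant
#' function separating the three jackal species from the Ethiopian wolf on
#' six dentognathic variables (mm scale):
#' `-0.577 Lp4 + 1.545 Bp4 + 0.277 Lm1trig - 0.839 Bm1tal + 0.256 Lcm2
#'  - 0.623 JBp3p4 - 14.966`.
#'
#' @format named numeric vector; element `"(constant)"` is the intercept.
#' @export
phi_published <- c(Lp4 = -0.577, Bp4 = 1.545, Lm1trig = 0.277,
                   Bm1tal = -0.839, Lcm2 = 0.256, JBp3p4 = -0.623,
                   "(constant)" = -14.966)

#' Principal component analysis of log-transformed measurements
#'
#' PCA (covariance of the log10 measurements, the usual choice for
#' same-unit morphometrics) over the extant species' specimens; any rows
#' labelled `"fossil"` are projected passively onto the fitted axes. The
#' sign convention makes each loading column's largest-magnitude entry
#' positive, so on the default synthetic data PC1 grows with overall size
#' and separates the hypercarnivorous from the mesocarnivorous guild.
#'
#' @param table measurement tibble ([generate_morpho_table()] layout:
#'   `species` plus measurement columns).
#' @param variables measurement columns (default: all 19).
#' @return object of class `log_pca`: `scores` (tibble with `species` and
#'   PC columns; fossil rows included), `loadings`, `sdev`, `center`.
#' @export
log_pca <- function(table, variables = morpho_variables()) {
  missing <- setdiff(variables, names(table))
  if (length(missing)) stop("missing variable(s): ",
                            paste(missing, collapse = ", "))
  X <- as.matrix(table[variables])
  if (any(!is.finite(X)) || any(X <= 0))
    stop("measurements must be positive and complete")
  L <- log10(X)
  extant <- table$species != "fossil"
  if (sum(extant) < 2) stop("need at least 2 extant specimens")
  ctr <- colMeans(L[extant, , drop = FALSE])
  Lc <- sweep(L, 2, ctr)
  S <- crossprod(Lc[extant, , drop = FALSE]) / (sum(extant) - 1)
  ev <- eigen(S, symmetric = TRUE)
  V <- ev$vectors
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(variables, paste0("PC", seq_along(variables)))
  scores <- Lc %*% V
  structure(list(
    scores = dplyr::bind_cols(tibble(species = table$species),
                              as_tibble(scores)),
    loadings = V, sdev = sqrt(pmax(ev$values, 0)), center = ctr),
    class = "log_pca")
}

#' @export
print.log_pca <- function(x, ...) {
  pv <- 100 * x$sdev^2 / sum(x$sdev^2)
  cat(sprintf("<log_pca> %d specimens; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), pv[1], pv[2]))
  invisible(x)
}

#' @export
autoplot.log_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$species,
                               shape = .data$species == "fossil")) +
    ggplot2::geom_point(size = 2) +
    ggplot2::guides(shape = "none") +
    ggplot2::labs(x = "PC1 (log size/shape)", y = "PC2")
}

# Wilks' lambda |W| / |T| for a variable subset and a 2+-group labelling.
wilks_lambda <- function(X, groups) {
  X <- as.matrix(X)
  g <- factor(groups)
  Tm <- crossprod(sweep(X, 2, colMeans(X)))
  W <- matrix(0, ncol(X), ncol(X))
  for (lv in levels(g)) {
    Xi <- X[g == lv, , drop = FALSE]
    W <- W + crossprod(sweep(Xi, 2, colMeans(Xi)))
  }
  det(W) / det(Tm)
}

#' Stepwise two-group linear discriminant analysis
#'
#' Forward stepwise variable selection by the Wilks' lambda criterion: at
#' each step the candidate minimizing the overall lambda enters if its
#' partial F-to-enter exceeds `f_enter`. The discriminant function for the
#' selected variables is Fisher's linear discriminant (pooled
#' within-group covariance), reported with a constant placing the cut-point
#' midway between the group centroid scores (R0); the leave-one-out
#' reclassification table and per-specimen posteriors come from
#' [MASS::lda()] with cross-validation.
#'
#' @param table measurement tibble with a `species` column.
#' @param group_a,group_b character vectors of species labels defining the
#'   two groups (defaults: the three jackals vs the Ethiopian wolf).
#' @param variables candidate measurement columns.
#' @param f_enter F-to-enter threshold (default 3.84).
#' @param use_log discriminate on log10 measurements instead of raw?
#' @return object of class `discriminant_model`: `variables`,
#'   `coefficients`, `constant`, `centroid_scores` (R1 = second group's
#'   centroid), `cut_point` (R0), `lambda_wilks`, `chi_square`, `p_value`,
#'   `loo_table`, `loo_accuracy`, `posterior`.
#' @export
fit_lda_stepwise <- function(table,
                             group_a = c("aureus", "adusta", "mesomelas"),
                             group_b = "simensis",
                             variables = morpho_variables(),
                             f_enter = 3.84, use_log = FALSE) {
  dat <- dplyr::filter(table, .data$species %in% c(group_a, group_b))
  if (!nrow(dat)) stop("no specimens in the requested groups")
  grp <- factor(ifelse(dat$species %in% group_a, "A", "B"))
  if (nlevels(grp) < 2) stop("need specimens from both groups")
  X <- as.matrix(dat[variables])
  if (use_log) X <- log10(X)
  n <- nrow(X); g <- 2L
  selected <- character(0)
  lambda_cur <- 1
  repeat {
    cands <- setdiff(variables, selected)
    if (!length(cands)) break
    lams <- vapply(cands, function(v)
      wilks_lambda(X[, c(selected, v), drop = FALSE], grp), numeric(1))
    best <- cands[which.min(lams)]
    lam_new <- min(lams)
    p_now <- length(selected)
    f_to_enter <- ((n - g - p_now) / (g - 1)) * (lambda_cur / lam_new - 1)
    if (!is.finite(f_to_enter) || f_to_enter < f_enter) break
    selected <- c(selected, best)
    lambda_cur <- lam_new
    if (n - g - length(selected) < 1) break
  }
  if (!length(selected)) {
    return(structure(list(variables = character(0), coefficients = numeric(0),
                          constant = NA_real_, lambda_wilks = 1,
                          chi_square = 0, p_value = 1, loo_table = NULL,
                          loo_accuracy = NA_real_, posterior = NULL,
                          centroid_scores = NULL, cut_point = NA_real_),
                     class = "discriminant_model"))
  }
  Xs <- X[, selected, drop = FALSE]
  # Fisher two-group discriminant on the pooled within-group covariance
  mA <- colMeans(Xs[grp == "A", , drop = FALSE])
  mB <- colMeans(Xs[grp == "B", , drop = FALSE])
  W <- (crossprod(sweep(Xs[grp == "A", , drop = FALSE], 2, mA)) +
          crossprod(sweep(Xs[grp == "B", , drop = FALSE], 2, mB))) / (n - g)
  a <- drop(solve(W, mB - mA))
  const <- -sum(a * (mA + mB)) / 2
  centroid_scores <- c(A = sum(a * mA) + const, B = sum(a * mB) + const)
  p_sel <- length(selected)
  chi2 <- -(n - 1 - (p_sel + g) / 2) * log(lambda_cur)
  lda_fit <- MASS::lda(Xs, grouping = grp)
  loo <- MASS::lda(Xs, grouping = grp, CV = TRUE)
  loo_table <- table(truth = grp, predicted = loo$class)
  structure(list(variables = selected, coefficients = setNames(a, selected),
                 constant = const, centroid_scores = centroid_scores,
                 cut_point = 0, lambda_wilks = lambda_cur,
                 chi_square = chi2,
                 p_value = pchisq(chi2, df = p_sel, lower.tail = FALSE),
                 loo_table = loo_table,
                 loo_accuracy = mean(loo$class == grp),
                 posterior = loo$posterior, lda = lda_fit),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model> %d variables [%s]; lambda = %.3f, chi2 = %.2f, LOO = %.1f%%\n",
              length(x$variables), paste(x$variables, collapse = ", "),
              x$lambda_wilks, x$chi_square, 100 * x$loo_accuracy))
  invisible(x)
}

#' @export
glance.discriminant_model <- function(x, ...) {
  tibble(n_variables = length(x$variables), lambda_wilks = x$lambda_wilks,
         chi_square = x$chi_square, p_value = x$p_value,
         loo_accuracy = x$loo_accuracy)
}

#' Apply a discriminant function to specimen measurements
#'
#' Evaluates a linear discriminant — either a fitted
#' [fit_lda_stepwise()] model or a plain coefficient vector such as
#' [phi_published] — on one or more specimens. The class is decided by the
#' score's side of the cut-point; posteriors are computed from the group
#' centroid scores when available (logistic in the score distance).
#'
#' @param model a `discriminant_model` or a named coefficient vector with a
#'   `"(constant)"` element.
#' @param measurements data frame/tibble (or named vector) of measurements.
#' @return tibble with `score`, `class` and, when derivable, `posterior`
#'   (probability of the second group, e.g. the Ethiopian wolf).
#' @export
apply_discriminant <- function(model, measurements) {
  if (is.numeric(model)) {
    const <- unname(model["(constant)"])
    if (is.na(const)) stop("coefficient vector needs a \"(constant)\" element")
    coefs <- model[setdiff(names(model), "(constant)")]
    cut <- 0; cents <- NULL
  } else {
    stopifnot(inherits(model, "discriminant_model"))
    coefs <- model$coefficients; const <- model$constant
    cut <- model$cut_point; cents <- model$centroid_scores
  }
  if (is.null(dim(measurements)))
    measurements <- as.data.frame(as.list(measurements))
  missing <- setdiff(names(coefs), names(measurements))
  if (length(missing))
    stop("missing variable(s): ", paste(missing, collapse = ", "))
  M <- as.matrix(measurements[names(coefs)])
  score <- drop(M %*% coefs) + const
  out <- tibble(score = score,
                class = ifelse(score > cut, "group_b", "group_a"))
  if (!is.null(cents)) {
    # With Fisher coefficients a = W^-1 (mB - mA) and the midpoint constant,
    # the score is the Gaussian log-likelihood ratio of group B vs A, so the
    # equal-prior posterior is its logistic transform.
    out$posterior <- stats::plogis(score)
  }
  out
}
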