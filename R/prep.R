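#' Standardized principal component transform of a climate stack
#'
#' Fits a correlation-matrix PCA on the non-missing cells of a present-day
#' stack. All components are kept (one per layer), so the transform is a
#' rotation of the standardized variables that removes collinearity without
#' discarding information; it can then be applied to any stack carrying the
#' same layer names (past projections included). The sign convention fixes
#' each loading column so its largest-magnitude entry is positive.
#'
#' @param present_stack a [climate_stack()].
#' @return object of class `pca_transform`: `means`, `scales`, `loadings`
#'   (orthonormal columns), `sdev` (component standard deviations),
#'   `variables`.
#' @export
fit_pca <- function(present_stack) {
  stopifnot(inherits(present_stack, "climate_stack"))
  vars <- names(present_stack$layers)
  if (length(vars) < 2) stop("need at least 2 layers")
  X <- sapply(present_stack$layers, function(l) as.vector(l$values))
  X <- X[complete.cases(X), , drop = FALSE]
  if (nrow(X) < length(vars)) stop("fewer non-missing cells than layers")
  mu <- colMeans(X)
  sc <- apply(X, 2, sd)
  zero <- sc < .Machine$double.eps^0.5
  if (any(zero)) {
    warning("constant layer(s) ", paste(vars[zero], collapse = ", "),
            "; scale guarded at 1")
    sc[zero] <- 1
  }
  Z <- scale(X, center = mu, scale = sc)
  ev <- eigen(crossprod(Z) / (nrow(Z) - 1), symmetric = TRUE)
  L <- ev$vectors
  for (j in seq_len(ncol(L))) {
    k <- which.max(abs(L[, j]))
    if (L[k, j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(vars, paste0("PC", seq_along(vars)))
  structure(list(means = mu, scales = sc, loadings = L,
                 sdev = sqrt(pmax(ev$values, 0)), variables = vars),
            class = "pca_transform")
}

#' Apply a fitted PCA transform to a stack
#'
#' @param pca a [fit_pca()] result.
#' @param stack a [climate_stack()] carrying at least the fitted layers.
#' @return a [climate_stack()] whose layers are the PC scores.
#' @export
pca_transform <- function(pca, stack) {
  stopifnot(inherits(pca, "pca_transform"), inherits(stack, "climate_stack"))
  missing <- setdiff(pca$variables, names(stack$layers))
  if (length(missing)) stop("stack lacks layer(s): ",
                            paste(missing, collapse = ", "))
  g <- stack$layers[[pca$variables[1]]]
  X <- sapply(stack$layers[pca$variables], function(l) as.vector(l$values))
  Z <- scale(X, center = pca$means, scale = pca$scales)
  S <- Z %*% pca$loadings
  layers <- lapply(seq_len(ncol(S)), function(j)
    grid_raster(matrix(S[, j], nrow(g$values), ncol(g$values)),
                cell_size = g$cell_size, origin = g$origin))
  names(layers) <- colnames(pca$loadings)
  climate_stack(layers, time_label = stack$time_label, scenario = stack$scenario)
}

#' Iterative variance-inflation-factor filtering
#'
#' Removes, one at a time, the layer with the largest VIF (1 / (1 - R^2) of
#' that layer regressed on the remaining ones over non-missing cells) while
#' any VIF exceeds `threshold`. Ties are broken by layer-name order, so the
#' result is deterministic.
#'
#' @param stack a [climate_stack()].
#' @param threshold VIF threshold (default 3).
#' @return character vector of retained layer names, with the final VIF table
#'   in attribute `"vif"`.
#' @export
vif_filter <- function(stack, threshold = 3) {
  stopifnot(inherits(stack, "climate_stack"))
  vars <- names(stack$layers)
  if (length(vars) < 2) stop("need at least 2 layers")
  X <- sapply(stack$layers, function(l) as.vector(l$values))
  X <- X[complete.cases(X), , drop = FALSE]
  vif_of <- function(cols) {
    vapply(seq_along(cols), function(j) {
      y <- X[, cols[j]]
      Z <- cbind(1, X[, cols[-j], drop = FALSE])
      fit <- stats::lm.fit(Z, y)
      rss <- sum(fit$residuals^2)
      tss <- sum((y - mean(y))^2)
      if (tss < .Machine$double.eps) return(Inf)
      r2 <- 1 - rss / tss
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  keep <- vars
  repeat {
    if (length(keep) < 2) {
      warning("fewer than 2 layers remain; stopping VIF filtering")
      break
    }
    v <- vif_of(keep)
    if (all(v <= threshold)) break
    # worst first; ties by name order
    worst <- keep[order(-v, keep)][1]
    keep <- setdiff(keep, worst)
  }
  v <- if (length(keep) >= 2) vif_of(keep) else rep(NA_real_, length(keep))
  out <- keep
  attr(out, "vif") <- setNames(v, keep)
  out
}

# Per-variable MESS similarity of target values against a reference sample,
# following the standard percentile definition: with f the percentage of
# reference values below the target,
#   f = 0          -> 100 * (t - min) / (max - min)        (negative below min)
#   0 < f <= 50    -> 2 f
#   50 < f < 100   -> 2 (100 - f)
#   f = 100        -> 100 * (max - t) / (max - min)        (negative above max)
mess_similarity <- function(ref, t) {
  ref <- ref[!is.na(ref)]
  n <- length(ref)
  if (!n) stop("empty reference sample")
  mn <- min(ref); mx <- max(ref)
  rng <- mx - mn
  if (rng < .Machine$double.eps) rng <- .Machine$double.eps
  f <- 100 * findInterval(t, sort(ref), left.open = TRUE) / n
  out <- numeric(length(t))
  out[f == 0] <- 100 * (t[f == 0] - mn) / rng
  sel <- f > 0 & f <= 50
  out[sel] <- 2 * f[sel]
  sel <- f > 50 & f < 100
  out[sel] <- 2 * (100 - f[sel])
  out[f == 100] <- 100 * (mx - t[f == 100]) / rng
  out[is.na(t)] <- NA_real_
  out
}

#' Multivariate environmental similarity surface
#'
#' Computes, for every cell of `target_stack`, the similarity of each
#' variable to a reference sample (typically the variable values at the
#' calibration presence + background points) and the minimum across
#' variables. Values are at most 100; negative values flag cells where at
#' least one variable falls outside the reference min-max range
#' (extrapolation).
#'
#' @param reference_values data frame / tibble, one column per variable.
#' @param target_stack a [climate_stack()] carrying those variables.
#' @return object of class `mess_map`: `minimum` ([grid_raster()]),
#'   `per_variable` (named list of [grid_raster()]).
#' @export
mess <- function(reference_values, target_stack) {
  stopifnot(inherits(target_stack, "climate_stack"))
  vars <- intersect(names(reference_values), names(target_stack$layers))
  if (!length(vars)) stop("no shared variables between reference and target")
  g <- target_stack$layers[[vars[1]]]
  per <- lapply(vars, function(v) {
    s <- mess_similarity(reference_values[[v]],
                         as.vector(target_stack$layers[[v]]$values))
    grid_raster(matrix(s, nrow(g$values), ncol(g$values)),
                cell_size = g$cell_size, origin = g$origin)
  })
  names(per) <- vars
  m <- do.call(pmin, c(lapply(per, function(r) r$values), list(na.rm = FALSE)))
  structure(list(minimum = grid_raster(m, cell_size = g$cell_size,
                                       origin = g$origin),
                 per_variable = per),
            class = "mess_map")
}

#' Screen projection variables by their MESS extrapolation extent
#'
#' A variable is dropped when its mean (over time bins) proportion of
#' out-of-range cells — cells with negative per-variable similarity — exceeds
#' `cutoff`.
#'
#' @param mess_maps list of [mess()] results, one per time bin.
#' @param cutoff maximal tolerated mean out-of-range proportion (default 0.20).
#' @return tibble with `variable`, `mean_out_of_range`, `retained`.
#' @export
screen_variables_by_mess <- function(mess_maps, cutoff = 0.20) {
  if (!length(mess_maps)) stop("need at least one time bin")
  vars <- names(mess_maps[[1]]$per_variable)
  props <- sapply(mess_maps, function(m)
    vapply(vars, function(v) {
      vals <- m$per_variable[[v]]$values
      mean(vals < 0, na.rm = TRUE)
    }, numeric(1)))
  props <- matrix(props, nrow = length(vars))
  mean_prop <- rowMeans(props)
  tibble(variable = vars, mean_out_of_range = mean_prop,
         retained = mean_prop <= cutoff)
}
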