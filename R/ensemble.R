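#' Enumerate variable subsets for small models
#'
#' All size-`subset_size` combinations of `variables`, in lexicographic
#' order. With five variables and subsets of four this yields the five
#' hindcast small models; with eight variables and subsets of six, the 28
#' forecast small models.
#'
#' @param variables character vector.
#' @param subset_size subset size.
#' @return list of character vectors.
#' @export
enumerate_subsets <- function(variables, subset_size) {
  if (subset_size > length(variables))
    stop("`subset_size` exceeds the number of variables")
  m <- combn(sort(variables), subset_size)
  lapply(seq_len(ncol(m)), function(i) m[, i])
}

#' Assign spatially separated cross-validation folds
#'
#' When the occurrences carry at least `k` distinct source polygons, folds
#' follow the polygons: polygons are ordered south to north by centroid and
#' grouped into `k` contiguous blocks. Otherwise the coordinates are
#' clustered into `k` spatial groups (k-means). All folds are non-empty.
#'
#' @param occ an [simulate_occurrences()] result (or any tibble with `x`,
#'   `y` and optionally `polygon`).
#' @param k number of folds (default 12).
#' @param seed integer seed for the clustering fallback.
#' @return integer vector of fold ids (1..k), with attribute `"method"`.
#' @export
assign_spatial_folds <- function(occ, k = 12, seed = 1) {
  n <- nrow(occ)
  if (k > n) stop("more folds than occurrences")
  if ("polygon" %in% names(occ) && length(unique(occ$polygon)) >= k) {
    ids <- sort(unique(occ$polygon))
    # south-to-north order by mean y of each polygon's points
    ord <- ids[order(vapply(ids, function(i) mean(occ$y[occ$polygon == i]),
                            numeric(1)))]
    grp <- setNames(as.integer(cut(seq_along(ord), breaks = k, labels = FALSE)),
                    ord)
    fold <- grp[as.character(occ$polygon)]
    method <- "source-polygon blocks"
  } else {
    set.seed(seed)
    km <- stats::kmeans(cbind(occ$x, occ$y), centers = k, nstart = 5)
    fold <- km$cluster
    method <- "k-means spatial clustering"
  }
  fold <- as.integer(fold)
  stopifnot(length(unique(fold)) == k)
  attr(fold, "method") <- method
  fold
}

#' Area under the ROC curve, Mann-Whitney form
#'
#' The probability that a randomly chosen presence outscores a randomly
#' chosen background point, ties counted one half.
#'
#' @param scores_presence,scores_background numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores_presence, scores_background) {
  if (!length(scores_presence) || !length(scores_background))
    stop("empty score vector")
  m <- length(scores_presence); n <- length(scores_background)
  r <- rank(c(scores_presence, scores_background))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Default tuning grid
#' @param classes candidate feature-class sets.
#' @param reg candidate regularization multipliers.
#' @return tibble with columns `classes`, `reg`.
#' @export
tune_grid <- function(classes = c("L", "LQ", "LQH", "H"),
                      reg = c(0.5, 1, 2, 4)) {
  tidyr::expand_grid(classes = classes, reg = reg)
}

#' Tune and fit an ensemble of small models
#'
#' For every size-`subset_size` combination of `variables`, runs
#' leave-one-fold-out cross-validation over the tuning grid (the held-out
#' fold's presences are scored against the full background, which is not
#' folded), selects the parameterization with maximal mean held-out AUC,
#' refits it on all the data, and assigns the member the accuracy weight
#' `max(0, 2 (cv_auc - 0.5))` (Somers' D floored at zero), normalized over
#' members.
#'
#' @param occ_env data frame of environmental values at the occurrences.
#' @param bg_env data frame of environmental values at the background points.
#' @param variables candidate variable names (columns of both data frames).
#' @param subset_size number of variables per small model.
#' @param folds integer fold id per occurrence ([assign_spatial_folds()]).
#' @param tuning tibble from [tune_grid()].
#' @param n_knots hinge/threshold knots per variable.
#' @param max_iter optimizer iteration cap passed to [fit_maxent()].
#' @param subsets optional explicit list of variable subsets (default: all
#'   [enumerate_subsets()] combinations).
#' @return object of class `small_model_ensemble`: `members` (tibble with
#'   `subset`, `classes`, `reg`, `cv_auc`, `model`), `weights`.
#' @export
tune_and_fit <- function(occ_env, bg_env, variables, subset_size, folds,
                         tuning = tune_grid(), n_knots = 5, max_iter = 200,
                         subsets = NULL) {
  if (is.null(subsets)) subsets <- enumerate_subsets(variables, subset_size)
  members <- vector("list", length(subsets))
  for (si in seq_along(subsets)) {
    vars <- subsets[[si]]
    occ_v <- occ_env[, vars, drop = FALSE]
    bg_v <- bg_env[, vars, drop = FALSE]
    best <- NULL
    for (gi in seq_len(nrow(tuning))) {
      cls <- tuning$classes[gi]; reg <- tuning$reg[gi]
      aucs <- c()
      ok <- TRUE
      for (f in sort(unique(folds))) {
        train <- occ_v[folds != f, , drop = FALSE]
        test <- occ_v[folds == f, , drop = FALSE]
        fit <- tryCatch({
          sp <- feature_spec(rbind(train, bg_v), classes = cls,
                             n_knots = n_knots)
          fit_maxent(train, bg_v, sp, reg_multiplier = reg,
                     max_iter = max_iter)
        }, error = function(e) NULL)
        if (is.null(fit)) { ok <- FALSE; break }
        sc_test <- drop(build_features(test, fit$spec) %*% fit$I)
        sc_bg <- drop(build_features(bg_v, fit$spec) %*% fit$I)
        aucs <- c(aucs, auc(sc_test, sc_bg))
      }
      if (!ok) { warning(sprintf("degenerate fit skipped (subset %d, %s, reg %g)",
                                 si, cls, reg)); next }
      mean_auc <- mean(aucs)
      if (is.null(best) || mean_auc > best$cv_auc)
        best <- list(classes = cls, reg = reg, cv_auc = mean_auc)
    }
    if (is.null(best)) next
    sp <- feature_spec(rbind(occ_v, bg_v), classes = best$classes,
                       n_knots = n_knots)
    model <- fit_maxent(occ_v, bg_v, sp, reg_multiplier = best$reg,
                        max_iter = max_iter)
    members[[si]] <- tibble(
      subset = paste(vars, collapse = "+"), classes = best$classes,
      reg = best$reg, cv_auc = best$cv_auc, model = list(model))
  }
  members <- dplyr::bind_rows(members[!vapply(members, is.null, logical(1))])
  if (!nrow(members)) stop("all small-model fits failed")
  w <- pmax(0, 2 * (members$cv_auc - 0.5))
  if (sum(w) > 0) w <- w / sum(w)
  structure(list(members = members, weights = w),
            class = "small_model_ensemble")
}

#' @export
print.small_model_ensemble <- function(x, ...) {
  cat(sprintf("<small_model_ensemble> %d members; cv AUC %.3f-%.3f\n",
              nrow(x$members), min(x$members$cv_auc), max(x$members$cv_auc)))
  invisible(x)
}

#' @export
tidy.small_model_ensemble <- function(x, ...) {
  dplyr::mutate(dplyr::select(x$members, -"model"), weight = x$weights)
}

#' @export
glance.small_model_ensemble <- function(x, ...) {
  tibble(n_members = nrow(x$members),
         mean_cv_auc = mean(x$members$cv_auc),
         max_cv_auc = max(x$members$cv_auc),
         n_zero_weight = sum(x$weights == 0))
}

#' Accuracy-weighted ensemble prediction
#'
#' Per-cell weighted mean of the members' logistic (HSI) outputs. When every
#' member has weight zero (no member beat chance in cross-validation) an
#' unweighted mean is used, with a warning.
#'
#' @param ens a [tune_and_fit()] ensemble.
#' @param stack a [climate_stack()].
#' @return a `suitability_map`.
#' @export
ensemble_predict <- function(ens, stack) {
  stopifnot(inherits(ens, "small_model_ensemble"))
  w <- ens$weights
  if (all(w == 0)) {
    warning("all ensemble weights are zero; using an unweighted mean")
    w <- rep(1 / length(w), length(w))
  }
  preds <- lapply(ens$members$model, predict_logistic, stack = stack)
  acc <- preds[[1]]$hsi$values * w[1]
  if (length(preds) > 1)
    for (i in 2:length(preds)) acc <- acc + preds[[i]]$hsi$values * w[i]
  g <- preds[[1]]$hsi
  structure(list(hsi = grid_raster(acc, cell_size = g$cell_size,
                                   origin = g$origin),
                 time_label = stack$time_label, scenario = stack$scenario),
            class = "suitability_map")
}
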