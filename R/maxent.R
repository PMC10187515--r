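#' Feature specification for the maximum-entropy model
#'
#' Turns raw environmental variables into "features": transformations whose
#' expectations under the fitted distribution are constrained towards their
#' presence-sample means. Classes follow the classic presence-background
#' maximum-entropy definitions: linear (L), quadratic (Q), product (P),
#' hinge (H) and threshold (T). Every feature maps calibration values into
#' \[0, 1\]: linear features are min-max scaled on calibration bounds (values
#' outside the bounds are clamped), quadratic features are squared scaled
#' linears, products multiply two scaled linears, hinges are forward/reverse
#' ramps anchored at knots inside the observed range, and thresholds are
#' step indicators at those knots.
#'
#' @param calib data frame of calibration values (presences + background),
#'   one column per variable.
#' @param classes character such as `"LQ"`, `"LQH"`, `"H"`; letters from
#'   L, Q, P, H, T.
#' @param n_knots number of interior knots per variable for hinge/threshold
#'   features.
#' @return object of class `feature_spec`.
#' @export
feature_spec <- function(calib, classes = "LQ", n_knots = 5) {
  if (!nrow(calib)) stop("empty calibration data")
  letters_ok <- c("L", "Q", "P", "H", "T")
  cls <- strsplit(toupper(classes), "")[[1]]
  if (!all(cls %in% letters_ok))
    stop("feature classes must be letters among L, Q, P, H, T")
  vars <- names(calib)
  bounds <- lapply(calib, function(v) range(v, na.rm = TRUE))
  knots <- lapply(bounds, function(b) {
    if (diff(b) <= 0) return(numeric(0))
    seq(b[1], b[2], length.out = n_knots + 2L)[-c(1L, n_knots + 2L)]
  })
  structure(list(variables = vars, classes = cls, bounds = bounds,
                 knots = knots),
            class = "feature_spec")
}

#' Build the feature matrix for a set of environmental values
#'
#' @param values data frame with the spec's variables.
#' @param spec a [feature_spec()].
#' @return numeric matrix, one column per feature, values in \[0, 1\].
#' @export
build_features <- function(values, spec) {
  stopifnot(inherits(spec, "feature_spec"))
  missing <- setdiff(spec$variables, names(values))
  if (length(missing)) stop("unknown/missing variable(s): ",
                            paste(missing, collapse = ", "))
  scaled <- lapply(spec$variables, function(v) {
    b <- spec$bounds[[v]]
    rng <- max(b[2] - b[1], .Machine$double.eps)
    pmin(pmax((values[[v]] - b[1]) / rng, 0), 1)
  })
  names(scaled) <- spec$variables
  out <- list()
  if ("L" %in% spec$classes)
    for (v in spec$variables) out[[paste0("L_", v)]] <- scaled[[v]]
  if ("Q" %in% spec$classes)
    for (v in spec$variables) out[[paste0("Q_", v)]] <- scaled[[v]]^2
  if ("P" %in% spec$classes && length(spec$variables) > 1) {
    cmb <- combn(spec$variables, 2)
    for (i in seq_len(ncol(cmb)))
      out[[paste0("P_", cmb[1, i], "_", cmb[2, i])]] <-
        scaled[[cmb[1, i]]] * scaled[[cmb[2, i]]]
  }
  if ("H" %in% spec$classes)
    for (v in spec$variables) {
      b <- spec$bounds[[v]]
      for (k in spec$knots[[v]]) {
        out[[sprintf("Hf_%s_%.6g", v, k)]] <-
          pmin(pmax((values[[v]] - k) / max(b[2] - k, .Machine$double.eps), 0), 1)
        out[[sprintf("Hr_%s_%.6g", v, k)]] <-
          pmin(pmax((k - values[[v]]) / max(k - b[1], .Machine$double.eps), 0), 1)
      }
    }
  if ("T" %in% spec$classes)
    for (v in spec$variables) {
      for (k in spec$knots[[v]])
        out[[sprintf("T_%s_%.6g", v, k)]] <- as.numeric(values[[v]] > k)
    }
  do.call(cbind, out)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit the presence-background maximum-entropy model
#'
#' Maximizes the L1-penalized presence log-likelihood of the Gibbs
#' distribution `P*(z(x)) = Q(x) exp(z(x) I) / sum_i Q(x_i) exp(z(x_i) I)`
#' over the background sample (uniform prior Q; the presences are appended to
#' the background for normalization, the standard convention). The penalty
#' for feature j is `reg_multiplier * max(sd_j(presences), 0.01) / sqrt(m)`
#' with m the number of presences. The convex objective is minimized by
#' proximal gradient descent (FISTA with backtracking), which handles the
#' non-smooth L1 term exactly; convergence when the proximal-gradient step
#' norm falls below `tol` or after `max_iter` iterations.
#'
#' @param presences data frame of environmental values at presence points.
#' @param background data frame of environmental values at background points.
#' @param spec a [feature_spec()].
#' @param reg_multiplier positive regularization multiplier (default 1).
#' @param tol convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 500).
#' @param add_presences append the presences to the background for
#'   normalization (default TRUE, the usual convention for a random
#'   background sample)? Set FALSE when the background already covers the
#'   presence cells, e.g. an exhaustive landscape sample, where appending
#'   would double-count them and tilt the prior.
#' @return object of class `niche_model`: `I` (coefficients), `spec`,
#'   `reg_multiplier`, `entropy_H` (entropy of the fitted raw distribution
#'   over the background, nats), `objective` (per-iteration penalized NLL),
#'   `converged`, `n_presence`, `n_background`.
#' @export
fit_maxent <- function(presences, background, spec, reg_multiplier = 1,
                       tol = 1e-6, max_iter = 500, add_presences = TRUE) {
  stopifnot(inherits(spec, "feature_spec"))
  if (!nrow(presences)) stop("need at least 1 presence")
  if (nrow(background) < 2) stop("need at least 2 background points")
  if (reg_multiplier <= 0) stop("`reg_multiplier` must be positive")
  Zp <- build_features(presences, spec)
  Zb <- build_features(background, spec)
  Za <- if (add_presences) rbind(Zb, Zp) else Zb  # Q support
  if (all(apply(Za, 2, function(x) diff(range(x)) < 1e-12)))
    stop("degenerate fit: no variation in any feature")
  m <- nrow(Zp)
  sds <- apply(Zp, 2, sd)
  sds[is.na(sds)] <- 0
  lambda <- reg_multiplier * pmax(sds, 0.01) / sqrt(m)
  zp_bar <- colMeans(Zp)

  smooth_obj <- function(I) {
    eta <- drop(Za %*% I)
    -sum(zp_bar * I) + log_sum_exp(eta)
  }
  smooth_grad <- function(I) {
    eta <- drop(Za %*% I)
    w <- exp(eta - log_sum_exp(eta))
    -zp_bar + drop(crossprod(Za, w))
  }
  prox <- function(x, t) sign(x) * pmax(abs(x) - t * lambda, 0)

  pen_obj <- function(I) smooth_obj(I) + sum(lambda * abs(I))
  # One backtracked proximal-gradient step from `from`; the sufficient-
  # decrease condition guarantees descent of the penalized objective when
  # stepping from the current iterate.
  bt_step <- function(from, step) {
    f0 <- smooth_obj(from)
    g <- smooth_grad(from)
    repeat {
      cand <- prox(from - step * g, step)
      d <- cand - from
      if (smooth_obj(cand) <= f0 + sum(g * d) + sum(d^2) / (2 * step) + 1e-12 ||
          step < 1e-12) break
      step <- step / 2
    }
    list(x = cand, step = step)
  }

  p <- ncol(Za)
  I <- numeric(p); y <- I; theta <- 1
  step <- 1
  objs <- pen_obj(I)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    st <- bt_step(y, step)
    cand <- st$x; step <- st$step
    if (pen_obj(cand) > objs[length(objs)]) {
      # monotone safeguard: plain descent step from the current iterate
      st <- bt_step(I, step)
      cand <- st$x; step <- st$step
      theta <- 1                              # restart the momentum
    }
    theta_new <- (1 + sqrt(1 + 4 * theta^2)) / 2
    y <- cand + ((theta - 1) / theta_new) * (cand - I)
    res <- sqrt(sum((cand - I)^2))
    I <- cand; theta <- theta_new
    objs <- c(objs, pen_obj(I))
    if (res < tol) { converged <- TRUE; break }
    step <- step * 1.5                        # allow the step to grow back
  }

  eta <- drop(Za %*% I)
  log_z <- log_sum_exp(eta)
  pr <- exp(eta - log_z)
  H <- -sum(pr * log(pmax(pr, 1e-300)))
  structure(list(I = setNames(I, colnames(Za)), spec = spec,
                 reg_multiplier = reg_multiplier, entropy_H = H,
                 log_z = log_z, lambda = lambda, objective = objs,
                 converged = converged,
                 n_presence = m, n_background = nrow(Zb)),
            class = "niche_model")
}

#' @export
print.niche_model <- function(x, ...) {
  cat(sprintf("<niche_model> %d features (%d nonzero), reg = %g, H = %.4f, %s\n",
              length(x$I), sum(x$I != 0), x$reg_multiplier, x$entropy_H,
              if (x$converged) "converged" else "max-iter reached"))
  invisible(x)
}

# Environmental values of a stack at all non-missing cells -> df + cell index
stack_env <- function(stack, variables) {
  missing <- setdiff(variables, names(stack$layers))
  if (length(missing)) stop("stack lacks variable(s): ",
                            paste(missing, collapse = ", "))
  X <- sapply(stack$layers[variables], function(l) as.vector(l$values))
  ok <- complete.cases(X)
  list(values = as.data.frame(X[ok, , drop = FALSE]), cells = which(ok))
}

#' Raw (relative occurrence rate) prediction
#'
#' Evaluates `exp(z(x) I) / Z_cal` with `Z_cal` the partition function of
#' the calibration background, so the raw scores sum to exactly 1 over the
#' background sample the model was normalized on. Projection stacks are
#' deliberately *not* renormalized per stack: keeping the calibration
#' normalizer makes a cell's score a function of its own environment alone,
#' so suitability is comparable across time bins and scenarios (the
#' canonical projection convention; out-of-range values are clamped by the
#' feature bounds).
#'
#' @param model a [fit_maxent()] model.
#' @param stack a [climate_stack()] carrying the model's variables, or a
#'   data frame of environmental values (returns a vector).
#' @return a [grid_raster()] of raw scores (a numeric vector for data-frame
#'   input).
#' @export
predict_raw <- function(model, stack) {
  stopifnot(inherits(model, "niche_model"))
  if (is.data.frame(stack)) {
    Z <- build_features(stack, model$spec)
    return(exp(drop(Z %*% model$I) - model$log_z))
  }
  stopifnot(inherits(stack, "climate_stack"))
  env <- stack_env(stack, model$spec$variables)
  Z <- build_features(env$values, model$spec)
  raw <- exp(drop(Z %*% model$I) - model$log_z)
  g <- stack$layers[[1]]
  out <- matrix(NA_real_, nrow(g$values), ncol(g$values))
  out[env$cells] <- raw
  grid_raster(out, cell_size = g$cell_size, origin = g$origin)
}

#' Logistic (habitat suitability index) prediction
#'
#' Transforms raw scores into the canonical logistic output
#' `c r / (1 + c r)` with `c = exp(H)`, H the entropy of the fitted raw
#' distribution over the background; a cell with typical background
#' suitability (`r = exp(-H)`) maps to 0.5.
#'
#' @param model a [fit_maxent()] model.
#' @param stack a [climate_stack()].
#' @return object of class `suitability_map`: `hsi` ([grid_raster()] in
#'   \[0, 1\]), `time_label`, `scenario`.
#' @export
predict_logistic <- function(model, stack) {
  raw <- predict_raw(model, stack)
  cc <- exp(model$entropy_H)
  v <- cc * raw$values / (1 + cc * raw$values)
  structure(list(hsi = grid_raster(v, cell_size = raw$cell_size,
                                   origin = raw$origin),
                 time_label = stack$time_label, scenario = stack$scenario),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  v <- x$hsi$values
  cat(sprintf("<suitability_map> t = %s; HSI in [%.3f, %.3f]\n",
              format(x$time_label), min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' @export
autoplot.suitability_map <- function(object, ...) {
  autoplot(object$hsi) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90",
                                  name = "HSI") +
    ggplot2::ggtitle(paste("t =", format(object$time_label)))
}
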