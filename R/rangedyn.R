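#' Minimum useful threshold for range binarization
#'
#' Scans a threshold grid (default 0.01 to 1 by 0.01) and returns the
#' largest threshold at which every time bin still keeps at least one cell
#' with HSI at or above it, so that no bin yields a null geographic range.
#' Equivalently, the minimum over bins of the maximal HSI, floored to the
#' threshold grid.
#'
#' @param hsi_series list of `suitability_map`s (or [grid_raster()]s).
#' @param thresholds candidate threshold grid.
#' @return object of class `threshold_result`: `mut`, `thresholds`,
#'   `nonzero` (bins x thresholds logical matrix).
#' @export
compute_mut <- function(hsi_series, thresholds = seq(0.01, 1, by = 0.01)) {
  if (!length(hsi_series)) stop("need at least one time bin")
  maxima <- vapply(hsi_series, function(m) {
    v <- if (inherits(m, "suitability_map")) m$hsi$values else m$values
    max(v, na.rm = TRUE)
  }, numeric(1))
  nonzero <- outer(maxima, thresholds, `>=`)
  ok <- apply(nonzero, 2, all)
  if (!any(ok)) {
    bad <- which.min(maxima)
    stop(sprintf("bin %d (max HSI %.4f) yields a null range even at threshold %.2f",
                 bad, maxima[bad], min(thresholds)))
  }
  structure(list(mut = max(thresholds[ok]), thresholds = thresholds,
                 nonzero = nonzero),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> MUT = %.2f over %d bins x %d thresholds\n",
              x$mut, nrow(x$nonzero), length(x$thresholds)))
  invisible(x)
}

#' Binarize a suitability map at a threshold
#'
#' Cells with HSI greater than or equal to `t` are in range.
#'
#' @param map a `suitability_map` or [grid_raster()].
#' @param t threshold in (0, 1].
#' @return list with `mask` (logical matrix) and `area` (cells x cell area).
#' @export
binarize_range <- function(map, t) {
  if (t <= 0 || t > 1) stop("`t` must be in (0, 1]")
  g <- if (inherits(map, "suitability_map")) map$hsi else map
  mask <- !is.na(g$values) & g$values >= t
  list(mask = mask, area = sum(mask) * g$cell_size^2)
}

#' Split an in-range map into good-to-best and good-to-worst areas
#'
#' Within the range mask, GB cells have HSI above 0.5 and GW cells have HSI
#' at or below 0.5 (a cell at exactly 0.5 is GW). A bin whose GB share
#' exceeds its GW share signals range expansion.
#'
#' @param map a `suitability_map` or [grid_raster()].
#' @param mask logical matrix from [binarize_range()].
#' @return list with `gb_area`, `gw_area`, `expansion`.
#' @export
gb_gw_split <- function(map, mask) {
  g <- if (inherits(map, "suitability_map")) map$hsi else map
  if (!any(mask)) return(list(gb_area = 0, gw_area = 0, expansion = FALSE))
  a <- g$cell_size^2
  gb <- sum(mask & g$values > 0.5, na.rm = TRUE) * a
  gw <- sum(mask & g$values <= 0.5, na.rm = TRUE) * a
  list(gb_area = gb, gw_area = gw, expansion = gb > gw)
}

#' Compare a bin's in-range suitability with the present
#'
#' Two-sample rank-sum (Wilcoxon) tests between the in-range HSI values of a
#' past bin and those of the present map: "better" means the one-sided
#' greater test is significant at `alpha`; "similar" means the two-sided
#' test is not significant.
#'
#' @param bin_values,present_values numeric in-range HSI samples.
#' @param alpha significance level (default 0.05).
#' @return list with `better`, `similar`, `p_greater`, `p_two_sided`.
#' @export
compare_bin_to_present <- function(bin_values, present_values, alpha = 0.05) {
  if (!length(bin_values) || !length(present_values)) stop("empty sample")
  if (length(unique(c(bin_values, present_values))) == 1L)
    return(list(better = FALSE, similar = TRUE, p_greater = 1, p_two_sided = 1))
  n1 <- length(bin_values); n2 <- length(present_values)
  ties <- anyDuplicated(c(bin_values, present_values)) > 0
  exact <- !ties && n1 <= 20 && n2 <= 20
  pg <- suppressWarnings(wilcox.test(bin_values, present_values,
                                     alternative = "greater",
                                     exact = exact))$p.value
  pt <- suppressWarnings(wilcox.test(bin_values, present_values,
                                     alternative = "two.sided",
                                     exact = exact))$p.value
  list(better = pg < alpha, similar = pt >= alpha,
       p_greater = pg, p_two_sided = pt)
}

#' Brown-Forsythe test for equality of variance (two groups)
#'
#' One-way ANOVA F statistic on the absolute deviations from the group
#' medians; robust to non-normality. Used to compare the variability of the
#' range-area series between bins younger and older than the glacial-cycle
#' switch.
#'
#' @param series_a,series_b numeric vectors (each of length at least 2).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
brown_forsythe <- function(series_a, series_b) {
  if (length(series_a) < 2 || length(series_b) < 2)
    stop("each group needs at least 2 values")
  za <- abs(series_a - median(series_a))
  zb <- abs(series_b - median(series_b))
  n1 <- length(za); n2 <- length(zb); n <- n1 + n2
  zbar <- mean(c(za, zb))
  ssb <- n1 * (mean(za) - zbar)^2 + n2 * (mean(zb) - zbar)^2
  ssw <- sum((za - mean(za))^2) + sum((zb - mean(zb))^2)
  if (ssw < .Machine$double.eps)
    stop("zero within-group variance in both groups; statistic undefined")
  f <- (ssb / 1) / (ssw / (n - 2))
  list(statistic = f, p_value = pf(f, 1, n - 2, lower.tail = FALSE),
       df = c(1, n - 2))
}

#' Trend regression with ARIMA errors
#'
#' Regresses a response series on a predictor, accounting for temporal
#' autocorrelation. First an ordinary least-squares fit is computed and its
#' residuals checked with a Ljung-Box test at lag `min(10, n/5)`. With no
#' significant autocorrelation the OLS fit is retained. Otherwise two
#' strategies generate regression-with-ARIMA-error candidates: (1) the AR
#' order is estimated from the OLS residuals by maximum likelihood, the
#' integration order takes 0 and 1, and the moving-average order ranges over
#' 0..6; (2) a fully automatic AIC grid search over (p, d, q) with p, q in
#' 0..3 and d in 0..1. The reported model minimizes AIC over all candidates.
#'
#' @param response numeric series (e.g. log10 range area).
#' @param predictor numeric series of equal length (e.g. mean temperature or
#'   log10 mean altitude).
#' @param alpha significance level of the residual-autocorrelation check.
#' @return object of class `trend_fit`: `family` ("OLS" or "ARIMA"),
#'   `order`, `slope`, `slope_se`, `p_value`, `aic`, `ols_slope`,
#'   `ljung_box_p`, `candidates`.
#' @export
fit_trend <- function(response, predictor, alpha = 0.05) {
  if (length(response) != length(predictor)) stop("series lengths differ")
  if (length(response) < 20) stop("need at least 20 observations")
  if (any(!is.finite(response)) || any(!is.finite(predictor)))
    stop("non-finite values in the series")
  n <- length(response)
  ols <- lm(response ~ predictor)
  lb_lag <- max(1, min(10, floor(n / 5)))
  lb <- Box.test(resid(ols), lag = lb_lag, type = "Ljung-Box",
                 fitdf = 0)$p.value
  ols_slope <- unname(coef(ols)[2])
  ols_se <- summary(ols)$coefficients[2, 2]
  ols_p <- summary(ols)$coefficients[2, 4]
  ols_aic <- AIC(ols)
  if (lb >= alpha) {
    return(structure(list(family = "OLS", order = c(0, 0, 0),
                          slope = ols_slope, slope_se = ols_se,
                          p_value = ols_p, aic = ols_aic,
                          ols_slope = ols_slope, ljung_box_p = lb,
                          candidates = tibble(p = 0, d = 0, q = 0,
                                              strategy = "OLS",
                                              aic = ols_aic)),
                     class = "trend_fit"))
  }
  fit_one <- function(p, d, q, strategy) {
    fit <- tryCatch(
      suppressWarnings(arima(response, order = c(p, d, q), xreg = predictor,
                             method = "ML")),
      error = function(e) tryCatch(
        suppressWarnings(arima(response, order = c(p, d, q), xreg = predictor,
                               method = "CSS-ML")),
        error = function(e) NULL))
    if (is.null(fit)) return(NULL)
    se <- suppressWarnings(sqrt(diag(fit$var.coef)))
    if (!is.finite(se["predictor"])) return(NULL)
    list(p = p, d = d, q = q, strategy = strategy, aic = AIC(fit),
         slope = unname(coef(fit)["predictor"]),
         slope_se = unname(se["predictor"]), fit = fit)
  }
  # Strategy 1: AR order from the OLS residuals by ML, d in {0,1}, MA 0..6
  ar_fit <- tryCatch(ar(resid(ols), order.max = 6, method = "mle"),
                     error = function(e) ar(resid(ols), order.max = 6))
  p_hat <- ar_fit$order
  cands <- list()
  for (d in 0:1) for (q in 0:6)
    cands[[length(cands) + 1L]] <- fit_one(p_hat, d, q, "residual-AR")
  # Strategy 2: automatic (p, d, q) grid search by AIC
  for (p in 0:3) for (d in 0:1) for (q in 0:3)
    cands[[length(cands) + 1L]] <- fit_one(p, d, q, "auto-grid")
  cands <- cands[!vapply(cands, is.null, logical(1))]
  if (!length(cands))
    stop("all ARIMA-error fits failed")
  tab <- dplyr::bind_rows(lapply(cands, function(cc)
    tibble(p = cc$p, d = cc$d, q = cc$q, strategy = cc$strategy,
           aic = cc$aic)))
  best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "aic"))]]
  z <- best$slope / best$slope_se
  structure(list(family = "ARIMA", order = c(best$p, best$d, best$q),
                 slope = best$slope, slope_se = best$slope_se,
                 p_value = 2 * pnorm(-abs(z)), aic = best$aic,
                 ols_slope = ols_slope, ljung_box_p = lb,
                 candidates = tab),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s(%d,%d,%d): slope = %.4g (se %.3g, p = %.3g), AIC = %.2f\n",
              x$family, x$order[1], x$order[2], x$order[3],
              x$slope, x$slope_se, x$p_value, x$aic))
  invisible(x)
}

#' @export
tidy.trend_fit <- function(x, ...) {
  tibble(term = "predictor", estimate = x$slope, std.error = x$slope_se,
         p.value = x$p_value)
}

#' @export
glance.trend_fit <- function(x, ...) {
  tibble(family = x$family, p = x$order[1], d = x$order[2], q = x$order[3],
         AIC = x$aic, ljung_box_p = x$ljung_box_p)
}

#' Per-bin mean annual temperature of a hindcast series
#'
#' The spatial mean, per time bin, of the average of the warmest-quarter and
#' coldest-quarter temperature layers — the annual-mean proxy used for the
#' range-temperature trend.
#'
#' @param stacks list of [climate_stack()]s carrying `BIO10` and `BIO11`.
#' @return numeric vector, one value per stack.
#' @export
bin_mean_temperature <- function(stacks) {
  vapply(stacks, function(s)
    mean((s$layers$BIO10$values + s$layers$BIO11$values) / 2, na.rm = TRUE),
    numeric(1))
}

#' Build the per-bin range-dynamics series
#'
#' Applies the minimum useful threshold to every bin's HSI map, accumulates
#' per-bin range area, in-range mean HSI, mean altitude and mean
#' temperature, splits the range into good-to-best and good-to-worst areas,
#' and runs the per-bin rank-sum comparison against the present map.
#'
#' @param past_maps list of `suitability_map`s (one per past bin).
#' @param present_map `suitability_map` for the present on the same grid.
#' @param altitude [grid_raster()] on the same grid (mean altitude within the
#'   range mask; pass the aggregated altitude surface).
#' @param temperature numeric vector, per-bin mean temperature
#'   ([bin_mean_temperature()]).
#' @param mut optional threshold; computed with [compute_mut()] over
#'   `c(past_maps, present_map)` when omitted.
#' @param alpha significance level for the rank-sum flags.
#' @return tibble of class `range_series`, one row per past bin, with the
#'   MUT in attribute `"mut"`.
#' @export
build_range_series <- function(past_maps, present_map, altitude = NULL,
                               temperature = NULL, mut = NULL, alpha = 0.05) {
  if (is.null(mut))
    mut <- compute_mut(c(past_maps, list(present_map)))$mut
  pres_bin <- binarize_range(present_map, mut)
  pres_vals <- present_map$hsi$values[pres_bin$mask]
  rows <- purrr::map(seq_along(past_maps), function(b) {
    m <- past_maps[[b]]
    bin <- binarize_range(m, mut)
    split <- gb_gw_split(m, bin$mask)
    vals <- m$hsi$values[bin$mask]
    cmp <- compare_bin_to_present(vals, pres_vals, alpha = alpha)
    tibble(
      time = m$time_label,
      range_area = bin$area,
      mean_hsi = mean(vals),
      mean_altitude = if (!is.null(altitude))
        mean(altitude$values[bin$mask], na.rm = TRUE) else NA_real_,
      mean_temperature = if (!is.null(temperature)) temperature[b] else NA_real_,
      gb_area = split$gb_area, gw_area = split$gw_area,
      expansion = split$expansion,
      better = cmp$better, similar = cmp$similar,
      p_greater = cmp$p_greater, p_two_sided = cmp$p_two_sided)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mut") <- mut
  class(out) <- c("range_series", class(out))
  out
}

#' @export
autoplot.range_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$range_area)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$expansion), size = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "age (ka)", y = "range area (cell units)",
                  colour = "GB > GW")
}
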