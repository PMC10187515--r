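#' Run the hindcast reconstruction end to end
#'
#' Ties the modules together for the past-projection arm of the analysis:
#' simulate presences inside the range polygons and inverse-distance
#' weighted background points; fit the standardized PCA on the five present
#' hindcast layers and transform presences, background and every projection
#' stack to PC scores; screen the PC variables by their mean MESS
#' out-of-range proportion across bins; tune and fit the ensemble of small
#' models (all size-4 subsets of the retained PCs) with spatial-block
#' cross-validation; project every past bin and the coarse present; and
#' assemble the per-bin range series at the minimum useful threshold.
#'
#' @param series a [generate_climate_series()] result.
#' @param regions a [generate_regions()] result.
#' @param n_occ number of presences (default 200).
#' @param n_bg requested background points (default 10000).
#' @param k_folds spatial folds (default 12).
#' @param subset_size variables per small model (default: one less than the
#'   number of retained PCs).
#' @param tuning tuning grid ([tune_grid()]); the default full grid is
#'   reduced here to keep a desk-scale run fast — pass `tune_grid()` for the
#'   complete search.
#' @param mess_cutoff MESS screening cutoff (default 0.20).
#' @param seed integer seed.
#' @return list of class `hindcast_run`: `occ`, `bg`, `folds`, `pca`,
#'   `mess_screen`, `ensemble`, `past_maps`, `present_map`, `range_series`,
#'   `mut`, `altitude_coarse`, `temperature`.
#' @export
run_hindcast <- function(series, regions, n_occ = 200, n_bg = 10000,
                         k_folds = 12, subset_size = NULL,
                         tuning = tune_grid(classes = c("L", "LQ"),
                                            reg = c(1, 2)),
                         mess_cutoff = 0.20, seed = 1) {
  stopifnot(inherits(series, "climate_series"))
  fine <- series$present_fine$layers[[1]]
  occ <- simulate_occurrences(regions, fine, n = n_occ, seed = seed)
  region <- build_background_region(regions, fine)
  bg <- simulate_background(region, occ, fine, n = n_bg, seed = seed + 1)
  folds <- assign_spatial_folds(occ, k = k_folds, seed = seed + 2)

  hind <- stack_subset(series$present_fine, hindcast_layers())
  pca <- fit_pca(hind)
  pc_fine <- pca_transform(pca, hind)
  pcs <- names(pc_fine$layers)
  occ_env <- stack_values(pc_fine, cells = occ$cell)[pcs]
  bg_env <- stack_values(pc_fine, cells = bg$cell)[pcs]

  # MESS screening of the PC variables across all past bins
  ref <- dplyr::bind_rows(occ_env, bg_env)
  mess_maps <- lapply(series$past, function(st)
    mess(ref, pca_transform(pca, st)))
  screen <- screen_variables_by_mess(mess_maps, cutoff = mess_cutoff)
  retained <- screen$variable[screen$retained]
  if (length(retained) < 2) stop("MESS screening retained fewer than 2 variables")
  if (is.null(subset_size)) subset_size <- length(retained) - 1L

  ens <- tune_and_fit(occ_env, bg_env, retained, subset_size, folds,
                      tuning = tuning)

  past_maps <- lapply(series$past, function(st)
    ensemble_predict(ens, pca_transform(pca, st)))
  present_map <- ensemble_predict(
    ens, pca_transform(pca, stack_subset(series$present_coarse,
                                         hindcast_layers())))

  alt_coarse <- aggregate_raster(series$altitude, series$config$agg_factor)
  temps <- bin_mean_temperature(series$past)
  rs <- build_range_series(past_maps, present_map, altitude = alt_coarse,
                           temperature = temps)
  structure(list(occ = occ, bg = bg, folds = folds, pca = pca,
                 mess_screen = screen, ensemble = ens,
                 past_maps = past_maps, present_map = present_map,
                 range_series = rs, mut = attr(rs, "mut"),
                 altitude_coarse = alt_coarse, temperature = temps,
                 config = series$config),
            class = "hindcast_run")
}

#' @export
print.hindcast_run <- function(x, ...) {
  cat(sprintf(paste0("<hindcast_run> %d presences, %d background, ",
                     "%d ensemble members, %d bins, MUT = %.2f\n"),
              nrow(x$occ), nrow(x$bg), nrow(x$ensemble$members),
              nrow(x$range_series), x$mut))
  invisible(x)
}

#' Range-dynamics statistics of a hindcast run
#'
#' Computes the variance comparison between bins younger and older than the
#' glacial-cycle switch (Brown-Forsythe on per-bin mean in-range HSI), and
#' the trend regressions of log10 range area on mean temperature and on
#' log10 mean altitude, with ARIMA-error handling of residual
#' autocorrelation.
#'
#' @param run a [run_hindcast()] result.
#' @param switch_ka age of the cycle switch (defaults to the generating
#'   configuration's).
#' @return list: `brown_forsythe` (statistic, p), `trend_temperature`,
#'   `trend_altitude` (both `trend_fit`).
#' @export
range_statistics <- function(run, switch_ka = run$config$switch_ka) {
  rs <- run$range_series
  young <- rs$time <= switch_ka
  bf <- brown_forsythe(rs$mean_hsi[young], rs$mean_hsi[!young])
  tt <- fit_trend(log10(rs$range_area), rs$mean_temperature)
  ta <- fit_trend(log10(rs$range_area), log10(rs$mean_altitude))
  list(brown_forsythe = bf, trend_temperature = tt, trend_altitude = ta)
}

#' Run the forecast arm: VIF filtering, ensemble fit, future projections
#'
#' Filters the nineteen present bioclimatic variables by iterative VIF,
#' fits the ensemble of small models on subsets of the retained variables
#' (each subset leaves out two variables), projects every future
#' (emulator, ssp, period) stack, and returns the per-scenario landscape
#' fragmentation metrics.
#'
#' @param series a [generate_climate_series()] result.
#' @param regions a [generate_regions()] result.
#' @param n_occ,n_bg,k_folds,tuning,seed as in [run_hindcast()].
#' @param vif_threshold VIF threshold (default 3).
#' @param subset_drop how many variables each small model leaves out
#'   (default 2, mirroring six-of-eight).
#' @param max_members cap on the number of subset models (keeps desk-scale
#'   runs tractable; NULL = all subsets).
#' @return list of class `forecast_run`: `occ`, `bg`, `retained`,
#'   `ensemble`, `future_maps`, `present_map`, `metrics` (landscape records
#'   incl. the present), `folds`.
#' @export
run_forecast <- function(series, regions, n_occ = 200, n_bg = 10000,
                         k_folds = 12,
                         tuning = tune_grid(classes = "LQ", reg = 1),
                         vif_threshold = 3, subset_drop = 2,
                         max_members = NULL, seed = 1) {
  stopifnot(inherits(series, "climate_series"))
  fine <- series$present_fine$layers[[1]]
  occ <- simulate_occurrences(regions, fine, n = n_occ, seed = seed)
  region <- build_background_region(regions, fine)
  bg <- simulate_background(region, occ, fine, n = n_bg, seed = seed + 1)
  folds <- assign_spatial_folds(occ, k = k_folds, seed = seed + 2)

  bio <- stack_subset(series$present_fine,
                      setdiff(names(series$present_fine$layers), "NPP"))
  retained <- vif_filter(bio, threshold = vif_threshold)
  subset_size <- length(retained) - subset_drop
  if (subset_size < 1) stop("too few retained variables after VIF filtering")

  occ_env <- stack_values(bio, cells = occ$cell)[retained]
  bg_env <- stack_values(bio, cells = bg$cell)[retained]
  subsets <- enumerate_subsets(retained, subset_size)
  if (!is.null(max_members) && length(subsets) > max_members)
    subsets <- subsets[seq_len(max_members)]  # deterministic lexicographic head
  ens <- tune_and_fit(occ_env, bg_env, retained, subset_size, folds,
                      tuning = tuning, subsets = subsets)

  future_maps <- lapply(series$future, function(st) ensemble_predict(ens, st))
  present_map <- ensemble_predict(ens, series$present_coarse)
  met_future <- dplyr::bind_rows(lapply(future_maps, landscape_metrics))
  met_present <- dplyr::bind_rows(lapply(names(series$config$emulators),
                                         function(em) {
    m <- landscape_metrics(present_map)
    dplyr::bind_rows(lapply(names(series$config$ssps), function(sp)
      dplyr::mutate(m, emulator = em, ssp = sp, period = "present")))
  }))
  metrics <- dplyr::bind_rows(met_present, met_future)
  structure(list(occ = occ, bg = bg, retained = retained, ensemble = ens,
                 future_maps = future_maps, present_map = present_map,
                 metrics = metrics, folds = folds),
            class = "forecast_run")
}

#' @export
print.forecast_run <- function(x, ...) {
  cat(sprintf("<forecast_run> %d retained variables, %d members, %d future stacks\n",
              length(x$retained), nrow(x$ensemble$members),
              length(x$future_maps)))
  invisible(x)
}
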