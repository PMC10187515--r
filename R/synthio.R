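#' Configuration for the synthetic study system
#'
#' Defaults describe a desk-scale stand-in for an Afroalpine endemic's study
#' system: a fine present-day climate grid (19 bioclimatic summaries plus net
#' primary productivity), a coarse 2-Ma hindcast series of five layers whose
#' temperature oscillation switches from ~41-ka to ~100-ka cycles at 1 Ma,
#' sixteen future stacks (4 emulators x 4 emission scenarios x 4 periods)
#' with monotone warming offsets, a ridge-shaped altitude surface negatively
#' correlated with temperature, twelve high-altitude range polygons arranged
#' north to south, a prey polygon, and tiled ecoregions.
#'
#' @param nx,ny fine-grid dimensions (cells).
#' @param cell_size fine-grid cell side (abstract km).
#' @param agg_factor aggregation factor from the fine to the coarse grid.
#' @param n_bins number of past time bins.
#' @param step_ka temporal step between past bins (ka).
#' @param switch_ka age of the cycle-period switch (ka before present).
#' @param period_old_ka,period_young_ka oscillation periods older/younger than
#'   `switch_ka` (ka).
#' @param amp_old,amp_young temperature oscillation amplitudes (deg C) older and
#'   younger than the switch; the younger amplitude is larger, emulating the
#'   stronger 100-ka glacial cycles.
#' @param lapse temperature decrease per unit altitude (deg C per km).
#' @param smooth_cells Gaussian-field smoothing bandwidth (cells).
#' @param emulators named numeric vector of emulator climate sensitivities.
#' @param ssps named numeric vector of end-of-century warming (deg C) per
#'   scenario at sensitivity 4.5.
#' @param periods future period labels (ordered).
#' @param n_polygons number of range polygons.
#' @param polygon_cells approximate side (cells) of each range polygon.
#' @param polygon_alt_frac fraction of the altitude relief where the range
#'   polygons sit (default 0.8): the species occupies a high alpine band
#'   below the bare summits, giving it an interior thermal optimum — colder
#'   cells exist above it, warmer below.
#' @param morpho_n named integer vector of per-species specimen counts.
#' @param morpho_cv coefficient of variation of the default morphometric
#'   covariance (diagonal, sd = cv x mean).
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(nx = 180, ny = 180, cell_size = 1, agg_factor = 4,
                         n_bins = 200, step_ka = 10, switch_ka = 1000,
                         period_old_ka = 41, period_young_ka = 100,
                         amp_old = 1.5, amp_young = 4,
                         lapse = 6.5, smooth_cells = 6,
                         emulators = c(MIROC6 = 2.6, `BCC-CSM2-MR` = 3,
                                       `CNRM-CM6-1` = 4.3, `CNRM-ESM2-1` = 4.8),
                         ssps = c(`126` = 1.0, `245` = 2.0,
                                  `370` = 3.5, `585` = 5.0),
                         periods = c("2021-2040", "2041-2060",
                                     "2061-2080", "2081-2100"),
                         n_polygons = 12, polygon_cells = 8,
                         polygon_alt_frac = 0.8,
                         morpho_n = c(simensis = 20, aureus = 19, adusta = 21,
                                      mesomelas = 21, latrans = 21, lupus = 22,
                                      pictus = 19, alpinus = 21),
                         morpho_cv = 0.05) {
  if (nx < 4 || ny < 4) stop("grid must be at least 4 x 4")
  if (n_bins < 2) stop("`n_bins` must be at least 2")
  if (cell_size <= 0) stop("`cell_size` must be positive")
  structure(as.list(environment()), class = "synth_config")
}

# Smooth Gaussian random field: separable kernel smoothing of white noise,
# rescaled to unit variance. Reflection padding keeps edge variance stable.
smooth_field <- function(nr, nc, bw) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (bw <= 0) return(z)
  half <- max(1L, ceiling(2 * bw))
  k <- exp(-0.5 * ((-half):half / bw)^2)
  k <- k / sum(k)
  pad_smooth <- function(m) {
    n <- nrow(m)
    idx <- c(rev(seq_len(min(half, n))), seq_len(n),
             n + 1 - rev(seq_len(min(half, n))))
    mp <- m[idx, , drop = FALSE]
    out <- apply(mp, 2, function(col) stats::filter(col, k, sides = 2))
    out[(half + 1):(half + n), , drop = FALSE]
  }
  z <- pad_smooth(z)
  z <- t(pad_smooth(t(z)))
  z / sd(as.vector(z))
}

# Deterministic massif-shaped altitude (km) plus a smooth random component:
# three conical peaks along a north-south line through the grid centre.
# Conical slopes make the area of an altitude band grow downslope (as on a
# real mountain), so a cooling that moves the suitable thermal band to lower
# elevations expands its area, and a warming contracts it onto the peaks.
synth_altitude <- function(config, seed) {
  set.seed(seed + 101L)
  nr <- config$ny; nc <- config$nx
  xs <- (seq_len(nc) - 0.5) / nc
  ys <- (seq_len(nr) - 0.5) / nr
  X <- matrix(rep(xs, each = nr), nr, nc)
  Y <- matrix(rep(ys, times = nc), nr, nc)
  peaks <- cbind(x = c(0.5, 0.5, 0.5), y = c(0.22, 0.5, 0.78))
  cone <- matrix(0, nr, nc)
  for (k in seq_len(nrow(peaks))) {
    r <- sqrt((X - peaks[k, "x"])^2 + (Y - peaks[k, "y"])^2)
    cone <- pmax(cone, 1 - r / 0.32)
  }
  cone[cone < 0] <- 0
  alt <- 1.5 + 2.5 * cone + 0.15 * smooth_field(nr, nc, config$smooth_cells)
  alt[alt < 0.2] <- 0.2
  grid_raster(alt, cell_size = config$cell_size)
}

# Present fine-resolution layers BIO1..BIO19 + NPP, built from altitude plus
# independent smooth anomalies. Temperatures in deg C, precipitation in mm.
synth_present_fine <- function(config, seed) {
  alt <- synth_altitude(config, seed)
  set.seed(seed + 202L)
  nr <- config$ny; nc <- config$nx
  a <- alt$values
  anom <- function(scale) scale * smooth_field(nr, nc, config$smooth_cells)
  t_ann <- 25 - config$lapse * a + anom(0.8)     # BIO1
  p_ann <- 600 + 300 * (a - mean(a)) + anom(60)  # BIO12
  p_ann[p_ann < 50] <- 50
  layers <- list(
    BIO1  = t_ann,
    BIO2  = 11 + anom(0.6),
    BIO3  = 80 + anom(2),
    BIO4  = 90 + 12 * (a - mean(a)) + anom(6),
    BIO5  = t_ann + 6 + anom(0.5),
    BIO6  = t_ann - 6 + anom(0.5),
    BIO7  = 12 + anom(0.8),
    BIO8  = t_ann + 1 + anom(0.6),
    BIO9  = t_ann - 1 + anom(0.6),
    BIO10 = t_ann + 2 + anom(0.5),
    BIO11 = t_ann - 2 + anom(0.5),
    BIO12 = p_ann,
    BIO13 = 0.22 * p_ann + anom(12),
    BIO14 = 0.02 * p_ann + anom(2),
    BIO15 = 70 + anom(5),
    BIO16 = 0.55 * p_ann + anom(20),
    BIO17 = 0.08 * p_ann + anom(6),
    BIO18 = 0.45 * p_ann + anom(18),
    BIO19 = 0.12 * p_ann + anom(8),
    NPP   = 900 + 0.8 * (p_ann - mean(p_ann)) - 40 * (t_ann - mean(t_ann)) +
      anom(50)
  )
  layers <- lapply(layers, grid_raster, cell_size = config$cell_size)
  climate_stack(layers, time_label = 0)
}

#' Generate the full synthetic climate series
#'
#' Builds the present fine stack, its coarse aggregate, an ordered series of
#' past coarse stacks carrying exactly the five hindcast layers
#' (`r paste(hindcast_layers(), collapse = ", ")`), and one future stack per
#' (emulator, ssp, period) combination obtained from the present coarse stack
#' by adding a monotone scenario-specific warming offset to temperature
#' layers (with a matching mild precipitation and productivity response).
#' Identical seeds give bitwise-identical output.
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return a list of class `climate_series` with elements `past` (list of
#'   [climate_stack()], youngest first), `present_fine`, `present_coarse`,
#'   `future` (named list, keys `emulator|ssp|period`), `altitude`
#'   (fine-grid [grid_raster()]) and `config`.
#' @export
generate_climate_series <- function(config = synth_config(), seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  present_fine <- synth_present_fine(config, seed)
  agg <- function(st, keep = names(st$layers)) {
    climate_stack(lapply(st$layers[keep], aggregate_raster, config$agg_factor),
                  time_label = st$time_label, scenario = st$scenario)
  }
  present_coarse <- agg(present_fine)

  # Past series: the five hindcast layers on the coarse grid, oscillating
  # with the configured orbital-style periods.
  set.seed(seed + 303L)
  base5 <- present_coarse$layers[hindcast_layers()]
  nrc <- nrow(base5[[1]]$values); ncc <- ncol(base5[[1]]$values)
  ages <- config$step_ka * seq_len(config$n_bins)
  past <- vector("list", config$n_bins)
  for (b in seq_len(config$n_bins)) {
    age <- ages[b]
    young <- age <= config$switch_ka
    period <- if (young) config$period_young_ka else config$period_old_ka
    amp <- if (young) config$amp_young else config$amp_old
    dT <- -amp * (1 + cos(2 * pi * age / period)) / 2   # 0 (interglacial) .. -amp (glacial)
    # Mild glacial drying: the moisture response is kept well below the
    # thermal signal (in niche-gradient units) so the thermal axis dominates
    # the band shift, as for a tropical-highland thermal specialist.
    dP <- 5 * dT
    noise <- function(s) s * smooth_field(nrc, ncc, config$smooth_cells /
                                            config$agg_factor)
    lay <- list(
      BIO10 = grid_raster(base5$BIO10$values + dT + noise(0.3),
                          cell_size = base5$BIO10$cell_size),
      BIO11 = grid_raster(base5$BIO11$values + dT + noise(0.3),
                          cell_size = base5$BIO10$cell_size),
      BIO18 = grid_raster(pmax(base5$BIO18$values + dP + noise(8), 5),
                          cell_size = base5$BIO10$cell_size),
      BIO19 = grid_raster(pmax(base5$BIO19$values + 0.3 * dP + noise(4), 2),
                          cell_size = base5$BIO10$cell_size),
      NPP   = grid_raster(pmax(base5$NPP$values + 10 * dT + noise(20), 10),
                          cell_size = base5$BIO10$cell_size)
    )
    past[[b]] <- climate_stack(lay, time_label = age)
  }

  # Future stacks: present coarse plus warming offsets. Offset grows with the
  # emulator's climate sensitivity, the scenario's emission severity and the
  # period's progress, so spatial-mean temperature is monotone in all three.
  future <- list()
  nper <- length(config$periods)
  for (em in names(config$emulators)) {
    for (ssp in names(config$ssps)) {
      for (ip in seq_len(nper)) {
        off <- (config$emulators[[em]] / 4.5) * config$ssps[[ssp]] * (ip / nper)
        lay <- present_coarse$layers
        for (nm in names(lay)) {
          v <- lay[[nm]]$values
          if (nm %in% c("BIO1", "BIO5", "BIO6", "BIO8", "BIO9",
                        "BIO10", "BIO11")) v <- v + off
          if (nm %in% c("BIO12", "BIO13", "BIO16", "BIO18")) v <- v * (1 - 0.02 * off)
          if (nm == "NPP") v <- v - 15 * off
          lay[[nm]] <- grid_raster(v, cell_size = lay[[nm]]$cell_size)
        }
        key <- paste(em, ssp, config$periods[ip], sep = "|")
        future[[key]] <- climate_stack(
          lay, time_label = config$periods[ip],
          scenario = list(emulator = em, ssp = ssp, period = config$periods[ip]))
      }
    }
  }

  structure(list(past = past, present_fine = present_fine,
                 present_coarse = present_coarse, future = future,
                 altitude = synth_altitude(config, seed), config = config),
            class = "climate_series")
}

#' @export
print.climate_series <- function(x, ...) {
  cat(sprintf(paste0("<climate_series> %d past bins (step %g ka), ",
                     "%d future stacks, fine %d x %d / coarse %d x %d\n"),
              length(x$past), x$config$step_ka, length(x$future),
              x$config$ny, x$config$nx,
              nrow(x$present_coarse$layers[[1]]$values),
              ncol(x$present_coarse$layers[[1]]$values)))
  invisible(x)
}

#' Generate range, prey and ecoregion polygons plus altitude
#'
#' Range polygons are rectangles centred on the high-altitude ridge, spread
#' north to south; the prey polygon is a wide band overlapping them; the
#' ecoregions tile the extent in a 2 x 2 block pattern.
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return a list of class `region_set`: `species_polygons` (list of vertex
#'   matrices), `prey_polygon`, `ecoregion_polygons`, `altitude`
#'   (fine [grid_raster()]).
#' @export
generate_regions <- function(config = synth_config(), seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  altitude <- synth_altitude(config, seed)
  set.seed(seed + 404L)
  W <- config$nx * config$cell_size
  H <- config$ny * config$cell_size
  k <- config$n_polygons
  side <- config$polygon_cells * config$cell_size
  # Place polygon centres greedily on the target alpine band (cells closest
  # to the configured fraction of the relief), with a minimum separation so
  # the polygons ring the peaks north to south.
  cells <- grid_cells(altitude)
  alt_t <- min(cells$value) +
    config$polygon_alt_frac * (max(cells$value) - min(cells$value))
  ord <- order(abs(cells$value - alt_t))
  centres <- matrix(NA_real_, 0, 2)
  min_sep <- 1.05 * side
  for (i in ord) {
    cx <- cells$x[i]; cy <- cells$y[i]
    if (cx < side / 2 || cx > W - side / 2 ||
        cy < side / 2 || cy > H - side / 2) next
    if (nrow(centres) &&
        any((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2 < min_sep^2)) next
    centres <- rbind(centres, c(cx, cy))
    if (nrow(centres) == k) break
  }
  if (nrow(centres) < k)
    stop("could not place the requested number of range polygons")
  jit <- (matrix(runif(2 * k), k, 2) - 0.5) * config$cell_size
  species <- lapply(seq_len(k), function(i) {
    cx <- min(max(centres[i, 1] + jit[i, 1], side / 2), W - side / 2)
    cy <- min(max(centres[i, 2] + jit[i, 2], side / 2), H - side / 2)
    rect_polygon(cx - side / 2, cy - side / 2, cx + side / 2, cy + side / 2)
  })
  x0 <- W / 2
  prey <- rect_polygon(max(x0 - 4 * side, 0), 0.02 * H,
                       min(x0 + 4 * side, W), 0.98 * H)
  eco <- list(rect_polygon(0, 0, W / 2, H / 2),
              rect_polygon(W / 2, 0, W, H / 2),
              rect_polygon(0, H / 2, W / 2, H),
              rect_polygon(W / 2, H / 2, W, H))
  structure(list(species_polygons = species, prey_polygon = prey,
                 ecoregion_polygons = eco, altitude = altitude,
                 config = config),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d range polygons, %d ecoregions, altitude %d x %d\n",
              length(x$species_polygons), length(x$ecoregion_polygons),
              nrow(x$altitude$values), ncol(x$altitude$values)))
  invisible(x)
}

#' The nineteen dentognathic measurement names
#'
#' Lower-tooth lengths/breadths (canine, p4, m1 trigonid/talonid, m2), the
#' canine-to-m2 span, and jaw depths/breadths at four positions (mm).
#' @return character vector of column names.
#' @export
morpho_variables <- function() {
  c("Lc", "Bc", "Lp4", "Bp4", "Lm1trig", "Bm1", "Lm1tal", "Bm1tal",
    "Lm2", "Bm2", "Lcm2", "JDc", "JBc", "JDp3p4", "JBp3p4", "JDp4m1",
    "JBp4m1", "JDm1m2", "JBm1m2")
}

# Default dentognathic mean vectors (mm). Mesocarnivores share a jackal-like
# baseline; hypercarnivores are scaled up and more robust, so the first
# principal component of the log-measurements separates the two guilds.
morpho_default_means <- function() {
  base <- c(Lc = 9.5, Bc = 6.2, Lp4 = 11.5, Bp4 = 5.2, Lm1trig = 14.5,
            Bm1 = 7.6, Lm1tal = 7.0, Bm1tal = 6.4, Lm2 = 9.0, Bm2 = 6.6,
            Lcm2 = 78, JDc = 19, JBc = 9.5, JDp3p4 = 18.5, JBp3p4 = 9.0,
            JDp4m1 = 20.5, JBp4m1 = 10.0, JDm1m2 = 21.5, JBm1m2 = 10.5)
  tweak <- function(v, f) { out <- base; out[names(f)] <- out[names(f)] * f; out * v }
  list(
    # mesocarnivorous guild
    simensis  = tweak(1.10, c(Lp4 = 1.10, Bp4 = 0.86, Lm1trig = 1.08,
                              Bm1tal = 0.90, Lcm2 = 1.12, JBp3p4 = 0.88)),
    aureus    = tweak(0.98, c(Bp4 = 1.04)),
    adusta    = tweak(0.95, c(Lm1tal = 1.06)),
    mesomelas = tweak(0.93, c(Bm1 = 1.03)),
    latrans   = tweak(1.12, c(JDc = 1.04)),
    # hypercarnivorous guild: larger, broader teeth, deeper jaws
    lupus     = tweak(1.55, c(Bp4 = 1.15, Bm1 = 1.12, JBc = 1.15,
                              JBp4m1 = 1.12, Lm1tal = 0.92)),
    pictus    = tweak(1.40, c(Bp4 = 1.18, Bm1 = 1.15, Lm1tal = 0.85,
                              JBp3p4 = 1.12)),
    alpinus   = tweak(1.32, c(Bp4 = 1.12, Lm1tal = 0.80, Lm2 = 0.85,
                              JBm1m2 = 1.10))
  )
}

#' Generate a multispecies dentognathic measurement table
#'
#' Draws specimens from per-species multivariate normal distributions over the
#' nineteen dentognathic variables. Defaults use the comparative sample sizes
#' (simensis 20, aureus 19, adusta 21, mesomelas 21, latrans 21, lupus 22,
#' pictus 19, alpinus 21) and place the hypercarnivorous and mesocarnivorous
#' guilds in separated mean clusters. Optionally appends one fossil specimen
#' drawn from the simensis distribution.
#'
#' @param config a [synth_config()] (only `morpho_n` and `morpho_cv` are used).
#' @param seed integer seed.
#' @param means optional named list of per-species mean vectors (19 values).
#' @param covariances optional named list of per-species 19 x 19 covariance
#'   matrices; default is diagonal with sd = `morpho_cv` x mean.
#' @param include_fossil append a fossil row drawn from the simensis model?
#' @return tibble with `species` and the nineteen measurement columns (mm).
#' @export
generate_morpho_table <- function(config = synth_config(), seed = 1,
                                  means = NULL, covariances = NULL,
                                  include_fossil = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed + 505L)
  vars <- morpho_variables()
  if (is.null(means)) means <- morpho_default_means()
  ns <- config$morpho_n
  if (is.null(names(ns)) || !all(names(ns) %in% names(means)))
    stop("`morpho_n` must be named by species present in `means`")
  draw <- function(n, mu, Sigma) {
    ev <- eigen(Sigma, symmetric = TRUE)
    if (any(ev$values < -1e-8 * max(abs(ev$values), 1)))
      stop("covariance must be positive semidefinite")
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(mu))
    t(mu + L %*% matrix(rnorm(length(mu) * n), length(mu), n))
  }
  rows <- purrr::map(names(ns), function(sp) {
    mu <- means[[sp]][vars]
    Sigma <- if (!is.null(covariances)) covariances[[sp]] else
      diag((config$morpho_cv * mu)^2, length(mu))
    m <- draw(ns[[sp]], mu, Sigma)
    colnames(m) <- vars
    dplyr::bind_cols(tibble(species = sp), as_tibble(m))
  })
  out <- dplyr::bind_rows(rows)
  if (include_fossil) {
    mu <- means[["simensis"]][vars]
    Sigma <- if (!is.null(covariances)) covariances[["simensis"]] else
      diag((config$morpho_cv * mu)^2, length(mu))
    m <- draw(1, mu, Sigma)
    colnames(m) <- vars
    out <- dplyr::bind_rows(out, dplyr::bind_cols(tibble(species = "fossil"),
                                                 as_tibble(m)))
  }
  if (any(out[vars] <= 0)) out[vars][out[vars] <= 0] <- 0.1
  out
}
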