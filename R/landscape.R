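#' Classify an HSI map into four suitability classes
#'
#' Class 1: HSI < 0.25 (worst); class 2: 0.25 <= HSI < 0.5; class 3:
#' 0.5 <= HSI < 0.75; class 4: HSI >= 0.75 (best). Missing cells stay
#' missing.
#'
#' @param map a `suitability_map` or [grid_raster()].
#' @return object of class `class_map`: integer matrix `classes`, plus the
#'   grid geometry.
#' @export
classify_hsi <- function(map) {
  g <- if (inherits(map, "suitability_map")) map$hsi else map
  v <- g$values
  cl <- matrix(NA_integer_, nrow(v), ncol(v))
  cl[!is.na(v) & v < 0.25] <- 1L
  cl[!is.na(v) & v >= 0.25 & v < 0.5] <- 2L
  cl[!is.na(v) & v >= 0.5 & v < 0.75] <- 3L
  cl[!is.na(v) & v >= 0.75] <- 4L
  structure(list(classes = cl, cell_size = g$cell_size, origin = g$origin),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  tab <- table(factor(as.vector(x$classes), levels = 1:4))
  cat(sprintf("<class_map> %d x %d cells; class counts: %s\n",
              nrow(x$classes), ncol(x$classes),
              paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' Label connected patches of a binary matrix
#'
#' Connected-component labelling with rook (4-neighbour) or queen
#' (8-neighbour) connectivity, by breadth-first flood fill.
#'
#' @param mask logical matrix.
#' @param neighbourhood 4 (default) or 8.
#' @return integer matrix of patch labels (0 = background).
#' @export
label_patches <- function(mask, neighbourhood = 4) {
  stopifnot(neighbourhood %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (neighbourhood == 4)
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  else
    as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5, , drop = FALSE]
  nxt <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% nr + 1L
      cl <- (cur - 1L) %/% nr + 1L
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1]; cc <- cl + offs[k, 2]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          idx <- (cc - 1L) * nr + rr
          if (mask[idx] && lab[idx] == 0L) {
            lab[idx] <- nxt
            queue <- c(queue, idx)
          }
        }
      }
    }
  }
  lab
}

# Single-count like adjacencies (shared edges) of a binary mask.
like_adjacencies <- function(mask) {
  m <- mask & !is.na(mask)
  horiz <- sum(m[, -ncol(m), drop = FALSE] & m[, -1, drop = FALSE])
  vert <- sum(m[-nrow(m), , drop = FALSE] & m[-1, , drop = FALSE])
  horiz + vert
}

# Maximum possible like adjacencies for a class of A cells packed into the
# most compact (near-square) patch.
max_like_adjacencies <- function(A) {
  if (A <= 1) return(0)
  n <- floor(sqrt(A))
  m <- A - n^2
  if (m == 0) 2 * n * (n - 1)
  else if (m <= n) 2 * n * (n - 1) + 2 * m - 1
  else 2 * n * (n - 1) + 2 * m - 2
}

#' Fragmentation metrics for one suitability class
#'
#' Patch-based FRAGSTATS-style metrics with rook connectivity:
#' \describe{
#'   \item{np}{number of patches.}
#'   \item{area_mn}{mean patch area, in cell-area units.}
#'   \item{ai}{aggregation index, `100 * e / max_e`: the single-count like
#'     adjacencies divided by their maximum for a maximally compact patch of
#'     the same total area (0-100; NA for a single-cell class).}
#'   \item{clumpy}{clumpiness: with `G = e2 / t2` the proportion of the
#'     class's double-count adjacencies that are like adjacencies and `P`
#'     the class's landscape proportion, `(G - P) / (1 - P)` when `G >= P`,
#'     else `(G - P) / P` (-1..1).}
#'   \item{cohesion}{patch cohesion,
#'     `100 * (1 - sum(p) / sum(p sqrt(a))) / (1 - 1 / sqrt(Z))` with patch
#'     perimeters p (cell edges), areas a (cells) and Z the landscape cell
#'     count (0-100).}
#'   \item{division}{`1 - sum((a / A)^2)` with A the landscape area: the
#'     probability that two random landscape locations fall in different
#'     patches of the class (0-1).}
#' }
#'
#' @param cmap a [classify_hsi()] result.
#' @param class_id class label (1-4).
#' @param neighbourhood patch connectivity, 4 (default) or 8.
#' @return one-row tibble: `class`, `np`, `area_mn`, `ai`, `clumpy`,
#'   `cohesion`, `division`.
#' @export
patch_metrics <- function(cmap, class_id, neighbourhood = 4) {
  stopifnot(inherits(cmap, "class_map"))
  cl <- cmap$classes
  if (!any(!is.na(cl))) stop("empty landscape")
  mask <- !is.na(cl) & cl == class_id
  Z <- sum(!is.na(cl))
  cell_area <- cmap$cell_size^2
  if (!any(mask))
    return(tibble(class = class_id, np = 0L, area_mn = NA_real_,
                  ai = NA_real_, clumpy = NA_real_, cohesion = NA_real_,
                  division = NA_real_))
  lab <- label_patches(mask, neighbourhood)
  areas <- tabulate(lab[lab > 0L])
  np <- length(areas)
  A <- sum(areas)
  # aggregation index (single-count adjacencies)
  e <- like_adjacencies(mask)
  maxe <- max_like_adjacencies(A)
  ai <- if (maxe > 0) 100 * e / maxe else NA_real_
  # clumpiness: total adjacencies involving the class (double count, among
  # non-missing neighbours)
  m_ok <- !is.na(cl)
  t2 <- sum(mask[, -ncol(cl), drop = FALSE] & m_ok[, -1, drop = FALSE]) +
    sum(mask[, -1, drop = FALSE] & m_ok[, -ncol(cl), drop = FALSE]) +
    sum(mask[-nrow(cl), , drop = FALSE] & m_ok[-1, , drop = FALSE]) +
    sum(mask[-1, , drop = FALSE] & m_ok[-nrow(cl), , drop = FALSE])
  P <- A / Z
  clumpy <- if (t2 > 0 && P < 1) {
    G <- 2 * e / t2
    if (G >= P) (G - P) / (1 - P) else (G - P) / P
  } else NA_real_
  # cohesion: perimeter of each patch in cell edges
  perims <- vapply(seq_len(np), function(j) {
    mj <- lab == j
    4L * sum(mj) - 2L * like_adjacencies(mj)
  }, numeric(1))
  cohesion <- if (Z > 1)
    100 * (1 - sum(perims) / sum(perims * sqrt(areas))) / (1 - 1 / sqrt(Z))
  else NA_real_
  division <- 1 - sum((areas / Z)^2)
  tibble(class = class_id, np = np, area_mn = mean(areas) * cell_area,
         ai = ai, clumpy = clumpy, cohesion = cohesion, division = division)
}

#' Fragmentation metrics for every suitability class of a map
#'
#' @param map a `suitability_map`, [grid_raster()] or [classify_hsi()] result.
#' @param neighbourhood patch connectivity (4 or 8).
#' @return tibble, one row per class 1-4, with the scenario key columns
#'   (`emulator`, `ssp`, `period`) when the map carries one.
#' @export
landscape_metrics <- function(map, neighbourhood = 4) {
  cmap <- if (inherits(map, "class_map")) map else classify_hsi(map)
  out <- dplyr::bind_rows(lapply(1:4, patch_metrics, cmap = cmap,
                                 neighbourhood = neighbourhood))
  if (!inherits(map, "class_map") && inherits(map, "suitability_map") &&
      !is.null(map$scenario)) {
    out$emulator <- map$scenario$emulator
    out$ssp <- map$scenario$ssp
    out$period <- map$scenario$period
  }
  out
}

# log10 transform of the strictly positive metrics; the signed clumpiness
# stays on its natural scale.
transform_metrics <- function(records, metrics) {
  for (m in metrics) {
    if (m == "clumpy") next
    if (any(records[[m]] <= 0, na.rm = TRUE))
      stop(sprintf("metric %s has non-positive values; cannot log10-transform", m))
    records[[m]] <- log10(records[[m]])
  }
  records
}

#' Two-way permutational MANOVA of landscape metrics across scenarios
#'
#' Compares the fragmentation-metric profiles between climate emulators and
#' future periods, treating the emission scenarios as repeated experiments:
#' permutations are restricted within `strata` levels. The worst class
#' (class 1) and the zero-variance `division` metric are excluded; the
#' strictly positive metrics are log10-transformed. Distances are Euclidean;
#' sums of squares are sequential (factor order as given). A pairwise
#' follow-up is run for each significant factor.
#'
#' @param records tibble from [landscape_metrics()] rows with `emulator`,
#'   `ssp`, `period` keys.
#' @param metrics response metric columns.
#' @param factors the two crossed factors (default emulator, period).
#' @param strata stratification column (default `ssp`).
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @param alpha significance level for launching the pairwise follow-up.
#' @return list of class `permanova_result`: `table` (per-term tibble with
#'   pseudo-F and p), `pairwise` (tibble or NULL), `n`.
#' @export
permanova_two_way <- function(records,
                              metrics = c("np", "area_mn", "ai", "clumpy",
                                          "cohesion"),
                              factors = c("emulator", "period"),
                              strata = "ssp", n_perm = 9999, seed = 1,
                              alpha = 0.05) {
  dat <- dplyr::filter(records, .data$class != 1)
  dat <- dat[complete.cases(dat[metrics]), , drop = FALSE]
  for (f in c(factors, strata))
    if (length(unique(dat[[f]])) < (if (f == strata) 1 else 2))
      stop(sprintf("factor %s needs at least 2 levels", f))
  dat <- transform_metrics(dat, metrics)
  Y <- as.matrix(dat[metrics])
  fml <- stats::as.formula(paste("Y ~", paste(factors, collapse = " + ")))
  set.seed(seed)
  ctrl <- permute::how(nperm = n_perm, blocks = factor(dat[[strata]]))
  res <- vegan::adonis2(fml, data = dat, method = "euclidean",
                        permutations = ctrl, by = "terms")
  tab <- tibble(term = rownames(res), df = res$Df, ss = res$SumOfSqs,
                pseudo_f = res$F, p_value = res$`Pr(>F)`)
  pairwise <- NULL
  sig <- tab$term[tab$term %in% factors &
                    !is.na(tab$p_value) & tab$p_value < alpha]
  if (length(sig)) {
    rows <- list()
    for (f in sig) {
      lev <- unique(dat[[f]])
      for (pair in enumerate_subsets(as.character(lev), 2)) {
        sub <- dat[dat[[f]] %in% pair, , drop = FALSE]
        Ys <- as.matrix(sub[metrics])
        set.seed(seed)
        ctrl2 <- permute::how(nperm = n_perm, blocks = factor(sub[[strata]]))
        r2 <- vegan::adonis2(stats::as.formula(paste("Ys ~", f)), data = sub,
                             method = "euclidean", permutations = ctrl2)
        rows[[length(rows) + 1L]] <-
          tibble(factor = f, level_1 = pair[1], level_2 = pair[2],
                 pseudo_f = r2$F[1], p_value = r2$`Pr(>F)`[1])
      }
    }
    pairwise <- dplyr::bind_rows(rows)
    pairwise$p_adjusted <- stats::p.adjust(pairwise$p_value, method = "BH")
  }
  structure(list(table = tab, pairwise = pairwise, n = nrow(dat)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("<permanova_result>\n")
  print(as.data.frame(x$table))
  invisible(x)
}

#' Mean-patch-area trend over projection periods
#'
#' Per emulator, regresses log10 mean patch area on the period index and the
#' suitability class (categorical). Zero/NA patch-area rows are dropped with
#' a message.
#'
#' @param records metrics tibble with `emulator`, `period`, `class`,
#'   `area_mn`; `period` must be orderable (its index is the regressor).
#' @param exclude_class classes to drop (default 1).
#' @return tibble of per-emulator coefficient estimates (term, estimate,
#'   std.error, p.value).
#' @export
patch_area_trend <- function(records, exclude_class = 1) {
  dat <- dplyr::filter(records, !(.data$class %in% exclude_class))
  bad <- is.na(dat$area_mn) | dat$area_mn <= 0
  if (any(bad)) {
    message(sprintf("dropping %d rows with zero/missing patch area", sum(bad)))
    dat <- dat[!bad, , drop = FALSE]
  }
  dat$period_index <- as.integer(factor(dat$period,
                                        levels = sort(unique(dat$period))))
  out <- lapply(split(dat, dat$emulator), function(d) {
    if (length(unique(d$period_index)) < 2) return(NULL)
    has_classes <- length(unique(d$class)) > 1
    fml <- if (has_classes) log10(area_mn) ~ period_index + factor(class)
    else log10(area_mn) ~ period_index
    fit <- lm(fml, data = d)
    cf <- summary(fit)$coefficients
    tibble(emulator = d$emulator[1], term = rownames(cf),
           estimate = cf[, 1], std.error = cf[, 2], p.value = cf[, 4])
  })
  dplyr::bind_rows(out[!vapply(out, is.null, logical(1))])
}

#' Ordinal regression of suitability class on landscape metrics
#'
#' Per emulator, fits a proportional-odds (ordinal logit) model of the
#' suitability class on the landscape metrics, each in interaction with the
#' period index; falls back to a multinomial logit with a warning when the
#' ordinal fit fails (e.g. perfect separation).
#'
#' @param records metrics tibble (`emulator`, `period`, `class` + metrics).
#' @param metrics explanatory metric columns.
#' @param exclude_class classes to drop (default 1).
#' @return tibble with one row per emulator term (`emulator`, `model`,
#'   `term`, `estimate`).
#' @export
class_metric_glm <- function(records,
                             metrics = c("np", "area_mn", "ai", "clumpy",
                                         "cohesion"),
                             exclude_class = 1) {
  dat <- dplyr::filter(records, !(.data$class %in% exclude_class))
  dat <- dat[complete.cases(dat[metrics]), , drop = FALSE]
  if (length(unique(dat$class)) < 2) stop("need at least 2 classes present")
  dat$period_index <- as.integer(factor(dat$period,
                                        levels = sort(unique(dat$period))))
  rhs <- paste(sprintf("%s * period_index", metrics), collapse = " + ")
  out <- lapply(split(dat, dat$emulator), function(d) {
    d$class_f <- factor(d$class, ordered = TRUE)
    fit <- tryCatch(
      suppressWarnings(MASS::polr(stats::as.formula(paste("class_f ~", rhs)),
                                  data = d, Hess = FALSE)),
      error = function(e) NULL)
    if (!is.null(fit))
      return(tibble(emulator = d$emulator[1], model = "ordinal-logit",
                    term = names(coef(fit)), estimate = unname(coef(fit))))
    warning("ordinal fit failed; falling back to multinomial logit")
    fit <- nnet::multinom(stats::as.formula(paste("factor(class) ~", rhs)),
                          data = d, trace = FALSE)
    cf <- coef(fit)
    if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1,
                                       dimnames = list(NULL, names(cf)))
    tibble(emulator = d$emulator[1], model = "multinomial-logit",
           term = rep(colnames(cf), each = nrow(cf)),
           estimate = as.vector(cf))
  })
  dplyr::bind_rows(out)
}
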