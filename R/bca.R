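# Taxon sets of every internal node of an hclust tree.
hclust_node_sets <- function(hc) {
  labs <- hc$labels
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    get <- function(j) if (j < 0) labs[-j] else sets[[j]]
    sets[[i]] <- sort(c(get(hc$merge[i, 1]), get(hc$merge[i, 2])))
  }
  sets
}

# Pairwise-agreement (Rand) similarity between two partitions of the same
# taxa: the fraction of taxon pairs on which the partitions agree about
# co-membership; 0 = totally different, 1 = identical.
partition_similarity <- function(u, v) {
  n <- length(u)
  if (n < 2) return(1)
  same_u <- outer(u, u, `==`)[upper.tri(matrix(0, n, n))]
  same_v <- outer(v, v, `==`)[upper.tri(matrix(0, n, n))]
  mean(same_u == same_v)
}

#' Bootstrap cluster analysis with sharpness testing
#'
#' Builds a reference UPGMA (average-linkage) dendrogram of the taxa from
#' the Euclidean distances between their mean scores, then bootstraps the
#' specimens (resampling with replacement within each taxon), reclusters,
#' and records (1) per-node support — the percentage of replicates whose
#' tree contains the same taxon set — and (2) for every partitioning level
#' k, the similarity G* between the reference and the replicate partition
#' (pairwise co-membership agreement, 0-1). The expected similarity G-degree
#' under the null that the resampled data carry no group structure is
#' obtained from matched replicates with specimen taxon labels permuted.
#' A partitioning level is declared sharp when `P(G-degree <= G*) > alpha`
#' (the published decision rule).
#'
#' @param scores tibble with a `species` column and numeric score columns
#'   (e.g. `log_pca(...)$scores`), or a numeric matrix plus `labels`.
#' @param labels taxon label per row (defaults to the `species` column).
#' @param n_boot bootstrap replicates (default 1000).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @param exclude labels to drop before clustering (default none).
#' @return object of class `bca_result`: `reference` (hclust), `support`
#'   (tibble: node taxon set, support %), `levels` (tibble per partition
#'   level: `k`, `g_star_mean`, `g_null_mean`, `p_sharp`, `sharp`),
#'   `n_boot`.
#' @export
bca <- function(scores, labels = NULL, n_boot = 1000, alpha = 0.05,
                seed = 1, exclude = character(0)) {
  if (n_boot < 1) stop("`n_boot` must be at least 1")
  if (is.null(labels)) {
    stopifnot("species" %in% names(scores))
    labels <- scores$species
    X <- as.matrix(scores[setdiff(names(scores), "species")])
  } else {
    X <- as.matrix(scores)
  }
  keep <- !(labels %in% exclude)
  X <- X[keep, , drop = FALSE]; labels <- labels[keep]
  taxa <- sort(unique(labels))
  if (length(taxa) < 3) stop("need at least 3 taxa")
  taxon_means <- function(Xm, lab) {
    t(vapply(taxa, function(s) colMeans(Xm[lab == s, , drop = FALSE]),
             numeric(ncol(Xm))))
  }
  cluster <- function(M) {
    hc <- hclust(dist(M), method = "average")
    hc$labels <- taxa
    hc
  }
  ref <- cluster(taxon_means(X, labels))
  ref_sets <- hclust_node_sets(ref)
  ks <- if (length(taxa) > 3) 2:(length(taxa) - 1) else 2
  ref_parts <- lapply(ks, function(k) cutree(ref, k = k))

  set.seed(seed)
  support_hits <- numeric(length(ref_sets))
  g_star <- matrix(NA_real_, n_boot, length(ks))
  g_null <- matrix(NA_real_, n_boot, length(ks))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(taxa, function(s) {
      w <- which(labels == s)
      sample(w, length(w), replace = TRUE)
    }))
    rep_hc <- cluster(taxon_means(X[idx, , drop = FALSE], labels[idx]))
    rep_sets <- hclust_node_sets(rep_hc)
    support_hits <- support_hits + vapply(ref_sets, function(s)
      any(vapply(rep_sets, identical, logical(1), s)), logical(1))
    null_hc <- cluster(taxon_means(X, sample(labels)))
    for (j in seq_along(ks)) {
      g_star[b, j] <- partition_similarity(ref_parts[[j]],
                                           cutree(rep_hc, k = ks[j]))
      g_null[b, j] <- partition_similarity(ref_parts[[j]],
                                           cutree(null_hc, k = ks[j]))
    }
  }
  p_sharp <- colMeans(g_null <= g_star)
  support <- tibble(
    node = vapply(ref_sets, paste, character(1), collapse = ","),
    n_taxa = lengths(ref_sets),
    support = 100 * support_hits / n_boot)
  levels <- tibble(k = ks, g_star_mean = colMeans(g_star),
                   g_null_mean = colMeans(g_null), p_sharp = p_sharp,
                   sharp = p_sharp > alpha)
  structure(list(reference = ref, support = support, levels = levels,
                 n_boot = n_boot),
            class = "bca_result")
}

#' @export
print.bca_result <- function(x, ...) {
  cat(sprintf("<bca_result> %d replicates\n", x$n_boot))
  print(as.data.frame(x$support))
  invisible(x)
}

#' @export
tidy.bca_result <- function(x, ...) x$support

#' @export
autoplot.bca_result <- function(object, ...) {
  hc <- object$reference
  dend <- stats::as.dendrogram(hc)
  dd <- ggplot2::ggplot() +
    ggplot2::theme_minimal() +
    ggplot2::labs(y = "UPGMA height", x = NULL)
  # simple segment rendering of the dendrogram
  segs <- dendro_segments(dend)
  dd + ggplot2::geom_segment(
    data = segs,
    ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                 yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = seq_along(hc$labels[hc$order]),
                                labels = hc$labels[hc$order])
}

# Flatten a dendrogram into plottable segments.
dendro_segments <- function(d) {
  segs <- list()
  walk <- function(node, xmid) {
    if (is.leaf(node)) return(attr(node, "x_pos"))
    xs <- numeric(0)
    for (i in seq_along(node)) xs <- c(xs, walk(node[[i]], xmid))
    h <- attr(node, "height")
    hs <- vapply(seq_along(node), function(i)
      if (is.leaf(node[[i]])) 0 else attr(node[[i]], "height"), numeric(1))
    for (i in seq_along(node))
      segs[[length(segs) + 1L]] <<- data.frame(x = xs[i], y = hs[i],
                                               xend = xs[i], yend = h)
    segs[[length(segs) + 1L]] <<- data.frame(x = min(xs), y = h,
                                             xend = max(xs), yend = h)
    mean(range(xs))
  }
  # assign leaf x positions in plotting order
  counter <- 0
  d <- stats::dendrapply(d, function(n) {
    if (is.leaf(n)) { counter <<- counter + 1; attr(n, "x_pos") <- counter }
    n
  })
  walk(d, 0)
  do.call(rbind, segs)
}
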