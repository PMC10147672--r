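#' Euclidean distance between grandparental birthplaces
#'
#' Plain Euclidean distance on decimal degrees,
#' `sqrt((lat_i - lat_j)^2 + (lon_i - lon_j)^2)` — deliberately not
#' great-circle, since the downstream filter is defined on raw coordinate
#' differences. Any missing coordinate gives a missing result, not zero.
#'
#' @param a,b numeric `(lat, lon)` pairs, or two-column matrices.
#' @return Distance(s) in degree units.
#' @export
gp_distance <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  stopifnot(ncol(a) == 2L, ncol(b) == 2L)
  check <- function(m) {
    lat <- m[, 1]; lon <- m[, 2]
    if (any(lat < -90 | lat > 90, na.rm = TRUE) ||
        any(lon < -180 | lon > 180, na.rm = TRUE))
      stop("coordinates outside valid latitude/longitude ranges")
  }
  check(a); check(b)
  unname(sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2))
}

## grandparent coordinate matrix (4 x 2) for one metadata row
gp_coords <- function(row) {
  m <- matrix(unlist(row[paste0("gp", rep(1:4, each = 2), "_",
                                c("lat", "lon"))]),
              ncol = 2L, byrow = TRUE)
  m[complete.cases(m), , drop = FALSE]
}

#' Mean grandparental-distance filter
#'
#' For each sample, the mean of [gp_distance()] over all unordered pairs of
#' located grandparents (up to 6 pairs); samples are kept when the mean is
#' at most `threshold` (inclusive). Samples with fewer than two located
#' grandparents are unevaluable — neither kept nor excluded.
#'
#' @param meta metadata with grandparental coordinate columns.
#' @param threshold mean-distance cutoff in degrees (default 0.5).
#' @return A list with `kept`, `excluded`, `unevaluable` id vectors and the
#'   per-sample `mean_distance`.
#' @export
mean_gp_distance_filter <- function(meta, threshold = 0.5) {
  md <- setNames(rep(NA_real_, nrow(meta)), meta$id)
  for (i in seq_len(nrow(meta))) {
    pts <- gp_coords(meta[i, ])
    if (nrow(pts) < 2L) next
    pr <- combn(nrow(pts), 2L)
    md[i] <- mean(gp_distance(pts[pr[1, ], , drop = FALSE],
                              pts[pr[2, ], , drop = FALSE]))
  }
  list(kept = meta$id[!is.na(md) & md <= threshold],
       excluded = meta$id[!is.na(md) & md > threshold],
       unevaluable = meta$id[is.na(md)],
       mean_distance = md)
}

#' Denomination-by-cluster composition test
#'
#' Pearson chi-squared test of the cluster x denomination contingency table
#' with a simulated p-value (fixed-margin tables, seeded,
#' `p = (1 + #{simulated >= observed}) / (n_sim + 1)` so p is never zero) —
#' appropriate when cell counts are low. Per-cell Pearson residuals and each
#' cell's share of the overall statistic are reported.
#'
#' @param clusters named cluster labels.
#' @param denominations named denomination labels over the same ids.
#' @param n_sim simulation replicates (default 2000).
#' @param seed integer seed.
#' @return An object of class `composition_test`: `table`, `proportions`,
#'   `statistic`, `p_value`, `residuals`, `residual_share`.
#' @export
composition_chisq <- function(clusters, denominations, n_sim = 2000L,
                              seed = 1L) {
  ids <- intersect(names(clusters), names(denominations))
  tab <- table(cluster = clusters[ids], denomination = denominations[ids])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("need >= 2 clusters and >= 2 denominations with nonzero margins")
  set.seed(derive_seed(seed, 47L))
  ct <- suppressWarnings(chisq.test(tab, simulate.p.value = TRUE,
                                    B = n_sim))
  share <- ct$residuals^2 / ct$statistic
  structure(list(table = tab, proportions = prop.table(tab, 1L),
                 statistic = unname(ct$statistic),
                 p_value = ct$p.value, residuals = ct$residuals,
                 residual_share = share, n_sim = n_sim),
            class = "composition_test")
}

#' @export
print.composition_test <- function(x, ...) {
  cat(sprintf("cluster x denomination chi-squared = %.3f, simulated p = %.4g (%d tables)\n",
              x$statistic, x$p_value, x$n_sim))
  top <- which(x$residual_share == max(x$residual_share), arr.ind = TRUE)[1, ]
  cat(sprintf("  largest cell contribution: %s / %s (%.1f%% of the statistic)\n",
              rownames(x$table)[top[1]], colnames(x$table)[top[2]],
              100 * max(x$residual_share)))
  invisible(x)
}

#' Median grandparental distance between cluster pairs
#'
#' For each unordered pair of clusters, the median of [gp_distance()] over
#' all cross-cluster pairs of located grandparental birthplaces. Pairs with
#' no located members give a missing entry.
#'
#' @param clusters named cluster labels.
#' @param meta metadata with grandparental coordinates.
#' @return A `data.frame` with `cluster1`, `cluster2`, `median_distance`.
#' @export
cluster_pair_geo_distance <- function(clusters, meta) {
  labs <- sort(unique(clusters))
  pts <- lapply(labs, function(l) {
    ids <- names(clusters)[clusters == l]
    do.call(rbind, lapply(ids, function(id) {
      r <- meta[meta$id == id, , drop = FALSE]
      if (!nrow(r)) return(NULL)
      gp_coords(r[1, ])
    }))
  })
  names(pts) <- labs
  pr <- combn(labs, 2L)
  out <- data.frame(cluster1 = pr[1, ], cluster2 = pr[2, ],
                    median_distance = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pr))) {
    A <- pts[[pr[1, k]]]; B <- pts[[pr[2, k]]]
    if (is.null(A) || is.null(B) || !nrow(A) || !nrow(B)) next
    ia <- rep(seq_len(nrow(A)), times = nrow(B))
    ib <- rep(seq_len(nrow(B)), each = nrow(A))
    out$median_distance[k] <- median(gp_distance(A[ia, , drop = FALSE],
                                                 B[ib, , drop = FALSE]))
  }
  out
}
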