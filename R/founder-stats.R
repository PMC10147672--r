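#' Within-cluster IBD sharing summaries
#'
#' For each individual, the mean segment count and mean total cM shared with
#' every other member of the same cluster (pairs that share nothing count as
#' zero — an individual who shares nothing still contributes, which keeps
#' isolated clusters from being biased upward). Cluster-level means carry
#' normal 95% confidence intervals (mean +/- 1.96 SE).
#'
#' @param segments a segment table.
#' @param clusters named character vector mapping every sample id to a
#'   cluster label.
#' @param band length band applied before summarising (default `c(3, 15)`).
#' @return A list with `individuals` (per-individual means) and `clusters`
#'   (per-cluster means with CIs); singleton clusters are excluded with a
#'   warning.
#' @export
within_cluster_ibd <- function(segments, clusters, band = c(3, 15)) {
  stopifnot(!is.null(names(clusters)))
  totals <- pair_totals(segments, band = band)
  sizes <- table(clusters)
  singles <- names(sizes)[sizes < 2L]
  if (length(singles))
    warning(sprintf("excluding singleton cluster(s): %s",
                    paste(singles, collapse = ", ")))
  ids <- names(clusters)[!clusters %in% singles]
  cl <- clusters[ids]
  key <- paste(totals$sample1, totals$sample2)
  tot_cm <- setNames(totals$total_cM, key)
  tot_n <- setNames(totals$n_segments, key)
  ind <- data.frame(id = ids, cluster = unname(cl),
                    mean_total_cM = NA_real_, mean_n_segments = NA_real_,
                    stringsAsFactors = FALSE)
  for (l in unique(cl)) {
    members <- ids[cl == l]
    for (i in seq_along(members)) {
      others <- members[-i]
      k <- paste(pmin(members[i], others), pmax(members[i], others))
      ind$mean_total_cM[ind$id == members[i]] <-
        sum(tot_cm[k], na.rm = TRUE) / length(others)
      ind$mean_n_segments[ind$id == members[i]] <-
        sum(tot_n[k], na.rm = TRUE) / length(others)
    }
  }
  cl_sum <- do.call(rbind, lapply(split(ind, ind$cluster), function(d) {
    n <- nrow(d)
    data.frame(cluster = d$cluster[1], n = n,
               mean_total_cM = mean(d$mean_total_cM),
               ci_lo_total = mean(d$mean_total_cM) -
                 1.96 * sd(d$mean_total_cM) / sqrt(n),
               ci_hi_total = mean(d$mean_total_cM) +
                 1.96 * sd(d$mean_total_cM) / sqrt(n),
               mean_n_segments = mean(d$mean_n_segments),
               ci_lo_n = mean(d$mean_n_segments) -
                 1.96 * sd(d$mean_n_segments) / sqrt(n),
               ci_hi_n = mean(d$mean_n_segments) +
                 1.96 * sd(d$mean_n_segments) / sqrt(n),
               stringsAsFactors = FALSE)
  }))
  rownames(cl_sum) <- NULL
  list(individuals = ind, clusters = cl_sum)
}

#' Runs-of-homozygosity summaries
#'
#' Per-individual total ROH (segments > `min_cM`), binned totals over
#' half-open cM bins, and the genomic inbreeding coefficient `F_ROH` (the
#' proportion of the genome covered by ROH longer than `f_roh_threshold_bp`).
#' The genome length is the sum of the genetic map's physical spans. When
#' cluster labels are supplied, cluster means are computed after one-shot
#' 6-SD outlier exclusion ([exclude_roh_outliers()]).
#'
#' @param hbd an HBD segment table (sample1 == sample2 rows).
#' @param map genetic map defining the genome extent.
#' @param clusters optional named cluster labels.
#' @param min_cM minimum ROH length counted in totals (default 1).
#' @param bins cM bin edges, half-open `[lo, hi)` (default
#'   `c(4, 8, 12, 20, 300)`).
#' @param f_roh_threshold_bp physical length threshold for `F_ROH`
#'   (default 1.5 Mb).
#' @param k_sd outlier rule passed to [exclude_roh_outliers()].
#' @return A list with `individuals` (totals, bins, `F_ROH`, consanguinity
#'   flag), `clusters` (means after outlier exclusion; `NULL` when no labels
#'   given), `excluded` outlier ids and `genome_bp`.
#' @export
roh_summaries <- function(hbd, map, clusters = NULL, min_cM = 1,
                          bins = c(4, 8, 12, 20, 300),
                          f_roh_threshold_bp = 1.5e6, k_sd = 6) {
  dt <- as.data.table(hbd)
  if (nrow(dt) && !all(dt$sample1 == dt$sample2))
    stop("HBD table must pair each sample with itself")
  genome_bp <- sum(vapply(split(map, map$chrom),
                          function(m) max(m$bp) - min(m$bp), numeric(1)))
  if (genome_bp <= 0) stop("genome length must be positive")
  dt <- dt[length_cM > min_cM]
  ids <- sort(unique(c(dt$sample1, names(clusters))))
  per <- data.frame(id = ids, stringsAsFactors = FALSE)
  agg <- function(f) {
    v <- setNames(rep(0, length(ids)), ids)
    if (nrow(dt)) {
      s <- dt[, .(val = f(.SD)), by = sample1]
      v[s$sample1] <- s$val
    }
    unname(v)
  }
  per$total_cM <- agg(function(d) sum(d$length_cM))
  for (b in seq_len(length(bins) - 1L)) {
    lo <- bins[b]; hi <- bins[b + 1L]
    per[[sprintf("bin_%g_%g_cM", lo, hi)]] <-
      agg(function(d) sum(d$length_cM[d$length_cM >= lo & d$length_cM < hi]))
  }
  per$f_roh <- agg(function(d) {
    bp <- d$end_bp - d$start_bp
    sum(bp[bp > f_roh_threshold_bp])
  }) / genome_bp
  flags <- consanguinity_flags(dt)
  per$consanguinity <- unname(flags[per$id])
  per$consanguinity[is.na(per$consanguinity)] <- FALSE

  cl_sum <- NULL
  excluded <- character(0)
  if (!is.null(clusters)) {
    per$cluster <- unname(clusters[per$id])
    tot <- setNames(per$total_cM, per$id)
    excluded <- exclude_roh_outliers(tot[names(clusters)], clusters,
                                     k_sd = k_sd)
    keep <- per[!(per$id %in% excluded) & !is.na(per$cluster), ]
    num <- setdiff(names(keep), c("id", "cluster", "consanguinity"))
    cl_sum <- do.call(rbind, lapply(split(keep, keep$cluster), function(d) {
      out <- as.data.frame(t(colMeans(d[num])))
      cbind(data.frame(cluster = d$cluster[1], n = nrow(d),
                       prop_consanguineous = mean(d$consanguinity),
                       stringsAsFactors = FALSE), out)
    }))
    rownames(cl_sum) <- NULL
  }
  list(individuals = per, clusters = cl_sum, excluded = excluded,
       genome_bp = genome_bp)
}

#' One-shot ROH outlier exclusion
#'
#' Flags individuals whose total ROH exceeds their cluster's mean by more
#' than `k_sd` standard deviations, where the mean and SD are taken over the
#' other cluster members (leave-one-out, so an extreme individual cannot
#' mask itself in a small cluster). A single pass: limits are not
#' re-estimated after exclusions.
#'
#' @param totals named per-individual total ROH (cM).
#' @param clusters named cluster labels over the same ids.
#' @param k_sd number of standard deviations (default 6).
#' @return Character vector of excluded ids.
#' @export
exclude_roh_outliers <- function(totals, clusters, k_sd = 6) {
  stopifnot(!is.null(names(totals)), !is.null(names(clusters)))
  clusters <- clusters[names(totals)]
  out <- character(0)
  for (l in unique(clusters)) {
    v <- totals[clusters == l & !is.na(clusters)]
    if (length(v) < 3L) next
    for (i in seq_along(v)) {
      rest <- v[-i]
      if (v[i] > mean(rest) + k_sd * sd(rest))
        out <- c(out, names(v)[i])
    }
  }
  out
}

#' Flag recent consanguinity from long ROH
#'
#' An individual is flagged when more than `min_total_cM` of the genome is
#' covered by ROH segments each longer than `min_seg_cM`.
#'
#' @param hbd an HBD segment table.
#' @param min_seg_cM per-segment length threshold (default 20).
#' @param min_total_cM qualifying total threshold (default 50).
#' @return Named logical vector over the samples present in `hbd`.
#' @export
consanguinity_flags <- function(hbd, min_seg_cM = 20, min_total_cM = 50) {
  dt <- as.data.table(hbd)
  if (!nrow(dt)) return(setNames(logical(0), character(0)))
  s <- dt[, .(qual = sum(length_cM[length_cM > min_seg_cM])), by = sample1]
  setNames(s$qual > min_total_cM, s$sample1)
}

#' IBD sharing versus geographic distance between cluster pairs
#'
#' For each unordered pair of clusters: the median between-cluster pairwise
#' total IBD (pairs sharing nothing count as zero), the median geographic
#' distance between members' grandparental birthplaces ([gp_distance()]),
#' and whether the two clusters carry the same majority denomination. The
#' test statistic is the coefficient of the same-denomination indicator in a
#' rank regression of median IBD on median distance; its one-sided p-value
#' comes from permuting denomination labels across clusters.
#'
#' @param totals a pair-sharing table (band-filtered as desired upstream).
#' @param clusters named cluster labels.
#' @param meta metadata with grandparental coordinates (see
#'   [read_metadata()]); must include a `denomination` column used to call
#'   each cluster's majority denomination.
#' @param n_perm permutation replicates (default 1000).
#' @param seed integer seed.
#' @return A list with the per-pair table, the observed indicator
#'   coefficient and the permutation p-value (`NA` when every cluster shares
#'   one denomination).
#' @export
ibd_vs_distance <- function(totals, clusters, meta, n_perm = 1000L,
                            seed = 1L) {
  labs <- sort(unique(clusters))
  if (length(labs) < 4L) stop("need at least 4 clusters")
  denom <- vapply(labs, function(l) {
    d <- meta$denomination[match(names(clusters)[clusters == l], meta$id)]
    d <- d[!is.na(d)]
    if (!length(d)) NA_character_ else names(sort(table(d),
                                                  decreasing = TRUE))[1]
  }, character(1))
  tot_key <- setNames(totals$total_cM, paste(totals$sample1, totals$sample2))
  geo <- cluster_pair_geo_distance(clusters, meta)
  pairs <- combn(labs, 2L)
  tab <- data.frame(cluster1 = pairs[1, ], cluster2 = pairs[2, ],
                    median_ibd_cM = NA_real_, median_distance = NA_real_,
                    same_denomination = NA, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    m1 <- names(clusters)[clusters == pairs[1, k]]
    m2 <- names(clusters)[clusters == pairs[2, k]]
    cross <- expand.grid(a = m1, b = m2, stringsAsFactors = FALSE)
    kk <- paste(pmin(cross$a, cross$b), pmax(cross$a, cross$b))
    v <- tot_key[kk]
    v[is.na(v)] <- 0
    tab$median_ibd_cM[k] <- median(v)
    gk <- geo$median_distance[geo$cluster1 == pairs[1, k] &
                                geo$cluster2 == pairs[2, k]]
    tab$median_distance[k] <- if (length(gk)) gk else NA_real_
    tab$same_denomination[k] <- denom[pairs[1, k]] == denom[pairs[2, k]]
  }
  if (length(unique(denom[!is.na(denom)])) < 2L)
    return(list(pairs = tab, coefficient = NA_real_, p_value = NA_real_,
                note = "all clusters share one denomination; test not applicable"))
  stat <- function(same) {
    fit <- lm(rank(tab$median_ibd_cM) ~ rank(tab$median_distance) + same)
    unname(coef(fit)[["same"]])
  }
  obs <- stat(as.numeric(tab$same_denomination))
  set.seed(derive_seed(seed, 41L))
  perm <- replicate(n_perm, {
    pd <- setNames(sample(denom), labs)
    stat(as.numeric(pd[tab$cluster1] == pd[tab$cluster2]))
  })
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(pairs = tab, coefficient = obs, p_value = p)
}
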