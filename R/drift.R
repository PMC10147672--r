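#' Group allele-frequency vectors from phased haplotypes
#'
#' @param haps 0/1 haplotype matrix (rows = haplotypes, two consecutive rows
#'   per individual in the order of `ids`; columns = sites).
#' @param sites site table (`chrom`, `pos`, and optionally `cM`).
#' @param ids sample ids in row-pair order.
#' @param members sample ids forming the group.
#' @return A `freq_vector` data.frame: `chrom`, `pos`, `p`, `n` (haploid
#'   sample size).
#' @export
group_freq <- function(haps, sites, ids, members) {
  idx <- match(members, ids)
  if (anyNA(idx)) stop("group members absent from haplotype matrix")
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  p <- colMeans(haps[rows, , drop = FALSE])
  freq_vector(sites$chrom, sites$pos, p, length(rows))
}

#' @rdname group_freq
#' @param chrom,pos site coordinates.
#' @param p allele frequencies in `[0, 1]`.
#' @param n haploid sample sizes (recycled).
#' @export
freq_vector <- function(chrom, pos, p, n) {
  stopifnot(all(p >= 0 & p <= 1), all(n >= 2))
  data.frame(chrom = as.character(chrom), pos = pos, p = p,
             n = rep_len(n, length(p)), stringsAsFactors = FALSE)
}

## intersect a list of freq_vectors on (chrom, pos)
intersect_freqs <- function(fvs) {
  key <- lapply(fvs, function(f) paste(f$chrom, f$pos))
  common <- Reduce(intersect, key)
  lapply(fvs, function(f) f[match(common, paste(f$chrom, f$pos)), ])
}

#' Patterson's D (ABBA-BABA) with block jackknife
#'
#' `D = sum((pW - pX)(pY - pZ)) / sum((pW + pX - 2 pW pX)(pY + pZ - 2 pY pZ))`
#' over sites shared by all four groups, with sites monomorphic in every
#' group dropped. The standard error is a delete-one block jackknife over
#' contiguous genetic-map blocks of `block_cM`. Sign semantics, pinned to the
#' formula: `D < 0` indicates excess allele sharing between X and Y (and W
#' with Z); `D > 0` the reverse pairing.
#'
#' @param W,X,Y,Z `freq_vector` data.frames (see [freq_vector()]).
#' @param map genetic map used to place sites into blocks.
#' @param block_cM jackknife block length in cM (default 5).
#' @param arrangement group labels recorded with the result.
#' @return An object of class `d_stat`: `D`, `se`, `z`, `n_blocks`,
#'   `n_sites`, `arrangement`.
#' @export
patterson_d <- function(W, X, Y, Z, map, block_cM = 5,
                        arrangement = c("W", "X", "Y", "Z")) {
  fv <- intersect_freqs(list(W, X, Y, Z))
  P <- do.call(cbind, lapply(fv, `[[`, "p"))
  mono <- rowSums(P == 0) == 4L | rowSums(P == 1) == 4L
  P <- P[!mono, , drop = FALSE]
  site <- fv[[1]][!mono, ]
  if (!nrow(P)) stop("no informative sites")
  num <- (P[, 1] - P[, 2]) * (P[, 3] - P[, 4])
  den <- (P[, 1] + P[, 2] - 2 * P[, 1] * P[, 2]) *
    (P[, 3] + P[, 4] - 2 * P[, 3] * P[, 4])
  cm <- bp_to_cm(map, site$chrom, site$pos)
  block <- paste(site$chrom, floor(cm / block_cM))
  num_b <- tapply(num, block, sum)
  den_b <- tapply(den, block, sum)
  informative <- den_b > 0
  num_b <- num_b[informative]
  den_b <- den_b[informative]
  B <- length(num_b)
  if (B < 2L) stop("fewer than 2 informative jackknife blocks")
  D <- sum(num_b) / sum(den_b)
  loo <- (sum(num_b) - num_b) / (sum(den_b) - den_b)
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  structure(list(D = D, se = se, z = if (se > 0) D / se else Inf * sign(D),
                 n_blocks = B, n_sites = nrow(P),
                 arrangement = arrangement), class = "d_stat")
}

#' @export
print.d_stat <- function(x, ...) {
  cat(sprintf("Patterson's D(%s) = %.5f  se = %.5f  z = %.2f  (%d sites, %d blocks)\n",
              paste(x$arrangement, collapse = ", "), x$D, x$se, x$z,
              x$n_sites, x$n_blocks))
  if (!is.null(x$interpretation)) cat(" ", x$interpretation, "\n")
  invisible(x)
}

#' Source-affinity D test for a cluster
#'
#' Wraps [patterson_d()] in the arrangement
#' `D(outgroup, cluster; source1, source2)`. Under the formula's sign
#' convention, excess affinity of the cluster to source 1 drives `D`
#' negative and excess affinity to source 2 drives it positive; the
#' interpretation is attached to the result.
#'
#' @param cluster,outgroup,source1_ref,source2_ref `freq_vector`s.
#' @param map genetic map.
#' @param block_cM jackknife block length.
#' @param labels optional group labels for reporting.
#' @return A `d_stat` with an `interpretation` field.
#' @export
d_source_affinity <- function(cluster, outgroup, source1_ref, source2_ref,
                              map, block_cM = 5,
                              labels = c("outgroup", "cluster", "source1",
                                         "source2")) {
  d <- patterson_d(outgroup, cluster, source1_ref, source2_ref, map,
                   block_cM = block_cM, arrangement = labels)
  d$interpretation <- sprintf(
    "D < 0: %s shares an excess of alleles with %s; D > 0: excess with %s",
    labels[2], labels[3], labels[4])
  d
}

#' Colony-specific drift D test
#'
#' Tests whether a cluster shows allele sharing in excess of a random draw
#' from the rest of the colony: draws `n_random` non-member colony
#' individuals without replacement (seeded; all of them, with a warning,
#' when fewer are available) and computes
#' `D(outgroup, cluster; source_ref, random colony)`. Running the test once
#' per source reference gives the two-axis drift design.
#'
#' @param haps,sites,ids phased haplotypes as in [group_freq()].
#' @param cluster_members ids of the tested cluster.
#' @param pool ids of colony individuals eligible for the random comparison
#'   panel (members of the tested cluster are removed automatically).
#' @param outgroup,source_ref `freq_vector`s.
#' @param map genetic map.
#' @param n_random panel size (default 500).
#' @param seed integer seed for the draw.
#' @param block_cM jackknife block length.
#' @return A `d_stat`; the drawn panel is attached as `random_panel`.
#' @export
nl_drift_test <- function(haps, sites, ids, cluster_members, pool,
                          outgroup, source_ref, map, n_random = 500L,
                          seed = 1L, block_cM = 5) {
  pool <- setdiff(pool, cluster_members)
  if (!length(pool)) stop("empty comparison pool after excluding the cluster")
  set.seed(derive_seed(seed, 43L))
  if (length(pool) < n_random) {
    warning(sprintf("pool has %d < n_random = %d individuals: using all",
                    length(pool), n_random))
    draw <- pool
  } else draw <- sample(pool, n_random)
  clus <- group_freq(haps, sites, ids, cluster_members)
  rand <- group_freq(haps, sites, ids, draw)
  d <- patterson_d(outgroup, clus, source_ref, rand, map,
                   block_cM = block_cM,
                   arrangement = c("outgroup", "cluster", "source",
                                   "random-colony"))
  d$interpretation <- paste(
    "D > 0: cluster shares an excess of alleles with the random colony",
    "panel (colony-specific drift); D < 0: excess with the source")
  d$random_panel <- sort(draw)
  d
}

#' Hudson's FST (ratio of averages)
#'
#' `FST = sum[(p1 - p2)^2 - p1(1 - p1)/(n1 - 1) - p2(1 - p2)/(n2 - 1)] /
#' sum[p1(1 - p2) + p2(1 - p1)]` over shared sites; the unbiased
#' ratio-of-averages form, so single-site estimates can be negative.
#'
#' @param group1,group2 `freq_vector`s with haploid sizes `n >= 2`.
#' @return An object of class `fst_result`: `fst`, `n_sites`.
#' @export
hudson_fst <- function(group1, group2) {
  fv <- intersect_freqs(list(group1, group2))
  p1 <- fv[[1]]$p; n1 <- fv[[1]]$n
  p2 <- fv[[2]]$p; n2 <- fv[[2]]$n
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (sum(den) == 0) stop("all shared sites are monomorphic")
  structure(list(fst = sum(num) / sum(den), n_sites = length(p1)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Hudson FST = %.5f (%d sites)\n", x$fst, x$n_sites))
  invisible(x)
}
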