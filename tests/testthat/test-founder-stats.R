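seg_pair <- function(s1, s2, len, chrom = "chr1", start = 1e6) {
  data.table::data.table(sample1 = s1, hap1 = 1L, sample2 = s2, hap2 = 1L,
                         chrom = chrom, start_bp = start,
                         end_bp = start + len * 1e6, lod = NA_real_,
                         length_cM = len)
}

hbd_row <- function(id, len, chrom = "chr1", start = 1e6) {
  data.table::data.table(sample1 = id, hap1 = 1L, sample2 = id, hap2 = 2L,
                         chrom = chrom, start_bp = start,
                         end_bp = start + len * 1e6, lod = NA_real_,
                         length_cM = len,
                         start_cM = start / 1e6, end_cM = start / 1e6 + len)
}

four_chrom_map <- function() data.frame(
  chrom = rep(paste0("chr", 1:4), each = 2),
  bp = rep(c(0, 100e6), 4), cM = rep(c(0, 100), 4))

test_that("within-cluster means count zero-sharing pairs as zeros", {
  segs <- rbind(seg_pair("a", "b", 5), seg_pair("a", "c", 5),
                seg_pair("b", "c", 5))
  cl <- c(a = "K", b = "K", c = "K", d = "K", e = "L")
  res <- suppressWarnings(within_cluster_ibd(segs, cl))
  ## a, b, c each share one 5 cM segment with two of their three partners
  abc <- res$individuals[res$individuals$id %in% c("a", "b", "c"), ]
  expect_equal(abc$mean_total_cM, rep(10 / 3, 3))
  expect_equal(abc$mean_n_segments, rep(2 / 3, 3))
  ## d shares nothing: contributes zero, is not dropped
  expect_equal(res$individuals$mean_total_cM[res$individuals$id == "d"], 0)
  ## the singleton cluster L is excluded with a warning
  expect_warning(within_cluster_ibd(segs, cl), "singleton")
  expect_false("L" %in% res$clusters$cluster)
  k <- res$clusters[res$clusters$cluster == "K", ]
  expect_true(k$ci_lo_total <= k$mean_total_cM &
                k$mean_total_cM <= k$ci_hi_total)
  ## zero-inclusion: adding a non-sharing member cannot raise the mean
  res3 <- suppressWarnings(within_cluster_ibd(segs, cl[1:3]))
  expect_lt(k$mean_total_cM,
            res3$clusters$mean_total_cM[res3$clusters$cluster == "K"])
})

test_that("colony clusters out-share source clusters on the default sim", {
  pi <- ped_ibd(1L)
  grp <- group_of_samples(pi)
  res <- suppressWarnings(within_cluster_ibd(pi$segs_band, grp))
  cl <- res$clusters
  colony_means <- cl$mean_total_cM[!cl$cluster %in% c("S1", "S2")]
  source_means <- cl$mean_total_cM[cl$cluster %in% c("S1", "S2")]
  expect_gt(min(colony_means), max(source_means))
})

test_that("ROH bins, totals and F_ROH follow the definitions", {
  map <- four_chrom_map()  # 400 Mb genome
  hbd <- rbind(hbd_row("x", 10), hbd_row("x", 30, chrom = "chr2"),
               hbd_row("y", 0.8), hbd_row("y", 2))
  res <- roh_summaries(hbd, map)
  xi <- res$individuals[res$individuals$id == "x", ]
  ## one 10 cM ROH sits in [8,12) alone
  expect_equal(xi$bin_8_12_cM, 10)
  expect_equal(xi$bin_4_8_cM, 0)
  expect_equal(xi$bin_12_20_cM, 0)
  expect_equal(xi$bin_20_300_cM, 30)
  expect_equal(xi$total_cM, 40)
  ## 40 Mb of >1.5 Mb ROH over a 400 Mb genome
  expect_equal(xi$f_roh, 0.1)
  ## segments at or below 1 cM are not counted
  yi <- res$individuals[res$individuals$id == "y", ]
  expect_equal(yi$total_cM, 2)
  ## bins partition the [4, 300) total exactly
  bins <- xi[, grep("^bin_", names(xi))]
  expect_equal(sum(unlist(bins)),
               sum(hbd$length_cM[hbd$sample1 == "x" &
                                   hbd$length_cM >= 4 &
                                   hbd$length_cM < 300]))
  expect_error(roh_summaries(hbd, data.frame(chrom = "chr1", bp = c(0, 0),
                                             cM = c(0, 1))), "positive")
})

test_that("the 6-SD outlier rule is one-shot and one-sided", {
  cl <- setNames(rep("K", 6), letters[1:6])
  ## all equal but one: SD = 0 within the rest, the high value is excluded
  tot <- setNames(c(10, 10, 10, 10, 10, 250), letters[1:6])
  expect_equal(exclude_roh_outliers(tot, cl), "f")
  ## an extreme individual at 10x the cluster mean is excluded
  tot2 <- setNames(c(9, 10, 11, 10, 9, 100), letters[1:6])
  expect_equal(exclude_roh_outliers(tot2, cl), "f")
  ## well-behaved Gaussian totals essentially never trip 6 SD
  set.seed(40)
  tot3 <- setNames(rnorm(500, 50, 5), paste0("i", 1:500))
  cl3 <- setNames(rep("K", 500), names(tot3))
  expect_equal(length(exclude_roh_outliers(tot3, cl3)), 0L)
})

test_that("consanguinity flags need >50 cM of >20 cM segments", {
  hbd <- rbind(hbd_row("hot", 25), hbd_row("hot", 30, chrom = "chr2"),
               hbd_row("cold", 19), hbd_row("cold", 19, chrom = "chr2"),
               hbd_row("cold", 19, chrom = "chr3"))
  fl <- consanguinity_flags(hbd)
  expect_true(fl[["hot"]])    # 25 + 30 = 55 > 50
  expect_false(fl[["cold"]])  # no single segment exceeds 20 cM
})

test_that("full-sib offspring show F_ROH near 0.25", {
  set.seed(77)
  L <- rep(100, 4)
  map <- four_chrom_map()
  froh <- replicate(20, {
    p1 <- list(h1 = founder_mosaic(L, 1L), h2 = founder_mosaic(L, 2L))
    p2 <- list(h1 = founder_mosaic(L, 3L), h2 = founder_mosaic(L, 4L))
    sib1 <- list(h1 = meiosis(p1, L), h2 = meiosis(p2, L))
    sib2 <- list(h1 = meiosis(p1, L), h2 = meiosis(p2, L))
    child <- list(h1 = meiosis(sib1, L), h2 = meiosis(sib2, L))
    hbd <- extract_true_hbd(list(kid = child), min_cM = 0)
    res <- roh_summaries(hbd, map, min_cM = 0)
    res$individuals$f_roh[res$individuals$id == "kid"]
  })
  expect_lt(abs(mean(froh) - 0.25), 0.08)
})

test_that("same-denomination cluster pairs share more IBD at distance", {
  sim <- default_sim(1L)
  grp <- group_of(sim)
  colony <- colony_ids(sim)
  totals <- pair_totals(sim$ibd, band = c(3, 15))
  ## genetic clusters (hierarchy level 2) restricted to colony members give
  ## enough clusters for the permutation test to resolve small p-values
  hc <- hc_default(1L)
  cl2 <- setNames(hc$level2[match(colony, hc$id)], colony)
  res <- ibd_vs_distance(totals, cl2, sim$samples, n_perm = 300, seed = 2)
  ## denomination follows the deme and demes with like sources share more:
  ## the indicator should be positive with a small permutation p
  expect_gt(res$coefficient, 0)
  expect_lt(res$p_value, 0.2)
  expect_error(ibd_vs_distance(totals, grp[colony][grp[colony] %in%
                                                     c("Avalon", "Burin")],
                               sim$samples), "4 clusters")
  ## all clusters one denomination: not applicable, not an error
  meta_one <- sim$samples
  meta_one$denomination[meta_one$role == "colony"] <- "Catholic"
  res2 <- ibd_vs_distance(totals, cl2, meta_one, n_perm = 50, seed = 1)
  expect_true(is.na(res2$p_value))
})
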