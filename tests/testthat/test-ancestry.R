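## helper: segment rows with given pair totals (one segment per entry)
seg_row <- function(s1, s2, len, chrom = "chr1") {
  data.table::data.table(sample1 = s1, hap1 = 1L, sample2 = s2, hap2 = 1L,
                         chrom = chrom, start_bp = 1e6,
                         end_bp = 1e6 + len * 1e6, lod = NA_real_,
                         length_cM = len)
}

test_that("profile rows are band-limited sharing proportions", {
  segs <- rbind(seg_row("t1", "sA", 6), seg_row("t1", "sB", 4),
                seg_row("t2", "sA", 16))  # 16 cM falls outside the band
  prof <- build_profiles(segs, c("t1", "t2"), c("sA", "sB", "sC"))
  expect_equal(unname(prof$X["t1", ]), c(0.6, 0.4, 0))
  ## t2 only shares a segment outside (3, 15): excluded and reported
  expect_equal(prof$excluded, "t2")
  expect_equal(nrow(prof$X), 1L)
  expect_equal(unname(prof$row_totals), 10)
  expect_equal(unname(diag(prof$Y)), c(0, 0, 0))
  expect_error(build_profiles(segs, "t1", character(0)), "empty source")
  expect_error(build_profiles(segs, c("t1", "sA"), c("sA", "sB")),
               "disjoint")
})

test_that("X equals a brute-force re-summation on simulated data", {
  sim <- small_sim()
  targets <- colony_ids(sim)
  sources <- reference_ids(sim)
  prof <- build_profiles(sim$ibd, targets, sources)
  df <- as.data.frame(sim$ibd)
  df <- df[df$length_cM > 3 & df$length_cM < 15, ]
  for (tg in rownames(prof$X)[1:5]) {
    brute <- vapply(sources, function(src) {
      sum(df$length_cM[(df$sample1 == tg & df$sample2 == src) |
                         (df$sample2 == tg & df$sample1 == src)])
    }, numeric(1))
    expect_equal(unname(prof$X[tg, ]), unname(brute / sum(brute)),
                 tolerance = 1e-12)
  }
})

test_that("NNLS recovers exact and mixed profiles", {
  Y <- rbind(c(0, 0.7, 0.3), c(0.6, 0, 0.4), c(0.5, 0.5, 0))
  rownames(Y) <- colnames(Y) <- paste0("s", 1:3)
  ## identity case: a row of Y maps to the unit vector
  expect_equal(unname(nnls_profile(Y[2, ], Y)), c(0, 1, 0),
               tolerance = 1e-8)
  ## known mixture
  x <- 0.3 * Y[1, ] + 0.7 * Y[2, ]
  beta <- nnls_profile(x, Y)
  expect_equal(unname(beta), c(0.3, 0.7, 0), tolerance = 1e-3)
  ## grid-search oracle over the simplex at 0.005 resolution agrees
  grid <- seq(0, 1, by = 0.005)
  best <- c(NA, NA, NA); best_r <- Inf
  for (b1 in grid) for (b2 in grid[grid <= 1 - b1 + 1e-12]) {
    b <- c(b1, b2, 1 - b1 - b2)
    r <- sum((x - drop(t(Y) %*% b))^2)
    if (r < best_r) { best_r <- r; best <- b }
  }
  expect_equal(unname(beta), best, tolerance = 0.005 + 1e-9)
  ## orthogonal profile: unresolvable, reported as NA not renormalised
  Y0 <- rbind(c(0, 1), c(1, 0))
  rownames(Y0) <- colnames(Y0) <- c("a", "b")
  expect_error(nnls_profile(c(1, 0), matrix(0, 2, 2)), "all-zero")
})

test_that("profiles are scale-invariant and permutation-equivariant", {
  sim <- small_sim()
  targets <- colony_ids(sim)[1:8]
  sources <- reference_ids(sim)
  p1 <- build_profiles(sim$ibd, targets, sources)
  scaled <- data.table::copy(sim$ibd)[, length_cM := length_cM * 3.7]
  p2 <- build_profiles(scaled, targets, sources,
                       band = c(3 * 3.7, 15 * 3.7))
  expect_equal(p1$X, p2$X, tolerance = 1e-12)
  perm <- rev(sources)
  p3 <- build_profiles(sim$ibd, targets, perm)
  expect_equal(p1$X[, perm], p3$X, tolerance = 1e-12)
  b1 <- nnls_profile(p1$X[1, ], p1$Y)
  b3 <- nnls_profile(p3$X[1, ], p3$Y)
  expect_equal(b1[perm], b3, tolerance = 1e-8)
})

test_that("aggregation sums to clusters and regions and applies the 5% rule", {
  segs <- rbind(seg_row("t1", "sA", 6), seg_row("t1", "sB", 4),
                seg_row("t2", "sA", 5), seg_row("t2", "sB", 5),
                seg_row("sA", "sB", 5), seg_row("sA", "sC", 5),
                seg_row("sB", "sC", 5))
  ## all sources in one cluster: every target is 100% that cluster
  fit <- estimate_ancestry(segs, c("t1", "t2"), c("sA", "sB", "sC"),
                           source_clusters = c(sA = "K", sB = "K",
                                               sC = "K"))
  expect_true(all(abs(fit$cluster_beta[, "K"] - 1) < 1e-9))
  expect_error(estimate_ancestry(segs, "t1", c("sA", "sB", "sC"),
                                 source_clusters = c(sA = "K", sB = "K")),
               "unlabeled")
  ## the >5% reporting rule never touches aggregation
  fit2 <- estimate_ancestry(
    segs, c("t1", "t2"), c("sA", "sB", "sC"),
    source_clusters = c(sA = "K1", sB = "K1", sC = "K2"),
    target_clusters = c(t1 = "T", t2 = "T"))
  expect_equal(rowSums(fit2$cluster_beta), c(t1 = 1, t2 = 1),
               tolerance = 1e-9)
  keep <- major_contributors(fit2, threshold = 0.05)
  expect_true(all(apply(keep, 2, max) > 0.05))
})

test_that("deme ancestry is recovered within 0.10 on the default simulation", {
  sim_pi <- ped_ibd(1L)
  grp <- group_of_samples(sim_pi)
  targets <- sim_pi$samples$id[sim_pi$samples$role == "colony"]
  sources <- sim_pi$samples$id[sim_pi$samples$role == "reference"]
  fit <- estimate_ancestry(sim_pi$segs_band, targets, sources,
                           source_clusters = grp[sources],
                           target_clusters = grp[targets])
  est <- fit$target_cluster_means[, "S1"]
  truth <- tapply(sim_pi$true_ancestry[targets], grp[targets], mean)
  truth <- truth[names(est)]
  expect_true(all(abs(est - truth) <= 0.10))
  expect_equal(order(est), order(truth))
})

test_that("the unsupervised cluster mixture resolves an admixed cluster", {
  ## constructed sharing: C shares equally with two near-isolated clusters
  ## A and B (a trace of A-B sharing keeps the self-excluded design solvable)
  segs <- rbind(
    seg_row("a1", "a2", 8), seg_row("a1", "a3", 8), seg_row("a2", "a3", 8),
    seg_row("b1", "b2", 8), seg_row("b1", "b3", 8), seg_row("b2", "b3", 8),
    seg_row("c1", "c2", 4), seg_row("c1", "c3", 4), seg_row("c2", "c3", 4),
    seg_row("a1", "b1", 3.5),
    seg_row("a1", "c1", 6), seg_row("a2", "c2", 6), seg_row("a3", "c3", 6),
    seg_row("b1", "c1", 6), seg_row("b2", "c2", 6), seg_row("b3", "c3", 6))
  cl <- setNames(rep(c("A", "B", "C"), each = 3),
                 c("a1", "a2", "a3", "b1", "b2", "b3", "c1", "c2", "c3"))
  M <- unsupervised_cluster_mixture(segs, cl)
  expect_equal(unname(diag(M)), c(0, 0, 0))
  expect_equal(M["C", "A"], 0.5, tolerance = 0.1)
  expect_equal(M["C", "B"], 0.5, tolerance = 0.1)
  expect_equal(unname(rowSums(M)), c(1, 1, 1), tolerance = 1e-9)
  ## an undersized cluster is dropped with a warning, the rest still run
  expect_warning(
    unsupervised_cluster_mixture(segs, c(cl, d1 = "D")), "excluding")
  expect_error(suppressWarnings(
    unsupervised_cluster_mixture(segs, cl[c(1:6, 7)])), "3 clusters")
})

test_that("supervised and unsupervised modes agree on a two-source colony", {
  sim <- small_sim()
  grp <- group_of(sim)
  targets <- colony_ids(sim)
  sources <- reference_ids(sim)
  fit <- estimate_ancestry(sim$ibd, targets, sources,
                           source_clusters = grp[sources],
                           target_clusters = grp[targets])
  ## unsupervised run per target cluster against the two source clusters,
  ## so both modes answer the same question (share of S1 vs S2)
  for (dn in rownames(fit$target_cluster_means)) {
    cl <- grp[c(targets[grp[targets] == dn], sources)]
    M <- suppressWarnings(unsupervised_cluster_mixture(sim$ibd, cl))
    sup <- fit$target_cluster_means[dn, c("S1", "S2")]
    unsup <- M[dn, c("S1", "S2")] / sum(M[dn, c("S1", "S2")])
    expect_lt(abs(sup[["S1"]] - unsup[["S1"]]), 0.1)
  }
})
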