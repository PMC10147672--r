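#' Build band-limited IBD-sharing profile matrices
#'
#' `X` has one row per target and one column per source individual; entry
#' `X[i, j]` is the proportion of target i's band-limited IBD total that is
#' shared with source j (each row is divided by its pre-normalisation sum,
#' which is recorded). `Y` is the analogous source-by-source matrix with the
#' self-sharing diagonal set to zero and rows renormalised. Targets with no
#' qualifying sharing are excluded and reported, never silently dropped.
#'
#' @param segments a segment table (cross-individual IBD).
#' @param targets character vector of target sample ids.
#' @param sources character vector of source sample ids (disjoint from
#'   `targets`).
#' @param band length band `c(min_cM, max_cM)`, strict inequalities
#'   (default `c(3, 15)`).
#' @return A list with elements `X`, `Y`, `row_totals` (pre-normalisation cM
#'   sums for retained targets), `excluded` (targets with zero qualifying
#'   sharing) and `band`.
#' @export
build_profiles <- function(segments, targets, sources, band = c(3, 15)) {
  if (!length(sources)) stop("empty source set")
  if (length(intersect(targets, sources)))
    stop("target and source id sets must be disjoint")
  dt <- filter_band(as.data.table(segments), band[1], band[2])
  dt <- dt[sample1 != sample2]
  X <- sharing_matrix(dt, targets, sources)
  Y <- sharing_matrix(dt, sources, sources)
  diag(Y) <- 0
  row_totals <- rowSums(X)
  excluded <- targets[row_totals == 0]
  X <- X[row_totals > 0, , drop = FALSE]
  X <- X / rowSums(X)
  y_tot <- rowSums(Y)
  if (any(y_tot == 0))
    warning(sprintf("%d source(s) share no band-limited IBD with any other source",
                    sum(y_tot == 0)))
  Y[y_tot > 0, ] <- Y[y_tot > 0, , drop = FALSE] / y_tot[y_tot > 0]
  list(X = X, Y = Y, row_totals = row_totals[row_totals > 0],
       excluded = excluded, band = band)
}

## sum matrix columns by group label, preserving dimnames for any shape
agg_columns <- function(M, groups) {
  labs <- sort(unique(unname(groups)))
  out <- matrix(NA_real_, nrow(M), length(labs),
                dimnames = list(rownames(M), labs))
  for (l in labs)
    out[, l] <- rowSums(M[, groups == l, drop = FALSE])
  out
}

## cM totals of `rows` individuals against `cols` individuals
sharing_matrix <- function(dt, rows, cols) {
  M <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  a <- dt[sample1 %in% rows & sample2 %in% cols]
  b <- dt[sample2 %in% rows & sample1 %in% cols & sample1 != sample2]
  if (nrow(a)) {
    t1 <- a[, .(cm = sum(length_cM)), by = .(r = sample1, s = sample2)]
    M[cbind(match(t1$r, rows), match(t1$s, cols))] <-
      M[cbind(match(t1$r, rows), match(t1$s, cols))] + t1$cm
  }
  if (nrow(b)) {
    t2 <- b[, .(cm = sum(length_cM)), by = .(r = sample2, s = sample1)]
    M[cbind(match(t2$r, rows), match(t2$s, cols))] <-
      M[cbind(match(t2$r, rows), match(t2$s, cols))] + t2$cm
  }
  M
}

#' Non-negative least-squares mixture coefficients for one profile
#'
#' Solves `argmin_{beta >= 0} || x - t(Y) %*% beta ||^2` and normalises to
#' `sum(beta) = 1`. A profile orthogonal to every source row yields an
#' all-zero solution which is reported as unresolvable (`NA` coefficients)
#' rather than normalised.
#'
#' @param x_row numeric sharing profile (length = number of sources).
#' @param Y source profile matrix (rows = source profiles).
#' @return Named coefficient vector summing to 1, or all-`NA` when
#'   unresolvable.
#' @export
nnls_profile <- function(x_row, Y) {
  if (all(Y == 0)) stop("all-zero source profile matrix")
  stopifnot(length(x_row) == ncol(Y))
  fit <- pracma::lsqnonneg(t(Y), as.numeric(x_row))
  beta <- fit$x
  beta[beta < 1e-10] <- 0
  if (sum(beta) == 0)
    return(setNames(rep(NA_real_, nrow(Y)), rownames(Y)))
  setNames(beta / sum(beta), rownames(Y))
}

#' Estimate ancestry profiles by band-limited IBD NNLS
#'
#' Models each target individual's band-limited IBD-sharing profile as a
#' non-negative mixture of the source individuals' profiles, then aggregates
#' the per-target coefficients by source cluster and, optionally, by region
#' (groups of source clusters). When target cluster labels are supplied the
#' per-individual profiles are additionally averaged within target clusters.
#'
#' @param segments a segment table.
#' @param targets,sources target and source sample ids.
#' @param source_clusters named character vector mapping every source id to
#'   its cluster label.
#' @param regions optional named character vector mapping source cluster
#'   labels to region labels.
#' @param target_clusters optional named character vector mapping target ids
#'   to their cluster labels.
#' @param band length band, default `c(3, 15)`.
#' @return An object of class `ancestry_fit`.
#' @export
estimate_ancestry <- function(segments, targets, sources, source_clusters,
                              regions = NULL, target_clusters = NULL,
                              band = c(3, 15)) {
  missing_src <- setdiff(sources, names(source_clusters))
  if (length(missing_src))
    stop(sprintf("unlabeled source(s): %s",
                 paste(head(missing_src, 3), collapse = ", ")))
  prof <- build_profiles(segments, targets, sources, band = band)
  beta <- t(apply(prof$X, 1L, nnls_profile, Y = prof$Y))
  colnames(beta) <- colnames(prof$X)

  cl <- source_clusters[colnames(beta)]
  cluster_beta <- agg_columns(beta, cl)

  region_beta <- NULL
  if (!is.null(regions)) {
    missing_reg <- setdiff(colnames(cluster_beta), names(regions))
    if (length(missing_reg))
      stop(sprintf("source cluster(s) without region: %s",
                   paste(missing_reg, collapse = ", ")))
    region_beta <- agg_columns(cluster_beta, regions[colnames(cluster_beta)])
  }

  target_cluster_means <- NULL
  if (!is.null(target_clusters)) {
    tc <- target_clusters[rownames(cluster_beta)]
    ok <- !is.na(tc) & !apply(is.na(cluster_beta), 1L, any)
    target_cluster_means <- do.call(rbind, lapply(
      split(seq_len(nrow(cluster_beta))[ok], tc[ok]),
      function(i) colMeans(cluster_beta[i, , drop = FALSE])))
  }

  structure(list(beta = beta, cluster_beta = cluster_beta,
                 region_beta = region_beta,
                 target_cluster_means = target_cluster_means,
                 excluded = prof$excluded, row_totals = prof$row_totals,
                 band = band, source_clusters = source_clusters),
            class = "ancestry_fit")
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat(sprintf("IBD-NNLS ancestry fit: %d targets x %d sources (band %g-%g cM)\n",
              nrow(x$beta), ncol(x$beta), x$band[1], x$band[2]))
  if (length(x$excluded))
    cat(sprintf("  %d target(s) excluded for zero band-limited sharing\n",
                length(x$excluded)))
  if (!is.null(x$target_cluster_means)) {
    cat("  target-cluster mean source-cluster proportions:\n")
    print(round(x$target_cluster_means, 3))
  }
  invisible(x)
}

#' @export
summary.ancestry_fit <- function(object, ...) {
  cm <- colMeans(object$cluster_beta, na.rm = TRUE)
  cat("mean source-cluster ancestry proportions over targets:\n")
  print(round(cm, 4))
  invisible(cm)
}

#' @export
coef.ancestry_fit <- function(object, level = c("cluster", "source", "region"),
                              ...) {
  level <- match.arg(level)
  switch(level, cluster = object$cluster_beta, source = object$beta,
         region = object$region_beta)
}

#' Major-contributor view of an ancestry fit
#'
#' Reporting filter (applied after aggregation, never before): keeps only
#' source clusters contributing strictly more than `threshold` to at least
#' one target cluster.
#'
#' @param fit an `ancestry_fit` with target-cluster means.
#' @param threshold minimum contribution (default 0.05).
#' @return The filtered target-cluster mean matrix.
#' @export
major_contributors <- function(fit, threshold = 0.05) {
  stopifnot(inherits(fit, "ancestry_fit"))
  m <- fit$target_cluster_means
  if (is.null(m)) stop("fit has no target cluster means")
  m[, apply(m, 2L, max) > threshold, drop = FALSE]
}

#' Unsupervised cluster-mixture NNLS
#'
#' Treats every cluster (target-side and source-side alike) as a mixture of
#' all other clusters' aggregate sharing profiles: each cluster's member-mean
#' band-limited profile over clusters is modelled by NNLS with the cluster
#' itself excluded from its own profile and from the design columns, and the
#' remaining profiles renormalised. Unlike the individual-level `Y` matrix,
#' a design cluster keeps its own within-cluster sharing (member-to-member
#' totals are meaningful at cluster level). The output diagonal is
#' identically zero.
#'
#' @param segments a segment table.
#' @param clusters named character vector mapping sample ids to cluster
#'   labels (at least 3 clusters).
#' @param band length band, default `c(3, 15)`.
#' @param min_members clusters with fewer members are excluded with a
#'   warning (default 3).
#' @return A cluster-by-cluster mixture matrix with zero diagonal and unit
#'   row sums.
#' @export
unsupervised_cluster_mixture <- function(segments, clusters, band = c(3, 15),
                                         min_members = 3L) {
  tab <- table(clusters)
  small <- names(tab)[tab < min_members]
  if (length(small)) {
    warning(sprintf("excluding cluster(s) with < %d members: %s",
                    min_members, paste(small, collapse = ", ")))
    clusters <- clusters[!clusters %in% small]
  }
  labs <- sort(unique(clusters))
  if (length(labs) < 3L) stop("need at least 3 clusters")
  dt <- filter_band(as.data.table(segments), band[1], band[2])
  dt <- dt[sample1 != sample2]
  ids <- names(clusters)
  M <- sharing_matrix(dt, ids, ids)
  ## per-individual totals against each cluster, then member means
  cl_cols <- vapply(labs, function(l)
    rowSums(M[, clusters == l, drop = FALSE]), numeric(length(ids)))
  prof <- do.call(rbind, lapply(labs, function(l)
    colMeans(cl_cols[clusters == l, , drop = FALSE])))
  dimnames(prof) <- list(labs, labs)
  out <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (l in labs) {
    x <- prof[l, labs != l]
    if (sum(x) == 0) { out[l, ] <- NA_real_; out[l, l] <- 0; next }
    x <- x / sum(x)
    Yd <- prof[labs != l, labs != l, drop = FALSE]
    rs <- rowSums(Yd)
    Yd[rs > 0, ] <- Yd[rs > 0, , drop = FALSE] / rs[rs > 0]
    out[l, labs != l] <- nnls_profile(x, Yd)
  }
  out
}
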