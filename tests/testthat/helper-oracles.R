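## Independent oracles used by the tests; deliberately brute-force and kept
## free of the code paths they check.

## founder label of one haplotype at arbitrary cM positions
fid_at <- function(mosaic_chrom, pos) {
  idx <- findInterval(pos, mosaic_chrom$end, left.open = TRUE) + 1L
  idx[idx > length(mosaic_chrom$fid)] <- length(mosaic_chrom$fid)
  mosaic_chrom$fid[idx]
}

## grid-scan IBD total (cM) between two individuals: founder labels compared
## at grid midpoints over every chromosome and haplotype combination
grid_ibd_total <- function(ind_a, ind_b, chrom_length_cM, step = 0.01) {
  tot <- 0
  for (cc in seq_along(chrom_length_cM)) {
    mids <- seq(step / 2, chrom_length_cM[cc] - step / 2, by = step)
    fa <- list(fid_at(ind_a$h1[[cc]], mids), fid_at(ind_a$h2[[cc]], mids))
    fb <- list(fid_at(ind_b$h1[[cc]], mids), fid_at(ind_b$h2[[cc]], mids))
    for (i in 1:2) for (j in 1:2)
      tot <- tot + step * sum(fa[[i]] == fb[[j]])
  }
  tot
}

## all set partitions of 1..n as membership vectors (restricted growth)
all_partitions <- function(n) {
  out <- list()
  recurse <- function(mem, k) {
    if (length(mem) == n) {
      out[[length(out) + 1L]] <<- mem
      return(invisible(NULL))
    }
    for (b in seq_len(k + 1L)) recurse(c(mem, b), max(k, b))
    invisible(NULL)
  }
  recurse(integer(0), 0L)
  out
}

## closed-form adjusted Rand index from a contingency table
ari_closed_form <- function(tab) {
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  a <- sum(comb2(rowSums(tab)))
  b <- sum(comb2(colSums(tab)))
  nC2 <- comb2(sum(tab))
  expected <- a * b / nC2
  (sum_ij - expected) / ((a + b) / 2 - expected)
}
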