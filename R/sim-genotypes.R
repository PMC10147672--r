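#' Draw founder-haplotype alleles
#'
#' One Bernoulli allele per founder haplotype and site, with success
#' probability equal to the founder's source-population frequency.
#'
#' @param freqs site table from [simulate_source_frequencies()].
#' @param fid_source founder-haplotype source labels (index = fid).
#' @param seed integer seed.
#' @return Integer 0/1 matrix, rows = founder haplotypes, columns = sites.
#' @export
draw_founder_alleles <- function(freqs, fid_source, seed = 1L) {
  set.seed(derive_seed(seed, 13L))
  n_site <- nrow(freqs)
  M <- matrix(0L, length(fid_source), n_site)
  for (src in unique(fid_source)) {
    rows <- which(fid_source == src)
    p <- freqs[[src]]
    M[rows, ] <- matrix(rbinom(length(rows) * n_site, 1L,
                               rep(p, each = length(rows))),
                        nrow = length(rows))
  }
  M
}

#' Realise phased genotypes from mosaics and founder alleles
#'
#' Each present-day haplotype's allele at a site is the allele of the
#' founder haplotype covering that site — deterministic given mosaics and
#' founder alleles, so identity by descent implies identity in state. Sites
#' outside the map range are rejected.
#'
#' @param mosaics named list of `list(h1, h2)` mosaics.
#' @param founder_alleles matrix from [draw_founder_alleles()].
#' @param freqs site table whose `chrom`, `pos`, `cM` columns give site
#'   positions.
#' @param chrom_length_cM chromosome lengths in cM.
#' @return Integer haplotype matrix with two rows per individual (rownames
#'   `"<id>|1"`, `"<id>|2"`) and one column per site.
#' @export
realize_genotypes <- function(mosaics, founder_alleles, freqs,
                              chrom_length_cM) {
  ids <- names(mosaics)
  chroms <- paste0("chr", seq_along(chrom_length_cM))
  site_idx <- lapply(seq_along(chroms), function(cc) {
    which(freqs$chrom == chroms[cc])
  })
  for (cc in seq_along(chroms)) {
    cm <- freqs$cM[site_idx[[cc]]]
    if (any(cm < 0 | cm > chrom_length_cM[cc]))
      stop(sprintf("site outside map range on %s", chroms[cc]))
  }
  H <- matrix(0L, 2L * length(ids), nrow(freqs),
              dimnames = list(as.vector(rbind(paste0(ids, "|1"),
                                              paste0(ids, "|2"))), NULL))
  for (i in seq_along(ids)) {
    for (h in 1:2) {
      mos <- mosaics[[i]][[h]]
      row <- 2L * (i - 1L) + h
      for (cc in seq_along(chroms)) {
        idx <- site_idx[[cc]]
        if (!length(idx)) next
        m <- mos[[cc]]
        seg <- findInterval(freqs$cM[idx], m$end, left.open = TRUE) + 1L
        seg[seg > length(m$fid)] <- length(m$fid)
        H[row, idx] <- founder_alleles[cbind(m$fid[seg], idx)]
      }
    }
  }
  H
}

#' Simulate outgroup genotypes
#'
#' Diploid outgroup individuals drawn site-wise Binomial(2, outgroup
#' frequency), represented as two pseudo-haplotypes per individual.
#'
#' @param freqs site table with an `outgroup` frequency column.
#' @param n_outgroup number of diploid individuals.
#' @param seed integer seed.
#' @return Haplotype matrix as in [realize_genotypes()]; ids `OUT.I###`.
#' @export
simulate_outgroup_genotypes <- function(freqs, n_outgroup, seed = 1L) {
  set.seed(derive_seed(seed, 17L))
  ids <- sprintf("OUT.I%03d", seq_len(n_outgroup))
  n_site <- nrow(freqs)
  H <- matrix(rbinom(2L * n_outgroup * n_site, 1L,
                     rep(freqs$outgroup, each = 2L * n_outgroup)),
              nrow = 2L * n_outgroup,
              dimnames = list(as.vector(rbind(paste0(ids, "|1"),
                                              paste0(ids, "|2"))), NULL))
  storage.mode(H) <- "integer"
  H
}

#' Write a phased VCF
#'
#' Minimal VCFv4.2 with phased `GT` fields (`"|"` separator); deterministic
#' given its inputs, so a write-read-write cycle is byte-identical.
#'
#' @param haps haplotype matrix (two rows per individual).
#' @param sites site table (`chrom`, `pos`).
#' @param ids sample ids in row-pair order.
#' @param path output path.
#' @export
write_phased_vcf <- function(haps, sites, ids, path) {
  stopifnot(nrow(haps) == 2L * length(ids), ncol(haps) == nrow(sites))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", unique(sites$chrom)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  a1 <- haps[seq(1L, nrow(haps), by = 2L), , drop = FALSE]
  a2 <- haps[seq(2L, nrow(haps), by = 2L), , drop = FALSE]
  gt <- matrix(paste0(a1, "|", a2), nrow = nrow(a1))
  lines <- paste(sites$chrom, format(sites$pos, scientific = FALSE,
                                     trim = TRUE),
                 paste0(sites$chrom, "_", format(sites$pos,
                                                 scientific = FALSE,
                                                 trim = TRUE)),
                 "A", "G", ".", "PASS", ".", "GT",
                 apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a phased VCF into a haplotype matrix
#'
#' @param path VCF path (plain or gzipped).
#' @return A list with `haps` (two rows per individual), `sites`
#'   (`chrom`, `pos`) and `ids`.
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  ids <- colnames(gt)
  sites <- data.frame(chrom = as.character(v@fix[, "CHROM"]),
                      pos = as.numeric(v@fix[, "POS"]),
                      stringsAsFactors = FALSE)
  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  H <- matrix(0L, 2L * length(ids), nrow(gt),
              dimnames = list(as.vector(rbind(paste0(ids, "|1"),
                                              paste0(ids, "|2"))), NULL))
  for (i in seq_along(ids)) {
    H[2L * i - 1L, ] <- a1[, i]
    H[2L * i, ] <- a2[, i]
  }
  list(haps = H, sites = sites, ids = ids)
}
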