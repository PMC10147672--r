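#' Extract true IBD segments from haplotype mosaics
#'
#' For every pair of haplotypes, maximal intervals over which the founder
#' haplotype identity matches are emitted as IBD segments (adjacent matching
#' intervals are coalesced before the length filter, including across founder
#' label changes, since the position-wise match is what defines descent).
#' Within-individual matches (the two haplotypes of one person) are the
#' HBD/ROH analogue and are returned by [extract_true_hbd()].
#'
#' @param x a `founder_pedigree` (from [simulate_pedigree()]) or a named list
#'   of `list(h1, h2)` mosaics.
#' @param min_cM minimum segment length retained (in cM, `length >= min_cM`).
#' @param pairs optional two-column matrix/data.frame of sample-id pairs to
#'   restrict the output to.
#' @param bp_per_cM physical scale used to emit bp coordinates (taken from the
#'   configuration when `x` is a `founder_pedigree`).
#' @return A `data.table` segment table with columns `sample1, hap1, sample2,
#'   hap2, chrom, start_bp, end_bp, lod, length_cM` (plus `start_cM, end_cM`).
#' @export
extract_true_ibd <- function(x, min_cM = 1, pairs = NULL, bp_per_cM = 1e6) {
  true_segments(x, min_cM = min_cM, pairs = pairs, bp_per_cM = bp_per_cM,
                within = FALSE)
}

#' @rdname extract_true_ibd
#' @export
extract_true_hbd <- function(x, min_cM = 1, bp_per_cM = 1e6) {
  true_segments(x, min_cM = min_cM, pairs = NULL, bp_per_cM = bp_per_cM,
                within = TRUE)
}

true_segments <- function(x, min_cM, pairs, bp_per_cM, within) {
  if (inherits(x, "founder_pedigree")) {
    bp_per_cM <- x$config$bp_per_cM
    mosaics <- x$mosaics
  } else mosaics <- x
  stopifnot(length(mosaics) >= 1L, !is.null(names(mosaics)))
  ids <- names(mosaics)
  n <- length(ids)

  ## flatten every haplotype's tiling into one segment table
  chunks <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    for (h in 1:2) {
      m <- mosaics[[i]][[h]]
      hap_id <- 2L * (i - 1L) + h
      per_chrom <- lapply(seq_along(m), function(cc) {
        mc <- m[[cc]]
        if (!length(mc$end)) return(NULL)
        list(hap = rep.int(hap_id, length(mc$end)),
             chrom = rep.int(cc, length(mc$end)),
             fid = mc$fid,
             start = c(0, mc$end[-length(mc$end)]),
             end = mc$end)
      })
      chunks[[hap_id]] <- per_chrom
    }
  }
  flat <- unlist(chunks, recursive = FALSE)
  flat <- flat[!vapply(flat, is.null, logical(1))]
  DT <- data.table(hap = unlist(lapply(flat, `[[`, "hap")),
                   chrom = unlist(lapply(flat, `[[`, "chrom")),
                   fid = unlist(lapply(flat, `[[`, "fid")),
                   start = unlist(lapply(flat, `[[`, "start")),
                   end = unlist(lapply(flat, `[[`, "end")))
  setorder(DT, chrom, fid, start)
  res <- ibd_intersect_cpp(DT$hap, DT$chrom, DT$fid, DT$start, DT$end,
                           within_only = within, cross_only = !within)
  out <- as.data.table(res)
  if (!nrow(out)) return(empty_segment_table())
  setnames(out, c("start", "end"), c("start_cM", "end_cM"))
  out[, length_cM := end_cM - start_cM]
  out <- out[length_cM >= min_cM - 1e-12]
  if (!nrow(out)) return(empty_segment_table())

  out[, sample1 := ids[(hap1 - 1L) %/% 2L + 1L]]
  out[, sample2 := ids[(hap2 - 1L) %/% 2L + 1L]]
  out[, hap1 := as.integer((hap1 - 1L) %% 2L + 1L)]
  out[, hap2 := as.integer((hap2 - 1L) %% 2L + 1L)]
  out[, chrom := paste0("chr", chrom)]
  out[, start_bp := round(start_cM * bp_per_cM)]
  out[, end_bp := round(end_cM * bp_per_cM)]
  out[, lod := NA_real_]
  out <- out[, .(sample1, hap1, sample2, hap2, chrom, start_bp, end_bp,
                 lod, length_cM, start_cM, end_cM)]
  out <- canonicalise_segments(out)
  if (!is.null(pairs)) {
    pairs <- as.data.frame(pairs)
    key_want <- paste(pmin(pairs[[1]], pairs[[2]]),
                      pmax(pairs[[1]], pairs[[2]]))
    out <- out[paste(sample1, sample2) %in% key_want]
  }
  out[]
}

empty_segment_table <- function() {
  data.table(sample1 = character(0), hap1 = integer(0),
             sample2 = character(0), hap2 = integer(0),
             chrom = character(0), start_bp = numeric(0),
             end_bp = numeric(0), lod = numeric(0),
             length_cM = numeric(0), start_cM = numeric(0),
             end_cM = numeric(0))
}
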