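#' Read a genetic map
#'
#' Accepts a 3-column TSV (`chrom`, `bp`, `cM`; header optional) or a PLINK
#' `.map` file (`chrom`, `id`, `cM`, `bp`). Within each chromosome the
#' anchors must be strictly increasing in both coordinates.
#'
#' @param path file path.
#' @return A validated `data.frame` with columns `chrom`, `bp`, `cM`.
#' @export
read_genetic_map <- function(path) {
  dt <- fread(path, header = "auto")
  if (ncol(dt) == 4L) {
    setnames(dt, c("chrom", "id", "cM", "bp"))
    dt <- dt[, .(chrom, bp, cM)]
  } else if (ncol(dt) == 3L) {
    setnames(dt, c("chrom", "bp", "cM"))
  } else stop("genetic map must have 3 (TSV) or 4 (PLINK .map) columns")
  map <- as.data.frame(dt)
  map$chrom <- as.character(map$chrom)
  validate_genetic_map(map)
  map
}

#' @rdname read_genetic_map
#' @param map a genetic map `data.frame`.
#' @export
write_genetic_map <- function(map, path) {
  validate_genetic_map(map)
  fwrite(map, path, sep = "\t")
  invisible(path)
}

validate_genetic_map <- function(map) {
  stopifnot(all(c("chrom", "bp", "cM") %in% names(map)))
  for (cc in unique(map$chrom)) {
    sub <- map[map$chrom == cc, ]
    if (nrow(sub) < 2L)
      stop(sprintf("genetic map needs >= 2 anchors on %s", cc))
    if (is.unsorted(sub$bp, strictly = TRUE) ||
        is.unsorted(sub$cM, strictly = TRUE))
      stop(sprintf("genetic map not strictly increasing on %s", cc))
  }
  invisible(TRUE)
}

#' Interpolate physical positions to genetic positions
#'
#' Linear interpolation between map anchors; positions outside the anchored
#' range are an error, not a clamp.
#'
#' @param map genetic map `data.frame` (`chrom`, `bp`, `cM`).
#' @param chrom chromosome labels (recycled against `bp`).
#' @param bp physical positions.
#' @return Genetic positions in cM.
#' @export
bp_to_cm <- function(map, chrom, bp) {
  validate_genetic_map(map)
  n <- max(length(chrom), length(bp))
  chrom <- rep_len(as.character(chrom), n)
  bp <- rep_len(bp, n)
  out <- rep(NA_real_, n)
  for (cc in unique(chrom)) {
    sub <- map[map$chrom == cc, ]
    if (!nrow(sub)) stop(sprintf("chromosome %s absent from genetic map", cc))
    i <- chrom == cc
    out[i] <- approx(sub$bp, sub$cM, xout = bp[i], rule = 1)$y
  }
  if (anyNA(out))
    stop(sprintf("position outside genetic map range (first offender: %s:%s)",
                 chrom[which(is.na(out))[1]],
                 format(bp[which(is.na(out))[1]], scientific = FALSE)))
  out
}

SEGMENT_COLS <- c("sample1", "hap1", "sample2", "hap2", "chrom",
                  "start_bp", "end_bp", "lod", "length_cM")

#' Read an IBD/HBD segment table
#'
#' Tab-delimited, 8 or 9 columns in the order `sample1 hap1 sample2 hap2
#' chrom start_bp end_bp [lod] length_cM`; the header is optional and `lod`
#' may be `"."`. When the `length_cM` column is absent it is recomputed from
#' the genetic map. HBD rows carry the same sample in both carrier slots.
#'
#' @param path file path.
#' @param map genetic map used to attach cM coordinates (and lengths when
#'   absent from the file).
#' @return A canonicalised segment `data.table` (columns as in
#'   [extract_true_ibd()]).
#' @export
read_ibd_table <- function(path, map) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  has_header <- identical(first[1], "sample1")
  dt <- fread(path, header = has_header, sep = "\t", na.strings = ".")
  if (ncol(dt) == 8L) {
    setnames(dt, SEGMENT_COLS[-9L])
    dt[, length_cM := NA_real_]
  } else if (ncol(dt) == 9L) {
    setnames(dt, SEGMENT_COLS)
  } else stop("segment table must have 8 or 9 tab-delimited columns")
  dt[, lod := as.numeric(lod)]
  dt[, chrom := as.character(chrom)]
  bad <- which(!(dt$start_bp < dt$end_bp))
  if (length(bad))
    stop(sprintf("segment with start_bp >= end_bp at line %d",
                 bad[1] + has_header))
  cm <- tryCatch(list(
    s = bp_to_cm(map, dt$chrom, dt$start_bp),
    e = bp_to_cm(map, dt$chrom, dt$end_bp)), error = function(err) err)
  if (inherits(cm, "error")) {
    ## rerun row-wise to report the offending line
    for (i in seq_len(nrow(dt))) {
      ok <- tryCatch({
        bp_to_cm(map, dt$chrom[i], c(dt$start_bp[i], dt$end_bp[i]))
        TRUE
      }, error = function(e) FALSE)
      if (!ok)
        stop(sprintf("segment outside genetic map range at line %d",
                     i + has_header))
    }
    stop(cm)
  }
  dt[, start_cM := cm$s]
  dt[, end_cM := cm$e]
  dt[is.na(length_cM), length_cM := end_cM - start_cM]
  if (any(dt$length_cM <= 0)) stop("non-positive segment length")
  self_hap <- dt$sample1 == dt$sample2 & dt$hap1 == dt$hap2
  if (any(self_hap)) stop("segment pairs a haplotype with itself")
  canonicalise_segments(dt)[]
}

#' Write an IBD/HBD segment table
#'
#' Writes the canonical 9-column tab-delimited dialect with `"."` for missing
#' LOD scores; writing a table read back with [read_ibd_table()] reproduces
#' the file byte for byte.
#'
#' @param segments a segment table.
#' @param path output path.
#' @export
write_ibd_table <- function(segments, path) {
  segments <- canonicalise_segments(as.data.table(segments))
  out <- segments[, .(
    sample1, hap1, sample2, hap2, chrom,
    start_bp = format(start_bp, scientific = FALSE, trim = TRUE),
    end_bp = format(end_bp, scientific = FALSE, trim = TRUE),
    lod = ifelse(is.na(lod), ".", format(lod, trim = TRUE)),
    length_cM = sprintf("%.6f", length_cM))]
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Canonicalise a segment table
#'
#' Orders each unordered carrier pair lexicographically (swapping haplotype
#' indices along with the samples) and sorts rows deterministically.
#'
#' @param segments a segment table.
#' @return The canonicalised `data.table`.
#' @export
canonicalise_segments <- function(segments) {
  dt <- as.data.table(segments)
  swap <- dt$sample1 > dt$sample2 |
    (dt$sample1 == dt$sample2 & dt$hap1 > dt$hap2)
  if (any(swap)) {
    s1 <- dt$sample1[swap]; h1 <- dt$hap1[swap]
    dt[swap, `:=`(sample1 = sample2, hap1 = hap2)]
    dt[swap, `:=`(sample2 = s1, hap2 = h1)]
  }
  setorder(dt, sample1, sample2, hap1, hap2, chrom, start_bp, end_bp)
  dt
}

#' Merge adjacent segment fragments
#'
#' Fragments of a putative larger IBD segment, broken up by detection error,
#' are re-joined: any two segments of the same carrier pair, haplotype
#' indices and chromosome separated by a cM gap of at most `max_gap_cM` are
#' replaced by their union, applied transitively. The merged length spans the
#' union (gaps included). Idempotent.
#'
#' @param segments a segment table with cM coordinates.
#' @param max_gap_cM maximum gap bridged, in cM (default 0.6).
#' @return The merged, canonicalised segment table.
#' @export
merge_adjacent_segments <- function(segments, max_gap_cM = 0.6) {
  if (max_gap_cM < 0) stop("max_gap_cM must be non-negative")
  dt <- canonicalise_segments(as.data.table(segments))
  if (!nrow(dt)) return(dt)
  stopifnot(all(c("start_cM", "end_cM") %in% names(dt)))
  setorder(dt, sample1, sample2, hap1, hap2, chrom, start_cM)
  dt[, grp := cumsum(start_cM > cummax(shift(end_cM, fill = -Inf)) +
                       max_gap_cM + 1e-9),
     by = .(sample1, sample2, hap1, hap2, chrom)]
  out <- dt[, .(start_bp = min(start_bp), end_bp = max(end_bp),
                lod = if (all(is.na(lod))) NA_real_ else max(lod, na.rm = TRUE),
                start_cM = min(start_cM), end_cM = max(end_cM)),
            by = .(sample1, sample2, hap1, hap2, chrom, grp)]
  out[, grp := NULL]
  out[, length_cM := end_cM - start_cM]
  setcolorder(out, c(SEGMENT_COLS, "start_cM", "end_cM"))
  canonicalise_segments(out)[]
}

#' Band-filter segments by genetic length
#'
#' Retains segments with `min_cM < length_cM < max_cM`, both inequalities
#' strict. Stage conventions: network clustering uses `(1, Inf)`, the
#' ancestry model and within-cluster summaries `(3, 15)`.
#'
#' @param segments a segment table.
#' @param min_cM,max_cM exclusive band bounds (`min_cM < max_cM`).
#' @return The filtered table.
#' @export
filter_band <- function(segments, min_cM = 3, max_cM = 15) {
  stopifnot(min_cM < max_cM)
  dt <- as.data.table(segments)
  dt[length_cM > min_cM & length_cM < max_cM]
}

#' Total band-limited sharing per individual pair
#'
#' Sums segment lengths and counts over all haplotype combinations of each
#' unordered individual pair, after optional band filtering. Within-individual
#' (HBD) rows are excluded.
#'
#' @param segments a segment table.
#' @param band optional `c(min_cM, max_cM)` passed to [filter_band()].
#' @return A `data.table` with columns `sample1`, `sample2` (lexicographic),
#'   `total_cM`, `n_segments`.
#' @export
pair_totals <- function(segments, band = NULL) {
  dt <- canonicalise_segments(as.data.table(segments))
  if (!is.null(band)) dt <- filter_band(dt, band[1], band[2])
  dt <- dt[sample1 != sample2]
  out <- dt[, .(total_cM = sum(length_cM), n_segments = .N),
            by = .(sample1, sample2)]
  setorder(out, sample1, sample2)
  out[]
}

#' Read/write the sample metadata table
#'
#' Tab-delimited columns: `id`, `group`, `role`, `denomination`, and four
#' grandparental coordinate pairs `gp1_lat, gp1_lon, ..., gp4_lon`.
#'
#' @param path file path.
#' @return `read_metadata`: a `data.frame`.
#' @export
read_metadata <- function(path) {
  as.data.frame(fread(path, sep = "\t", header = TRUE, na.strings = "NA"))
}

#' @rdname read_metadata
#' @param meta metadata `data.frame`.
#' @export
write_metadata <- function(meta, path) {
  fwrite(meta, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
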