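## Haplotype mosaics.
##
## A present-day haplotype is represented as, per chromosome, a run-length
## tiling of the cM axis by founder-haplotype labels:
##   list(end = <increasing segment end positions, last == chrom length>,
##        fid = <integer founder-haplotype id per segment>)
## Segment starts are implicit (0, end[-n]). Every simulated haplotype tiles
## its chromosome exactly: no gaps, no overlaps.

#' Create a founder haplotype mosaic
#'
#' A founder haplotype carries a single label over every chromosome.
#'
#' @param chrom_length_cM numeric vector of chromosome lengths in cM.
#' @param fid integer founder-haplotype id.
#' @return A mosaic: list over chromosomes of `list(end, fid)`.
#' @export
founder_mosaic <- function(chrom_length_cM, fid) {
  lapply(chrom_length_cM, function(L) list(end = L, fid = as.integer(fid)))
}

## Splice one chromosome: alternate between parental haplotypes A and B at
## the crossover positions `cuts`, starting from haplotype `first` (1 or 2).
splice_chrom <- function(A, B, L, cuts, first) {
  if (L <= 0) return(list(end = numeric(0), fid = integer(0)))
  P <- list(A, B)
  bounds <- c(cuts, L)
  n_piece <- length(bounds)
  ends <- vector("list", n_piece)
  fids <- vector("list", n_piece)
  a <- 0
  cur <- first
  for (i in seq_len(n_piece)) {
    b <- bounds[i]
    if (b > a) {
      h <- P[[cur]]
      pe <- h$end
      j1 <- findInterval(a, pe) + 1L
      j2 <- findInterval(b, pe, left.open = TRUE) + 1L
      e <- pe[j1:j2]
      e[length(e)] <- b
      ends[[i]] <- e
      fids[[i]] <- h$fid[j1:j2]
    }
    a <- b
    cur <- 3L - cur
  }
  e <- unlist(ends, use.names = FALSE)
  f <- unlist(fids, use.names = FALSE)
  if (length(e) > 1L) {
    keep <- c(f[-length(f)] != f[-1L], TRUE)
    e <- e[keep]
    f <- f[keep]
  }
  list(end = e, fid = f)
}

#' Simulate one meiosis
#'
#' Crossover counts are Poisson with mean `length_cM / 100` per chromosome
#' (no interference, no obligate chiasma), positions uniform on the cM axis.
#' The gamete alternates between the two parental haplotypes starting from a
#' fair coin. Randomness is drawn from the current R RNG stream; `cuts` and
#' `first` can be forced for deterministic construction.
#'
#' @param parent a list `list(h1 = <mosaic>, h2 = <mosaic>)`.
#' @param chrom_length_cM chromosome lengths in cM.
#' @param cuts optional list (per chromosome) of forced crossover positions.
#' @param first optional integer vector (per chromosome) of the starting
#'   parental haplotype, 1 or 2.
#' @return A gamete mosaic tiling the map.
#' @export
meiosis <- function(parent, chrom_length_cM, cuts = NULL, first = NULL) {
  n <- length(chrom_length_cM)
  out <- vector("list", n)
  for (cc in seq_len(n)) {
    L <- chrom_length_cM[cc]
    if (L <= 0) {
      out[[cc]] <- list(end = numeric(0), fid = integer(0))
      next
    }
    k <- if (is.null(cuts)) rpois(1L, L / 100) else length(cuts[[cc]])
    cx <- if (is.null(cuts)) sort(runif(k, 0, L)) else sort(cuts[[cc]])
    f1 <- if (is.null(first)) sample.int(2L, 1L) else as.integer(first[cc])
    out[[cc]] <- splice_chrom(parent$h1[[cc]], parent$h2[[cc]], L, cx, f1)
  }
  out
}

#' Check that a mosaic tiles its map exactly
#'
#' @param mosaic a haplotype mosaic.
#' @param chrom_length_cM chromosome lengths in cM.
#' @return `TRUE` if every chromosome is tiled with no gaps or overlaps.
#' @export
mosaic_tiles_map <- function(mosaic, chrom_length_cM) {
  for (cc in seq_along(chrom_length_cM)) {
    m <- mosaic[[cc]]
    L <- chrom_length_cM[cc]
    if (L <= 0) {
      if (length(m$end)) return(FALSE)
      next
    }
    if (!length(m$end)) return(FALSE)
    if (abs(m$end[length(m$end)] - L) > 1e-9) return(FALSE)
    if (is.unsorted(m$end, strictly = TRUE)) return(FALSE)
    if (m$end[1] <= 0) return(FALSE)
    if (length(m$fid) != length(m$end)) return(FALSE)
  }
  TRUE
}

## cM carried by founder haplotypes in `fid_set`, over both haplotypes.
mosaic_cm_in <- function(h1, h2, fid_set) {
  tot <- 0
  for (m in c(h1, h2)) {
    if (!length(m$end)) next
    len <- diff(c(0, m$end))
    tot <- tot + sum(len[m$fid %in% fid_set])
  }
  tot
}
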