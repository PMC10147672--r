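#' Simulate per-population allele frequencies
#'
#' Site positions are drawn uniformly per chromosome; ancestral frequencies
#' are uniform on `ancestral_freq_range`; each population's frequency is
#' drawn from the Balding-Nichols distribution
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` with that population's
#' divergence `F` (the outgroup uses `outgroup_F`). As `F` approaches 0 the
#' population frequency collapses onto the ancestral frequency; `F` in
#' \{0, 1\} is rejected.
#'
#' @param config a [sim_config()].
#' @return A `data.frame` with columns `chrom`, `pos`, `cM`, `ancestral`, one
#'   column per source population and `outgroup`.
#' @export
simulate_source_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 11L))
  sites <- do.call(rbind, lapply(seq_len(config$n_chrom), function(cc) {
    L_bp <- round(config$chrom_length_cM[cc] * config$bp_per_cM)
    pos <- sort(sample.int(L_bp - 1L, config$n_sites_per_chrom))
    data.frame(chrom = paste0("chr", cc), pos = pos,
               cM = pos / config$bp_per_cM, stringsAsFactors = FALSE)
  }))
  rng <- config$ancestral_freq_range
  sites$ancestral <- runif(nrow(sites), rng[1], rng[2])
  for (s in config$sources)
    sites[[s$name]] <- balding_nichols(sites$ancestral, s$F_div)
  sites$outgroup <- balding_nichols(sites$ancestral, config$outgroup_F)
  sites
}

#' Balding-Nichols drifted allele frequencies
#'
#' @param p ancestral allele frequencies.
#' @param F divergence parameter in (0, 1).
#' @return Drifted frequencies, one draw per element of `p`.
#' @export
balding_nichols <- function(p, F) {
  if (!is.numeric(F) || length(F) != 1L || F <= 0 || F >= 1)
    stop("Balding-Nichols F must lie strictly between 0 and 1")
  stopifnot(all(p > 0 & p < 1))
  rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}
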