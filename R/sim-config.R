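#' Deme specification for the founder-colony simulator
#'
#' A deme is an isolated coastal community ("bay") founded by a small number
#' of settlers drawn from two diverged source populations.
#'
#' @param name deme label.
#' @param n_founders number of diploid founders (>= 4).
#' @param p_source1 probability that a founder's parents are drawn from the
#'   first source population (the rest come from the second).
#' @param centroid numeric `(lat, lon)` of the deme in decimal degrees; the
#'   birthplace recorded for members' grandparents is this point plus noise.
#' @param jitter_sd standard deviation, in degrees, of grandparental
#'   birthplace noise around the centroid.
#' @param majority_denomination denomination label assigned to most members.
#' @return A list of class `deme_spec`.
#' @export
deme_spec <- function(name, n_founders = 40L, p_source1 = 0.5,
                      centroid = c(47.5, -53.0), jitter_sd = 0.05,
                      majority_denomination = "Protestant") {
  stopifnot(is.character(name), length(name) == 1L,
            n_founders >= 4L,
            p_source1 >= 0, p_source1 <= 1,
            length(centroid) == 2L, jitter_sd >= 0)
  structure(list(name = name, n_founders = as.integer(n_founders),
                 p_source1 = p_source1, centroid = as.numeric(centroid),
                 jitter_sd = jitter_sd,
                 majority_denomination = majority_denomination),
            class = "deme_spec")
}

#' Source-population specification
#'
#' Each source population drifts away from a common ancestral allele-frequency
#' pool under the Balding-Nichols model and is simulated as a finite
#' random-mating pedigree, so that colony individuals genuinely share IBD with
#' the present-day reference panel exported from it.
#'
#' @param name population label (e.g. `"S1"` for the Irish-like source).
#' @param F_div Balding-Nichols divergence from the ancestral pool, in (0, 1).
#' @param pop_size constant diploid population size per generation.
#' @param n_generations pedigree depth; must be at least the colony's
#'   founding generation so founders can be drawn at the right time.
#' @param n_reference number of present-day individuals exported as the
#'   ancestry reference panel (`<= pop_size`).
#' @return A list of class `source_pop_spec`.
#' @export
source_pop_spec <- function(name, F_div = 0.02, pop_size = 150L,
                            n_generations = 20L, n_reference = 60L) {
  stopifnot(F_div > 0, F_div < 1, pop_size >= 2L,
            n_generations >= 1L, n_reference <= pop_size, n_reference >= 0L)
  structure(list(name = name, F_div = F_div, pop_size = as.integer(pop_size),
                 n_generations = as.integer(n_generations),
                 n_reference = as.integer(n_reference)),
            class = "source_pop_spec")
}

default_demes <- function() {
  list(
    deme_spec("Avalon",    p_source1 = 0.9, centroid = c(47.2, -53.2),
              majority_denomination = "Catholic"),
    deme_spec("Burin",     p_source1 = 0.7, centroid = c(47.0, -55.1),
              majority_denomination = "Catholic"),
    deme_spec("Trinity",   p_source1 = 0.3, centroid = c(48.0, -53.4),
              majority_denomination = "Protestant"),
    deme_spec("NotreDame", p_source1 = 0.1, centroid = c(49.3, -55.0),
              majority_denomination = "Protestant")
  )
}

#' Colony specification
#'
#' @param demes list of [deme_spec()] objects.
#' @param founding_generation generations before present at which the colony
#'   was founded (>= 2).
#' @param growth_rate per-generation multiplicative growth. The default
#'   (`NULL`) is chosen so the final colony size is about `target_size`.
#' @param migration_rate per-individual, per-generation probability of mating
#'   in a deme other than the natal one; in \[0, 0.5\].
#' @param denomination_fidelity probability that a member is assigned the
#'   deme-majority denomination rather than another one.
#' @param target_size approximate present-day colony size used to derive the
#'   default growth rate.
#' @return A list of class `colony_spec`.
#' @export
colony_spec <- function(demes = default_demes(), founding_generation = 12L,
                        growth_rate = NULL, migration_rate = 0.01,
                        denomination_fidelity = 0.9, target_size = 400L) {
  stopifnot(founding_generation >= 2L,
            migration_rate >= 0, migration_rate <= 0.5,
            denomination_fidelity >= 0, denomination_fidelity <= 1,
            length(demes) >= 1L)
  if (!all(vapply(demes, inherits, logical(1), "deme_spec")))
    stop("`demes` must be a list of deme_spec objects")
  nm <- vapply(demes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("deme names must be unique")
  structure(list(demes = demes,
                 founding_generation = as.integer(founding_generation),
                 growth_rate = growth_rate, migration_rate = migration_rate,
                 denomination_fidelity = denomination_fidelity,
                 target_size = as.integer(target_size)),
            class = "colony_spec")
}

#' Simulation configuration for the founder-colony generator
#'
#' Fixing `seed` fixes every downstream artefact byte-for-byte; component
#' stages draw their randomness from sub-streams derived with [derive_seed()].
#'
#' @param seed master integer seed.
#' @param n_chrom number of chromosomes.
#' @param chrom_length_cM genetic length of each chromosome (recycled).
#' @param bp_per_cM constant physical-to-genetic scale of the default map.
#' @param n_sites_per_chrom biallelic sites simulated per chromosome.
#' @param ancestral_freq_range range of the uniform ancestral allele frequency.
#' @param sources list of two [source_pop_spec()] objects.
#' @param colony a [colony_spec()].
#' @param outgroup_F Balding-Nichols divergence of the outgroup population.
#' @param n_outgroup diploid outgroup individuals genotyped for the outgroup
#'   frequency panel.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chrom = 4L, chrom_length_cM = 100,
                       bp_per_cM = 1e6, n_sites_per_chrom = 2000L,
                       ancestral_freq_range = c(0.05, 0.95),
                       sources = list(source_pop_spec("S1"),
                                      source_pop_spec("S2")),
                       colony = colony_spec(), outgroup_F = 0.15,
                       n_outgroup = 50L) {
  stopifnot(n_chrom >= 1L, all(chrom_length_cM > 0), bp_per_cM > 0,
            n_sites_per_chrom >= 1L,
            length(ancestral_freq_range) == 2L,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] <= ancestral_freq_range[2],
            outgroup_F > 0, outgroup_F < 1, n_outgroup >= 1L)
  if (length(sources) != 2L ||
      !all(vapply(sources, inherits, logical(1), "source_pop_spec")))
    stop("exactly two source_pop_spec objects are required")
  if (!inherits(colony, "colony_spec")) stop("`colony` must be a colony_spec")
  for (s in sources)
    if (s$n_generations < colony$founding_generation)
      stop("source pedigree depth must cover the colony founding generation")
  cfg <- structure(list(
    seed = as.integer(seed), n_chrom = as.integer(n_chrom),
    chrom_length_cM = rep(as.numeric(chrom_length_cM),
                          length.out = as.integer(n_chrom)),
    bp_per_cM = bp_per_cM, n_sites_per_chrom = as.integer(n_sites_per_chrom),
    ancestral_freq_range = as.numeric(ancestral_freq_range),
    sources = sources, colony = colony, outgroup_F = outgroup_F,
    n_outgroup = as.integer(n_outgroup)), class = "sim_config")
  if (is.null(cfg$colony$growth_rate)) {
    n0 <- sum(vapply(cfg$colony$demes, `[[`, integer(1), "n_founders"))
    cfg$colony$growth_rate <-
      (cfg$colony$target_size / n0)^(1 / cfg$colony$founding_generation)
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  d <- x$colony$demes
  cat("founder-colony simulation config\n")
  cat(sprintf("  seed %d | %d chromosomes x %s cM | %d sites/chrom\n",
              x$seed, x$n_chrom, paste(unique(x$chrom_length_cM),
                                       collapse = "/"),
              x$n_sites_per_chrom))
  cat(sprintf("  sources: %s\n", paste(vapply(x$sources, function(s)
    sprintf("%s (F=%.3g, N=%d, refs=%d)", s$name, s$F_div, s$pop_size,
            s$n_reference), character(1)), collapse = "; ")))
  cat(sprintf("  colony: founded %d generations ago, growth %.3f/gen, migration %.3g\n",
              x$colony$founding_generation, x$colony$growth_rate,
              x$colony$migration_rate))
  for (dm in d)
    cat(sprintf("    deme %-10s founders=%d p_source1=%.2f %s\n",
                dm$name, dm$n_founders, dm$p_source1,
                dm$majority_denomination))
  invisible(x)
}

#' Default genetic map of a simulation configuration
#'
#' Constant `bp_per_cM` anchors: `(0 bp, 0 cM)` and the chromosome end.
#'
#' @param config a [sim_config()].
#' @return A `data.frame` with columns `chrom`, `bp`, `cM`.
#' @export
sim_genetic_map <- function(config) {
  data.frame(
    chrom = rep(paste0("chr", seq_len(config$n_chrom)), each = 2L),
    bp = as.numeric(rbind(0, config$chrom_length_cM * config$bp_per_cM)),
    cM = as.numeric(rbind(0, config$chrom_length_cM)),
    stringsAsFactors = FALSE
  )
}
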