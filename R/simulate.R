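#' Simulate a complete founder-colony study dataset
#'
#' Runs the full generator: source-population allele frequencies, the source
#' and colony pedigrees with recombination, true IBD/HBD extraction from the
#' haplotype mosaics, and phased genotypes (colony, reference panels and an
#' outgroup). Everything is reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param min_ibd_cM minimum true segment length retained (default 1 cM).
#' @return An object of class `founder_sim` with elements `config`, `map`,
#'   `samples` (present-day metadata including outgroup rows), `pedigree`,
#'   `mosaics`, `true_ancestry`, `ibd`, `hbd`, `freqs` (per-population site
#'   frequencies), `haps` (phased haplotype matrix over colony + references +
#'   outgroup), `sites`, and `ids` (row-pair order of `haps`).
#' @export
simulate_founder_colony <- function(config = sim_config(), min_ibd_cM = 1) {
  stopifnot(inherits(config, "sim_config"))
  ped <- simulate_pedigree(config)
  freqs <- simulate_source_frequencies(config)
  ibd <- extract_true_ibd(ped, min_cM = min_ibd_cM)
  hbd <- extract_true_hbd(ped, min_cM = min_ibd_cM)
  founder_alleles <- draw_founder_alleles(freqs, ped$fid_source,
                                          seed = config$seed)
  H <- realize_genotypes(ped$mosaics, founder_alleles, freqs,
                         config$chrom_length_cM)
  HO <- simulate_outgroup_genotypes(freqs, config$n_outgroup,
                                    seed = config$seed)
  haps <- rbind(H, HO)
  out_ids <- sub("\\|1$", "", rownames(HO)[seq(1L, nrow(HO), 2L)])
  samples <- ped$samples
  out_meta <- samples[0, ]
  out_meta[seq_along(out_ids), "id"] <- out_ids
  out_meta$group <- "outgroup"
  out_meta$role <- "outgroup"
  samples <- rbind(samples, out_meta)
  rownames(samples) <- NULL
  structure(list(config = config, map = sim_genetic_map(config),
                 samples = samples, pedigree = ped$pedigree,
                 mosaics = ped$mosaics, true_ancestry = ped$true_ancestry,
                 fid_source = ped$fid_source,
                 ibd = ibd, hbd = hbd, freqs = freqs,
                 haps = haps, sites = freqs[, c("chrom", "pos", "cM")],
                 ids = c(names(ped$mosaics), out_ids)),
            class = "founder_sim")
}

#' @export
print.founder_sim <- function(x, ...) {
  cat("synthetic founder-colony dataset\n")
  print(x$config)
  cat(sprintf("  %d present-day samples (%d colony, %d reference, %d outgroup)\n",
              nrow(x$samples), sum(x$samples$role == "colony"),
              sum(x$samples$role == "reference"),
              sum(x$samples$role == "outgroup")))
  cat(sprintf("  true IBD segments >= %s cM: %d | HBD: %d | sites: %d\n",
              format(min(x$ibd$length_cM)), nrow(x$ibd), nrow(x$hbd),
              nrow(x$sites)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the four input kinds the analysis pipeline consumes — phased VCF,
#' IBD and HBD segment tables, genetic map TSV, metadata TSV — plus a ground
#' truth JSON (ancestry fractions, deme labels, pedigree parent pointers).
#'
#' @param sim a `founder_sim`.
#' @param dir output directory (created if needed).
#' @return Named vector of the files written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "founder_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    ibd = file.path(dir, "ibd.tsv"),
    hbd = file.path(dir, "hbd.tsv"),
    map = file.path(dir, "map.tsv"),
    meta = file.path(dir, "metadata.tsv"),
    truth = file.path(dir, "truth.json"))
  write_phased_vcf(sim$haps, sim$sites, sim$ids, paths["vcf"])
  write_ibd_table(sim$ibd, paths["ibd"])
  write_ibd_table(sim$hbd, paths["hbd"])
  write_genetic_map(sim$map, paths["map"])
  write_metadata(sim$samples, paths["meta"])
  colony <- sim$samples$id[sim$samples$role == "colony"]
  truth <- list(
    true_ancestry_s1 = as.list(sim$true_ancestry),
    deme = as.list(setNames(sim$samples$group[match(colony, sim$samples$id)],
                            colony)),
    pedigree = sim$pedigree[, c("id", "father", "mother", "group", "tbp")])
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
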