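#' Run the end-to-end pipeline
#'
#' Executes the requested stages in dependency order — simulate, network,
#' ancestry, stats, drift, geo — writing every stage's outputs under
#' `out_dir` and a run manifest (`manifest.json`) recording the package
#' version, seeds, parameters and an md5 checksum of every artefact. Reruns
#' with an identical configuration are byte-identical. Later stages read the
#' files earlier stages wrote; a missing upstream output is an error naming
#' the stage that needed it.
#'
#' @param config a nested list (or path to a YAML file with the same
#'   structure): `seed`; `stages` (character subset of the six stage names);
#'   optional `inputs` (paths to `ibd`, `hbd`, `map`, `meta`, `vcf` when the
#'   simulate stage is off); optional per-stage parameter lists `simulate`
#'   (arguments to [sim_config()]), `network` (`max_edge_cM`, `levels`,
#'   `min_subgraph`, `resolution`), `ancestry` (`band`), `stats` (`band`),
#'   `geo` (`filter_threshold`, `n_sim`).
#' @param out_dir output directory.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  stages <- config$stages %||%
    c("simulate", "network", "ancestry", "stats", "drift", "geo")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(path, stage) {
    if (is.null(path) || !file.exists(path))
      stop(sprintf("stage '%s' needs missing upstream output: %s",
                   stage, path %||% "<unset>"))
    path
  }
  paths <- list()
  manifest <- list(package = "founderscape",
                   version = as.character(utils::packageVersion("founderscape")),
                   seed = seed, stages = stages, parameters = list())

  if ("simulate" %in% stages) {
    sim_args <- config$simulate %||% list()
    sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    sim <- simulate_founder_colony(cfg)
    paths <- as.list(write_simulation(sim, out_dir))
    manifest$parameters$simulate <-
      list(n_chrom = cfg$n_chrom, chrom_length_cM = cfg$chrom_length_cM,
           n_sites_per_chrom = cfg$n_sites_per_chrom,
           growth_rate = cfg$colony$growth_rate,
           migration_rate = cfg$colony$migration_rate,
           founding_generation = cfg$colony$founding_generation)
  } else {
    paths <- as.list(config$inputs %||% list())
  }

  map <- read_genetic_map(need(paths$map, "network"))
  meta <- read_metadata(need(paths$meta, "network"))

  if ("network" %in% stages) {
    np <- config$network %||% list()
    segs <- merge_adjacent_segments(
      read_ibd_table(need(paths$ibd, "network"), map),
      max_gap_cM = np$merge_gap_cM %||% 0.6)
    analysed <- meta$id[meta$role %in% c("colony", "reference")]
    totals <- pair_totals(segs, band = c(np$min_cM %||% 1, Inf))
    g <- build_graph(totals[totals$sample1 %in% analysed &
                              totals$sample2 %in% analysed],
                     max_edge_cM = np$max_edge_cM %||% 142,
                     nodes = analysed)
    hc <- hierarchical_cluster(g, levels = np$levels %||% 3L,
                               min_subgraph = np$min_subgraph %||% 10L,
                               seed = seed,
                               resolution = np$resolution %||% 1.0)
    paths$clusters <- file.path(out_dir, "clusters.tsv")
    fwrite(as.data.table(unclass(hc)), paths$clusters, sep = "\t")
    manifest$parameters$network <- list(max_edge_cM = np$max_edge_cM %||% 142,
                                        levels = np$levels %||% 3L)
  }

  if ("ancestry" %in% stages) {
    ap <- config$ancestry %||% list()
    band <- ap$band %||% c(3, 15)
    segs <- merge_adjacent_segments(
      read_ibd_table(need(paths$ibd, "ancestry"), map))
    targets <- meta$id[meta$role == "colony"]
    sources <- meta$id[meta$role == "reference"]
    src_cl <- setNames(meta$group[match(sources, meta$id)], sources)
    tgt_cl <- setNames(meta$group[match(targets, meta$id)], targets)
    fit <- estimate_ancestry(segs, targets, sources, src_cl,
                             target_clusters = tgt_cl, band = band)
    paths$ancestry <- file.path(out_dir, "ancestry.tsv")
    bt <- data.table(id = rownames(fit$cluster_beta), fit$cluster_beta)
    fwrite(bt, paths$ancestry, sep = "\t")
    paths$ancestry_cluster_means <- file.path(out_dir,
                                              "ancestry_cluster_means.tsv")
    fwrite(data.table(cluster = rownames(fit$target_cluster_means),
                      fit$target_cluster_means),
           paths$ancestry_cluster_means, sep = "\t")
    paths$ancestry_exclusions <- file.path(out_dir,
                                           "ancestry_exclusions.txt")
    writeLines(fit$excluded, paths$ancestry_exclusions)
    manifest$parameters$ancestry <- list(band = band)
  }

  if ("stats" %in% stages) {
    sp <- config$stats %||% list()
    band <- sp$band %||% c(3, 15)
    segs <- merge_adjacent_segments(
      read_ibd_table(need(paths$ibd, "stats"), map))
    hbd <- read_ibd_table(need(paths$hbd, "stats"), map)
    cl_tab <- fread(need(paths$clusters, "stats"))
    clusters <- setNames(cl_tab$level2, cl_tab$id)
    wci <- suppressWarnings(within_cluster_ibd(segs, clusters, band = band))
    paths$within_cluster_ibd <- file.path(out_dir, "within_cluster_ibd.tsv")
    fwrite(as.data.table(wci$clusters), paths$within_cluster_ibd, sep = "\t")
    roh <- roh_summaries(hbd, map, clusters = clusters)
    paths$roh <- file.path(out_dir, "roh.tsv")
    fwrite(as.data.table(roh$individuals), paths$roh, sep = "\t")
    manifest$parameters$stats <- list(band = band)
  }

  if ("drift" %in% stages) {
    vcf <- read_phased_vcf(need(paths$vcf, "drift"))
    sites <- vcf$sites
    sites$cM <- bp_to_cm(map, sites$chrom, sites$pos)
    grp <- split(meta$id, meta$group)
    fvs <- lapply(grp, function(m) group_freq(vcf$haps, sites, vcf$ids, m))
    ref_names <- unique(meta$group[meta$role == "reference"])
    colony_groups <- unique(meta$group[meta$role == "colony"])
    rows <- list()
    for (dn in colony_groups) {
      d <- d_source_affinity(fvs[[dn]], fvs[["outgroup"]],
                             fvs[[ref_names[1]]], fvs[[ref_names[2]]], map,
                             labels = c("outgroup", dn, ref_names))
      rows[[dn]] <- data.frame(test = "source_affinity", cluster = dn,
                               D = d$D, se = d$se, z = d$z,
                               n_blocks = d$n_blocks)
    }
    fst <- hudson_fst(fvs[[ref_names[1]]], fvs[[ref_names[2]]])
    rows[["fst"]] <- data.frame(test = "hudson_fst_sources", cluster = NA,
                                D = fst$fst, se = NA, z = NA,
                                n_blocks = NA)
    paths$drift <- file.path(out_dir, "drift.tsv")
    fwrite(rbindlist(rows), paths$drift, sep = "\t")
  }

  if ("geo" %in% stages) {
    gp <- config$geo %||% list()
    cl_tab <- fread(need(paths$clusters, "geo"))
    colony_ids <- meta$id[meta$role == "colony"]
    clusters <- setNames(cl_tab$level2, cl_tab$id)[colony_ids]
    filt <- mean_gp_distance_filter(meta[meta$role == "colony", ],
                                    threshold = gp$filter_threshold %||% 0.5)
    denom <- setNames(meta$denomination[match(colony_ids, meta$id)],
                      colony_ids)
    comp <- composition_chisq(clusters, denom,
                              n_sim = gp$n_sim %||% 2000L, seed = seed)
    paths$geo <- file.path(out_dir, "geo.json")
    jsonlite::write_json(list(
      kept = filt$kept, excluded = filt$excluded,
      unevaluable = filt$unevaluable,
      chisq_statistic = comp$statistic, chisq_p = comp$p_value),
      paths$geo, auto_unbox = TRUE, digits = NA)
    manifest$parameters$geo <- list(filter_threshold =
                                      gp$filter_threshold %||% 0.5)
  }

  files <- unlist(paths)
  files <- files[file.exists(files)]
  manifest$files <- as.list(setNames(unname(tools::md5sum(files)),
                                     names(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
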