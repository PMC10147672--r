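## Shared simulation fixtures, memoised so expensive datasets are built once
## per test session.

.sim_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = .sim_cache))
    assign(key, build(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

## the four study demes with a configurable founder count
study_demes <- function(n_founders = 40L) {
  list(
    deme_spec("Avalon", n_founders = n_founders, p_source1 = 0.9,
              centroid = c(47.2, -53.2), majority_denomination = "Catholic"),
    deme_spec("Burin", n_founders = n_founders, p_source1 = 0.7,
              centroid = c(47.0, -55.1), majority_denomination = "Catholic"),
    deme_spec("Trinity", n_founders = n_founders, p_source1 = 0.3,
              centroid = c(48.0, -53.4),
              majority_denomination = "Protestant"),
    deme_spec("NotreDame", n_founders = n_founders, p_source1 = 0.1,
              centroid = c(49.3, -55.0),
              majority_denomination = "Protestant")
  )
}

## full default-config dataset (genotypes included)
default_sim <- function(seed = 1L) {
  cache_get(paste0("full_", seed), function()
    simulate_founder_colony(sim_config(seed = seed)))
}

## pedigree summaries + reduced IBD products (pair totals and the 3-15 cM
## band) — the full segment table of a default colony runs to ~1e6 rows, so
## cached sweep fixtures keep only what the analyses consume
ped_ibd <- function(seed = 1L, migration = 0.01, n_founders = 40L) {
  cache_get(sprintf("pi_%d_%g_%d", seed, migration, n_founders), function() {
    cfg <- sim_config(seed = seed,
                      colony = colony_spec(demes = study_demes(n_founders),
                                           migration_rate = migration))
    ped <- simulate_pedigree(cfg)
    ibd <- extract_true_ibd(ped)
    out <- list(cfg = cfg, samples = ped$samples, pedigree = ped$pedigree,
                true_ancestry = ped$true_ancestry,
                totals = pair_totals(ibd, band = c(1, Inf)),
                segs_band = filter_band(ibd, 3, 15))
    rm(ibd, ped)
    gc(verbose = FALSE)
    out
  })
}

## fixed seed set for the founder-count sweep: seeds under which colonies of
## 5, 10 and 20 founders per deme all survive to the present (tiny demes go
## extinct under many seeds; extinction is a hard error by design)
FOUNDER_SWEEP_SEEDS <- c(2L, 15L, 25L)

## small two-deme configuration for fast end-to-end checks
small_config <- function(seed = 1L, target_size = 40L, n_sites = 150L,
                         migration = 0.05) {
  sim_config(
    seed = seed, n_sites_per_chrom = n_sites,
    sources = list(source_pop_spec("S1", pop_size = 40L,
                                   n_generations = 8L, n_reference = 10L),
                   source_pop_spec("S2", pop_size = 40L,
                                   n_generations = 8L, n_reference = 10L)),
    colony = colony_spec(
      demes = list(deme_spec("East", n_founders = 10L, p_source1 = 0.9,
                             centroid = c(47.2, -53.2),
                             majority_denomination = "Catholic"),
                   deme_spec("West", n_founders = 10L, p_source1 = 0.1,
                             centroid = c(49.3, -55.0),
                             majority_denomination = "Protestant")),
      founding_generation = 5L, migration_rate = migration,
      target_size = target_size),
    n_outgroup = 10L)
}

small_sim <- function(seed = 1L) {
  cache_get(paste0("small_", seed), function()
    simulate_founder_colony(small_config(seed = seed)))
}

group_of <- function(sim) setNames(sim$samples$group, sim$samples$id)

group_of_samples <- function(x) setNames(x$samples$group, x$samples$id)

## hierarchical clustering of the default-config sharing graph, memoised
hc_default <- function(seed = 1L) {
  cache_get(paste0("hc_", seed), function() {
    pi <- ped_ibd(seed)
    g <- build_graph(pi$totals, nodes = pi$samples$id)
    hierarchical_cluster(g, seed = seed)
  })
}

colony_ids <- function(sim) sim$samples$id[sim$samples$role == "colony"]

reference_ids <- function(sim) sim$samples$id[sim$samples$role == "reference"]
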