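#' Simulate the founder-colony pedigree and haplotype mosaics
#'
#' Two source populations evolve as discrete-generation random-mating finite
#' pedigrees. At the colony founding generation, each deme's founders are
#' sampled as offspring of source-population parents according to the deme's
#' `p_source1`; thereafter demes mate monogamously within deme (selfing
#' impossible, sib mating permitted) except that with probability
#' `migration_rate` an individual joins another deme's mating pool for that
#' generation. Offspring counts are Poisson with mean `2 * growth_rate` per
#' couple. Grandparental birthplaces are the grandparent's natal deme centroid
#' plus Gaussian jitter; denomination follows the deme majority with
#' probability `denomination_fidelity`.
#'
#' @param config a [sim_config()].
#' @return A list of class `founder_pedigree` with elements `config`,
#'   `lengths`, `mosaics` (named list of `list(h1, h2)` for every present-day
#'   individual: colony plus reference panels), `samples` (present-day
#'   metadata), `pedigree` (all simulated individuals with parent pointers and
#'   true S1 ancestry), `fid_source` (founder-haplotype id to source label)
#'   and `true_ancestry` (named vector over present-day individuals).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 23L))
  L <- config$chrom_length_cM
  genome_cM <- sum(L)
  s1 <- config$sources[[1]]
  s2 <- config$sources[[2]]
  col <- config$colony
  fg <- col$founding_generation

  fid_source <- character(0)
  ped <- list()   # per-generation data.frames, bound at the end

  stash <- list()      # source generation feeding the colony founders
  final_src <- list()  # present-day source generations
  next_fid <- 1L

  for (s in list(s1, s2)) {
    gF <- s$n_generations - fg
    ids <- sprintf("%s.G%02d.I%03d", s$name, 0L, seq_len(s$pop_size))
    pop <- vector("list", s$pop_size)
    for (i in seq_len(s$pop_size)) {
      pop[[i]] <- list(h1 = founder_mosaic(L, next_fid),
                       h2 = founder_mosaic(L, next_fid + 1L))
      next_fid <- next_fid + 2L
    }
    fid_source <- c(fid_source, rep(s$name, 2L * s$pop_size))
    ped[[length(ped) + 1L]] <- data.frame(
      id = ids, father = NA_character_, mother = NA_character_,
      group = s$name, tbp = s$n_generations, stringsAsFactors = FALSE)
    if (gF == 0L) stash[[s$name]] <- list(ids = ids, pop = pop)
    for (g in seq_len(s$n_generations)) {
      new_ids <- sprintf("%s.G%02d.I%03d", s$name, g, seq_len(s$pop_size))
      new_pop <- vector("list", s$pop_size)
      fa <- mo <- character(s$pop_size)
      for (i in seq_len(s$pop_size)) {
        pr <- sample.int(s$pop_size, 2L)
        new_pop[[i]] <- list(h1 = meiosis(pop[[pr[1]]], L),
                             h2 = meiosis(pop[[pr[2]]], L))
        fa[i] <- ids[pr[1]]
        mo[i] <- ids[pr[2]]
      }
      ped[[length(ped) + 1L]] <- data.frame(
        id = new_ids, father = fa, mother = mo, group = s$name,
        tbp = s$n_generations - g, stringsAsFactors = FALSE)
      pop <- new_pop
      ids <- new_ids
      if (g == gF) stash[[s$name]] <- list(ids = ids, pop = pop)
    }
    final_src[[s$name]] <- list(ids = ids, pop = pop)
  }

  s1_fids <- which(fid_source == s1$name)
  anc_s1 <- function(ind)
    mosaic_cm_in(ind$h1, ind$h2, s1_fids) / (2 * genome_cM)

  ## --- colony founding ---------------------------------------------------
  demes <- col$demes
  ids <- character(0)
  deme_of <- character(0)
  pop <- list()
  anc <- numeric(0)
  fa <- mo <- character(0)
  for (d in demes) {
    for (i in seq_len(d$n_founders)) {
      src <- if (runif(1) < d$p_source1) s1$name else s2$name
      st <- stash[[src]]
      pr <- sample.int(length(st$ids), 2L)
      ind <- list(h1 = meiosis(st$pop[[pr[1]]], L),
                  h2 = meiosis(st$pop[[pr[2]]], L))
      pop[[length(pop) + 1L]] <- ind
      ids <- c(ids, sprintf("NL.%s.G%02d.I%04d", d$name, 0L, i))
      deme_of <- c(deme_of, d$name)
      fa <- c(fa, st$ids[pr[1]])
      mo <- c(mo, st$ids[pr[2]])
      anc <- c(anc, anc_s1(ind))
    }
  }
  ped[[length(ped) + 1L]] <- data.frame(
    id = ids, father = fa, mother = mo, group = deme_of, tbp = fg,
    ancestry_s1 = anc, stringsAsFactors = FALSE)

  deme_names <- vapply(demes, `[[`, character(1), "name")

  ## --- colony generations ------------------------------------------------
  for (g in seq_len(fg)) {
    n <- length(ids)
    pool <- deme_of
    if (length(deme_names) > 1L && col$migration_rate > 0) {
      mig <- runif(n) < col$migration_rate
      for (i in which(mig))
        pool[i] <- sample(setdiff(deme_names, deme_of[i]), 1L)
    }
    new_ids <- character(0)
    new_deme <- character(0)
    new_pop <- list()
    new_fa <- new_mo <- character(0)
    new_anc <- numeric(0)
    for (dn in deme_names) {
      members <- which(pool == dn)
      if (length(members) < 2L)
        stop(sprintf("deme %s extinct at colony generation %d: no mating pair",
                     dn, g))
      members <- members[sample.int(length(members))]
      n_pair <- length(members) %/% 2L
      kid <- 0L
      for (p in seq_len(n_pair)) {
        a <- members[2L * p - 1L]
        b <- members[2L * p]
        n_off <- rpois(1L, 2 * col$growth_rate)
        if (n_off == 0L) next
        for (o in seq_len(n_off)) {
          kid <- kid + 1L
          ind <- list(h1 = meiosis(pop[[a]], L), h2 = meiosis(pop[[b]], L))
          new_pop[[length(new_pop) + 1L]] <- ind
          new_ids <- c(new_ids,
                       sprintf("NL.%s.G%02d.I%04d", dn, g, kid))
          new_deme <- c(new_deme, dn)
          new_fa <- c(new_fa, ids[a])
          new_mo <- c(new_mo, ids[b])
          new_anc <- c(new_anc, anc_s1(ind))
        }
      }
    }
    if (!length(new_ids))
      stop(sprintf("colony produced no offspring at generation %d", g))
    ped[[length(ped) + 1L]] <- data.frame(
      id = new_ids, father = new_fa, mother = new_mo, group = new_deme,
      tbp = fg - g, ancestry_s1 = new_anc, stringsAsFactors = FALSE)
    ids <- new_ids
    deme_of <- new_deme
    pop <- new_pop
  }

  ## --- present-day sample set --------------------------------------------
  mosaics <- setNames(pop, ids)
  samples <- data.frame(id = ids, group = deme_of, role = "colony",
                        stringsAsFactors = FALSE)
  for (s in list(s1, s2)) {
    fin <- final_src[[s$name]]
    take <- sort(sample.int(length(fin$ids), s$n_reference))
    mosaics <- c(mosaics, setNames(fin$pop[take], fin$ids[take]))
    samples <- rbind(samples, data.frame(
      id = fin$ids[take], group = s$name, role = "reference",
      stringsAsFactors = FALSE))
  }

  ped <- lapply(ped, function(p) {
    if (is.null(p$ancestry_s1)) p$ancestry_s1 <- NA_real_
    p
  })
  pedigree <- do.call(rbind, ped)
  rownames(pedigree) <- NULL

  true_ancestry <- vapply(mosaics, anc_s1, numeric(1))

  ## --- denomination and grandparental birthplaces ------------------------
  centroid <- lapply(demes, `[[`, "centroid")
  names(centroid) <- deme_names
  jitter_sd <- setNames(vapply(demes, `[[`, numeric(1), "jitter_sd"),
                        deme_names)
  majority <- setNames(vapply(demes, `[[`, character(1),
                              "majority_denomination"), deme_names)
  denoms <- unique(unname(majority))
  parent_of <- setNames(pedigree$father, pedigree$id)
  mother_of <- setNames(pedigree$mother, pedigree$id)
  group_of <- setNames(pedigree$group, pedigree$id)

  gp_cols <- matrix(NA_real_, nrow(samples), 8L)
  denomination <- rep(NA_character_, nrow(samples))
  is_col <- samples$role == "colony"
  for (i in which(is_col)) {
    id <- samples$id[i]
    dn <- samples$group[i]
    maj <- majority[[dn]]
    denomination[i] <- if (length(denoms) == 1L ||
                           runif(1) < col$denomination_fidelity) maj
                       else sample(setdiff(denoms, maj), 1L)
    pa <- parent_of[[id]]
    ma <- mother_of[[id]]
    gps <- c(parent_of[[pa]], mother_of[[pa]],
             parent_of[[ma]], mother_of[[ma]])
    for (k in seq_len(4L)) {
      gdeme <- if (!is.na(gps[k]) && group_of[[gps[k]]] %in% deme_names)
        group_of[[gps[k]]] else dn
      ctr <- centroid[[gdeme]]
      gp_cols[i, 2L * k - 1L] <- ctr[1] + rnorm(1L, 0, jitter_sd[[gdeme]])
      gp_cols[i, 2L * k] <- ctr[2] + rnorm(1L, 0, jitter_sd[[gdeme]])
    }
  }
  colnames(gp_cols) <- as.vector(t(outer(paste0("gp", 1:4), c("lat", "lon"),
                                         paste, sep = "_")))
  samples <- cbind(samples, denomination = denomination,
                   as.data.frame(gp_cols))

  structure(list(config = config, lengths = L, mosaics = mosaics,
                 samples = samples, pedigree = pedigree,
                 fid_source = fid_source, true_ancestry = true_ancestry),
            class = "founder_pedigree")
}

#' @export
print.founder_pedigree <- function(x, ...) {
  cat(sprintf("founder pedigree: %d present-day individuals (%d colony, %d reference)\n",
              nrow(x$samples), sum(x$samples$role == "colony"),
              sum(x$samples$role == "reference")))
  invisible(x)
}
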