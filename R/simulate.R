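#' Simulation configuration for multi-species PPR/RFL fixtures
#'
#' Describes a synthetic study: a set of species each carrying one-per-species
#' orthologous PPR families, plus one restorer-of-fertility-like (RFL)
#' family shared by most species, recently and repeatedly duplicated in the
#' focal species as tandem arrays at planted genomic coordinates.  Every
#' downstream stage (motif scan, classification, RFL screen, orthologous
#' clustering, phylogeny, hotspot mapping) can be validated against the
#' ground truth this generator emits.
#'
#' Divergence parameters are i.i.d. per-residue substitution probabilities
#' (no indels unless `indel_rate > 0`), applied along the simulated descent:
#' family ancestors diverge from the bundled motif templates at
#' `family_divergence`; species orthologs diverge from their family ancestor
#' at `species_divergence`; the RFL family carries one internal lineage per
#' planted array (`rfl_lineage_divergence` from the RFL ancestor), with
#' focal-species array members at `array_divergence` from their lineage and
#' other species' members at `rfl_species_divergence`.
#'
#' @param seed Integer RNG seed; fixed seed gives identical output.
#' @param n_species Number of species (default 14).
#' @param focal_species Species tag carrying the planted arrays (default
#'   the first species).
#' @param n_background_families One-per-species ortholog families
#'   (default 10).  Families span varying subsets of species so the
#'   cluster-size trend has spread.
#' @param family_divergence Divergence of each family ancestor from the
#'   motif templates (default 0.6; set 0 for scan/classify fixtures whose
#'   motifs must match the bundled profiles).
#' @param species_divergence Within-family, between-species divergence
#'   (default 0.05).
#' @param rfl_species Species carrying RFL genes (default all but the last
#'   species, which stands in for a lineage that lost the family).
#' @param rfl_lineage_divergence,rfl_species_divergence,array_divergence
#'   RFL internal divergences (defaults 0.15, 0.12, 0.03).
#' @param arrays List of planted focal-species arrays, each a list with
#'   `chrom`, `start` (bp), `n_genes`, `gap` (inter-gene gap, bp).  The
#'   defaults plant three arrays of 7, 8 and 5 genes.
#' @param n_rfl_per_lineage_other RFL genes per lineage in each non-focal
#'   RFL species (default 1).
#' @param n_rfl_motifs,n_background_motifs P-motif counts for RFL and
#'   background P-class proteins (defaults 16 and `8:12`).
#' @param noise_rate Extra per-residue observational noise applied to every
#'   emitted protein (default 0).
#' @param indel_rate Per-residue indel probability (default 0; off).
#' @param linker_range Inter-motif linker length range in residues
#'   (default 5-20).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_species = 14,
                       focal_species = NULL,
                       n_background_families = 10,
                       family_divergence = 0.6,
                       species_divergence = 0.05,
                       rfl_species = NULL,
                       rfl_lineage_divergence = 0.15,
                       rfl_species_divergence = 0.12,
                       array_divergence = 0.03,
                       arrays = NULL,
                       n_rfl_per_lineage_other = 1,
                       n_rfl_motifs = 16,
                       n_background_motifs = 8:12,
                       noise_rate = 0,
                       indel_rate = 0,
                       linker_range = c(5, 20)) {
  if (noise_rate < 0 || noise_rate >= 1) {
    abort("noise_rate must be in [0, 1)")
  }
  species <- sprintf("sp%02d", seq_len(n_species))
  focal_species <- focal_species %||% species[1]
  rfl_species <- rfl_species %||% head(species, -1)
  if (!(focal_species %in% rfl_species)) {
    abort("focal_species must be among rfl_species")
  }
  arrays <- arrays %||% list(
    list(chrom = "Ch2", start = 18800000L, n_genes = 7L, gap = 30000L),
    list(chrom = "Ch5", start = 5100000L, n_genes = 8L, gap = 30000L),
    list(chrom = "Ch7", start = 370000L, n_genes = 5L, gap = 30000L)
  )
  structure(
    list(
      seed = seed, n_species = n_species, species = species,
      focal_species = focal_species,
      n_background_families = n_background_families,
      family_divergence = family_divergence,
      species_divergence = species_divergence,
      rfl_species = rfl_species,
      rfl_lineage_divergence = rfl_lineage_divergence,
      rfl_species_divergence = rfl_species_divergence,
      array_divergence = array_divergence,
      arrays = arrays,
      n_rfl_per_lineage_other = n_rfl_per_lineage_other,
      n_rfl_motifs = n_rfl_motifs,
      n_background_motifs = n_background_motifs,
      noise_rate = noise_rate,
      indel_rate = indel_rate,
      linker_range = linker_range
    ),
    class = "sim_config"
  )
}

#' Simulate one protein from a motif architecture
#'
#' Concatenates motif templates in the given order, with an `M` start
#' residue and random inter-motif linkers, then applies per-residue
#' substitution noise (the initial Met is kept so the protein is not
#' flagged as a pseudogene).  The planted motif coordinates are attached as
#' attribute `planted`.
#'
#' @param architecture Character vector of motif names, e.g.
#'   `c("P", "L", "S", "E")`.
#' @param templates Named motif template vector (default
#'   [motif_templates()]).
#' @param noise_rate Per-residue substitution probability.
#' @param id,species Record identifiers.
#' @param linker_range Linker length range (default 5-20 residues).
#' @param indel_rate Per-residue indel probability (default 0).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A one-row record tibble with attribute `planted` (tibble
#'   `profile`, `start`, `end`).
#' @export
simulate_protein <- function(architecture, templates = motif_templates(),
                             noise_rate = 0, id = "sim1", species = "simsp",
                             linker_range = c(5, 20), indel_rate = 0,
                             seed = NULL) {
  if (length(architecture) == 0) {
    abort("architecture must list at least one motif")
  }
  unknown <- setdiff(architecture, names(templates))
  if (length(unknown) > 0) {
    abort(paste0("unknown motif name(s): ", paste(unknown, collapse = ", ")))
  }
  run <- function() {
    parts <- "M"
    planted <- list()
    pos <- 1L
    for (motif in architecture) {
      linker <- random_linker(linker_range)
      pos <- pos + nchar(linker)
      tmpl <- templates[[motif]]
      planted[[length(planted) + 1]] <- tibble(
        profile = motif, start = pos + 1L, end = pos + nchar(tmpl)
      )
      pos <- pos + nchar(tmpl)
      parts <- c(parts, linker, tmpl)
    }
    parts <- c(parts, random_linker(linker_range))
    seq <- paste(parts, collapse = "")
    seq <- paste0("M", apply_noise(substr(seq, 2, nchar(seq)), noise_rate))
    if (indel_rate > 0) {
      seq <- paste0("M", apply_indels(substr(seq, 2, nchar(seq)), indel_rate))
    }
    rec <- tibble(
      id = id, species = species, seq = seq, locus_id = NA_character_
    )
    attr(rec, "planted") <- bind_rows(planted)
    rec
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

random_linker <- function(linker_range) {
  len <- sample(linker_range[1]:linker_range[2], 1)
  paste(sample(AA_CANONICAL, len, replace = TRUE), collapse = "")
}

apply_noise <- function(seq, rate) {
  mutate_residues(seq, rate)
}

apply_indels <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (ch in chars) {
    u <- stats::runif(1)
    if (u < rate / 2) {
      next # deletion
    } else if (u < rate) {
      out <- c(out, ch, sample(AA_CANONICAL, 1)) # insertion
    } else {
      out <- c(out, ch)
    }
  }
  paste(out, collapse = "")
}

#' Simulate a multi-species protein set with planted RFL arrays
#'
#' See [sim_config()] for the generative model.  Ground truth covers every
#' downstream stage: per-protein subclass and RFL status, per-family
#' ortholog assignment, and the planted hotspot regions.
#'
#' @param config A [sim_config()].
#' @return A list with elements `records` (all proteins, `locus_id` set),
#'   `loci` (gene coordinate tibble), `references` (three synthetic
#'   restorer reference records drawn from distinct non-focal RFL
#'   lineages), and `truth` (list: `proteins` tibble with `id`, `species`,
#'   `subclass`, `is_rfl`, `family`; `hotspots` tibble; `config` echo).
#' @export
simulate_multispecies <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  check_arrays(config)
  with_seed(config$seed, simulate_multispecies_impl(config))
}

check_arrays <- function(config) {
  spans <- map(config$arrays, function(a) {
    # generous per-gene footprint bound for the overlap check
    len <- a$n_genes * 5000 + (a$n_genes - 1) * a$gap
    tibble(chrom = a$chrom, start = a$start, end = a$start + len)
  })
  spans <- bind_rows(spans)
  for (ch in unique(spans$chrom)) {
    s <- arrange(spans[spans$chrom == ch, ], .data$start)
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      abort(paste0("planted arrays overlap on chromosome ", ch))
    }
  }
  invisible(TRUE)
}

simulate_multispecies_impl <- function(config) {
  templates <- motif_templates()
  records <- list()
  truth <- list()
  subclass_probs <- c(
    P = 0.50, PLS_plain = 0.12, E = 0.18, Eplus = 0.08, DYW = 0.12
  )
  add_record <- function(id, species, seq, family, subclass, is_rfl) {
    records[[length(records) + 1]] <<- tibble(
      id = id, species = species, seq = seq, locus_id = id
    )
    truth[[length(truth) + 1]] <<- tibble(
      id = id, species = species, subclass = subclass,
      is_rfl = is_rfl, family = family
    )
  }

  # ---- background one-per-species ortholog families -----------------------
  n_sp <- config$n_species
  counts <- rep(seq(max(3, n_sp - 8), n_sp), length.out = config$n_background_families)
  for (f in seq_len(config$n_background_families)) {
    subclass <- sample(names(subclass_probs), 1, prob = subclass_probs)
    arch <- architecture_for(subclass, config)
    anc <- ancestor_sequence(arch, templates, config$family_divergence, config)
    members <- sort(c(
      config$focal_species,
      sample(setdiff(config$species, config$focal_species), counts[f] - 1)
    ))
    for (sp in members) {
      id <- sprintf("%s|bg%02d", sp, f)
      seq <- descend(anc, config$species_divergence, config$noise_rate,
        indel_rate = config$indel_rate
      )
      add_record(id, sp, seq, sprintf("fam_bg%02d", f), subclass, FALSE)
    }
  }

  # ---- the RFL family -----------------------------------------------------
  arch_rfl <- rep("P", config$n_rfl_motifs)
  rfl_anc <- ancestor_sequence(arch_rfl, templates, config$family_divergence, config)
  n_lineages <- length(config$arrays)
  lineage_anc <- map(seq_len(n_lineages), function(l) {
    mutate_protein(rfl_anc, config$rfl_lineage_divergence)
  })
  other_rfl_species <- setdiff(config$rfl_species, config$focal_species)
  for (l in seq_len(n_lineages)) {
    for (sp in other_rfl_species) {
      for (m in seq_len(config$n_rfl_per_lineage_other)) {
        id <- sprintf("%s|rfl_l%d_%d", sp, l, m)
        seq <- descend(lineage_anc[[l]], config$rfl_species_divergence,
          config$noise_rate,
          indel_rate = config$indel_rate
        )
        add_record(id, sp, seq, "fam_rfl", "P", TRUE)
      }
    }
  }
  # focal-species tandem arrays, one per lineage
  array_gene_ids <- vector("list", n_lineages)
  for (l in seq_len(n_lineages)) {
    a <- config$arrays[[l]]
    ids <- sprintf("%s|rfl_a%d_%d", config$focal_species, l, seq_len(a$n_genes))
    array_gene_ids[[l]] <- ids
    for (g in seq_len(a$n_genes)) {
      seq <- descend(lineage_anc[[l]], config$array_divergence,
        config$noise_rate,
        indel_rate = config$indel_rate
      )
      add_record(ids[g], config$focal_species, seq, "fam_rfl", "P", TRUE)
    }
  }

  records <- bind_rows(records)
  truth_proteins <- bind_rows(truth)

  # ---- references: known restorers from non-focal lineages ----------------
  ref_lineages <- rep(seq_len(n_lineages), length.out = 3)
  references <- bind_rows(map(1:3, function(r) {
    tibble(
      id = sprintf("refsp%d|restorer%d", r, r),
      species = sprintf("refsp%d", r),
      seq = mutate_protein(lineage_anc[[ref_lineages[r]]], 0.08),
      locus_id = NA_character_
    )
  }))

  # ---- gene loci ----------------------------------------------------------
  loci <- place_loci(records, config, array_gene_ids)

  hotspots <- bind_rows(map(seq_len(n_lineages), function(l) {
    ids <- array_gene_ids[[l]]
    g <- loci[loci$gene_id %in% ids, ]
    tibble(
      species = config$focal_species,
      chrom = config$arrays[[l]]$chrom,
      start = min(g$start), end = max(g$end),
      gene_count = length(ids)
    )
  }))

  list(
    records = records,
    loci = loci,
    references = references,
    truth = list(
      proteins = truth_proteins,
      hotspots = hotspots,
      config = config
    )
  )
}

architecture_for <- function(subclass, config) {
  if (subclass == "P") {
    n <- if (length(config$n_background_motifs) > 1) {
      sample(config$n_background_motifs, 1)
    } else {
      config$n_background_motifs
    }
    return(rep("P", n))
  }
  k <- sample(2:4, 1)
  triplets <- rep(c("P", "L", "S"), k)
  switch(subclass,
    PLS_plain = triplets,
    E = c(triplets, "E"),
    Eplus = c(triplets, "E", "Eplus"),
    DYW = c(triplets, "E", "DYW")
  )
}

# Family ancestor: motif instances and linkers drawn once, each motif
# instance independently diverged from its template.
ancestor_sequence <- function(architecture, templates, divergence, config) {
  parts <- "M"
  for (motif in architecture) {
    parts <- c(
      parts,
      random_linker(config$linker_range),
      mutate_residues(templates[[motif]], divergence)
    )
  }
  parts <- c(parts, random_linker(config$linker_range))
  paste(parts, collapse = "")
}

mutate_protein <- function(seq, divergence) {
  paste0("M", mutate_residues(substr(seq, 2, nchar(seq)), divergence))
}

descend <- function(anc, divergence, noise_rate, indel_rate = 0) {
  seq <- mutate_protein(anc, divergence)
  if (noise_rate > 0) {
    seq <- paste0("M", apply_noise(substr(seq, 2, nchar(seq)), noise_rate))
  }
  if (indel_rate > 0) {
    seq <- paste0("M", apply_indels(substr(seq, 2, nchar(seq)), indel_rate))
  }
  seq
}

# Background genes at regular spacing per species chromosome; array genes
# tandem at the planted coordinates.
place_loci <- function(records, config, array_gene_ids) {
  array_ids <- unlist(array_gene_ids)
  loci <- list()
  spacing <- 150000L
  chroms <- sprintf("Ch%d", 1:7)
  for (sp in unique(records$species)) {
    ids <- records$id[records$species == sp & !(records$id %in% array_ids)]
    for (k in seq_along(ids)) {
      rec_len <- nchar(records$seq[records$id == ids[k]])
      chrom <- chroms[(k - 1) %% length(chroms) + 1]
      start <- 1000000L + ((k - 1) %/% length(chroms)) * spacing
      loci[[length(loci) + 1]] <- tibble(
        gene_id = ids[k], chrom = chrom,
        start = start, end = start + 3L * (rec_len + 1L) - 1L,
        strand = "+"
      )
    }
  }
  for (l in seq_along(array_gene_ids)) {
    a <- config$arrays[[l]]
    ids <- array_gene_ids[[l]]
    pos <- a$start
    for (g in seq_along(ids)) {
      rec_len <- nchar(records$seq[records$id == ids[g]])
      gene_len <- 3L * (rec_len + 1L)
      loci[[length(loci) + 1]] <- tibble(
        gene_id = ids[g], chrom = a$chrom,
        start = as.integer(pos), end = as.integer(pos + gene_len - 1L),
        strand = "+"
      )
      pos <- pos + gene_len + a$gap
    }
  }
  arrange(bind_rows(loci), .data$gene_id)
}

#' Score pipeline outputs against simulator ground truth
#'
#' @param outputs Named list with any of: `classified` (from
#'   [classify_all()]), `rfl_calls` (from [consensus_rfl()]), `clusters`
#'   (from [mcl_cluster()]), `regions` (from [hotspot_regions()]).
#' @param truth The `truth` element returned by [simulate_multispecies()].
#' @return A tibble `metric`, `value` with, depending on the supplied
#'   outputs: `subclass_accuracy`, `rfl_precision`, `rfl_recall`,
#'   `rfl_fpr`, `ortho_ari`, `hotspot_recall`.
#' @export
evaluate_against_truth <- function(outputs, truth) {
  metrics <- list()
  tp <- truth$proteins
  if (!is.null(outputs$classified)) {
    cl <- outputs$classified
    unknown <- setdiff(cl$protein_id, tp$id)
    if (length(unknown) > 0) {
      abort(paste0(
        "classified ids not in truth: ", paste(head(unknown, 3), collapse = ", ")
      ))
    }
    joined <- left_join(cl, tp, by = c(protein_id = "id"))
    metrics$subclass_accuracy <- mean(joined$subclass.x == joined$subclass.y)
  }
  if (!is.null(outputs$rfl_calls)) {
    calls <- outputs$rfl_calls
    unknown <- setdiff(calls$protein_id, tp$id)
    if (length(unknown) > 0) {
      abort(paste0(
        "rfl_calls ids not in truth: ", paste(head(unknown, 3), collapse = ", ")
      ))
    }
    joined <- left_join(calls, tp, by = c(protein_id = "id"))
    pred <- joined$candidate
    pos <- joined$is_rfl
    metrics$rfl_precision <- if (any(pred)) mean(pos[pred]) else NA_real_
    metrics$rfl_recall <- if (any(pos)) mean(pred[pos]) else NA_real_
    metrics$rfl_fpr <- if (any(!pos)) mean(pred[!pos]) else NA_real_
  }
  if (!is.null(outputs$clusters)) {
    cl <- outputs$clusters
    joined <- dplyr::inner_join(cl, tp, by = c(protein_id = "id"))
    if (nrow(joined) == 0) {
      abort("clusters share no ids with truth")
    }
    metrics$ortho_ari <- mclust::adjustedRandIndex(
      joined$cluster_id, joined$family
    )
  }
  if (!is.null(outputs$regions)) {
    th <- truth$hotspots
    recovered <- map_lgl(seq_len(nrow(th)), function(i) {
      r <- outputs$regions
      any(
        r$species == th$species[i] & r$chrom == th$chrom[i] &
          r$start <= th$end[i] & r$end >= th$start[i]
      )
    })
    metrics$hotspot_recall <- if (nrow(th) > 0) mean(recovered) else NA_real_
  }
  tibble(
    metric = names(metrics),
    value = as.numeric(unlist(metrics))
  )
}
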