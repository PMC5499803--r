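test_that("simulated proteins contain their planted motifs verbatim", {
  tmpl <- motif_templates()
  rec <- simulate_protein(c("P", "P", "P"), noise_rate = 0, seed = 1)
  expect_equal(
    lengths(regmatches(rec$seq, gregexpr(tmpl[["P"]], rec$seq, fixed = TRUE))),
    3L
  )
  planted <- attr(rec, "planted")
  expect_equal(nrow(planted), 3)
  for (i in 1:3) {
    expect_equal(
      substr(rec$seq, planted$start[i], planted$end[i]),
      tmpl[["P"]]
    )
  }
  expect_equal(substr(rec$seq, 1, 1), "M")

  # same seed, same sequence
  rec2 <- simulate_protein(c("P", "P", "P"), noise_rate = 0, seed = 1)
  expect_identical(rec$seq, rec2$seq)

  expect_error(simulate_protein(c("P", "Q7")), "unknown motif")
  expect_error(simulate_protein(character(0)), "at least one")
})

test_that("substitution noise hits at the configured rate", {
  set.seed(73)
  rate <- 0.05
  n_sub <- 0
  n_tot <- 0
  tmpl <- motif_templates()
  for (i in 1:100) {
    clean <- simulate_protein(rep("P", 10), noise_rate = 0, seed = 1000 + i)
    noisy <- simulate_protein(rep("P", 10), noise_rate = rate, seed = 1000 + i)
    # identical linker draws under the same seed make the pair comparable
    a <- strsplit(clean$seq, "")[[1]]
    b <- strsplit(noisy$seq, "")[[1]]
    expect_equal(length(a), length(b))
    n_sub <- n_sub + sum(a != b)
    n_tot <- n_tot + length(a)
  }
  expect_lt(abs(n_sub / n_tot - rate), 0.01)
})

test_that("multispecies simulation is deterministic and truth-consistent", {
  cfg <- sim_config(seed = 79, n_species = 4, n_background_families = 4)
  sim1 <- simulate_multispecies(cfg)
  sim2 <- simulate_multispecies(cfg)
  expect_identical(sim1$records, sim2$records)
  expect_identical(sim1$loci, sim2$loci)

  # emitted FASTA/GFF3 re-read through the formats module reproduce truth
  dir <- withr::local_tempdir()
  fasta <- file.path(dir, "all.fasta")
  write_fasta(sim1$records, fasta)
  expect_equal(read_fasta(fasta)$seq, sim1$records$seq)
  gff <- file.path(dir, "loci.gff3")
  write_gff_loci(sim1$loci, gff)
  back <- read_gff_loci(gff)
  expect_equal(
    back[order(back$gene_id), c("gene_id", "chrom", "start", "end")],
    sim1$loci[
      order(sim1$loci$gene_id),
      c("gene_id", "chrom", "start", "end")
    ]
  )

  # planted hotspot truth covers the array genes exactly
  expect_equal(sort(sim1$truth$hotspots$gene_count), c(5L, 7L, 8L))
  for (i in seq_len(nrow(sim1$truth$hotspots))) {
    h <- sim1$truth$hotspots[i, ]
    members <- sim1$loci[
      sim1$loci$chrom == h$chrom & sim1$loci$start >= h$start &
        sim1$loci$end <= h$end,
    ]
    expect_equal(nrow(members), h$gene_count)
  }

  # background family sizes match the planted species spread
  fam_sizes <- table(sim1$truth$proteins$family)
  expect_true(all(fam_sizes[grepl("bg", names(fam_sizes))] <= cfg$n_species))

  # every record id is unique and species-tagged
  expect_equal(anyDuplicated(sim1$records$id), 0L)
})

test_that("degenerate configurations are rejected or handled", {
  overlapping <- sim_config(
    seed = 1,
    arrays = list(
      list(chrom = "Ch2", start = 100000L, n_genes = 5L, gap = 30000L),
      list(chrom = "Ch2", start = 120000L, n_genes = 5L, gap = 30000L)
    )
  )
  expect_error(simulate_multispecies(overlapping), "overlap")
  expect_error(sim_config(noise_rate = 1), "noise_rate")
})

test_that("truth evaluation scores identity outputs perfectly", {
  sim <- simulate_multispecies(sim_config(
    seed = 83, n_species = 4, n_background_families = 4
  ))
  tp <- sim$truth$proteins
  outputs <- list(
    classified = tibble::tibble(
      protein_id = tp$id, species = tp$species, subclass = tp$subclass,
      n_motifs = 0L, motif_string = "", pseudogene = FALSE
    ),
    rfl_calls = tibble::tibble(
      protein_id = tp$id, candidate = tp$is_rfl, n_lists = 4L
    ),
    clusters = tibble::tibble(
      cluster_id = tp$family, protein_id = tp$id, species = tp$species
    ),
    regions = dplyr::mutate(sim$truth$hotspots,
      clade_id = "c", span_kb = 0, .before = 1
    )
  )
  metrics <- evaluate_against_truth(outputs, sim$truth)
  vals <- setNames(metrics$value, metrics$metric)
  expect_equal(unname(vals["subclass_accuracy"]), 1)
  expect_equal(unname(vals["rfl_recall"]), 1)
  expect_equal(unname(vals["rfl_fpr"]), 0)
  expect_equal(unname(vals["ortho_ari"]), 1)
  expect_equal(unname(vals["hotspot_recall"]), 1)

  # empty predictions give zero recall
  none <- evaluate_against_truth(
    list(rfl_calls = tibble::tibble(
      protein_id = tp$id, candidate = FALSE, n_lists = 0L
    )),
    sim$truth
  )
  expect_equal(none$value[none$metric == "rfl_recall"], 0)

  # unknown ids are an error
  expect_error(
    evaluate_against_truth(
      list(classified = tibble::tibble(
        protein_id = "ghost", species = "x", subclass = "P"
      )),
      sim$truth
    ),
    "not in truth"
  )
})

test_that("cluster agreement equals the contingency-table formula", {
  truth <- list(proteins = tibble::tibble(
    id = paste0("g", 1:6), species = "sp",
    subclass = "P", is_rfl = FALSE,
    family = c("f1", "f1", "f1", "f2", "f2", "f3")
  ))
  pred <- tibble::tibble(
    cluster_id = c("a", "a", "b", "b", "c", "c"),
    protein_id = paste0("g", 1:6),
    species = "sp"
  )
  got <- evaluate_against_truth(list(clusters = pred), truth)
  want <- oracle_ari(pred$cluster_id, truth$proteins$family)
  expect_equal(got$value[got$metric == "ortho_ari"], want, tolerance = 1e-12)
})
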