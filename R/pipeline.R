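#' Default pipeline parameters
#'
#' Every tunable of every stage, with its documented default.  A config
#' file (flat `key: value` YAML) may override any of them; unknown keys are
#' rejected so typos fail loudly.
#'
#' @return Named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    # inputs
    fasta = NULL, # ';'-separated FASTA paths
    gff = NULL, # gene loci (GFF3)
    references_fasta = NULL, # known restorer proteins
    profile_dir = NULL, # optional externally built profiles
    focal_species = NULL, # species whose PPRs anchor the analysis
    outdir = "rflscout_out",
    seed = 1,
    # motif scan / classification
    threshold_frac = 0.35,
    min_motifs = 2,
    # RFL screen
    cluster_threshold = 0.6,
    min_cluster_size = 4,
    min_id = 50,
    min_cov = 50,
    required_lists = 3,
    # orthologous clustering
    min_neg_log_e = 5,
    kmer = 4,
    inflation = 1.5,
    prune = 1e-5,
    max_iter = 100,
    tol = 1e-6,
    # phylogeny / hotspots
    clade_min_size = 3,
    max_fraction_unplaced = 0,
    # simulator
    sim_n_species = 14,
    sim_n_background_families = 10,
    sim_family_divergence = 0.6,
    sim_noise_rate = 0
  )
}

#' Read a pipeline configuration file
#'
#' @param path Path to a flat YAML file of `key: value` pairs.
#' @return The defaults from [pipeline_defaults()] with the file's values
#'   merged in; unknown keys are an error.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path))
  }
  user <- yaml::read_yaml(path)
  merge_config(user %||% list())
}

merge_config <- function(user) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0(
      "unknown config key(s): ", paste(unknown, collapse = ", ")
    ))
  }
  defaults[names(user)] <- user
  defaults
}

#' Run a pipeline stage
#'
#' Orchestrates the stages over a shared output directory:
#' \describe{
#'   \item{simulate}{Emit a synthetic multi-species data set with truth.}
#'   \item{scan}{Motif-scan the input proteomes into motif tracks.}
#'   \item{classify}{Classify tracks into PPR subclasses.}
#'   \item{rfl}{Consensus RFL candidate screen of the P subfamily.}
#'   \item{ortho}{QC, similarity graph, MCL clustering, supercluster call.}
#'   \item{tree}{Neighbor-joining tree of the RFL supercluster.}
#'   \item{hotspots}{Species-specific clades and genomic hotspot regions.}
#'   \item{all}{scan, classify, rfl, then ortho, tree, hotspots.}
#' }
#' Every stage writes TSV reports plus a `manifest_<stage>.tsv` recording
#' all parameter values and input checksums; reruns with identical inputs
#' and config are byte-identical.
#'
#' @param stage One of the stage names above.
#' @param config A config list ([pipeline_defaults()] /
#'   [read_pipeline_config()]), or a path to a YAML config file.
#' @param ... Individual parameter overrides (highest precedence).
#' @return Invisibly, a named list of the files written.
#' @export
run_pipeline <- function(stage, config = pipeline_defaults(), ...) {
  stages <- c(
    "simulate", "scan", "classify", "rfl", "ortho", "tree", "hotspots", "all"
  )
  if (!(stage %in% stages)) {
    abort(paste0("unknown stage '", stage, "'"))
  }
  if (is.character(config)) {
    config <- read_pipeline_config(config)
  } else {
    config <- merge_config(config[!map_lgl(config, is.null)])
  }
  overrides <- list(...)
  if (length(overrides) > 0) {
    config <- merge_config(utils::modifyList(
      config[!map_lgl(config, is.null)], overrides
    ))
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    files <- c(
      stage_scan(config), stage_classify(config), stage_rfl(config),
      stage_ortho(config), stage_tree(config), stage_hotspots(config)
    )
    return(invisible(files))
  }
  files <- switch(stage,
    simulate = stage_simulate(config),
    scan = stage_scan(config),
    classify = stage_classify(config),
    rfl = stage_rfl(config),
    ortho = stage_ortho(config),
    tree = stage_tree(config),
    hotspots = stage_hotspots(config)
  )
  invisible(files)
}

out_path <- function(config, ...) {
  file.path(config$outdir, ...)
}

write_report <- function(df, path) {
  # '.' marks missing values in all TSV reports
  df <- mutate(df, across(dplyr::everything(), function(x) {
    ifelse(is.na(x), ".", as.character(x))
  }))
  readr::write_tsv(df, path)
  path
}

write_manifest <- function(config, stage, inputs) {
  params <- config[!map_lgl(config, is.null)]
  rows <- tibble(
    key = paste0("param:", names(params)),
    value = map_chr(params, function(v) paste(format(v), collapse = ";"))
  )
  inputs <- inputs[file.exists(inputs)]
  if (length(inputs) > 0) {
    rows <- bind_rows(rows, tibble(
      key = paste0("input:", basename(inputs)),
      value = unname(tools::md5sum(inputs))
    ))
  }
  path <- out_path(config, paste0("manifest_", stage, ".tsv"))
  readr::write_tsv(rows, path)
  path
}

load_input_records <- function(config) {
  if (is.null(config$fasta)) {
    abort("config key 'fasta' is required for this stage")
  }
  paths <- strsplit(config$fasta, ";", fixed = TRUE)[[1]]
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("input FASTA not found: ", paste(missing, collapse = ", ")))
  }
  bind_rows(map(paths, read_fasta))
}

stage_simulate <- function(config) {
  sim <- simulate_multispecies(sim_config(
    seed = config$seed,
    n_species = config$sim_n_species,
    n_background_families = config$sim_n_background_families,
    family_divergence = config$sim_family_divergence,
    noise_rate = config$sim_noise_rate
  ))
  dir <- out_path(config, "sim")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (sp in unique(sim$records$species)) {
    f <- file.path(dir, paste0(sp, ".fasta"))
    write_fasta(sim$records[sim$records$species == sp, ], f)
    files <- c(files, f)
  }
  ref_path <- file.path(dir, "references.fasta")
  write_fasta(sim$references, ref_path)
  gff_path <- file.path(dir, "loci.gff3")
  write_gff_loci(sim$loci, gff_path)
  tp <- file.path(dir, "truth_proteins.tsv")
  write_report(sim$truth$proteins, tp)
  th <- file.path(dir, "truth_hotspots.tsv")
  write_report(sim$truth$hotspots, th)
  manifest <- write_manifest(config, "simulate", character(0))
  invisible(c(files, ref_path, gff_path, tp, th, manifest))
}

get_profiles <- function(config) {
  if (!is.null(config$profile_dir)) {
    read_profiles(config$profile_dir)
  } else {
    default_profiles(threshold_frac = config$threshold_frac)
  }
}

stage_scan <- function(config) {
  records <- load_input_records(config)
  profiles <- get_profiles(config)
  hits <- scan_proteins(records, profiles)
  tracks <- assemble_tracks(hits)
  f1 <- write_report(hits, out_path(config, "hits.tsv"))
  f2 <- write_report(tracks, out_path(config, "tracks.tsv"))
  manifest <- write_manifest(
    config, "scan", strsplit(config$fasta, ";", fixed = TRUE)[[1]]
  )
  invisible(c(f1, f2, manifest))
}

read_tracks_file <- function(config) {
  path <- out_path(config, "tracks.tsv")
  if (!file.exists(path)) {
    abort("tracks.tsv not found; run the scan stage first")
  }
  readr::read_tsv(
    path,
    col_types = readr::cols(
      protein_id = "c", profile = "c", start = "i", end = "i", score = "d"
    ),
    na = "."
  )
}

stage_classify <- function(config) {
  records <- load_input_records(config)
  tracks <- read_tracks_file(config)
  classified <- classify_all(records, tracks, min_motifs = config$min_motifs)
  summary <- summarize_classes(classified)
  f1 <- write_report(classified, out_path(config, "classified.tsv"))
  f2 <- write_report(tidy(summary), out_path(config, "class_summary.tsv"))
  manifest <- write_manifest(
    config, "classify", strsplit(config$fasta, ";", fixed = TRUE)[[1]]
  )
  invisible(c(f1, f2, manifest))
}

stage_rfl <- function(config) {
  if (is.null(config$references_fasta)) {
    abort("config key 'references_fasta' is required for the rfl stage")
  }
  records <- load_input_records(config)
  classified_path <- out_path(config, "classified.tsv")
  if (!file.exists(classified_path)) {
    abort("classified.tsv not found; run the classify stage first")
  }
  classified <- readr::read_tsv(
    classified_path,
    col_types = readr::cols(.default = "c"), na = "."
  )
  p_ids <- classified$protein_id[classified$subclass == "P"]
  p_records <- records[records$id %in% p_ids, ]
  references <- read_fasta(config$references_fasta)
  files <- character(0)
  if (nrow(p_records) > 0) {
    ladder <- cluster_ladder(p_records)
    files <- c(files, write_report(ladder, out_path(config, "cluster_ladder.tsv")))
    calls <- consensus_rfl(
      p_records, references,
      cluster_threshold = config$cluster_threshold,
      min_cluster_size = config$min_cluster_size,
      min_id = config$min_id, min_cov = config$min_cov,
      required_lists = config$required_lists
    )
  } else {
    calls <- tibble(
      protein_id = character(), in_cluster_list = logical(),
      in_ref1 = logical(), in_ref2 = logical(), in_ref3 = logical(),
      n_lists = integer(), candidate = logical()
    )
  }
  files <- c(files, write_report(calls, out_path(config, "rfl_calls.tsv")))
  manifest <- write_manifest(config, "rfl", c(
    strsplit(config$fasta, ";", fixed = TRUE)[[1]], config$references_fasta
  ))
  invisible(c(files, manifest))
}

focal_ids <- function(config, records) {
  focal <- config$focal_species %||% records$species[1]
  records$id[records$species == focal]
}

stage_ortho <- function(config) {
  records <- load_input_records(config)
  qc <- qc_filter(records)
  graph <- similarity_graph(
    qc$retained,
    min_neg_log_e = config$min_neg_log_e, k = config$kmer
  )
  pairs <- call_pairs(graph)
  clusters <- mcl_cluster(
    graph,
    inflation = config$inflation, prune = config$prune,
    max_iter = config$max_iter, tol = config$tol
  )
  fit <- find_rfl_cluster(clusters, focal_ids(config, qc$retained))
  f <- c(
    write_report(qc$discarded, out_path(config, "qc_discarded.tsv")),
    write_report(pairs, out_path(config, "ortho_pairs.tsv")),
    write_report(clusters, out_path(config, "clusters.tsv")),
    write_report(tidy(fit), out_path(config, "cluster_summary.tsv")),
    write_report(glance(fit), out_path(config, "rfl_cluster_call.tsv"))
  )
  manifest <- write_manifest(
    config, "ortho", strsplit(config$fasta, ";", fixed = TRUE)[[1]]
  )
  invisible(c(f, manifest))
}

stage_tree <- function(config) {
  records <- load_input_records(config)
  clusters_path <- out_path(config, "clusters.tsv")
  call_path <- out_path(config, "rfl_cluster_call.tsv")
  if (!file.exists(clusters_path) || !file.exists(call_path)) {
    abort("ortho stage outputs not found; run the ortho stage first")
  }
  clusters <- readr::read_tsv(
    clusters_path,
    col_types = readr::cols(.default = "c"), na = "."
  )
  call <- readr::read_tsv(
    call_path,
    col_types = readr::cols(.default = "c"), na = "."
  )
  target <- if (!is.na(call$outlier_id[1])) {
    call$outlier_id[1]
  } else {
    call$top_cluster_id[1] # fall back to the strongest candidate cluster
  }
  member_ids <- clusters$protein_id[clusters$cluster_id == target]
  members <- records[records$id %in% member_ids, ]
  if (nrow(members) < 3) {
    abort("the selected cluster has fewer than 3 members; cannot build a tree")
  }
  d <- pairwise_distances(members)
  tree <- nj_tree(d)
  f <- out_path(config, "rfl_tree.nwk")
  write_newick_tree(tree, f)
  manifest <- write_manifest(
    config, "tree", strsplit(config$fasta, ";", fixed = TRUE)[[1]]
  )
  invisible(c(f, manifest))
}

stage_hotspots <- function(config) {
  tree_path <- out_path(config, "rfl_tree.nwk")
  if (!file.exists(tree_path)) {
    abort("rfl_tree.nwk not found; run the tree stage first")
  }
  if (is.null(config$gff)) {
    abort("config key 'gff' is required for the hotspots stage")
  }
  tree <- read_newick_tree(tree_path)
  loci <- read_gff_loci(config$gff)
  clades <- extract_species_clades(tree, min_size = config$clade_min_size)
  regions <- hotspot_regions(
    clades, loci,
    min_size = config$clade_min_size,
    max_fraction_unplaced = config$max_fraction_unplaced
  )
  f <- c(
    write_report(clades, out_path(config, "clades.tsv")),
    write_report(regions, out_path(config, "hotspot_regions.tsv"))
  )
  manifest <- write_manifest(config, "hotspots", c(tree_path, config$gff))
  invisible(c(f, manifest))
}
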