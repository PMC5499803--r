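#' Pairwise p-distance matrix from global alignments
#'
#' For each pair of records, computes the p-distance
#' `1 - identical aligned columns / aligned columns` (gap columns excluded)
#' from a global (Needleman-Wunsch) alignment under the same scoring
#' configuration as the local searches.
#'
#' @param records A record tibble with >= 2 rows.
#' @param labels Optional labels for the matrix; defaults to
#'   `species:protein_id`.
#' @param config An [align_config()].
#' @return A symmetric, zero-diagonal numeric matrix.
#' @export
pairwise_distances <- function(records, labels = NULL, config = align_config()) {
  records <- validate_records(records)
  n <- nrow(records)
  if (n < 2) {
    abort("pairwise_distances() needs at least 2 records")
  }
  labels <- labels %||% paste0(records$species, ":", records$id)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (j in 2:n) {
    st <- aln_many(
      records$seq[seq_len(j - 1)], records$seq[j],
      config, type = "global"
    )
    aligned <- st$n_ident + st$n_mismatch
    p <- 1 - st$n_ident / aligned
    d[seq_len(j - 1), j] <- p
    d[j, seq_len(j - 1)] <- p
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with a deterministic tie-break (among pairs
#' minimising the Q-criterion, the lexicographically smallest label pair is
#' joined) and negative branch lengths clamped to zero.
#'
#' By default the distance reduction is variance-weighted in the BIONJ
#' manner: the new node's distances are a convex combination of the joined
#' pair's, weighted to minimise the variance of the reduced matrix.  On
#' exactly additive matrices every weighting recovers the true topology, so
#' the two methods only differ on noisy distance estimates, where the
#' weighted reduction is markedly less prone to misplacing single leaves of
#' tight clusters; `method = "nj"` selects the classic equal-weight
#' reduction.
#'
#' @param dist_matrix Square symmetric matrix with zero diagonal, n >= 3.
#' @param labels Taxon labels; default `rownames(dist_matrix)`.
#' @param method `"bionj"` (variance-weighted reduction, default) or
#'   `"nj"` (classic reduction).
#' @return An unrooted `phylo` object.
#' @export
nj_tree <- function(dist_matrix, labels = rownames(dist_matrix),
                    method = c("bionj", "nj")) {
  method <- match.arg(method)
  d <- as.matrix(dist_matrix)
  n <- nrow(d)
  if (n < 3) {
    abort("nj_tree() needs at least 3 taxa")
  }
  if (ncol(d) != n || max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-12)) {
    abort("dist_matrix must be square and symmetric with a zero diagonal")
  }
  if (is.null(labels)) {
    labels <- paste0("t", seq_len(n))
  }
  v <- d # variance estimates, initialised to the distances
  # each active node is represented by its newick subtree string
  sub <- paste0("@", seq_len(n), "@") # placeholder tokens, resolved at the end
  active <- seq_len(n)
  lab <- labels
  repeat {
    m <- length(active)
    if (m == 3) {
      break
    }
    dm <- d[active, active, drop = FALSE]
    r <- rowSums(dm)
    q <- (m - 2) * dm - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    ties <- which(q - qmin < 1e-12, arr.ind = TRUE)
    ties <- ties[ties[, 1] < ties[, 2], , drop = FALSE]
    # lexicographically smallest (sorted) label pair among the tied joins
    pair_lab <- t(apply(ties, 1, function(ij) {
      sort(c(lab[active[ij[1]]], lab[active[ij[2]]]))
    }))
    pick <- order(pair_lab[, 1], pair_lab[, 2])[1]
    i <- active[ties[pick, 1]]
    j <- active[ties[pick, 2]]
    bi <- d[i, j] / 2 + (sum(d[i, active]) - sum(d[j, active])) / (2 * (m - 2))
    bj <- d[i, j] - bi
    others <- setdiff(active, c(i, j))
    lambda <- 0.5
    if (method == "bionj" && v[i, j] > 1e-12) {
      lambda <- 0.5 +
        sum(v[j, others] - v[i, others]) / (2 * (m - 2) * v[i, j])
      lambda <- min(max(lambda, 0), 1)
    }
    # new internal node u replaces i and j
    u <- nrow(d) + 1L
    du <- lambda * (d[i, others] - bi) + (1 - lambda) * (d[j, others] - bj)
    vu <- lambda * v[i, others] + (1 - lambda) * v[j, others] -
      lambda * (1 - lambda) * v[i, j]
    d <- rbind(cbind(d, 0), 0)
    v <- rbind(cbind(v, 0), 0)
    d[u, others] <- du
    d[others, u] <- du
    v[u, others] <- vu
    v[others, u] <- vu
    sub <- c(sub, sprintf(
      "(%s:%.10g,%s:%.10g)", sub[i], max(bi, 0), sub[j], max(bj, 0)
    ))
    lab <- c(lab, "")
    active <- c(others, u)
  }
  # connect the last three nodes to a central vertex (three-point formulas),
  # leaving the customary unrooted trifurcation
  i <- active[1]
  j <- active[2]
  k <- active[3]
  li <- (d[i, j] + d[i, k] - d[j, k]) / 2
  lj <- (d[i, j] + d[j, k] - d[i, k]) / 2
  lk <- (d[i, k] + d[j, k] - d[i, j]) / 2
  text <- sprintf(
    "(%s:%.10g,%s:%.10g,%s:%.10g);",
    sub[i], max(li, 0), sub[j], max(lj, 0), sub[k], max(lk, 0)
  )
  tree <- ape::read.tree(text = text)
  idx <- as.integer(gsub("@", "", tree$tip.label, fixed = TRUE))
  tree$tip.label <- labels[idx]
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Maximal single-species clades
#'
#' Finds every maximal monophyletic clade whose leaves all carry the same
#' species tag (leaf labels `species:protein_id`) and have at least
#' `min_size` members.  Nested single-species clades are reported only at
#' their maximal extent.
#'
#' Rooted trees are read as given.  For unrooted trees (e.g. neighbor
#' joining output) monophyly is judged on bipartitions: a clade is a
#' single-species side of an edge, i.e. a group that is monophyletic under
#' every rooting outside it.  This avoids the artifact where a root placed
#' inside a species cluster (as midpoint rooting can do when that cluster
#' spans the tree diameter) splits one real clade in two.
#'
#' @param tree A `phylo` object.
#' @param min_size Minimum clade size (default 3).
#' @return A long tibble: `clade_id`, `species`, `protein_id`, `size`,
#'   ordered by first leaf.
#' @export
extract_species_clades <- function(tree, min_size = 3) {
  rooted <- ape::is.rooted(tree)
  n_tip <- length(tree$tip.label)
  leaf <- split_leaf_label(tree$tip.label)
  if (anyNA(leaf$species)) {
    abort("leaf labels must follow the 'species:protein_id' scheme")
  }
  n_node <- n_tip + tree$Nnode
  # leaves below each node in the stored (arbitrary) rooting
  tips_under <- vector("list", n_node)
  for (i in seq_len(n_tip)) tips_under[[i]] <- i
  for (e in ape::postorder(tree)) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    tips_under[[parent]] <- c(tips_under[[parent]], tips_under[[child]])
  }
  tips_under <- map(tips_under, sort)
  all_tips <- seq_len(n_tip)
  candidates <- tips_under
  if (!rooted) {
    # each edge also separates the complement side
    candidates <- c(candidates, map(tips_under, function(s) setdiff(all_tips, s)))
  }
  candidates <- unique(candidates[lengths(candidates) >= max(min_size, 1)])
  single <- map_lgl(candidates, function(s) {
    length(unique(leaf$species[s])) == 1
  })
  candidates <- candidates[single]
  if (length(candidates) == 0) {
    return(tibble(
      clade_id = character(), species = character(),
      protein_id = character(), size = integer()
    ))
  }
  is_maximal <- map_lgl(seq_along(candidates), function(i) {
    !any(map_lgl(seq_along(candidates), function(j) {
      j != i && length(candidates[[j]]) > length(candidates[[i]]) &&
        all(candidates[[i]] %in% candidates[[j]])
    }))
  })
  maximal <- candidates[is_maximal]
  maximal <- maximal[order(map_int(maximal, 1))]
  out <- bind_rows(imap(maximal, function(tips, k) {
    tibble(
      clade_id = sprintf("clade%02d", as.integer(k)),
      species = leaf$species[tips[1]],
      protein_id = leaf$protein_id[tips],
      size = length(tips)
    )
  }))
  arrange(out, .data$clade_id, .data$protein_id)
}

#' Genomic hotspot regions from species-specific clades
#'
#' Maps clade members to gene loci, groups them by chromosome, and emits a
#' region per chromosome group with at least `min_size` genes: the span
#' from the smallest locus start to the largest locus end, with the size in
#' kb rounded half-up.  Clade members without a locus are tolerated up to
#' `max_fraction_unplaced` (and excluded from the span); a clade whose
#' members are all unplaced is skipped with a warning.
#'
#' @param clades A clade tibble from [extract_species_clades()].
#' @param loci A locus tibble (see [read_gff_loci()]) keyed by `gene_id`
#'   matching the clade `protein_id`s.
#' @param min_size Minimum genes per region (default 3).
#' @param max_fraction_unplaced Tolerated fraction of clade members without
#'   a locus (default 0).
#' @return A tibble: `clade_id`, `species`, `chrom`, `start`, `end`,
#'   `span_kb`, `gene_count`.
#' @export
hotspot_regions <- function(clades, loci, min_size = 3,
                            max_fraction_unplaced = 0) {
  if (nrow(clades) == 0) {
    return(tibble(
      clade_id = character(), species = character(), chrom = character(),
      start = integer(), end = integer(), span_kb = double(),
      gene_count = integer()
    ))
  }
  out <- list()
  for (cid in unique(clades$clade_id)) {
    members <- clades[clades$clade_id == cid, ]
    placed <- left_join(members, loci, by = c(protein_id = "gene_id"))
    unplaced <- is.na(placed$chrom)
    if (all(unplaced)) {
      warn(sprintf("clade %s has no members with loci; skipped", cid))
      next
    }
    frac_unplaced <- mean(unplaced)
    if (frac_unplaced > max_fraction_unplaced) {
      abort(sprintf(
        "clade %s has %.0f%% unplaced members (max allowed %.0f%%)",
        cid, 100 * frac_unplaced, 100 * max_fraction_unplaced
      ))
    }
    placed <- placed[!unplaced, ]
    groups <- split(placed, placed$chrom)
    for (g in groups) {
      if (nrow(g) < min_size) next
      start <- min(g$start)
      end <- max(g$end)
      out[[length(out) + 1]] <- tibble(
        clade_id = cid,
        species = g$species[1],
        chrom = g$chrom[1],
        start = as.integer(start),
        end = as.integer(end),
        span_kb = round_half_up((end - start) / 1000),
        gene_count = nrow(g)
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(
      clade_id = character(), species = character(), chrom = character(),
      start = integer(), end = integer(), span_kb = double(),
      gene_count = integer()
    ))
  }
  arrange(bind_rows(out), .data$clade_id, .data$chrom, .data$start)
}

#' Fraction of the combined genome covered by hotspot regions
#'
#' @param regions A region tibble from [hotspot_regions()].
#' @param genome_sizes Named numeric vector of genome sizes in bp, one per
#'   species contributing a region.
#' @return Percentage (2 decimals, half-up) of the combined genome size of
#'   contributing species covered by the regions.
#' @export
genome_fraction <- function(regions, genome_sizes) {
  if (nrow(regions) == 0) {
    return(0)
  }
  species <- unique(regions$species)
  missing <- setdiff(species, names(genome_sizes))
  if (length(missing) > 0) {
    abort(paste0(
      "missing genome size for species: ", paste(missing, collapse = ", ")
    ))
  }
  total_span <- sum(regions$end - regions$start)
  total_genome <- sum(genome_sizes[species])
  round_half_up(100 * total_span / total_genome, 2)
}
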