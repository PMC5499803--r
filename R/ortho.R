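#' Quality-control filter for translated proteins
#'
#' Retains sequences longer than 30 residues whose stop-symbol (`*`)
#' fraction does not exceed 10% — the standard pre-clustering hygiene for
#' raw ORF translations.
#'
#' @param records A record tibble.
#' @return A list with `retained` (record tibble) and `discarded` (record
#'   tibble plus a `reason` column).
#' @export
qc_filter <- function(records) {
  records <- validate_records(records)
  len <- nchar(records$seq)
  n_stop <- stringr::str_count(records$seq, stringr::fixed("*"))
  stop_frac <- ifelse(len > 0, n_stop / len, 0)
  too_short <- len <= 30
  too_stopped <- stop_frac > 0.10
  keep <- !too_short & !too_stopped
  reason <- dplyr::case_when(
    too_short ~ "length <= 30 aa",
    too_stopped ~ "stop fraction > 10%",
    TRUE ~ NA_character_
  )
  list(
    retained = records[keep, ],
    discarded = mutate(records[!keep, ], reason = reason[!keep])
  )
}

#' All-vs-all similarity graph
#'
#' Builds the weighted protein graph behind orthologous clustering.  Pairs
#' sharing at least one exact k-mer (default k = 4) are aligned locally;
#' the alignment score is converted to an approximate E-value through a
#' Karlin-Altschul-style formula `E = K * m * n * 2^(-bits)` with fixed
#' `K = 0.1` and `bits = lambda * score / ln 2` (`lambda = 0.267`, the
#' gapped BLOSUM62 constant).  An edge is kept when
#' `-log10(E) >= min_neg_log_e`; weights are `-log10(E)` capped at 300.
#' Only the ranking/threshold behaviour of the weights matters downstream,
#' so the constants are fixed rather than calibrated.
#'
#' @param records A QC-filtered record tibble.
#' @param min_neg_log_e Edge cutoff on `-log10(E)` (default 5, i.e. the
#'   conventional 1e-5 homology-search cutoff).
#' @param k K-mer length for the shared-word prefilter (default 4);
#'   `k = 0` disables the prefilter.
#' @param cap Weight cap (default 300).
#' @param config An [align_config()].
#' @return A `similarity_graph`: list with `nodes` (tibble `id`, `species`)
#'   and `edges` (tibble `from`, `to`, `weight`; undirected, no
#'   self-edges).
#' @export
similarity_graph <- function(records, min_neg_log_e = 5, k = 4, cap = 300,
                             config = align_config()) {
  records <- validate_records(records)
  n <- nrow(records)
  nodes <- records[, c("id", "species")]
  edges <- tibble(from = character(), to = character(), weight = double())
  if (n >= 2) {
    pairs <- candidate_pairs(records$seq, k)
    if (nrow(pairs) > 0) {
      lens <- nchar(records$seq)
      scores <- sw_scores(records$seq, pairs$i, pairs$j, config)
      bits <- 0.267 * scores / log(2)
      neg_log_e <- bits * log10(2) -
        log10(0.1 * lens[pairs$i] * lens[pairs$j])
      weights <- pmin(neg_log_e, cap)
      keep <- weights >= min_neg_log_e
      edges <- tibble(
        from = records$id[pairs$i[keep]],
        to = records$id[pairs$j[keep]],
        weight = weights[keep]
      )
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf(
    "<similarity_graph> %d proteins (%d species), %d edges\n",
    nrow(x$nodes), length(unique(x$nodes$species)), nrow(x$edges)
  ))
  invisible(x)
}

# Unordered index pairs (i < j) sharing at least one exact k-mer.
candidate_pairs <- function(seqs, k) {
  n <- length(seqs)
  all_pairs <- function() {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    tibble(i = idx[, "row"], j = idx[, "col"])
  }
  if (k <= 0) {
    return(all_pairs())
  }
  kmer_sets <- map(seqs, function(s) {
    if (nchar(s) < k) {
      return(character(0))
    }
    starts <- seq_len(nchar(s) - k + 1)
    unique(substring(s, starts, starts + k - 1))
  })
  members_by_kmer <- split(
    rep(seq_len(n), lengths(kmer_sets)),
    unlist(kmer_sets)
  )
  members_by_kmer <- members_by_kmer[lengths(members_by_kmer) >= 2]
  if (length(members_by_kmer) == 0) {
    return(tibble(i = integer(), j = integer()))
  }
  pair_i <- unlist(map(members_by_kmer, function(v) rep(v, each = length(v))))
  pair_j <- unlist(map(members_by_kmer, function(v) rep(v, times = length(v))))
  keep <- pair_i < pair_j
  key <- pair_i[keep] * (n + 1) + pair_j[keep]
  first <- !duplicated(key)
  out <- tibble(i = pair_i[keep][first], j = pair_j[keep][first])
  arrange(out, .data$i, .data$j)
}

#' Call ortholog, in-paralog and co-ortholog pairs
#'
#' From a similarity graph with species tags: orthologs are reciprocal best
#' cross-species edges (all tied partners kept); in-paralogs are
#' within-species edges at least as heavy as the lighter member's best
#' cross-species edge (members with no cross-species edge always qualify);
#' co-orthologs are cross-species edges, not already orthologs, whose
#' endpoints are linked to an ortholog pair through in-paralog connected
#' components.  Weights are then normalised by the mean weight of their
#' pair type within each species pair.
#'
#' @param graph A `similarity_graph`.
#' @return A tibble: `id1`, `id2`, `species1`, `species2`, `type`
#'   (`ortholog`, `in_paralog`, `co_ortholog`), `weight`, `norm_weight`.
#' @export
call_pairs <- function(graph) {
  nodes <- graph$nodes
  edges <- graph$edges
  if (nrow(edges) == 0) {
    return(tibble(
      id1 = character(), id2 = character(), species1 = character(),
      species2 = character(), type = character(),
      weight = double(), norm_weight = double()
    ))
  }
  sp <- setNames(nodes$species, nodes$id)
  ed <- mutate(edges,
    sp_from = sp[.data$from], sp_to = sp[.data$to],
    cross = .data$sp_from != .data$sp_to
  )
  # directed view of cross-species edges
  cross <- ed[ed$cross, ]
  directed <- bind_rows(
    tibble(a = cross$from, b = cross$to, sp_b = cross$sp_to, weight = cross$weight),
    tibble(a = cross$to, b = cross$from, sp_b = cross$sp_from, weight = cross$weight)
  )
  if (nrow(directed) > 0) {
    # best weight from each node into each other species (ties all kept)
    best <- directed |>
      group_by(.data$a, .data$sp_b) |>
      dplyr::filter(.data$weight == max(.data$weight)) |>
      ungroup()
    best_key <- paste(best$a, best$b)
    is_best <- function(a, b) paste(a, b) %in% best_key
    ortho <- cross[is_best(cross$from, cross$to) & is_best(cross$to, cross$from), ]
    # best cross-species weight per node (0 when none)
    best_cross <- directed |>
      group_by(.data$a) |>
      summarise(best = max(.data$weight), .groups = "drop")
    bc <- setNames(best_cross$best, best_cross$a)
  } else {
    ortho <- cross
    bc <- numeric(0)
  }
  node_best <- function(id) ifelse(is.na(bc[id]), 0, bc[id])
  within <- ed[!ed$cross, ]
  inpar <- within[
    within$weight >= pmin(node_best(within$from), node_best(within$to)),
  ]
  # in-paralog closure: connected components of the in-paralog subgraph,
  # every node its own component by default
  comp <- setNames(seq_len(nrow(nodes)), nodes$id)
  if (nrow(inpar) > 0) {
    g <- igraph::graph_from_data_frame(
      inpar[, c("from", "to")],
      directed = FALSE,
      vertices = data.frame(name = nodes$id)
    )
    comp <- igraph::components(g)$membership[nodes$id]
  }
  ortho_comp_key <- unique(c(
    paste(comp[ortho$from], comp[ortho$to]),
    paste(comp[ortho$to], comp[ortho$from])
  ))
  ortho_key <- paste(
    pmin(ortho$from, ortho$to), pmax(ortho$from, ortho$to)
  )
  cross_key <- paste(pmin(cross$from, cross$to), pmax(cross$from, cross$to))
  is_ortho <- cross_key %in% ortho_key
  is_coortho <- !is_ortho &
    paste(comp[cross$from], comp[cross$to]) %in% ortho_comp_key
  typed <- bind_rows(
    mutate(cross[is_ortho, ], type = "ortholog"),
    mutate(cross[is_coortho, ], type = "co_ortholog"),
    mutate(inpar, type = "in_paralog")
  )
  typed <- typed |>
    mutate(
      id1 = pmin(.data$from, .data$to),
      id2 = pmax(.data$from, .data$to),
      species1 = pmin(.data$sp_from, .data$sp_to),
      species2 = pmax(.data$sp_from, .data$sp_to)
    ) |>
    group_by(.data$type, .data$species1, .data$species2) |>
    mutate(norm_weight = .data$weight / mean(.data$weight)) |>
    ungroup() |>
    select("id1", "id2", "species1", "species2", "type", "weight", "norm_weight") |>
    arrange(.data$type, .data$species1, .data$species2, .data$id1, .data$id2)
  typed
}

#' Markov clustering of a similarity graph
#'
#' Standard MCL on the column-stochastic transition matrix (self-loops set
#' to each node's maximum incident weight): repeatedly square the matrix
#' (expansion), raise entries to `inflation` and renormalise columns
#' (inflation), and drop entries below `prune`, until the largest entry
#' change falls below `tol` or `max_iter` is reached.  Clusters are the
#' connected components of the non-zero structure of the limit matrix.
#' Deterministic for a fixed input.
#'
#' @param graph A `similarity_graph`, or a pair-call tibble from
#'   [call_pairs()] (in which case `norm_weight` is used).
#' @param inflation Inflation exponent (default 1.5).
#' @param prune Entries below this value are zeroed each iteration
#'   (default 1e-5).
#' @param max_iter Iteration cap (default 100); hitting it returns the
#'   current clustering with a warning and `converged = FALSE`.
#' @param tol Convergence tolerance on the max entry change (default 1e-6).
#' @return A tibble `cluster_id`, `protein_id`, `species`, with attributes
#'   `converged`, `iterations` and `max_col_dev` (worst deviation of a
#'   column sum from 1 across all inflation steps).
#' @export
mcl_cluster <- function(graph, inflation = 1.5, prune = 1e-5,
                        max_iter = 100, tol = 1e-6) {
  if (inherits(graph, "similarity_graph")) {
    nodes <- graph$nodes
    edges <- graph$edges
  } else {
    edges <- tibble(
      from = graph$id1, to = graph$id2,
      weight = graph$norm_weight %||% graph$weight
    )
    ids <- sort(unique(c(edges$from, edges$to)))
    species <- if (!is.null(graph$species1)) {
      sp <- c(
        setNames(graph$species1, graph$id1),
        setNames(graph$species2, graph$id2)
      )
      unname(sp[ids])
    } else {
      rep(NA_character_, length(ids))
    }
    nodes <- tibble(id = ids, species = species)
  }
  n <- nrow(nodes)
  if (n == 0) {
    abort("mcl_cluster() needs a non-empty graph")
  }
  A <- matrix(0, n, n, dimnames = list(nodes$id, nodes$id))
  if (nrow(edges) > 0) {
    A[cbind(edges$from, edges$to)] <- edges$weight
    A[cbind(edges$to, edges$from)] <- edges$weight
  }
  # self-loop regularisation: max incident weight (1 for isolated nodes)
  loop <- apply(A, 2, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  iter <- 0L
  max_col_dev <- 0
  while (iter < max_iter) {
    iter <- iter + 1L
    M_new <- M %*% M
    M_new <- M_new^inflation
    M_new <- sweep(M_new, 2, colSums(M_new), "/")
    max_col_dev <- max(max_col_dev, max(abs(colSums(M_new) - 1)))
    M_new[M_new < prune] <- 0
    M_new <- sweep(M_new, 2, colSums(M_new), "/")
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("MCL did not converge within %d iterations", max_iter))
  }
  structure_graph <- igraph::graph_from_adjacency_matrix(
    1 * ((M > 0) | (t(M) > 0)),
    mode = "undirected", diag = FALSE
  )
  membership <- igraph::components(structure_graph)$membership
  out <- tibble(
    cluster_id = sprintf("MCL%04d", as.integer(membership)),
    protein_id = nodes$id,
    species = nodes$species
  ) |>
    arrange(.data$cluster_id, .data$protein_id)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iter
  attr(out, "max_col_dev") <- max_col_dev
  out
}

#' Detect the outlying RFL supercluster
#'
#' Restricts the clustering to clusters containing at least one focal-species
#' PPR, regresses `log2(protein_count)` on `species_count` by least squares,
#' and flags the cluster with the largest positive residual as the RFL
#' supercluster when (a) that residual exceeds 3 sample standard deviations
#' of the remaining clusters' residuals and (b) its protein count is more
#' than 3 times the second-largest eligible cluster.  The spread is
#' estimated leaving the candidate out: an extreme point otherwise masks
#' itself (with n points the largest attainable z-score is (n-1)/sqrt(n),
#' so an all-inclusive 3-sd rule could never fire on fewer than ~12
#' clusters however extreme the outlier).  Both criteria are reported
#' separately in the diagnostics, so a "no outlier" verdict is
#' inspectable.
#'
#' @param clusters A cluster tibble from [mcl_cluster()].
#' @param focal_ppr_ids Protein ids of the focal species' PPR genes.
#' @return An `rfl_outlier_fit` object; see [tidy.rfl_outlier_fit()] and
#'   [glance.rfl_outlier_fit()].
#' @export
find_rfl_cluster <- function(clusters, focal_ppr_ids) {
  summary <- clusters |>
    group_by(.data$cluster_id) |>
    summarise(
      n_proteins = n(),
      n_species = length(unique(.data$species)),
      has_focal = any(.data$protein_id %in% focal_ppr_ids),
      .groups = "drop"
    )
  eligible <- dplyr::filter(summary, .data$has_focal)
  if (nrow(eligible) < 3) {
    abort(sprintf(
      "need >= 3 clusters containing focal PPRs to fit the size trend (got %d)",
      nrow(eligible)
    ))
  }
  fit <- lm(log2(n_proteins) ~ n_species, data = eligible)
  eligible$residual <- unname(residuals(fit))
  top_idx <- which.max(eligible$residual)
  resid_sd <- sd(eligible$residual[-top_idx])
  top <- eligible[top_idx, ]
  second_n <- max(eligible$n_proteins[-top_idx])
  resid_flag <- top$residual > 0 && top$residual > 3 * resid_sd
  size_flag <- top$n_proteins > 3 * second_n
  outlier_id <- if (resid_flag && size_flag) top$cluster_id else NA_character_
  eligible$outlier <- eligible$cluster_id %in% outlier_id
  structure(
    list(
      clusters = eligible,
      fit = fit,
      outlier_id = outlier_id,
      top_cluster_id = top$cluster_id,
      top_residual = top$residual,
      resid_sd = resid_sd,
      second_largest_n = second_n,
      resid_flag = resid_flag,
      size_flag = size_flag
    ),
    class = "rfl_outlier_fit"
  )
}

#' @export
print.rfl_outlier_fit <- function(x, ...) {
  cat(sprintf(
    "<rfl_outlier_fit> %d eligible clusters\n", nrow(x$clusters)
  ))
  if (is.na(x$outlier_id)) {
    cat(sprintf(
      "  no outlier (residual criterion %s, size criterion %s)\n",
      ifelse(x$resid_flag, "met", "not met"),
      ifelse(x$size_flag, "met", "not met")
    ))
  } else {
    top <- x$clusters[x$clusters$cluster_id == x$outlier_id, ]
    cat(sprintf(
      "  outlier %s: %d proteins from %d species (residual %.2f, %.1fx second largest)\n",
      x$outlier_id, top$n_proteins, top$n_species, x$top_residual,
      top$n_proteins / x$second_largest_n
    ))
  }
  invisible(x)
}

#' Per-cluster diagnostics of the supercluster fit
#'
#' @param x An `rfl_outlier_fit`.
#' @param ... Unused.
#' @return A tibble with one row per eligible cluster: counts, residual
#'   and outlier flag.
#' @export
tidy.rfl_outlier_fit <- function(x, ...) {
  select(
    x$clusters, "cluster_id", "n_species", "n_proteins",
    "residual", "outlier"
  )
}

#' One-row summary of the supercluster fit
#'
#' @param x An `rfl_outlier_fit`.
#' @param ... Unused.
#' @export
glance.rfl_outlier_fit <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$clusters),
    outlier_id = x$outlier_id,
    top_cluster_id = x$top_cluster_id,
    top_residual = x$top_residual,
    resid_sd = x$resid_sd,
    second_largest_n = x$second_largest_n,
    resid_criterion = x$resid_flag,
    size_criterion = x$size_flag
  )
}

#' Species-count versus cluster-size scatterplot
#'
#' The diagnostic view behind the supercluster call: cluster size (log2)
#' against the number of species per cluster, outlier highlighted.
#'
#' @param object An `rfl_outlier_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rfl_outlier_fit <- function(object, ...) {
  df <- object$clusters
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$n_species, y = log2(.data$n_proteins)
  )) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier), size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
      linewidth = 0.4, colour = "grey40"
    ) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "black", `TRUE` = "red"), guide = "none"
    ) +
    ggplot2::labs(
      x = "species per cluster", y = "log2 proteins per cluster",
      title = "Clusters containing focal-species PPRs"
    ) +
    ggplot2::theme_minimal()
}
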