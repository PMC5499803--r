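#' Greedy incremental identity clustering
#'
#' CD-HIT-style clustering: sequences are sorted by length (descending, ties
#' by id ascending) and each joins the first existing cluster whose
#' representative it matches at `threshold` clustering identity, else founds
#' a new cluster.  Clustering identity is the number of identical positions
#' in the optimal local alignment divided by the length of the shorter
#' sequence (the CD-HIT convention, distinct from the aligned-column
#' identity used by [reference_hit_list()]).
#'
#' @param records A record tibble.
#' @param threshold Identity threshold in (0, 1].
#' @param config An [align_config()].
#' @return A tibble with columns `cluster_id`, `representative_id`,
#'   `protein_id`, `identity` (identity to the representative; 1 for the
#'   representative itself).
#' @export
greedy_cluster <- function(records, threshold, config = align_config()) {
  if (threshold <= 0 || threshold > 1) {
    abort("threshold must be in (0, 1]")
  }
  records <- validate_records(records)
  if (nrow(records) == 0) {
    return(tibble(
      cluster_id = character(), representative_id = character(),
      protein_id = character(), identity = double()
    ))
  }
  ord <- order(-nchar(records$seq), records$id)
  records <- records[ord, ]
  reps <- integer(0) # row indices of representatives, in founding order
  assignment <- integer(nrow(records))
  identity <- numeric(nrow(records))
  for (i in seq_len(nrow(records))) {
    placed <- FALSE
    if (length(reps) > 0) {
      ident <- clustering_identity(
        records$seq[i], records$seq[reps],
        config = config
      )
      ok <- which(ident >= threshold)
      if (length(ok) > 0) {
        assignment[i] <- ok[1]
        identity[i] <- ident[ok[1]]
        placed <- TRUE
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assignment[i] <- length(reps)
      identity[i] <- 1
    }
  }
  tibble(
    cluster_id = sprintf("C%03d", assignment),
    representative_id = records$id[reps[assignment]],
    protein_id = records$id,
    identity = identity
  ) |>
    arrange(.data$cluster_id, desc(.data$identity), .data$protein_id)
}

# Identities in the local alignment divided by the shorter sequence length;
# vectorised over `reps`.
clustering_identity <- function(seq, reps, config) {
  st <- aln_many(reps, seq, config, type = "local")
  st$n_ident / pmin(nchar(seq), nchar(reps))
}

#' Cluster counts across an identity-threshold ladder
#'
#' Reports, for each threshold, the number of clusters and the size of the
#' largest cluster; a compact view of how the set collapses as the
#' clustering identity is relaxed (only the 0.6 level feeds the RFL
#' consensus call).
#'
#' @param records A record tibble.
#' @param thresholds Identity thresholds (default 0.9, 0.8, 0.7, 0.6, 0.5).
#' @param config An [align_config()].
#' @return A tibble: `threshold`, `n_clusters`, `max_size`,
#'   `n_clusters_ge4`.
#' @export
cluster_ladder <- function(records, thresholds = c(0.9, 0.8, 0.7, 0.6, 0.5),
                           config = align_config()) {
  bind_rows(map(thresholds, function(t) {
    cl <- greedy_cluster(records, t, config = config)
    sizes <- table(cl$cluster_id)
    tibble(
      threshold = t,
      n_clusters = length(sizes),
      max_size = if (length(sizes)) max(sizes) else 0L,
      n_clusters_ge4 = sum(sizes >= 4)
    )
  }))
}

#' Proteins similar to a known restorer reference
#'
#' Aligns every record (as query) against one reference restorer protein
#' and keeps ids passing the homology gate: percent identity over aligned
#' columns >= `min_id` and query coverage >= `min_cov` (both boundaries
#' inclusive).
#'
#' @param records A record tibble (candidate PPRs; each is the alignment
#'   query).
#' @param reference A one-row record tibble or an amino-acid string.
#' @param min_id,min_cov Thresholds in percent (default 50 each).
#' @param config An [align_config()].
#' @return Character vector of qualifying protein ids.
#' @export
reference_hit_list <- function(records, reference, min_id = 50, min_cov = 50,
                               config = align_config()) {
  records <- validate_records(records)
  ref_seq <- if (is.character(reference)) reference else reference$seq[1]
  if (is.null(ref_seq) || !nzchar(ref_seq)) {
    abort("reference sequence is empty")
  }
  if (nrow(records) == 0) {
    return(character(0))
  }
  st <- aln_many(records$seq, ref_seq, config, type = "local")
  aligned <- st$n_ident + st$n_mismatch
  pct_id <- ifelse(aligned > 0, 100 * st$n_ident / aligned, 0)
  cov <- ifelse(st$score > 0, 100 * (st$qend - st$qstart + 1) / nchar(records$seq), 0)
  records$id[st$score > 0 & pct_id >= min_id & cov >= min_cov]
}

#' Consensus RFL candidate call
#'
#' Combines four membership lists: (1) membership in a greedy identity
#' cluster of at least `min_cluster_size` sequences at `cluster_threshold`
#' identity, and (2-4) similarity to each of three known restorer
#' references ([reference_hit_list()]).  A protein on at least
#' `required_lists` of the four lists is called a candidate RFL.
#'
#' @param records Record tibble of P-subfamily PPR proteins to screen.
#' @param references A record tibble (or list of sequences) of reference
#'   restorer proteins; exactly 3 unless `required_lists` is reconfigured.
#' @param cluster_threshold Identity for the clustering list (default 0.6).
#' @param min_cluster_size Minimum cluster size for list membership
#'   (default 4).
#' @param min_id,min_cov Reference-list gates in percent (default 50).
#' @param required_lists Minimum number of list memberships for candidacy
#'   (default 3).
#' @param config An [align_config()].
#' @return A tibble: `protein_id`, `in_cluster_list`, `in_ref1` ...,
#'   `n_lists`, `candidate`.
#' @export
consensus_rfl <- function(records, references, cluster_threshold = 0.6,
                          min_cluster_size = 4, min_id = 50, min_cov = 50,
                          required_lists = 3, config = align_config()) {
  records <- validate_records(records)
  if (is.character(references)) {
    references <- tibble(
      id = paste0("ref", seq_along(references)),
      species = "reference", seq = references, locus_id = NA_character_
    )
  }
  references <- validate_records(references)
  if (nrow(references) != 3 && required_lists == 3) {
    abort(paste0(
      "consensus_rfl() expects exactly 3 references (got ",
      nrow(references), "); adjust `required_lists` to use a different panel"
    ))
  }
  clusters <- greedy_cluster(records, cluster_threshold, config = config)
  big <- clusters |>
    group_by(.data$cluster_id) |>
    dplyr::filter(n() >= min_cluster_size) |>
    ungroup()
  membership <- tibble(
    protein_id = records$id,
    in_cluster_list = records$id %in% big$protein_id
  )
  for (r in seq_len(nrow(references))) {
    hits <- reference_hit_list(
      records, references[r, ],
      min_id = min_id, min_cov = min_cov, config = config
    )
    membership[[paste0("in_ref", r)]] <- records$id %in% hits
  }
  list_cols <- setdiff(names(membership), "protein_id")
  membership$n_lists <- as.integer(rowSums(membership[list_cols]))
  membership$candidate <- membership$n_lists >= required_lists
  membership
}
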