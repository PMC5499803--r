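test_that("QC filter applies the length and stop-fraction rules exactly", {
  recs <- tibble::tibble(
    id = paste0("q", 1:5), species = "sp",
    seq = c(
      strrep("A", 30), # length 30: discarded
      strrep("A", 31), # length 31: retained
      paste0(strrep("A", 90), strrep("*", 10)), # exactly 10% stops: retained
      paste0(strrep("A", 89), strrep("*", 11)), # 11% stops: discarded
      strrep("A", 100)
    ),
    locus_id = NA_character_
  )
  qc <- qc_filter(recs)
  expect_setequal(qc$retained$id, c("q2", "q3", "q5"))
  expect_setequal(qc$discarded$id, c("q1", "q4"))
  # partition: retained and discarded cover the input, disjointly
  expect_setequal(c(qc$retained$id, qc$discarded$id), recs$id)

  empty <- qc_filter(recs[0, ])
  expect_equal(nrow(empty$retained), 0)
  expect_equal(nrow(empty$discarded), 0)
})

test_that("similarity graph links homologs and ignores shuffled sequences", {
  set.seed(59)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  seq200 <- paste(sample(aa, 200, replace = TRUE), collapse = "")
  recs <- tibble::tibble(
    id = c("a", "b"), species = c("s1", "s2"),
    seq = c(seq200, seq200), locus_id = NA_character_
  )
  g <- similarity_graph(recs)
  expect_equal(nrow(g$edges), 1)
  expect_gte(g$edges$weight, 5)
  expect_lte(g$edges$weight, 300)

  # empirical null: shuffled unrelated proteins stay unlinked
  misses <- 0
  for (i in 1:100) {
    r2 <- tibble::tibble(
      id = c("a", "b"), species = c("s1", "s2"),
      seq = c(
        paste(sample(aa, 200, replace = TRUE), collapse = ""),
        paste(sample(aa, 200, replace = TRUE), collapse = "")
      ),
      locus_id = NA_character_
    )
    misses <- misses + (nrow(similarity_graph(r2)$edges) > 0)
  }
  expect_lte(misses, 1)
})

test_that("k-mer prefilter loses no edges on small sets", {
  sim <- simulate_multispecies(sim_config(
    seed = 61, n_species = 4, n_background_families = 4
  ))
  recs <- head(sim$records, 40)
  with_filter <- similarity_graph(recs, k = 4)$edges
  without <- similarity_graph(recs, k = 0)$edges
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_setequal(key(with_filter), key(without))
})

test_that("pair calling types orthologs, in-paralogs and co-orthologs", {
  # two species, one protein each, one edge: a single ortholog pair with
  # normalised weight 1
  g <- structure(list(
    nodes = tibble::tibble(id = c("a1", "b1"), species = c("A", "B")),
    edges = tibble::tibble(from = "a1", to = "b1", weight = 42)
  ), class = "similarity_graph")
  pairs <- call_pairs(g)
  expect_equal(pairs$type, "ortholog")
  expect_equal(pairs$norm_weight, 1)

  # duplicated a1/a2 both hitting b1: hand-enumerated expectation
  g <- structure(list(
    nodes = tibble::tibble(id = c("a1", "a2", "b1"), species = c("A", "A", "B")),
    edges = tibble::tibble(
      from = c("a1", "a2", "a1"),
      to = c("b1", "b1", "a2"),
      weight = c(50, 40, 60)
    )
  ), class = "similarity_graph")
  pairs <- call_pairs(g)
  expect_equal(
    pairs$type[pairs$id1 == "a1" & pairs$id2 == "b1"], "ortholog"
  )
  expect_equal(
    pairs$type[pairs$id1 == "a1" & pairs$id2 == "a2"], "in_paralog"
  )
  expect_equal(
    pairs$type[pairs$id1 == "a2" & pairs$id2 == "b1"], "co_ortholog"
  )

  # no cross-species edges: everything within species is an in-paralog
  g <- structure(list(
    nodes = tibble::tibble(id = c("a1", "a2", "a3"), species = "A"),
    edges = tibble::tibble(
      from = c("a1", "a2"), to = c("a2", "a3"), weight = c(5, 6)
    )
  ), class = "similarity_graph")
  pairs <- call_pairs(g)
  expect_equal(sort(unique(pairs$type)), "in_paralog")
  expect_equal(nrow(pairs), 2)
})

test_that("MCL separates components and matches a reference iteration", {
  # two disconnected triangles
  tri <- function(ids, sp) {
    tibble::tibble(
      from = ids[c(1, 2, 3)], to = ids[c(2, 3, 1)], weight = 10
    )
  }
  g <- structure(list(
    nodes = tibble::tibble(
      id = c(paste0("x", 1:3), paste0("y", 1:3)),
      species = rep(c("A", "B"), each = 3)
    ),
    edges = dplyr::bind_rows(tri(paste0("x", 1:3)), tri(paste0("y", 1:3)))
  ), class = "similarity_graph")
  cl <- mcl_cluster(g)
  expect_equal(length(unique(cl$cluster_id)), 2)
  expect_equal(unname(table(cl$cluster_id)[unique(cl$cluster_id)]),
    c(3L, 3L),
    ignore_attr = TRUE
  )
  expect_true(attr(cl, "converged"))
  expect_lt(attr(cl, "max_col_dev"), 1e-9)

  # single node
  g1 <- structure(list(
    nodes = tibble::tibble(id = "solo", species = "A"),
    edges = tibble::tibble(from = character(), to = character(), weight = double())
  ), class = "similarity_graph")
  expect_equal(nrow(mcl_cluster(g1)), 1)

  # 12-node barbell: two 6-cliques joined by one weak edge (10:1)
  clique_edges <- function(ids, w) {
    combs <- utils::combn(ids, 2)
    tibble::tibble(from = combs[1, ], to = combs[2, ], weight = w)
  }
  ids1 <- paste0("L", 1:6)
  ids2 <- paste0("R", 1:6)
  edges <- dplyr::bind_rows(
    clique_edges(ids1, 10), clique_edges(ids2, 10),
    tibble::tibble(from = "L1", to = "R1", weight = 1)
  )
  g2 <- structure(list(
    nodes = tibble::tibble(id = c(ids1, ids2), species = "A"),
    edges = edges
  ), class = "similarity_graph")
  cl2 <- mcl_cluster(g2, inflation = 1.5)
  expect_equal(length(unique(cl2$cluster_id)), 2)
  expect_equal(sort(as.integer(table(cl2$cluster_id))), c(6L, 6L))

  # independent dense reference iteration agrees on the partition
  adj <- matrix(0, 12, 12, dimnames = list(c(ids1, ids2), c(ids1, ids2)))
  adj[cbind(edges$from, edges$to)] <- edges$weight
  adj[cbind(edges$to, edges$from)] <- edges$weight
  want <- oracle_mcl_membership(adj)
  got <- as.integer(factor(cl2$cluster_id[match(c(ids1, ids2), cl2$protein_id)]))
  expect_equal(oracle_ari(got, want), 1)

  # partition property: every node appears exactly once
  expect_setequal(cl2$protein_id, c(ids1, ids2))
  expect_equal(anyDuplicated(cl2$protein_id), 0L)
})

test_that("supercluster detection uses both residual and size criteria", {
  mk_clusters <- function(sizes, species_counts, focal_in = seq_along(sizes)) {
    dplyr::bind_rows(lapply(seq_along(sizes), function(i) {
      tibble::tibble(
        cluster_id = sprintf("MCL%02d", i),
        protein_id = c(
          if (i %in% focal_in) "sp01|ppr" else NULL,
          sprintf("c%d_m%d", i, seq_len(sizes[i] - (i %in% focal_in)))
        ),
        species = sprintf("s%02d", rep_len(seq_len(species_counts[i]), sizes[i]))
      )
    }))
  }
  # equal sizes: no outlier
  cl <- mk_clusters(rep(8, 6), rep(8, 6))
  fit <- find_rfl_cluster(cl, "sp01|ppr")
  expect_true(is.na(fit$outlier_id))

  # a 40-protein cluster among one-per-species clusters: flagged
  cl <- mk_clusters(c(6, 7, 8, 9, 10, 11, 12, 40), c(6, 7, 8, 9, 10, 11, 12, 12))
  fit <- find_rfl_cluster(cl, "sp01|ppr")
  expect_equal(fit$outlier_id, "MCL08")
  expect_true(fit$resid_flag)
  expect_true(fit$size_flag)

  # residuals agree with the closed-form least-squares solve
  td <- tidy(fit)
  want <- oracle_ls_residuals(td$n_species, log2(td$n_proteins))
  expect_equal(td$residual, want, tolerance = 1e-9)

  expect_error(
    find_rfl_cluster(mk_clusters(c(4, 5), c(4, 5)), "sp01|ppr"),
    ">= 3 clusters"
  )
  expect_s3_class(glance(fit), "tbl_df")
  expect_s3_class(autoplot(fit), "ggplot")
})
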