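simple_cfg <- function() {
  align_config(match = 2, mismatch = -1, gap_open = -2, gap_extend = -2)
}

test_that("local alignment reports score, identity and coverage", {
  seq100 <- strrep("ARNDWHKMFPST", 9)
  st <- local_align(seq100, seq100)
  expect_equal(st$pct_identity, 100)
  expect_equal(st$query_cov, 100)

  st <- local_align("AWGHE", "AWHE", config = simple_cfg())
  expect_equal(st$score, 6)

  # disjoint alphabets: no positive-scoring alignment
  st <- local_align(strrep("K", 20), strrep("R", 20), config = simple_cfg())
  expect_equal(st$score, 0)
  expect_equal(st$query_cov, 0)
  expect_true(is.na(st$pct_identity))

  expect_error(local_align("", "AA"), "non-empty")
})

test_that("local alignment scores equal the exhaustive Gotoh oracle", {
  set.seed(29)
  aa <- c("A", "R", "N", "D", "W", "H", "K")
  for (i in 1:200) {
    q <- paste(sample(aa, sample(3:12, 1), replace = TRUE), collapse = "")
    s <- paste(sample(aa, sample(3:12, 1), replace = TRUE), collapse = "")
    got <- local_align(q, s, config = simple_cfg())$score
    want <- oracle_local_score(q, s,
      match = 2, mismatch = -1, gap_open = -2, gap_extend = -2
    )
    expect_equal(got, want, info = paste(q, s))
  }
})

test_that("the batch score kernel agrees with the full aligner and the oracle", {
  set.seed(97)
  aa <- c("A", "R", "N", "D", "W", "H", "K", "M", "F", "P")
  seqs <- vapply(1:12, function(i) {
    paste(sample(aa, sample(8:60, 1), replace = TRUE), collapse = "")
  }, "")
  pairs <- expand.grid(i = 1:12, j = 1:12)
  pairs <- pairs[pairs$i < pairs$j, ]
  cfg <- simple_cfg()
  batch <- rflscout:::sw_scores(seqs, pairs$i, pairs$j, cfg)
  for (p in seq_len(nrow(pairs))) {
    expect_equal(
      batch[p],
      local_align(seqs[pairs$i[p]], seqs[pairs$j[p]], config = cfg)$score
    )
  }
  short <- pairs[nchar(seqs[pairs$i]) <= 12 & nchar(seqs[pairs$j]) <= 12, ]
  for (p in seq_len(nrow(short))) {
    expect_equal(
      rflscout:::sw_scores(seqs, short$i[p], short$j[p], cfg),
      oracle_local_score(seqs[short$i[p]], seqs[short$j[p]], 2, -1, -2, -2)
    )
  }
})

test_that("greedy clustering groups identical sequences and honours bounds", {
  recs <- tibble::tibble(
    id = c("A", "B", "C"), species = "sp",
    seq = c(strrep("ARNDKWH", 10), strrep("ARNDKWH", 10), strrep("MFPSTYV", 10)),
    locus_id = NA_character_
  )
  cl <- greedy_cluster(recs, 0.9)
  expect_equal(length(unique(cl$cluster_id)), 2)
  expect_equal(
    sort(cl$protein_id[cl$cluster_id == cl$cluster_id[cl$protein_id == "A"]]),
    c("A", "B")
  )

  # threshold 1 on distinct sequences: all singletons
  set.seed(31)
  recs <- random_records(8)
  cl <- greedy_cluster(recs, 1)
  expect_equal(length(unique(cl$cluster_id)), 8)
})

test_that("every member meets the identity bound to its representative", {
  set.seed(37)
  base <- strrep("ARNDKWHMFPST", 25)
  recs <- tibble::tibble(
    id = paste0("m", 1:10), species = "sp",
    seq = c(
      vapply(1:6, function(i) rflscout:::mutate_residues(base, 0.1), ""),
      random_records(4)$seq
    ),
    locus_id = NA_character_
  )
  threshold <- 0.6
  cl <- greedy_cluster(recs, threshold)
  # post-hoc verification over all member/representative pairs
  for (i in seq_len(nrow(cl))) {
    rep_seq <- recs$seq[recs$id == cl$representative_id[i]]
    mem_seq <- recs$seq[recs$id == cl$protein_id[i]]
    ident <- rflscout:::clustering_identity(mem_seq, rep_seq, align_config())
    expect_gte(ident + 1e-9, threshold)
  }
})

test_that("greedy clustering is order independent", {
  set.seed(41)
  base <- strrep("ARNDKWHMFPST", 20)
  recs <- tibble::tibble(
    id = sprintf("m%02d", 1:12), species = "sp",
    seq = c(
      vapply(1:8, function(i) rflscout:::mutate_residues(base, 0.15), ""),
      random_records(4, len_range = c(100, 200))$seq
    ),
    locus_id = NA_character_
  )
  cl1 <- greedy_cluster(recs, 0.6)
  cl2 <- greedy_cluster(recs[sample(nrow(recs)), ], 0.6)
  expect_equal(cl1, cl2)
})

test_that("reference hit list applies inclusive identity/coverage gates", {
  ref <- strrep("ARNDKWHMFPST", 20)
  recs <- tibble::tibble(
    id = c("same", "partial"), species = "sp",
    seq = c(ref, paste0(substr(ref, 1, 10), strrep("G", 290))),
    locus_id = NA_character_
  )
  hits <- reference_hit_list(recs, ref)
  expect_true("same" %in% hits)
  expect_false("partial" %in% hits) # 10 of 300 residues: coverage far below 50

  # boundary inclusivity: thresholds equal to the measured stats still pass
  set.seed(43)
  probe <- rflscout:::mutate_residues(ref, 0.3)
  st <- local_align(probe, ref)
  recs2 <- tibble::tibble(
    id = "probe", species = "sp", seq = probe, locus_id = NA_character_
  )
  expect_equal(
    reference_hit_list(recs2, ref,
      min_id = st$pct_identity, min_cov = st$query_cov
    ),
    "probe"
  )
  expect_equal(
    reference_hit_list(recs2, ref, min_id = st$pct_identity + 1e-6),
    character(0)
  )
})

test_that("consensus call needs three of four lists and is monotone", {
  set.seed(47)
  ancestor <- rflscout:::mutate_residues(strrep("ARNDKWHMFPSTEQ", 30), 0.2)
  rfl_like <- vapply(1:5, function(i) {
    rflscout:::mutate_residues(ancestor, 0.05)
  }, "")
  unrelated <- random_records(4, len_range = c(300, 380))$seq
  recs <- tibble::tibble(
    id = c(paste0("rfl", 1:5), paste0("bg", 1:4)),
    species = "sp",
    seq = c(rfl_like, unrelated),
    locus_id = NA_character_
  )
  refs <- vapply(1:3, function(i) {
    rflscout:::mutate_residues(ancestor, 0.08)
  }, "")
  calls <- consensus_rfl(recs, refs)
  expect_true(all(calls$candidate[grepl("^rfl", calls$protein_id)]))
  expect_false(any(calls$candidate[grepl("^bg", calls$protein_id)]))
  expect_true(all(calls$n_lists[grepl("^rfl", calls$protein_id)] >= 3))

  # candidate iff n_lists >= required; lowering the requirement never
  # removes candidacy (monotone in list membership)
  calls2 <- consensus_rfl(recs, refs, required_lists = 2)
  expect_true(all(calls2$candidate[calls$candidate]))
  expect_equal(calls$candidate, calls$n_lists >= 3)

  expect_error(consensus_rfl(recs, refs[1:2]), "3 references")
})

test_that("cluster ladder reports the collapse across identity levels", {
  set.seed(53)
  base <- strrep("ARNDKWHMFPST", 25)
  recs <- tibble::tibble(
    id = sprintf("m%02d", 1:8), species = "sp",
    seq = c(
      vapply(1:5, function(i) rflscout:::mutate_residues(base, 0.12), ""),
      random_records(3, len_range = c(200, 280))$seq
    ),
    locus_id = NA_character_
  )
  ladder <- cluster_ladder(recs, thresholds = c(0.9, 0.6))
  expect_equal(ladder$threshold, c(0.9, 0.6))
  # relaxing the threshold can only merge clusters
  expect_gte(ladder$n_clusters[1], ladder$n_clusters[2])
  expect_gte(ladder$max_size[2], 5)
})
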