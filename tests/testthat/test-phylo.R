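test_that("p-distances come from global alignment identity", {
  recs <- tibble::tibble(
    id = c("a", "b"), species = "sp",
    seq = c("AAAA", "AAAT"), locus_id = NA_character_
  )
  d <- pairwise_distances(recs, config = align_config(match = 2, mismatch = -1))
  expect_equal(d["sp:a", "sp:b"], 0.25)
  expect_equal(diag(d), c("sp:a" = 0, "sp:b" = 0))

  recs$seq <- c("MARNDKWH", "MARNDKWH")
  d <- pairwise_distances(recs)
  expect_equal(d["sp:a", "sp:b"], 0)
})

test_that("distance matrices are symmetric with zero diagonal", {
  set.seed(67)
  recs <- random_records(20, len_range = c(30, 60))
  d <- pairwise_distances(recs)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 20))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("three taxa give the closed-form star tree", {
  d <- matrix(
    c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0),
    3, 3,
    dimnames = list(c("a", "b", "c"), c("a", "b", "c"))
  )
  tree <- nj_tree(d)
  expect_equal(length(tree$tip.label), 3)
  expect_false(ape::is.rooted(tree))
  # closed-form three-point branch lengths
  la <- (0.3 + 0.5 - 0.6) / 2
  lb <- (0.3 + 0.6 - 0.5) / 2
  lc <- (0.5 + 0.6 - 0.3) / 2
  lens <- setNames(
    tree$edge.length[match(seq_len(3), tree$edge[, 2])],
    tree$tip.label
  )
  expect_equal(unname(lens[c("a", "b", "c")]), c(la, lb, lc))

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  bad <- d
  bad[1, 2] <- 0.9
  expect_error(nj_tree(bad), "symmetric")
})

test_that("neighbor joining recovers additive and ultrametric trees", {
  set.seed(71)
  # additive 4-taxon matrix from a known tree
  tr <- ape::rtree(4)
  tr$edge.length <- runif(nrow(tr$edge), 0.2, 1)
  d <- ape::cophenetic.phylo(tr)
  rec <- nj_tree(d)
  expect_equal(phangorn::RF.dist(ape::unroot(tr), rec), 0)

  # balanced ultrametric 8-leaf tree
  tr8 <- ape::stree(8, type = "balanced")
  tr8$edge.length <- rep(1, nrow(tr8$edge))
  d8 <- ape::cophenetic.phylo(tr8)
  rec8 <- nj_tree(d8)
  expect_equal(phangorn::RF.dist(ape::unroot(tr8), rec8), 0)

  # random additive matrices, exact topology recovery
  for (i in 1:20) {
    n <- sample(6:10, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
    d <- ape::cophenetic.phylo(tr)
    ord <- sample(rownames(d))
    rec <- nj_tree(d[ord, ord])
    expect_equal(phangorn::RF.dist(ape::unroot(tr), rec), 0)
  }
})

test_that("species clades are maximal, disjoint and size-filtered", {
  tree <- read_newick_tree(
    text = "(('sp1:a':1,'sp1:b':1):1,('sp2:c':1,'sp2:d':1):1);"
  )
  clades <- extract_species_clades(tree, min_size = 2)
  expect_equal(length(unique(clades$clade_id)), 2)
  expect_equal(unique(clades$size), 2L)

  # nested single-species groups report only the maximal extent
  tree <- read_newick_tree(text = paste0(
    "((((('sp1:a':1,'sp1:b':1):1,'sp1:c':1):1,",
    "('sp1:d':1,'sp1:e':1):1):1,'sp2:x':1),'sp2:y':3);"
  ))
  clades <- extract_species_clades(tree, min_size = 2)
  sp1 <- clades[clades$species == "sp1", ]
  expect_equal(unique(sp1$size), 5L)
  expect_setequal(sp1$protein_id, c("a", "b", "c", "d", "e"))

  # clades are pairwise leaf-disjoint
  expect_equal(anyDuplicated(clades$protein_id), 0L)
})

test_that("hotspot regions reproduce reference spans under half-up rounding", {
  # loci evenly placed between the bounds of two published RFL-dense regions
  mk <- function(clade, species, chrom, start, end, n) {
    pts <- round(seq(start, end, length.out = n))
    list(
      clades = tibble::tibble(
        clade_id = clade, species = species,
        protein_id = sprintf("%s_g%d", clade, seq_len(n)), size = n
      ),
      loci = tibble::tibble(
        gene_id = sprintf("%s_g%d", clade, seq_len(n)),
        chrom = chrom, start = pts, end = pts, strand = "+"
      )
    )
  }
  rice <- mk("c1", "rice", "Ch10", 18823675, 19143586, 6)
  regions <- hotspot_regions(rice$clades, rice$loci)
  expect_equal(regions$span_kb, 320)
  expect_equal(regions$gene_count, 6)

  barley <- mk("c2", "barley", "Ch1", 47176692, 50263441, 3)
  expect_equal(hotspot_regions(barley$clades, barley$loci)$span_kb, 3087)

  # groups below min_size are dropped
  single <- mk("c3", "rice", "Ch8", 374091, 383986, 2)
  expect_equal(nrow(hotspot_regions(single$clades, single$loci)), 0)
  expect_equal(
    hotspot_regions(single$clades, single$loci, min_size = 2)$span_kb, 10
  )

  # all members unplaced: skipped with a warning
  expect_warning(
    out <- hotspot_regions(
      rice$clades,
      tibble::tibble(
        gene_id = "other", chrom = "Ch1",
        start = 1L, end = 2L, strand = "+"
      )
    ),
    "skipped"
  )
  expect_equal(nrow(out), 0)

  # partial placement beyond the tolerated fraction errors
  expect_error(
    hotspot_regions(rice$clades, rice$loci[-1, ]),
    "unplaced"
  )
})

test_that("genome fraction sums spans over contributing genomes", {
  regions <- tibble::tibble(
    clade_id = c("c1", "c2"), species = c("rice", "rice"),
    chrom = c("Ch1", "Ch2"),
    start = c(1000000L, 5000000L), end = c(1800000L, 5500000L),
    span_kb = c(800, 500), gene_count = c(4L, 3L)
  )
  expect_equal(genome_fraction(regions, c(rice = 1e9)), 0.13)
  expect_equal(genome_fraction(regions[0, ], c(rice = 1e9)), 0)
  expect_error(genome_fraction(regions, c(maize = 1e9)), "rice")

  # two species: matches an independent hand sum
  regions2 <- dplyr::bind_rows(
    regions,
    tibble::tibble(
      clade_id = "c3", species = "maize", chrom = "Ch8",
      start = 100000L, end = 400000L, span_kb = 300, gene_count = 3L
    )
  )
  sizes <- c(rice = 4e8, maize = 2.1e9)
  want <- round(100 * (800000 + 500000 + 300000) / (4e8 + 2.1e9), 2)
  expect_equal(genome_fraction(regions2, sizes), want)
})
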