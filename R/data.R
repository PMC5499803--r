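#' Curated survey tables of RFL-dense genomic regions
#'
#' Two small reference tables bundled with the package, compiled from
#' published surveys of restorer-of-fertility-like (RFL) genes in sequenced
#' grass genomes and Arabidopsis:
#' \describe{
#'   \item{`rfl_region_reference()`}{Species-specific genomic regions of
#'     high RFL density: `clade`, `species`, `chrom`, `start`, `end` (bp,
#'     1-based inclusive) and `n_genes`, the number of RFL genes in the
#'     region.  Useful as a positive control for [hotspot_regions()] span
#'     arithmetic and as a realistic scale reference.}
#'   \item{`rfl_clade_counts()`}{Per-species RFL counts across the four
#'     major clades of the cross-species RFL cluster, plus the per-species
#'     totals.}
#' }
#'
#' @return A tibble.
#' @export
rfl_region_reference <- function() {
  readr::read_tsv(
    system.file("extdata", "rfl_region_reference.tsv", package = "rflscout"),
    show_col_types = FALSE
  )
}

#' @rdname rfl_region_reference
#' @export
rfl_clade_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "rfl_clade_counts.tsv", package = "rflscout"),
    show_col_types = FALSE
  )
}
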