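#' Read protein records from a FASTA file
#'
#' Reads amino-acid FASTA into the tidy record table used throughout the
#' package.  The species tag is taken from the header token before the first
#' `|` when present; otherwise the file-level `species` argument is used.
#' Sequences may contain the twenty canonical residues plus `X` (unknown)
#' and `*` (stop); anything else is an error naming the record and position.
#'
#' @param path Path to a FASTA file.
#' @param species Optional file-level species tag, used for headers without
#'   a `species|` prefix.
#' @return A tibble with columns `id`, `species`, `seq`, `locus_id`.
#' @export
read_fasta <- function(path, species = NULL) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  n_headers <- sum(startsWith(readLines(path, warn = FALSE), ">"))
  if (n_headers == 0) {
    return(tibble(
      id = character(), species = character(),
      seq = character(), locus_id = character()
    ))
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", ")))
  }
  has_prefix <- grepl("|", ids, fixed = TRUE)
  sp <- ifelse(has_prefix, sub("\\|.*$", "", ids), species %||% NA_character_)
  if (any(is.na(sp) | sp == "")) {
    abort(paste0(
      "no species tag for record(s) ",
      paste(ids[is.na(sp) | sp == ""], collapse = ", "),
      "; add a 'species|' header prefix or pass `species =`"
    ))
  }
  validate_records(tibble(
    id = ids, species = unname(sp),
    seq = unname(toupper(as.character(set))), locus_id = NA_character_
  ))
}

#' Write protein records to FASTA
#'
#' @param records A record tibble (see [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- validate_records(records)
  set <- Biostrings::AAStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read gene loci from GFF3
#'
#' Keeps `gene`-type rows only and returns their 1-based inclusive
#' coordinates exactly as stored in the GFF3.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gff_loci <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("GFF3 file not found: ", path))
  }
  gff <- as_tibble(as.data.frame(rtracklayer::readGFF(
    path,
    columns = c("seqid", "type", "start", "end", "strand"),
    tags = "ID"
  )))
  genes <- dplyr::filter(gff, .data$type == "gene")
  if (nrow(genes) > 0 && any(is.na(genes$ID) | genes$ID == "")) {
    abort("GFF3 gene row without an ID attribute")
  }
  if (any(genes$start > genes$end)) {
    bad <- genes$ID[genes$start > genes$end]
    abort(paste0("locus with start > end: ", paste(bad, collapse = ", ")))
  }
  loci <- tibble(
    gene_id = as.character(genes$ID),
    chrom = as.character(genes$seqid),
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    strand = as.character(genes$strand)
  )
  dup <- loci$gene_id[duplicated(loci$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene id(s) in GFF3: ", paste(unique(dup), collapse = ", ")))
  }
  loci
}

#' Read gene loci from BED
#'
#' BED intervals are 0-based half-open; they are converted to the 1-based
#' inclusive convention used internally, so a BED row `(chr1, 99, 400)`
#' becomes `start = 100, end = 400`.
#'
#' @param path Path to a BED file with at least 4 columns (name required).
#' @return A tibble as in [read_gff_loci()].
#' @export
read_bed_loci <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("BED file not found: ", path))
  }
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm) || any(is.na(nm) | nm == "")) {
    abort("BED input needs a name column to serve as gene_id")
  }
  tibble(
    gene_id = as.character(nm),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.integer(BiocGenerics::start(gr)),
    end = as.integer(BiocGenerics::end(gr)),
    strand = as.character(BiocGenerics::strand(gr))
  )
}

#' Write gene loci to GFF3
#'
#' @param loci A locus tibble (see [read_gff_loci()]).
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff_loci <- function(loci, path, source = "rflscout") {
  strand <- ifelse(loci$strand %in% c("+", "-"), loci$strand, ".")
  lines <- sprintf(
    "%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
    loci$chrom, source, loci$start, loci$end, strand, loci$gene_id
  )
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read precomputed domain hits from a HMMER3 per-domain table
#'
#' Imports the whitespace-delimited `--domtblout` dialect written by
#' external profile scanners.  Envelope coordinates become the hit interval
#' and the per-domain bit score becomes the hit score.  Profile names are
#' mapped to the package's six motif classes through a user-supplied alias
#' table; rows with unmapped names are skipped with a warning (the count of
#' skips is available as `attr(, "n_skipped")`).
#'
#' @param path Path to a domtblout file (`#` lines are comments).
#' @param alias Named character vector mapping scanner profile names to
#'   `P`, `L`, `S`, `E`, `Eplus` or `DYW`, e.g.
#'   `c(PPR = "P", PPR_long = "L")`.
#' @return A tibble with columns `protein_id`, `profile`, `start`, `end`,
#'   `score`, sorted as read.
#' @export
read_domtblout <- function(path, alias) {
  if (!file.exists(path)) {
    abort(paste0("domtblout file not found: ", path))
  }
  if (is.null(names(alias)) || !all(alias %in% MOTIF_CLASSES)) {
    abort("`alias` must be a named vector with values in P, L, S, E, Eplus, DYW")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- tibble(
      protein_id = character(), profile = character(),
      start = integer(), end = integer(), score = double()
    )
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  fields <- strsplit(trimws(lines), "\\s+")
  short <- which(lengths(fields) < 21)
  if (length(short) > 0) {
    abort(sprintf("domtblout line %d has fewer than 21 fields", short[1]))
  }
  get_col <- function(i) map_chr(fields, i)
  num_col <- function(i, what) {
    raw <- get_col(i)
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      abort(sprintf(
        "non-numeric %s '%s' in domtblout", what, raw[which(is.na(val))[1]]
      ))
    }
    val
  }
  hits <- tibble(
    protein_id = get_col(1),
    profile_raw = get_col(4),
    score = num_col(14, "score"),
    start = as.integer(num_col(20, "envelope start")),
    end = as.integer(num_col(21, "envelope end"))
  )
  mapped <- hits$profile_raw %in% names(alias)
  n_skipped <- sum(!mapped)
  if (n_skipped > 0) {
    warn(sprintf(
      "skipped %d domtblout hit(s) with unmapped profile name(s): %s",
      n_skipped, paste(unique(hits$profile_raw[!mapped]), collapse = ", ")
    ))
  }
  out <- hits |>
    dplyr::filter(mapped) |>
    mutate(profile = unname(alias[.data$profile_raw])) |>
    select("protein_id", "profile", "start", "end", "score")
  attr(out, "n_skipped") <- n_skipped
  out
}

# ---- newick ----------------------------------------------------------------

# Leaf labels follow the "species:protein_id" scheme, which collides with
# newick's branch-length colon.  On disk such labels are single-quoted; in
# memory they are plain strings.  ape's writer would mangle quoted colons,
# so quoting is handled here and a placeholder keeps ape's parser happy.
COLON_TOKEN <- "__rfs_colon__"

#' Read a tree from newick
#'
#' Accepts a single rooted or unrooted newick string.  Leaf labels of the
#' form `'species:protein_id'` (single-quoted) are supported and returned
#' unquoted.  Missing branch lengths default to 1.
#'
#' @param path Path to a newick file, or a literal newick string via `text`.
#' @param text Optional newick string (overrides `path`).
#' @return An [ape::read.tree()]-style `phylo` object.
#' @export
read_newick_tree <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path)) {
      abort(paste0("newick file not found: ", path %||% "<missing>"))
    }
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  check_parens(text)
  # protect quoted labels, then hand to ape
  protected <- protect_quoted_labels(text)
  tree <- tryCatch(
    ape::read.tree(text = protected),
    error = function(e) abort(paste0("newick parse error: ", conditionMessage(e)))
  )
  if (is.null(tree)) {
    abort("newick parse error: not a valid tree")
  }
  tree$tip.label <- gsub(COLON_TOKEN, ":", tree$tip.label, fixed = TRUE)
  if (!is.null(tree$node.label)) {
    tree$node.label <- gsub(COLON_TOKEN, ":", tree$node.label, fixed = TRUE)
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  tree
}

check_parens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("newick parse error: unbalanced ')' at position %d", i))
      }
    }
  }
  if (in_quote) abort("newick parse error: unterminated quoted label")
  if (depth != 0L) {
    abort(sprintf(
      "newick parse error: %d unclosed '(' at end of input", depth
    ))
  }
  invisible(TRUE)
}

escape_regex <- function(x) {
  gsub("([][{}()*+?.\\\\^$|])", "\\\\\\1", x)
}

protect_quoted_labels <- function(text) {
  m <- gregexpr("'[^']*'", text)[[1]]
  if (m[1] == -1) {
    return(text)
  }
  out <- text
  # replace from the right so match positions stay valid
  for (i in rev(seq_along(m))) {
    start <- m[i]
    len <- attr(m, "match.length")[i]
    label <- substr(out, start + 1, start + len - 2)
    label <- gsub(":", COLON_TOKEN, label, fixed = TRUE)
    out <- paste0(substr(out, 1, start - 1), label, substr(out, start + len, nchar(out)))
  }
  out
}

#' Write a tree to newick
#'
#' Labels containing a colon (the `species:protein_id` scheme) are
#' single-quoted so the output stays valid newick.
#'
#' @param tree A `phylo` object.
#' @param path Output path; when `NULL` the newick string is returned.
#' @return The newick string, invisibly when written to `path`.
#' @export
write_newick_tree <- function(tree, path = NULL) {
  tmp <- tree
  needs_quote <- grepl(":", tmp$tip.label, fixed = TRUE)
  tmp$tip.label <- gsub(":", COLON_TOKEN, tmp$tip.label, fixed = TRUE)
  text <- ape::write.tree(tmp)
  for (lab in unique(tmp$tip.label[needs_quote])) {
    text <- gsub(
      paste0("(?<=[(,])", escape_regex(lab), "(?=[:,)])"),
      paste0("'", gsub(COLON_TOKEN, ":", lab, fixed = TRUE), "'"),
      text,
      perl = TRUE
    )
  }
  text <- gsub(COLON_TOKEN, ":", text, fixed = TRUE)
  if (is.null(path)) {
    return(text)
  }
  writeLines(text, path)
  invisible(text)
}
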