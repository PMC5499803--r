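#' Alignment scoring configuration
#'
#' Bundles the substitution scores and affine gap penalties used by every
#' alignment in the pipeline (local candidate-vs-reference searches, the
#' all-vs-all similarity graph, greedy identity clustering and the global
#' alignments behind tree distances).
#'
#' Gap convention: a gap of length L costs `gap_open + (L - 1) * gap_extend`,
#' i.e. the opening charge already covers the first gapped position.  Both
#' penalties are given as negative numbers.
#'
#' @param substitution Either the name of a bundled substitution matrix
#'   (currently `"BLOSUM62"`) or a square numeric matrix with amino-acid
#'   dimnames.  Ignored when `match` is given.
#' @param match,mismatch Optional simple scoring: build a matrix with `match`
#'   on the diagonal and `mismatch` elsewhere.  `X` scores 0 against
#'   everything; `*` scores `mismatch` against everything (including itself).
#' @param gap_open Penalty for a gap of length 1 (negative, default -10).
#' @param gap_extend Penalty per additional gapped position (negative,
#'   default -1).
#' @return An object of class `align_config`.
#' @export
#' @examples
#' align_config(match = 2, mismatch = -1, gap_open = -2, gap_extend = -2)
align_config <- function(substitution = "BLOSUM62", match = NULL, mismatch = -1,
                         gap_open = -10, gap_extend = -1) {
  if (!is.null(match)) {
    letters <- AA_ALLOWED
    mat <- matrix(mismatch, length(letters), length(letters),
      dimnames = list(letters, letters)
    )
    diag(mat) <- match
    mat["X", ] <- 0
    mat[, "X"] <- 0
    mat["*", ] <- mismatch
    mat[, "*"] <- mismatch
  } else if (is.character(substitution)) {
    if (!identical(substitution, "BLOSUM62")) {
      abort("only the bundled 'BLOSUM62' matrix is available by name")
    }
    mat <- get_blosum62()
  } else {
    mat <- as.matrix(substitution)
    if (is.null(dimnames(mat)) || !identical(rownames(mat), colnames(mat))) {
      abort("a custom substitution matrix needs identical row and column names")
    }
  }
  if (gap_open > 0 || gap_extend > 0) {
    abort("gap penalties must be <= 0")
  }
  structure(
    list(matrix = mat, gap_open = gap_open, gap_extend = gap_extend),
    class = "align_config"
  )
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Translate the package gap convention (open + (L-1) * extend) into the
# Biostrings one (opening + L * extension, positive penalties).
biostrings_gaps <- function(config) {
  list(
    opening = -config$gap_open + config$gap_extend,
    extension = -config$gap_extend
  )
}

# Vectorised pairwise alignment of many patterns against one subject.
# Returns per-pattern score / match counts / spans.  type is "local" or
# "global"; scores_only skips the traceback for speed.
aln_many <- function(patterns, subject, config, type = "local",
                     scores_only = FALSE) {
  gaps <- biostrings_gaps(config)
  pat <- Biostrings::AAStringSet(patterns)
  subj <- Biostrings::AAString(subject)
  if (scores_only) {
    return(Biostrings::pairwiseAlignment(
      pat, subj,
      type = type, substitutionMatrix = config$matrix,
      gapOpening = gaps$opening, gapExtension = gaps$extension,
      scoreOnly = TRUE
    ))
  }
  aln <- Biostrings::pairwiseAlignment(
    pat, subj,
    type = type, substitutionMatrix = config$matrix,
    gapOpening = gaps$opening, gapExtension = gaps$extension
  )
  p <- Biostrings::pattern(aln)
  s <- Biostrings::subject(aln)
  tibble(
    score = Biostrings::score(aln),
    n_ident = Biostrings::nmatch(aln),
    n_mismatch = Biostrings::nmismatch(aln),
    qstart = BiocGenerics::start(p),
    qend = BiocGenerics::end(p),
    sstart = BiocGenerics::start(s),
    send = BiocGenerics::end(s)
  )
}

# Batch Smith-Waterman scores for index pairs over one sequence vector,
# through the compiled Gotoh kernel.  Same scoring convention as
# local_align(); used where only scores are needed (the all-vs-all graph).
sw_scores <- function(seqs, i_idx, j_idx, config = align_config()) {
  alphabet <- rownames(config$matrix)
  enc <- map(strsplit(seqs, "", fixed = TRUE), function(chars) {
    idx <- match(chars, alphabet)
    if (anyNA(idx)) {
      abort(paste0(
        "residue(s) outside the substitution alphabet: ",
        paste(unique(chars[is.na(idx)]), collapse = ", ")
      ))
    }
    as.integer(idx - 1L)
  })
  sw_score_pairs(
    enc, as.integer(i_idx), as.integer(j_idx),
    config$matrix, config$gap_open, config$gap_extend
  )
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment under affine gap penalties, reporting the
#' summary statistics the RFL screen filters on: percent identity over
#' aligned (non-gap) columns, and query coverage as the fraction of the
#' query spanned by the alignment.
#'
#' @param query,subject Amino-acid strings (non-empty).
#' @param config An [align_config()].
#' @return A one-row tibble with columns `score`, `pct_identity`,
#'   `query_cov`, `qstart`, `qend`, `sstart`, `send`, `n_ident`,
#'   `aligned_cols`.  When no alignment scores above zero, `score` is 0 and
#'   the remaining columns are `NA` (coverage 0).
#' @export
#' @examples
#' local_align("AWGHE", "AWHE",
#'   config = align_config(match = 2, mismatch = -1, gap_open = -2, gap_extend = -2)
#' )
local_align <- function(query, subject, config = align_config()) {
  if (!nzchar(query) || !nzchar(subject)) {
    abort("local_align() needs non-empty sequences")
  }
  st <- aln_many(query, subject, config, type = "local")
  aligned <- st$n_ident + st$n_mismatch
  if (st$score <= 0 || aligned == 0) {
    return(tibble(
      score = 0, pct_identity = NA_real_, query_cov = 0,
      qstart = NA_integer_, qend = NA_integer_,
      sstart = NA_integer_, send = NA_integer_,
      n_ident = 0L, aligned_cols = 0L
    ))
  }
  tibble(
    score = st$score,
    pct_identity = 100 * st$n_ident / aligned,
    query_cov = 100 * (st$qend - st$qstart + 1) / nchar(query),
    qstart = st$qstart, qend = st$qend,
    sstart = st$sstart, send = st$send,
    n_ident = st$n_ident, aligned_cols = as.integer(aligned)
  )
}
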