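#' Round half away from zero
#'
#' Rounds `x` to `digits` decimal places with ties going up (0.5 -> 1),
#' unlike [base::round()] which rounds half to even.  Used wherever the
#' package reports integer percentages or kilobase spans, so that e.g. a
#' 319,911 bp region prints as 320 kb.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_up(0.5)       # 1
#' round_half_up(319.911)   # 320
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Validate a table of protein records
#'
#' Checks the invariants every downstream stage relies on: unique non-empty
#' ids, non-empty species tags, and sequences restricted to the twenty
#' canonical amino acids plus `X` (unknown) and `*` (stop).
#'
#' @param records A data frame with columns `id`, `species`, `seq`.
#' @return `records` as a tibble, invisibly validated (columns `id`,
#'   `species`, `seq`, `locus_id`).
#' @export
validate_records <- function(records) {
  records <- as_tibble(records)
  required <- c("id", "species", "seq")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort(paste0("records is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"locus_id" %in% names(records)) {
    records$locus_id <- NA_character_
  }
  if (any(is.na(records$id) | records$id == "")) {
    abort("every record must have a non-empty id")
  }
  dup <- records$id[duplicated(records$id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate record id(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (any(is.na(records$species) | records$species == "")) {
    bad <- records$id[is.na(records$species) | records$species == ""]
    abort(paste0("record(s) without a species tag: ", paste(bad, collapse = ", ")))
  }
  for (i in seq_len(nrow(records))) {
    check_residues(records$seq[i], records$id[i])
  }
  records[, c("id", "species", "seq", "locus_id")]
}

check_residues <- function(seq, id) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA_ALLOWED))
  if (length(bad) > 0) {
    abort(sprintf(
      "record '%s' has illegal residue '%s' at position %d",
      id, chars[bad[1]], bad[1]
    ))
  }
  invisible(TRUE)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# Split "species:protein_id" leaf labels at the first colon.
split_leaf_label <- function(labels) {
  species <- sub(":.*$", "", labels)
  protein <- sub("^[^:]*:", "", labels)
  no_colon <- !grepl(":", labels, fixed = TRUE)
  species[no_colon] <- NA_character_
  protein[no_colon] <- labels[no_colon]
  tibble(label = labels, species = species, protein_id = protein)
}
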