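#' Classify a motif track into the P or PLS subfamily
#'
#' A protein qualifies as a PPR when its track carries at least `min_motifs`
#' P/L/S repeat hits.  PPRs with at least one L and one S repeat belong to
#' the PLS subfamily; all others are P-subfamily (arrays built almost
#' entirely from the canonical 35-aa P repeat).
#'
#' @param track A track tibble (see [assemble_track()]).
#' @param min_motifs Minimum number of P/L/S hits for PPR status
#'   (default 2).
#' @return One of `"NOT_PPR"`, `"P"`, `"PLS"`.
#' @export
classify_architecture <- function(track, min_motifs = 2) {
  repeats <- track$profile[track$profile %in% PPR_REPEAT_CLASSES]
  if (length(repeats) < min_motifs) {
    return("NOT_PPR")
  }
  if (any(repeats == "L") && any(repeats == "S")) "PLS" else "P"
}

#' Resolve the C-terminal subclass of a PLS protein
#'
#' PLS proteins are subclassified by the RNA-editing-associated C-terminal
#' domains, with precedence DYW > E+ > E.  A qualifying domain hit must lie
#' C-terminal to the last P/L/S repeat; hits upstream of the repeat array
#' are ignored with a warning (they cannot be terminal domains).
#'
#' @param track A track tibble whose architecture is PLS.
#' @return One of `"PLS_plain"`, `"E"`, `"Eplus"`, `"DYW"`.
#' @export
detect_cterminal_class <- function(track) {
  repeats <- track[track$profile %in% PPR_REPEAT_CLASSES, ]
  cterm <- track[!(track$profile %in% PPR_REPEAT_CLASSES), ]
  if (nrow(cterm) == 0) {
    return("PLS_plain")
  }
  last_repeat_end <- if (nrow(repeats) > 0) max(repeats$end) else 0L
  misplaced <- cterm$start <= last_repeat_end
  if (any(misplaced)) {
    warn(sprintf(
      "ignoring %d C-terminal domain hit(s) upstream of the repeat array%s",
      sum(misplaced),
      if (is.na(track$protein_id[1])) "" else paste0(" (", track$protein_id[1], ")")
    ))
    cterm <- cterm[!misplaced, ]
  }
  if (any(cterm$profile == "DYW")) {
    "DYW"
  } else if (any(cterm$profile == "Eplus")) {
    "Eplus"
  } else if (any(cterm$profile == "E")) {
    "E"
  } else {
    "PLS_plain"
  }
}

#' Flag likely pseudogenes
#'
#' A record is flagged when its translation looks truncated or interrupted:
#' it does not start with Met, a stop codon (`*`) occurs before the end of
#' the last motif hit, or the last motif hit runs into the final 5 residues
#' of the sequence (no trailing region, i.e. truncated mid-motif).
#'
#' @param record A one-row record tibble, or an amino-acid string.
#' @param track The protein's motif track.
#' @return Logical.
#' @export
flag_pseudogene <- function(record, track) {
  seq <- if (is.character(record)) record else record$seq[1]
  if (substr(seq, 1, 1) != "M") {
    return(TRUE)
  }
  if (nrow(track) == 0) {
    return(FALSE)
  }
  last_end <- max(track$end)
  stops <- which(strsplit(seq, "", fixed = TRUE)[[1]] == "*")
  if (any(stops <= last_end)) {
    return(TRUE)
  }
  if (nchar(seq) - last_end < 5) {
    return(TRUE)
  }
  FALSE
}

#' Classify every protein in a record set
#'
#' Composes [classify_architecture()], [detect_cterminal_class()] and
#' [flag_pseudogene()] over a record table and its motif tracks.
#'
#' @param records A record tibble.
#' @param tracks A track tibble covering the same proteins (from
#'   [assemble_tracks()]); a record with no rows in `tracks` is treated as
#'   having an empty track.
#' @param min_motifs Passed to [classify_architecture()].
#' @return A tibble with one row per record: `protein_id`, `species`,
#'   `subclass` (`NOT_PPR`, `P`, `PLS_plain`, `E`, `Eplus`, `DYW`),
#'   `n_motifs` (P/L/S hit count), `motif_string`, `pseudogene`.
#' @export
classify_all <- function(records, tracks, min_motifs = 2) {
  records <- validate_records(records)
  if (nrow(records) == 0) {
    return(tibble(
      protein_id = character(), species = character(),
      subclass = character(), n_motifs = integer(),
      motif_string = character(), pseudogene = logical()
    ))
  }
  if (nrow(tracks) > 0) {
    unknown <- setdiff(unique(tracks$protein_id), records$id)
    if (length(unknown) > 0) {
      abort(paste0(
        "tracks refer to unknown record id(s): ",
        paste(unknown, collapse = ", ")
      ))
    }
  }
  rows <- map(seq_len(nrow(records)), function(i) {
    id <- records$id[i]
    track <- tracks[tracks$protein_id == id, , drop = FALSE]
    arch <- classify_architecture(track, min_motifs = min_motifs)
    subclass <- if (arch == "PLS") detect_cterminal_class(track) else arch
    tibble(
      protein_id = id,
      species = records$species[i],
      subclass = subclass,
      n_motifs = sum(track$profile %in% PPR_REPEAT_CLASSES),
      motif_string = motif_string(track),
      pseudogene = flag_pseudogene(records[i, ], track)
    )
  })
  bind_rows(rows)
}

#' Summarise a classified protein set
#'
#' Counts per subclass with integer percentages (rounded half-up, computed
#' on the PPR total), the derived PLS-subfamily and editing-class totals,
#' and the mean P/L/S motif count of a highlighted subset (e.g. RFL
#' candidates) versus all other PPRs, to 1 decimal.
#'
#' @param classified Output of [classify_all()].
#' @param highlight_ids Optional protein ids to contrast against the rest;
#'   every id must be present in `classified`.
#' @return A `ppr_class_summary`: list with `counts` (tibble `subclass`,
#'   `n`, `pct`), `total_ppr`, `pls_total`, `editing_total`,
#'   `mean_motifs_highlight`, `mean_motifs_rest`.
#' @export
summarize_classes <- function(classified, highlight_ids = NULL) {
  if (!is.null(highlight_ids)) {
    missing <- setdiff(highlight_ids, classified$protein_id)
    if (length(missing) > 0) {
      abort(paste0(
        "highlight id(s) not in classified set: ",
        paste(missing, collapse = ", ")
      ))
    }
  }
  ppr <- dplyr::filter(classified, .data$subclass != "NOT_PPR")
  total <- nrow(ppr)
  subclasses <- setdiff(SUBCLASS_LEVELS, "NOT_PPR")
  counts <- tibble(
    subclass = subclasses,
    n = map_int(subclasses, function(s) sum(ppr$subclass == s))
  )
  counts$pct <- if (total > 0) {
    round_half_up(100 * counts$n / total)
  } else {
    rep(NA_real_, nrow(counts))
  }
  editing_total <- sum(counts$n[counts$subclass %in% c("E", "Eplus", "DYW")])
  pls_total <- editing_total + counts$n[counts$subclass == "PLS_plain"]
  mean_hl <- mean_rest <- NA_real_
  if (!is.null(highlight_ids)) {
    hl <- ppr$protein_id %in% highlight_ids
    if (any(hl)) mean_hl <- round_half_up(mean(ppr$n_motifs[hl]), 1)
    if (any(!hl)) mean_rest <- round_half_up(mean(ppr$n_motifs[!hl]), 1)
  }
  structure(
    list(
      counts = counts,
      total_ppr = total,
      pls_total = as.integer(pls_total),
      editing_total = as.integer(editing_total),
      mean_motifs_highlight = mean_hl,
      mean_motifs_rest = mean_rest
    ),
    class = "ppr_class_summary"
  )
}

#' @export
print.ppr_class_summary <- function(x, ...) {
  cat(sprintf("PPR classification summary: %d PPR proteins\n", x$total_ppr))
  df <- x$counts
  pct <- ifelse(is.na(df$pct), ".", paste0(df$pct, "%"))
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-10s %5d  %s\n", df$subclass[i], df$n[i], pct[i]))
  }
  cat(sprintf(
    "  PLS subfamily total %d; editing classes (E/E+/DYW) %d\n",
    x$pls_total, x$editing_total
  ))
  if (!is.na(x$mean_motifs_highlight)) {
    cat(sprintf(
      "  mean P/L/S motifs: %.1f (highlighted) vs %.1f (rest)\n",
      x$mean_motifs_highlight, x$mean_motifs_rest
    ))
  }
  invisible(x)
}

#' @rdname summarize_classes
#' @param x A `ppr_class_summary`.
#' @param ... Unused.
#' @export
tidy.ppr_class_summary <- function(x, ...) {
  x$counts
}

#' @rdname summarize_classes
#' @export
glance.ppr_class_summary <- function(x, ...) {
  tibble(
    total_ppr = x$total_ppr,
    n_P = x$counts$n[x$counts$subclass == "P"],
    pls_total = x$pls_total,
    editing_total = x$editing_total,
    mean_motifs_highlight = x$mean_motifs_highlight,
    mean_motifs_rest = x$mean_motifs_rest
  )
}

#' Bar chart of subclass counts
#'
#' @param object A `ppr_class_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppr_class_summary <- function(object, ...) {
  df <- mutate(object$counts,
    subclass = factor(.data$subclass, levels = setdiff(SUBCLASS_LEVELS, "NOT_PPR"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subclass, y = .data$n)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(
      x = NULL, y = "proteins",
      title = sprintf("PPR subclasses (n = %d)", object$total_ppr)
    ) +
    ggplot2::theme_minimal()
}
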