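#' Bundled motif consensus templates
#'
#' Fixed consensus strings for the six motif classes: the canonical 35-aa
#' P repeat, the long (36 aa) L and short (31 aa) S variants, and the three
#' C-terminal domains E, E+ and DYW (the latter ending in the eponymous
#' Asp-Tyr-Trp triplet).  These are synthetic sequences: arbitrary but
#' frozen, they seed both the default scanning profiles and the protein
#' simulator, so scan/classify tests are closed-loop.
#'
#' @return Named character vector with elements `P`, `L`, `S`, `E`,
#'   `Eplus`, `DYW`.
#' @export
motif_templates <- function() {
  c(
    P     = "GLMDRAILYYETRIRMDAIHGDEVINHSGTDSHCT",
    L     = "DMTGSQHCTTIPEVPFLRNPNASSMRLNHHHNHIPY",
    S     = "QYNVCMLCAHRAEAVWIPMTKPMWVYSIMRN",
    E     = "VISSMKAWQFYRYHQASTSRTWENMYCPDDNCPT",
    Eplus = "YNLFTKTDPDWWSHEHHELHDSQKNVEFANDTDCPLIDCVGTCFKNWS",
    DYW   = "HMLAIANSVRMWGRVQADYSCQAYFEYARAPDRYKNDMFDYW"
  )
}

#' Build a position-specific log-odds profile from an aligned block
#'
#' Each profile column `c` scores residue `a` as
#' `log2(((count_ca + w * bg_a) / (N + w)) / bg_a)` bits, i.e. observed
#' frequencies smoothed towards the background with pseudocount weight `w`.
#' The acceptance threshold for a scanning window defaults to a fixed
#' fraction of the maximum attainable window score.
#'
#' @param aligned_block Character vector of >= 2 equal-length, gapless
#'   amino-acid strings.
#' @param name Motif class name (`P`, `L`, `S`, `E`, `Eplus` or `DYW`).
#' @param pseudocount_weight Total pseudocount weight `w` (default 1).
#' @param background Named numeric vector of background frequencies for the
#'   20 canonical residues (default uniform 0.05).  Must be positive.
#' @param threshold_frac Window-score threshold as a fraction of the maximum
#'   attainable score (default 0.35).
#' @return A `motif_profile` object: list with `name`, `length`, `logodds`
#'   (length x 20 matrix of bits), `threshold` and `max_score`.
#' @export
#' @examples
#' build_profile(c("AC", "AC", "AD"), name = "P")
build_profile <- function(aligned_block, name, pseudocount_weight = 1,
                          background = NULL, threshold_frac = 0.35) {
  if (length(aligned_block) < 2) {
    abort("build_profile() needs at least 2 sequences")
  }
  lens <- nchar(aligned_block)
  if (length(unique(lens)) != 1) {
    abort("aligned_block sequences must all have the same length")
  }
  if (is.null(background)) {
    background <- setNames(rep(1 / 20, 20), AA_CANONICAL)
  }
  background <- background[AA_CANONICAL]
  if (anyNA(background) || any(background <= 0)) {
    abort("background must give a positive frequency for all 20 residues")
  }
  len <- lens[1]
  n <- length(aligned_block)
  w <- pseudocount_weight
  chars <- do.call(rbind, strsplit(toupper(aligned_block), "", fixed = TRUE))
  if (any(!(chars %in% AA_CANONICAL))) {
    abort("aligned_block must be gapless and use only the 20 canonical residues")
  }
  logodds <- matrix(0, nrow = len, ncol = 20,
    dimnames = list(NULL, AA_CANONICAL)
  )
  for (pos in seq_len(len)) {
    counts <- table(factor(chars[, pos], levels = AA_CANONICAL))
    freq <- (as.numeric(counts) + w * background) / (n + w)
    logodds[pos, ] <- log2(freq / background)
  }
  max_score <- sum(apply(logodds, 1, max))
  structure(
    list(
      name = name, length = len, logodds = logodds,
      threshold = threshold_frac * max_score, max_score = max_score
    ),
    class = "motif_profile"
  )
}

#' @export
print.motif_profile <- function(x, ...) {
  cat(sprintf(
    "<motif_profile %s> %d columns, max window score %.1f bits, threshold %.1f\n",
    x$name, x$length, x$max_score, x$threshold
  ))
  invisible(x)
}

#' Default scanning profiles for the six motif classes
#'
#' Profiles are built from a deterministic set of noisy samples of the
#' bundled templates (20 samples per class, 10% residue substitution,
#' fixed seed), giving each column a dominant consensus residue with
#' realistic minor counts.
#'
#' @param threshold_frac Window-score threshold fraction passed to
#'   [build_profile()].
#' @return Named list of `motif_profile` objects.
#' @export
default_profiles <- function(threshold_frac = 0.35) {
  templates <- motif_templates()
  with_seed(990101, {
    profiles <- imap(as.list(templates), function(tmpl, nm) {
      samples <- map_chr(seq_len(20), function(i) mutate_residues(tmpl, 0.10))
      build_profile(samples, name = nm, threshold_frac = threshold_frac)
    })
  })
  profiles
}

# Substitute each residue with probability `rate`, drawing the replacement
# uniformly from the 19 other canonical residues.
mutate_residues <- function(seq, rate) {
  if (rate <= 0) {
    return(seq)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- map_chr(chars[hit], function(old) {
      sample(setdiff(AA_CANONICAL, old), 1)
    })
  }
  paste(chars, collapse = "")
}

#' Serialise motif profiles to TSV
#'
#' One file per motif class (`<name>.tsv`), a header comment carrying the
#' threshold, then one row per profile column with the 20 residue scores.
#'
#' @param profiles Named list of `motif_profile` objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_profiles <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in profiles) {
    path <- file.path(dir, paste0(p$name, ".tsv"))
    con <- file(path, "w")
    writeLines(sprintf("# motif=%s threshold=%.10g", p$name, p$threshold), con)
    writeLines(paste(c("pos", AA_CANONICAL), collapse = "\t"), con)
    for (i in seq_len(p$length)) {
      writeLines(paste(c(i, sprintf("%.10g", p$logodds[i, ])), collapse = "\t"), con)
    }
    close(con)
  }
  invisible(dir)
}

#' Read motif profiles written by [write_profiles()]
#'
#' @param dir Directory containing `<name>.tsv` profile files.
#' @return Named list of `motif_profile` objects.
#' @export
read_profiles <- function(dir) {
  paths <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(paths) == 0) {
    abort(paste0("no profile TSVs found in ", dir))
  }
  profiles <- map(paths, function(path) {
    lines <- readLines(path, warn = FALSE)
    meta <- lines[1]
    name <- sub("^# motif=(\\S+).*$", "\\1", meta)
    threshold <- as.numeric(sub("^.*threshold=(\\S+).*$", "\\1", meta))
    body <- utils::read.table(
      text = lines[-1], header = TRUE, sep = "\t", check.names = FALSE
    )
    logodds <- as.matrix(body[, AA_CANONICAL])
    dimnames(logodds) <- list(NULL, AA_CANONICAL)
    structure(
      list(
        name = name, length = nrow(logodds), logodds = logodds,
        threshold = threshold, max_score = sum(apply(logodds, 1, max))
      ),
      class = "motif_profile"
    )
  })
  setNames(profiles, map_chr(profiles, "name"))
}

#' Scan one protein with one profile
#'
#' Ungapped fixed-length sliding window: every window whose summed log-odds
#' score meets the profile threshold is reported, overlaps included
#' (overlap resolution happens later in [assemble_track()]).  Non-canonical
#' residues (`X`, `*`) contribute 0 bits per column, i.e. they score as
#' background.
#'
#' @param profile A `motif_profile`.
#' @param record A one-row record tibble, or a plain amino-acid string.
#' @param threshold Optional override of the profile threshold (bits).
#' @return A tibble of hits: `protein_id`, `profile`, `start`, `end`,
#'   `score` (empty when the sequence is shorter than the profile).
#' @export
scan_profile <- function(profile, record, threshold = NULL) {
  if (is.character(record)) {
    record <- tibble(id = NA_character_, seq = record)
  }
  seq <- record$seq[1]
  id <- record$id[1]
  threshold <- threshold %||% profile$threshold
  scores <- window_scores(profile, seq)
  keep <- which(scores >= threshold)
  len <- profile$length
  name <- profile$name
  tibble(
    protein_id = rep(id, length(keep)),
    profile = rep(name, length(keep)),
    start = as.integer(keep),
    end = as.integer(keep + len - 1L),
    score = scores[keep]
  )
}

# Scores of every window position (1 .. n - L + 1); numeric(0) when the
# sequence is shorter than the profile.
window_scores <- function(profile, seq) {
  len <- profile$length
  n <- nchar(seq)
  if (n < len) {
    return(numeric(0))
  }
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], AA_CANONICAL)
  # per-position score vectors; unknown residues score 0
  n_win <- n - len + 1L
  total <- numeric(n_win)
  for (col in seq_len(len)) {
    res <- idx[col:(col + n_win - 1L)]
    sc <- ifelse(is.na(res), 0, profile$logodds[col, ][res])
    total <- total + sc
  }
  total
}

#' Scan many proteins with many profiles
#'
#' @param records A record tibble (see [read_fasta()]).
#' @param profiles Named list of `motif_profile`s (default
#'   [default_profiles()]).
#' @return A tibble of raw (possibly overlapping) hits across all records
#'   and profiles.
#' @export
scan_proteins <- function(records, profiles = default_profiles()) {
  records <- validate_records(records)
  out <- vector("list", nrow(records) * length(profiles))
  k <- 1L
  for (i in seq_len(nrow(records))) {
    for (p in profiles) {
      out[[k]] <- scan_profile(p, records[i, ])
      k <- k + 1L
    }
  }
  bind_rows(out)
}

#' Resolve overlapping hits into a maximal-score motif track
#'
#' Picks the subset of pairwise non-overlapping hits with the largest total
#' score (weighted interval scheduling by dynamic programming), so each
#' protein gets a unique, reproducible motif architecture.  Ties are broken
#' in favour of more hits, then leftmost starts, then profile-name order
#' P < L < S < E < Eplus < DYW.
#'
#' @param hits A hit tibble for a single protein (as from
#'   [scan_proteins()] or [read_domtblout()]).
#' @return The selected hits, sorted by `start`, with attribute
#'   `total_score`.
#' @export
assemble_track <- function(hits) {
  if (nrow(hits) == 0) {
    out <- hits
    attr(out, "total_score") <- 0
    return(out)
  }
  if (length(unique(hits$protein_id)) > 1) {
    abort("assemble_track() expects hits from a single protein")
  }
  prof_rank <- match(hits$profile, MOTIF_CLASSES)
  ord <- order(hits$end, hits$start, prof_rank)
  hits <- hits[ord, ]
  prof_rank <- prof_rank[ord]
  n <- nrow(hits)
  # best[[i]]: optimal selection among hits 1..i (indices into `hits`)
  # value[i], count[i] track the score and size of that selection
  value <- numeric(n + 1)
  count <- integer(n + 1)
  sel <- vector("list", n + 1)
  sel[[1]] <- integer(0)
  for (i in seq_len(n)) {
    # last hit ending strictly before hits$start[i]
    j <- max(c(0L, which(hits$end[seq_len(i - 1)] < hits$start[i])))
    take_value <- value[j + 1] + hits$score[i]
    take_count <- count[j + 1] + 1L
    take_sel <- c(sel[[j + 1]], i)
    keep_value <- value[i]
    keep_count <- count[i]
    keep_sel <- sel[[i]]
    if (prefer_selection(
      take_value, take_count, take_sel,
      keep_value, keep_count, keep_sel,
      hits, prof_rank
    )) {
      value[i + 1] <- take_value
      count[i + 1] <- take_count
      sel[[i + 1]] <- take_sel
    } else {
      value[i + 1] <- keep_value
      count[i + 1] <- keep_count
      sel[[i + 1]] <- keep_sel
    }
  }
  chosen <- sel[[n + 1]]
  out <- hits[chosen[order(hits$start[chosen])], ]
  attr(out, "total_score") <- sum(out$score)
  out
}

# TRUE when selection a beats selection b under the tie-break order:
# higher score, then more hits, then lexicographically smaller start
# vector, then smaller profile-rank vector.
prefer_selection <- function(va, ca, sa, vb, cb, sb, hits, prof_rank) {
  if (abs(va - vb) > 1e-9) {
    return(va > vb)
  }
  if (ca != cb) {
    return(ca > cb)
  }
  sa_ord <- sa[order(hits$start[sa])]
  sb_ord <- sb[order(hits$start[sb])]
  for (k in seq_len(min(length(sa_ord), length(sb_ord)))) {
    if (hits$start[sa_ord[k]] != hits$start[sb_ord[k]]) {
      return(hits$start[sa_ord[k]] < hits$start[sb_ord[k]])
    }
    if (prof_rank[sa_ord[k]] != prof_rank[sb_ord[k]]) {
      return(prof_rank[sa_ord[k]] < prof_rank[sb_ord[k]])
    }
  }
  FALSE
}

#' Assemble tracks for every protein in a hit table
#'
#' @param hits A hit tibble covering any number of proteins.
#' @return A tibble of non-overlapping hits across proteins; per-protein
#'   total scores are recomputable as the per-protein score sums.
#' @export
assemble_tracks <- function(hits) {
  if (nrow(hits) == 0) {
    return(hits)
  }
  hits |>
    group_by(.data$protein_id) |>
    dplyr::group_modify(function(df, key) {
      assemble_track(mutate(df, protein_id = key$protein_id))[
        ,
        c("profile", "start", "end", "score")
      ]
    }) |>
    ungroup()
}

# Compact architecture string for report tables, e.g. "PLSPLS-E".
motif_string <- function(track) {
  if (nrow(track) == 0) {
    return("")
  }
  track <- arrange(track, .data$start)
  sym <- c(P = "P", L = "L", S = "S", E = "E", Eplus = "+", DYW = "D")
  repeats <- track$profile %in% PPR_REPEAT_CLASSES
  body <- paste(sym[track$profile[repeats]], collapse = "")
  cterm <- track$profile[!repeats]
  if (length(cterm) > 0) {
    paste0(body, "-", paste(cterm, collapse = "-"))
  } else {
    body
  }
}
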