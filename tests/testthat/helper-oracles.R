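# Independent oracles used to cross-check the package implementations.
# Each is written as plainly as possible and shares no code with R/.

# Affine-gap Smith-Waterman score by explicit Gotoh DP.  Gap convention
# matches the package: a gap of length L costs open + (L - 1) * extend.
oracle_local_score <- function(query, subject, match = 2, mismatch = -1,
                               gap_open = -2, gap_extend = -2) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(q)
  m <- length(s)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1) # gap in subject (consumes query)
  Iy <- matrix(NEG, n + 1, m + 1) # gap in query (consumes subject)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (q[i - 1] == s[j - 1]) match else mismatch
      M[i, j] <- sub + max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1], 0)
      Ix[i, j] <- max(M[i - 1, j] + gap_open, Ix[i - 1, j] + gap_extend)
      Iy[i, j] <- max(M[i, j - 1] + gap_open, Iy[i, j - 1] + gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Optimal non-overlapping hit subset by exhaustive enumeration (<= 15 hits).
oracle_best_track_score <- function(hits) {
  n <- nrow(hits)
  if (n == 0) {
    return(0)
  }
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) == 0) next
    ord <- idx[order(hits$start[idx])]
    valid <- length(ord) == 1 ||
      all(hits$end[ord[-length(ord)]] < hits$start[ord[-1]])
    if (valid) best <- max(best, sum(hits$score[ord]))
  }
  best
}

# Independent dense Markov-clustering iteration with explicit loops.
oracle_mcl_membership <- function(adj, inflation = 1.5, prune = 1e-5,
                                  tol = 1e-6, max_iter = 100) {
  n <- nrow(adj)
  A <- adj
  for (v in seq_len(n)) {
    mx <- max(A[, v])
    A[v, v] <- if (mx > 0) mx else 1
  }
  for (v in seq_len(n)) A[, v] <- A[, v] / sum(A[, v])
  for (it in seq_len(max_iter)) {
    B <- A %*% A
    B <- B^inflation
    for (v in seq_len(n)) B[, v] <- B[, v] / sum(B[, v])
    B[B < prune] <- 0
    for (v in seq_len(n)) B[, v] <- B[, v] / sum(B[, v])
    delta <- max(abs(B - A))
    A <- B
    if (delta < tol) break
  }
  # connected components of the non-zero structure, by hand (BFS)
  nz <- (A > 0) | (t(A) > 0)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cur <- cur + 1L
    queue <- v
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- cur
      queue <- c(queue, which(nz[u, ] & is.na(comp)))
    }
  }
  comp
}

# Least-squares residuals by the normal equations.
oracle_ls_residuals <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(y - X %*% beta)
}

# Adjusted Rand index straight from the contingency-table formula.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Random amino-acid records for round-trip and property tests.
random_records <- function(n, len_range = c(20, 60), species = "spX",
                           prefix = "r") {
  aa <- c(
    "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
  )
  tibble::tibble(
    id = paste0(species, "|", prefix, seq_len(n)),
    species = species,
    seq = vapply(seq_len(n), function(i) {
      paste(sample(aa, sample(len_range[1]:len_range[2], 1), replace = TRUE),
        collapse = ""
      )
    }, character(1)),
    locus_id = NA_character_
  )
}

make_hits <- function(starts, ends, scores, profiles = NULL, id = "p1") {
  tibble::tibble(
    protein_id = id,
    profile = profiles %||% rep("P", length(starts)),
    start = as.integer(starts),
    end = as.integer(ends),
    score = as.numeric(scores)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
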