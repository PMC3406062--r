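# Independent oracles used across the suite. None of these share code with
# the package's C++ aligner: a plain-R Gotoh DP (score only), an exhaustive
# enumeration over all alignments for tiny pairs, Biostrings as a third
# party cross-check, and brute-force tallies for prevalence/triage.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# plain-R affine-gap DP, score only (independent re-implementation)
oracle_align_score <- function(a, b, p = align_params()) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A)
  n <- length(B)
  NEG <- -1e18
  H <- matrix(NEG, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)  # gap in a (consumes b)
  F <- matrix(NEG, m + 1, n + 1)  # gap in b (consumes a)
  H[1, 1] <- 0
  for (j in seq_len(n)) {
    g <- if (p$end_gaps_free) 0 else p$gap_open + (j - 1) * p$gap_extend
    H[1, j + 1] <- g
    if (!p$end_gaps_free) E[1, j + 1] <- g
  }
  for (i in seq_len(m)) {
    g <- if (p$end_gaps_free) 0 else p$gap_open + (i - 1) * p$gap_extend
    H[i + 1, 1] <- g
    if (!p$end_gaps_free) F[i + 1, 1] <- g
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] + p$gap_open,
                             E[i + 1, j] + p$gap_extend)
      F[i + 1, j + 1] <- max(H[i, j + 1] + p$gap_open,
                             F[i, j + 1] + p$gap_extend)
      s <- if (A[i] == B[j]) p$match else p$mismatch
      H[i + 1, j + 1] <- max(H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
    }
  }
  if (p$end_gaps_free) {
    max(H[m + 1, ], H[, n + 1])
  } else {
    H[m + 1, n + 1]
  }
}

# score one explicit gapped alignment (terminal gap runs free if configured)
oracle_score_columns <- function(ca, cb, p = align_params()) {
  L <- length(ca)
  free <- rep(FALSE, L)
  if (p$end_gaps_free) {
    for (row in list(ca, cb)) {
      ng <- which(row != "-")
      if (length(ng) > 0) {
        if (ng[1] > 1) free[seq_len(ng[1] - 1)] <-
            free[seq_len(ng[1] - 1)] | row[seq_len(ng[1] - 1)] == "-"
        if (ng[length(ng)] < L) {
          idx <- (ng[length(ng)] + 1):L
          free[idx] <- free[idx] | row[idx] == "-"
        }
      } else {
        free <- free | row == "-"
      }
    }
  }
  s <- 0
  in_gap_a <- FALSE
  in_gap_b <- FALSE
  for (k in seq_len(L)) {
    if (ca[k] != "-" && cb[k] != "-") {
      s <- s + if (ca[k] == cb[k]) p$match else p$mismatch
      in_gap_a <- in_gap_b <- FALSE
    } else if (ca[k] == "-") {
      if (!free[k]) {
        s <- s + if (in_gap_a) p$gap_extend else p$gap_open
      }
      in_gap_a <- TRUE
      in_gap_b <- FALSE
    } else {
      if (!free[k]) {
        s <- s + if (in_gap_b) p$gap_extend else p$gap_open
      }
      in_gap_b <- TRUE
      in_gap_a <- FALSE
    }
  }
  s
}

# exhaustive enumeration of every global alignment (tiny inputs only)
oracle_enumerate_score <- function(a, b, p = align_params()) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, ca, cb) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, oracle_score_columns(ca, cb, p))
      return(invisible(NULL))
    }
    if (i <= length(A) && j <= length(B)) {
      rec(i + 1, j + 1, c(ca, A[i]), c(cb, B[j]))
    }
    if (i <= length(A)) rec(i + 1, j, c(ca, A[i]), c(cb, "-"))
    if (j <= length(B)) rec(i, j + 1, c(ca, "-"), c(cb, B[j]))
    invisible(NULL)
  }
  rec(1, 1, character(0), character(0))
  best
}

# third-party DP cross-check; same scoring scheme (gap of length g costs
# -(1 + g) here <=> gap_open -2 / gap_extend -1 in package terms)
biostrings_score <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                substitutionMatrix = mat,
                                gapOpening = 1, gapExtension = 1,
                                scoreOnly = TRUE)
}

# brute-force bimera: max over breakpoints and both orders of the summed
# per-position match profiles
oracle_bimera <- function(query, pa, pb, align = align_params()) {
  prof <- function(p) {
    mostwanted:::.match_profile(query, p, align)
  }
  fa <- prof(pa)
  fb <- prof(pb)
  L <- length(fa)
  best <- -Inf
  best_bp <- NA_integer_
  for (ord in 1:2) {
    f1 <- if (ord == 1) fa else fb
    f2 <- if (ord == 1) fb else fa
    for (i in 0:L) {
      v <- sum(f1[seq_len(i)]) + sum(f2[seq_len(L - i) + i])
      if (v > best) {
        best <- v
        best_bp <- i
      }
    }
  }
  list(model_identity = best / L, breakpoint = best_bp)
}
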