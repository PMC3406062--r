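# Global alignment, percent identity, best-match search, aligning fraction
# and single-cell matching, validated against enumeration, an independent
# R DP, and Biostrings.

test_that("global_align handles the worked examples", {
  aln <- global_align("ACGT", "ACGT")
  expect_equal(nchar(aln$aligned_a), 4)
  expect_false(grepl("-", paste0(aln$aligned_a, aln$aligned_b)))
  expect_equal(percent_identity(aln), 1)

  aln <- global_align("ACGTACGT", "ACGACGT")
  gaps <- sum(strsplit(aln$aligned_b, "")[[1]] == "-")
  expect_equal(gaps, 1)  # one internal gap column
  expect_equal(percent_identity(aln), 7 / 8)

  expect_equal(percent_identity(global_align("ACGTACGTAC", "ACGTTCGTAC")),
               0.90)
  expect_error(global_align("ACXT", "ACGT"), "non-IUPAC")
})

test_that("alignment invariants: degapping restores inputs, equal lengths", {
  set.seed(11)
  for (k in 1:20) {
    a <- random_dna(sample(5:40, 1))
    b <- random_dna(sample(5:40, 1))
    aln <- global_align(a, b)
    expect_equal(nchar(aln$aligned_a), nchar(aln$aligned_b))
    expect_equal(gsub("-", "", aln$aligned_a), a)
    expect_equal(gsub("-", "", aln$aligned_b), b)
  }
})

test_that("alignment score matches exhaustive enumeration on tiny pairs", {
  set.seed(7)
  for (endfree in c(TRUE, FALSE)) {
    p <- align_params(end_gaps_free = endfree)
    for (k in 1:12) {
      a <- random_dna(sample(2:6, 1))
      b <- random_dna(sample(2:6, 1))
      expect_equal(global_align(a, b, p)$score,
                   oracle_enumerate_score(a, b, p),
                   info = paste(a, b, "endfree", endfree))
    }
  }
  # the spec's worked pair, enumerated in full
  p <- align_params()
  expect_equal(global_align("ACGTACGT", "ACGACGT", p)$score,
               oracle_enumerate_score("ACGTACGT", "ACGACGT", p))
})

test_that("alignment score matches an independent DP on 200 random pairs", {
  set.seed(13)
  for (k in 1:200) {
    a <- random_dna(sample(10:200, 1))
    b <- random_dna(sample(10:200, 1))
    endfree <- k %% 2 == 0
    p <- align_params(end_gaps_free = endfree)
    expect_equal(global_align(a, b, p)$score, oracle_align_score(a, b, p))
  }
})

test_that("alignment score agrees with Biostrings overlap alignment", {
  set.seed(17)
  for (k in 1:25) {
    a <- random_dna(sample(20:150, 1))
    b <- random_dna(sample(20:150, 1))
    expect_equal(global_align(a, b)$score, biostrings_score(a, b))
  }
})

test_that("identity is reflexive, symmetric, and exact for interior substitutions", {
  set.seed(23)
  for (k in 1:10) {
    a <- random_dna(200)
    expect_equal(seq_identity(a, a), 1)
    b <- random_dna(200)
    expect_equal(seq_identity(a, b), seq_identity(b, a))
  }
  # substitution-only mutants away from the ends: identity = 1 - s/L exactly
  for (div in c(0.01, 0.03, 0.05, 0.10)) {
    L <- 300
    a <- random_dna(L)
    chars <- strsplit(a, "")[[1]]
    n_sub <- round(div * L)
    pos <- sample(10:(L - 10), n_sub)
    for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
    b <- paste(chars, collapse = "")
    expect_equal(seq_identity(a, b), 1 - n_sub / L)
  }
})

test_that("unrelated sequences never look like strong matches", {
  # with free end gaps the score-optimal alignment of unrelated sequences
  # is a short overlap; the identity denominator guards against reporting
  # it as a high-identity hit
  set.seed(29)
  for (k in 1:20) {
    expect_lt(seq_identity(random_dna(250), random_dna(250)), 0.6)
  }
})

test_that("percent_identity counts from the oracle alignment", {
  aln <- global_align("ACGTACGT", "ACGACGT")
  expect_equal(percent_identity(aln), 7 / 8)
  expect_error(percent_identity(global_align("AAAA", "CCCC")),
               "terminal-gap")
})

test_that("aligning_fraction measures query bases inside the aligned region", {
  a <- random_dna(60)
  aln <- global_align(a, a)
  expect_equal(aligning_fraction(aln), 1)

  # truncated queries: fraction equals a direct count from the alignment
  set.seed(31)
  ref <- random_dna(200)
  for (k in 1:10) {
    n <- sample(60:180, 1)
    off <- sample(0:(200 - n), 1)
    q <- substr(ref, off + 1, off + n)
    aln <- global_align(q, ref)
    ca <- strsplit(aln$aligned_a, "")[[1]]
    cb <- strsplit(aln$aligned_b, "")[[1]]
    gap <- ca == "-" | cb == "-"
    lead <- match(FALSE, gap) - 1
    trail <- match(FALSE, rev(gap)) - 1
    core <- seq_len(length(ca) - lead - trail) + lead
    expect_equal(aligning_fraction(aln, n), sum(ca[core] != "-") / n)
    expect_equal(aligning_fraction(aln, n), 1)  # full sub-region aligns
  }
  # 80 of the query's 100 bases inside the aligned region -> 0.8
  aln80 <- global_align(paste0(substr(ref, 1, 80), random_dna(20)), ref)
  expect_equal(aligning_fraction(aln80, 100),
               {
                 ca <- strsplit(aln80$aligned_a, "")[[1]]
                 cb <- strsplit(aln80$aligned_b, "")[[1]]
                 gap <- ca == "-" | cb == "-"
                 lead <- match(FALSE, gap) - 1
                 trail <- match(FALSE, rev(gap)) - 1
                 core <- seq_len(length(ca) - lead - trail) + lead
                 min(1, sum(ca[core] != "-") / 100)
               })
})

test_that("best_match equals an exhaustive scan and breaks ties by record order", {
  set.seed(37)
  refs <- setNames(vapply(1:20, function(i) random_dna(120), character(1)),
                   sprintf("ref_%02d", 1:20))
  db <- ref_db(refs, "scan_db", "comprehensive")
  for (k in 1:50) {
    base <- refs[[sample(20, 1)]]
    q <- mutate_sequence(base, runif(1, 0, 0.1), seed = k)$sequence
    hit <- best_match(q, db)
    ids <- vapply(refs, function(r) seq_identity(q, r), numeric(1))
    expect_equal(hit$identity, max(ids))
    expect_equal(hit$ref_id, names(refs)[which.max(ids)])
  }
  # exact tie: identical records -> first wins
  db2 <- ref_db(c(r1 = refs[[1]], r2 = refs[[1]]), "tie_db", "comprehensive")
  expect_equal(best_match(refs[[1]], db2)$ref_id, "r1")
  expect_equal(best_match(refs[[1]], db2)$identity, 1)
})

test_that("best_match identity is monotone as records are added", {
  set.seed(41)
  q <- random_dna(150)
  refs <- c(far = mutate_sequence(q, 0.3, seed = 1)$sequence,
            mid = mutate_sequence(q, 0.1, seed = 2)$sequence,
            near = mutate_sequence(q, 0.02, seed = 3)$sequence)
  prev <- -Inf
  for (n in 1:3) {
    db <- ref_db(refs[seq_len(n)], "grow", "comprehensive")
    id <- best_match(q, db)$identity
    expect_gte(id, prev)
    prev <- id
  }
})

test_that("match_single_cells picks the read with the best aligning fraction", {
  set.seed(43)
  otus <- setNames(vapply(1:5, function(i) random_dna(250), character(1)),
                   sprintf("otu_%04d", 1:5))
  db <- ref_db(otus, "otu_db", "comprehensive")

  # forward read covers 95% of its length, "reverse" read only 60%
  fwd <- substr(otus[[2]], 1, 237)
  rev_frag <- paste0(substr(otus[[2]], 100, 189), random_dna(60))
  res <- match_single_cells(list(cellA = c(fwd, rev_frag)), db,
                            reverse_complement = FALSE)
  expect_equal(res$read_index, 1)
  expect_equal(res$otu_id, "otu_0002")

  # exact read -> its OTU at identity 1, in either orientation
  res2 <- match_single_cells(list(c1 = otus[[3]], c2 = revcomp(otus[[3]])),
                             db, reverse_complement = TRUE)
  expect_equal(res2$otu_id, c("otu_0003", "otu_0003"))
  expect_equal(res2$identity, c(1, 1))
  expect_true(all(res2$assigned))

  expect_error(match_single_cells(list(bad = character(0)), db),
               "empty read list")
})

test_that("synthetic single cells map back to their source OTUs", {
  fx <- small_world()
  res <- small_result()
  keep <- res$records$otu_id
  cons <- setNames(
    vapply(res$clustering$otus, `[[`, character(1), "consensus"),
    vapply(res$clustering$otus, `[[`, character(1), "otu_id"))
  db <- ref_db(cons[keep], "otus", "comprehensive")
  ot <- otu_truth(res$clustering$otus, fx$truth$reads)

  set.seed(47)
  sources <- ot$source_id[!ot$truth_chimeric & ot$otu_id %in% keep]
  sources <- unique(sources[!is.na(sources)])
  cells <- lapply(sources, function(s) {
    full <- fx$pool$sources[[s]]
    n <- nchar(full)
    vapply(1:2, function(i) {
      len <- sample(floor(0.6 * n):n, 1)
      q <- substr(full, 1, len)
      if (i == 2) revcomp(q) else q
    }, character(1))
  })
  names(cells) <- sources
  res_cells <- match_single_cells(cells, db, id_threshold = 0.97)
  hit_src <- ot$source_id[match(res_cells$otu_id, ot$otu_id)]
  expect_gte(mean(hit_src == sources), 0.95)
})
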