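# Generator: source pools, controlled mutation, sample simulation with
# planted chimeras, reference databases, and the planted-class
# self-consistency.

test_that("generate_source_pool: single source, determinism, separation", {
  p1 <- generate_source_pool(1, 100, 0.1, seed = 7)
  expect_length(p1$sources, 1)
  expect_equal(nchar(p1$sources[[1]]), 100)

  p2 <- generate_source_pool(1, 100, 0.1, seed = 7)
  expect_identical(p1, p2)

  pool <- generate_source_pool(20, 300, 0.10, seed = 3)
  ids <- combn(20, 2, function(ij)
    seq_identity(pool$sources[[ij[1]]], pool$sources[[ij[2]]]))
  expect_true(all(ids < 0.90))
  expect_error(generate_source_pool(0, 100), "n_sources")
})

test_that("mutate_sequence hits its divergence target", {
  set.seed(5)
  s <- random_dna(300)
  m0 <- mutate_sequence(s, 0, seed = 1)
  expect_identical(m0$sequence, s)
  expect_equal(m0$realized_identity, 1)

  # substitution-only: exactly round(0.05 * 300) positions differ
  m <- mutate_sequence(s, 0.05, indel_fraction = 0, seed = 1)
  expect_equal(nchar(m$sequence), 300)
  diff <- sum(strsplit(s, "")[[1]] != strsplit(m$sequence, "")[[1]])
  expect_equal(diff, round(0.05 * 300))

  # with indels: realized identity lands near 1 - divergence
  for (seed in 1:5) {
    m <- mutate_sequence(s, 0.12, indel_fraction = 0.2, seed = seed)
    expect_gte(m$realized_identity, 0.86)
    expect_lte(m$realized_identity, 0.90)
  }
  expect_error(mutate_sequence(s, 0.7), "divergence")
})

test_that("mutate realized identity tracks 1 - divergence within 0.02", {
  set.seed(19)
  s <- random_dna(250)
  for (div in c(0.02, 0.05, 0.08, 0.12, 0.15)) {
    m <- mutate_sequence(s, div, indel_fraction = 0.1, seed = 100 + div * 100)
    expect_lt(abs(m$realized_identity - (1 - div)), 0.02)
  }
})

make_design <- function(pool, ..., seed = 1) {
  n <- length(pool$sources)
  sites <- c("gut", "mouth")
  plan <- matrix(0.5, n, 2, dimnames = list(names(pool$sources), sites))
  defaults <- list(body_sites = sites, samples_per_site = 5,
                   reads_per_sample = 40, prevalence_plan = plan,
                   error_rate = 0, indel_rate = 0, chimera_rate = 0,
                   seed = seed)
  args <- modifyList(defaults, list(...))
  do.call(simulation_design, args)
}

test_that("noise-free simulation copies sources exactly and conserves reads", {
  pool <- generate_source_pool(4, 120, seed = 2)
  des <- make_design(pool)
  sim <- simulate_samples(pool, des)
  expect_length(sim$reads, 2 * 5 * 40)
  expect_true(all(sim$reads %in% pool$sources))
  # every read attributed exactly once
  expect_setequal(sim$truth$reads$read_id, names(sim$reads))
  expect_equal(anyDuplicated(sim$truth$reads$read_id), 0)
  expect_equal(sum(sim$truth$sources$planted_reads), length(sim$reads))
  # metadata covers every read with one region tag
  expect_setequal(sim$metadata$read_id, names(sim$reads))
  expect_length(unique(sim$metadata$region), 1)
})

test_that("simulation is deterministic: identical seeds, identical files", {
  pool <- generate_source_pool(3, 100, seed = 4)
  des <- make_design(pool, error_rate = 0.01, chimera_rate = 0.1, seed = 9)
  s1 <- simulate_samples(pool, des)
  s2 <- simulate_samples(pool, des)
  expect_identical(s1, s2)
  d1 <- tempfile()
  d2 <- tempfile()
  write_simulation(s1, dir = d1)
  write_simulation(s2, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("planted chimera count is binomial around the configured rate", {
  pool <- generate_source_pool(6, 150, seed = 6)
  # presence 0.9 so every sample holds >= 2 sources (chimeras need parents)
  plan <- matrix(0.9, 6, 2,
                 dimnames = list(names(pool$sources), c("gut", "mouth")))
  des <- make_design(pool, samples_per_site = 5, reads_per_sample = 100,
                     prevalence_plan = plan, chimera_rate = 0.1, seed = 21)
  sim <- simulate_samples(pool, des)
  n <- length(sim$reads)  # 1000
  n_chim <- sum(sim$truth$reads$is_chimera)
  expect_equal(n, 1000)
  # 95% binomial interval around 0.1 * 1000
  expect_gte(n_chim, qbinom(0.025, n, 0.1))
  expect_lte(n_chim, qbinom(0.975, n, 0.1))
  chim <- sim$truth$reads[sim$truth$reads$is_chimera, ]
  expect_true(all(!is.na(chim$parent_a) & !is.na(chim$parent_b)))
  expect_true(all(chim$parent_a != chim$parent_b))
  # breakpoints inside the central 60% of the read
  expect_true(all(chim$breakpoint >= ceiling(0.2 * 150) &
                    chim$breakpoint <= floor(0.8 * 150)))
  # chimeric reads reconstruct as parentA-head + parentB-tail (no noise)
  r1 <- chim[1, ]
  templ <- paste0(substr(pool$sources[[r1$parent_a]], 1, r1$breakpoint),
                  substr(pool$sources[[r1$parent_b]], r1$breakpoint + 1,
                         150))
  expect_identical(unname(sim$reads[r1$read_id]), templ)
})

test_that("planted prevalence is recovered within the binomial interval", {
  pool <- generate_source_pool(5, 100, seed = 8)
  n <- length(pool$sources)
  plan <- matrix(0.5, n, 1, dimnames = list(names(pool$sources), "gut"))
  des <- simulation_design(body_sites = "gut", samples_per_site = 40,
                           reads_per_sample = 60, prevalence_plan = plan,
                           error_rate = 0, chimera_rate = 0, seed = 12)
  sim <- simulate_samples(pool, des)
  tr <- sim$truth$reads
  lo <- qbinom(0.025, 40, 0.5) / 40
  hi <- qbinom(0.975, 40, 0.5) / 40
  for (s in names(pool$sources)) {
    present <- length(unique(tr$sample_id[tr$source_id == s &
                                            !is.na(tr$source_id)]))
    expect_gte(present / 40, lo)
    expect_lte(present / 40, hi)
  }
})

test_that("reference databases follow the divergence plan", {
  pool <- generate_source_pool(4, 250, seed = 10)
  src <- names(pool$sources)
  plan <- list(
    seqdb = list(category = "sequenced_human",
                 divergence = setNames(c(0, 0.05, 0.12, 0.12), src)),
    cultdb = list(category = "cultured_named",
                  divergence = setNames(rep(0.02, 3), src[1:3])))
  dbs <- generate_reference_databases(pool, plan, seed = 5)

  # divergence 0 -> verbatim copy
  expect_identical(unname(dbs$dbs$seqdb$sequences[paste0(src[1], "|seqdb")]),
                   unname(pool$sources[[src[1]]]))
  # omitted source absent from that database
  expect_false(paste0(src[4], "|cultdb") %in%
                 names(dbs$dbs$cultdb$sequences))
  # realized identities recorded and close to plan
  ids <- dbs$identities
  expect_equal(nrow(ids), 4 + 3)
  expect_true(all(abs(ids$realized_identity - (1 - ids$divergence)) < 0.02))

  bad <- list(seqdb = list(category = "sequenced_human",
                           divergence = c(nosuch = 0.1)),
              cultdb = plan$cultdb)
  expect_error(generate_reference_databases(pool, bad, seed = 1),
               "unknown source")
  expect_error(
    generate_reference_databases(pool, plan["seqdb"], seed = 1),
    "cultured_named")
})

test_that("planted classes follow the triage rules (self-consistency)", {
  fx <- small_world()
  cls <- fx$truth$classes
  redo <- assign_priority(cls$planted_seq_identity,
                          cls$planted_max_prevalence, triage_thresholds())
  expect_identical(cls$planted_class, redo)

  # divergence 0.12 + prevalent -> high; 0.05 -> medium; 0 -> low
  t <- triage_thresholds()
  expect_equal(assign_priority(100 * (1 - 0.12), 0.5, t), "high")
  expect_equal(assign_priority(100 * (1 - 0.05), 0.5, t), "medium")
  expect_equal(assign_priority(100, 0.5, t), "low")
})

test_that("standard fixture plants all bands and both prevalence regimes", {
  fx <- small_world()
  cls <- fx$truth$classes
  expect_setequal(unique(cls$planted_class), c("high", "medium", "low"))
  expect_true(any(cls$planted_max_prevalence >= 0.2))
  expect_true(any(cls$planted_max_prevalence < 0.2))
  ids <- cls$planted_seq_identity
  expect_true(any(ids >= 99), info = "band 99-100")
  expect_true(any(ids >= 92 & ids <= 96))
  expect_true(any(ids >= 80 & ids <= 88))
})
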