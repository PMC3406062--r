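# OTU table construction, per-site prevalence, mean relative abundance,
# each checked against brute-force tallies.

mk_meta <- function(n_samples, sites, reads_per_sample = 10) {
  samples <- sprintf("s%03d", seq_len(n_samples))
  site <- rep_len(sites, n_samples)
  do.call(rbind, lapply(seq_len(n_samples), function(i) {
    data.frame(read_id = sprintf("%s_r%02d", samples[i],
                                 seq_len(reads_per_sample)),
               sample_id = samples[i], subject_id = samples[i],
               body_site = site[i], region = "V1-V3",
               stringsAsFactors = FALSE)
  }))
}

test_that("build_otu_table counts reads per sample and rejects unknown ids", {
  meta <- mk_meta(2, "gut", 5)
  mem <- data.frame(read_id = meta$read_id[1:3], otu_id = "otu_1")
  tab <- build_otu_table(mem, meta)
  expect_equal(unname(tab["otu_1", "s001"]), 3L)
  expect_equal(unname(tab["otu_1", "s002"]), 0L)

  empty <- build_otu_table(data.frame(read_id = character(0),
                                      otu_id = character(0)), meta)
  expect_equal(nrow(empty), 0)
  expect_equal(ncol(empty), 2)

  bad <- data.frame(read_id = "ghost_read", otu_id = "otu_1")
  expect_error(build_otu_table(bad, meta), "ghost_read")
})

test_that("row/column sums match independent tallies on a random table", {
  set.seed(71)
  meta <- mk_meta(20, c("gut", "mouth", "skin"), 50)  # 1000 reads
  mem <- data.frame(read_id = meta$read_id,
                    otu_id = sample(sprintf("otu_%02d", 1:15), 1000,
                                    replace = TRUE))
  tab <- build_otu_table(mem, meta)
  for (o in rownames(tab)) {
    expect_equal(sum(tab[o, ]), sum(mem$otu_id == o))
  }
  for (s in colnames(tab)) {
    expect_equal(sum(tab[, s]),
                 sum(meta$sample_id[match(mem$read_id,
                                          meta$read_id)] == s))
  }
  expect_true(all(colSums(tab) <= 50))
})

test_that("prevalence_by_site matches the worked example and brute force", {
  meta <- mk_meta(20, c("saliva", "stool"), 2)
  stool <- unique(meta$sample_id[meta$body_site == "stool"])
  saliva <- unique(meta$sample_id[meta$body_site == "saliva"])
  pick <- function(samples) meta$read_id[match(samples, meta$sample_id)]
  mem <- data.frame(read_id = c(pick(stool[1:3]), pick(saliva[1])),
                    otu_id = "otu_1")
  tab <- build_otu_table(mem, meta)
  pr <- prevalence_by_site(tab)
  expect_equal(pr$prev_stool, 0.3)
  expect_equal(pr$prev_saliva, 0.1)
  expect_equal(pr$max_site, "stool")
  expect_equal(pr$max_prevalence, 0.3)

  # random table vs exhaustive per-site tally
  set.seed(73)
  meta2 <- mk_meta(200, c("a_site", "b_site", "c_site", "d_site"), 5)
  mem2 <- data.frame(read_id = sample(meta2$read_id, 600),
                     otu_id = sample(sprintf("o%02d", 1:50), 600,
                                     replace = TRUE))
  tab2 <- build_otu_table(mem2, meta2)
  pr2 <- prevalence_by_site(tab2, presence_min = 1)
  sites <- sort(unique(meta2$body_site))
  for (i in sample(nrow(pr2), 10)) {
    o <- pr2$otu_id[i]
    for (s in sites) {
      cols <- meta2$sample_id[!duplicated(meta2$sample_id) &
                                meta2$body_site == s]
      brute <- mean(vapply(cols, function(cc) {
        reads <- mem2$read_id[mem2$otu_id == o]
        any(meta2$sample_id[match(reads, meta2$read_id)] == cc)
      }, logical(1)))
      expect_equal(pr2[[paste0("prev_", s)]][i], brute)
    }
    expect_equal(pr2$max_prevalence[i],
                 max(unlist(pr2[i, paste0("prev_", sites)])))
  }
})

test_that("prevalence ties go to the lexicographically first site", {
  meta <- mk_meta(4, c("b_site", "a_site"), 2)
  mem <- data.frame(read_id = meta$read_id[!duplicated(meta$sample_id)],
                    otu_id = "otu_1")
  pr <- prevalence_by_site(build_otu_table(mem, meta))
  expect_equal(pr$prev_a_site, 1)
  expect_equal(pr$prev_b_site, 1)
  expect_equal(pr$max_site, "a_site")
})

test_that("prevalence is monotone non-increasing in presence_min", {
  set.seed(77)
  meta <- mk_meta(30, c("gut", "mouth"), 20)
  mem <- data.frame(read_id = sample(meta$read_id, 400),
                    otu_id = sample(sprintf("o%d", 1:8), 400, TRUE))
  tab <- build_otu_table(mem, meta)
  prev1 <- prevalence_by_site(tab, presence_min = 1)
  prev2 <- prevalence_by_site(tab, presence_min = 2)
  prev3 <- prevalence_by_site(tab, presence_min = 3)
  for (s in c("prev_gut", "prev_mouth")) {
    expect_true(all(prev2[[s]] <= prev1[[s]]))
    expect_true(all(prev3[[s]] <= prev2[[s]]))
  }
})

test_that("mean_relative_abundance matches its definition", {
  meta <- mk_meta(3, "gut", 4)
  mem <- data.frame(
    read_id = c(meta$read_id[1:4], meta$read_id[5:6], meta$read_id[9:12]),
    otu_id = c(rep("o1", 4), rep("o1", 2), rep("o2", 4)))
  tab <- build_otu_table(mem, meta)
  mra <- suppressWarnings(mean_relative_abundance(tab))
  # sample1: o1=4/4; sample2: o1=2/2; sample3: o2=4/4
  expect_equal(unname(mra["o1"]), mean(c(1, 1, 0)))
  expect_equal(unname(mra["o2"]), mean(c(0, 0, 1)))

  # single OTU -> 1; per-sample relative abundances sum to 1
  one <- build_otu_table(data.frame(read_id = meta$read_id[1:4],
                                    otu_id = "solo"), meta)
  expect_equal(unname(suppressWarnings(mean_relative_abundance(one))["solo"]),
               1)

  set.seed(79)
  meta2 <- mk_meta(10, c("gut", "mouth"), 10)
  mem2 <- data.frame(read_id = meta2$read_id,
                     otu_id = sample(sprintf("o%d", 1:5), 100, TRUE))
  tab2 <- build_otu_table(mem2, meta2)
  rel <- sweep(unclass(tab2), 2, colSums(tab2), "/")
  expect_equal(unname(colSums(rel)), rep(1, 10))
  brute <- rowMeans(rel)
  expect_equal(mean_relative_abundance(tab2), brute)

  all_empty <- build_otu_table(data.frame(read_id = character(0),
                                          otu_id = character(0)), meta)
  expect_error(mean_relative_abundance(all_empty), "empty")
})

test_that("planted prevalence is recovered on the small world", {
  fx <- small_world()
  res <- small_result()
  ot <- otu_truth(res$clustering$otus, fx$truth$reads)
  prev <- res$prevalence
  plan <- fx$design$prevalence_plan
  n <- fx$design$samples_per_site
  # prevalent sources: estimated max prevalence within the 95% binomial
  # band of the planted probability (detection loss makes it one-sided)
  for (i in seq_len(nrow(ot))) {
    if (ot$truth_chimeric[i] || is.na(ot$source_id[i])) next
    s <- ot$source_id[i]
    p_plant <- max(plan[s, ])
    if (p_plant < 0.3) next
    est <- prev$max_prevalence[prev$otu_id == ot$otu_id[i]]
    expect_lte(est, qbinom(0.995, n, p_plant) / n)
    expect_gte(est, qbinom(0.005, n, p_plant) / n - 2 / n)
  }
})
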