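# The standard validation world: a fixed synthetic community whose planted
# quantities span all three identity bands and both prevalence regimes, at
# survey-like (but desk-scale) sampling depth. All of its parameters are
# stated here once; tests measure against this world, they do not tune it.

#' The standard synthetic validation fixture
#'
#' Sixty random sources (250 nt) whose planted identities to the
#' sequenced-human databases sit in three bands -- 99-100% (low priority),
#' ~92.5-95.5% (medium) and ~81-87% (high/"most wanted") -- with, inside
#' every band, half the sources planted prevalent (presence probability 0.6
#' at a home site) and half rare (0.05 everywhere). Five body sites, 40
#' samples per site, 200 reads per sample; geometric rank-abundance
#' (p = 0.03, so even rank-60 sources receive reads at this depth); 1%
#' substitution and 0.1% indel error; 5% of reads are two-parent chimeras
#' amplified from per-sample templates. Reference databases: two
#' sequenced-human collections (the second 4 points more divergent), a
#' near-complete comprehensive collection (1% divergence), a cultured-named
#' collection at 80% of the sequenced divergence (so cultured identity is
#' never materially below sequenced identity) and a distant
#' cultured-unnamed collection.
#'
#' @param seed integer master seed.
#' @param n_sources,samples_per_site,reads_per_sample size of the world;
#'   the defaults are the standard fixture, smaller values give a cheap
#'   world with the same structure for unit tests.
#' @return list: `pool`, `design`, `reads`, `metadata`, `ref_dbs` (named
#'   list of [ref_db()]), `manifest`, and `truth` (per-read attributions,
#'   per-source planted prevalence/identities/classes).
#' @export
standard_fixture <- function(seed = 1, n_sources = 60, samples_per_site = 40,
                             reads_per_sample = 200) {
  stopifnot(n_sources >= 6)
  sites <- c("nares", "saliva", "skin", "stool", "vaginal")
  pool <- generate_source_pool(n_sources, length = 250,
                               min_divergence = 0.10, seed = seed)
  src <- names(pool$sources)

  band <- (seq_len(n_sources) - 1) %% 3        # 0 low-div, 1 medium, 2 high
  pos <- ((seq_len(n_sources) - 1) %/% 3) + 1  # position within band
  nb <- vapply(0:2, function(b) sum(band == b), integer(1))
  d <- numeric(n_sources)
  ramp <- function(lo, hi, n) if (n == 1) (lo + hi) / 2 else
    seq(lo, hi, length.out = n)
  d[band == 0] <- ramp(0.000, 0.010, nb[1])
  d[band == 1] <- ramp(0.045, 0.075, nb[2])
  d[band == 2] <- ramp(0.130, 0.190, nb[3])
  names(d) <- src

  prevalent <- pos %% 2 == 1
  home <- sites[(seq_len(n_sources) - 1) %% length(sites) + 1]
  plan <- matrix(0.05, nrow = n_sources, ncol = length(sites),
                 dimnames = list(src, sites))
  for (i in seq_len(n_sources)) {
    if (prevalent[i]) {
      plan[i, ] <- 0.08
      plan[i, home[i]] <- 0.60
    }
  }

  design <- simulation_design(
    body_sites = sites, samples_per_site = samples_per_site,
    reads_per_sample = reads_per_sample, prevalence_plan = plan,
    abundance_model = list(type = "geometric", p = 0.03),
    error_rate = 0.01, indel_rate = 0.001, chimera_rate = 0.05,
    chimera_copies = 5, region = "V1-V3", seed = seed + 1L)
  sim <- simulate_samples(pool, design)

  db_plan <- list(
    gold_human = list(category = "sequenced_human", divergence = d),
    hmp_strains = list(category = "sequenced_human",
                       divergence = pmin(d + 0.04, 0.5)),
    silva_like = list(category = "comprehensive",
                      divergence = setNames(rep(0.01, n_sources), src)),
    gg_named = list(category = "cultured_named", divergence = 0.8 * d),
    gg_unnamed = list(category = "cultured_unnamed",
                      divergence = setNames(rep(0.25, n_sources), src)))
  refdbs <- generate_reference_databases(pool, db_plan, seed = seed + 2L)

  truth <- sim$truth
  truth$identities <- refdbs$identities
  truth$classes <- planted_classes(refdbs$identities, truth$prevalence)

  list(pool = pool, design = design, reads = sim$reads,
       metadata = sim$metadata, ref_dbs = refdbs$dbs,
       manifest = db_manifest(refdbs$dbs), truth = truth)
}

#' Ground-truth attribution of OTUs
#'
#' Maps each OTU back to the generator's truth: its majority source among
#' non-chimeric member reads and the fraction of chimeric members. An OTU
#' is truth-chimeric when more than half of its reads are planted chimeras.
#'
#' @param otus list of OTUs from [cluster_reads()].
#' @param truth_reads the `truth$reads` table from [simulate_samples()].
#' @return data.frame: `otu_id`, `n_reads`, `source_id` (majority, NA if
#'   none), `frac_chimeric`, `truth_chimeric`.
#' @export
otu_truth <- function(otus, truth_reads) {
  rows <- lapply(otus, function(o) {
    tr <- truth_reads[match(o$member_read_ids, truth_reads$read_id), ,
                      drop = FALSE]
    frac_chim <- mean(tr$is_chimera)
    srcs <- tr$source_id[!tr$is_chimera]
    maj <- if (length(srcs) > 0) {
      names(sort(table(srcs), decreasing = TRUE))[1]
    } else NA_character_
    data.frame(otu_id = o$otu_id, n_reads = o$n_reads, source_id = maj,
               frac_chimeric = frac_chim,
               truth_chimeric = frac_chim > 0.5, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score pipeline output against the planted ground truth
#'
#' @param result a [most_wanted_pipeline()] result.
#' @param truth the fixture's `truth` (with `classes` from
#'   [planted_classes()]).
#' @return list: `class_recovery` (fraction of planted classes recovered;
#'   a source with no recovered OTU counts as a miss),
#'   `chimera_sensitivity`, `chimera_false_flag_rate`, counts, and a
#'   `per_source` table.
#' @export
recovery_summary <- function(result, truth) {
  ot <- otu_truth(result$clustering$otus, truth$reads)
  v <- result$verdicts
  chim <- ot$truth_chimeric
  flagged <- v$chimeric[match(ot$otu_id, v$otu_id)]
  sens <- if (any(chim)) mean(flagged[chim]) else NA_real_
  ffr <- if (any(!chim)) mean(flagged[!chim]) else NA_real_

  cls <- truth$classes
  per_source <- lapply(seq_len(nrow(cls)), function(i) {
    s <- cls$source_id[i]
    cand <- ot[!ot$truth_chimeric & !is.na(ot$source_id) &
                 ot$source_id == s, , drop = FALSE]
    if (nrow(cand) == 0) {
      return(data.frame(source_id = s, otu_id = NA_character_,
                        planted_class = cls$planted_class[i],
                        assigned_class = NA_character_, recovered = FALSE,
                        stringsAsFactors = FALSE))
    }
    oid <- cand$otu_id[which.max(cand$n_reads)]
    assigned <- result$records$priority_class[
      match(oid, result$records$otu_id)]
    data.frame(source_id = s, otu_id = oid,
               planted_class = cls$planted_class[i],
               assigned_class = if (length(assigned) == 0) NA_character_
                                else assigned,
               recovered = isTRUE(assigned == cls$planted_class[i]),
               stringsAsFactors = FALSE)
  })
  per_source <- do.call(rbind, per_source)
  list(class_recovery = mean(per_source$recovered),
       n_sources = nrow(per_source),
       chimera_sensitivity = sens,
       n_chimeric_otus = sum(chim),
       chimera_false_flag_rate = ffr,
       n_clean_otus = sum(!chim),
       per_source = per_source)
}
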