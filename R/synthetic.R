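# Synthetic amplicon communities with planted ground truth: random source
# sequences stand in for the true taxa; reads carry point error and planted
# two-parent chimeras; reference databases are mutated copies of the sources
# at controlled divergence. Everything downstream is testable against the
# recorded truth.

#' Generate a pool of well-separated source sequences
#'
#' Sources are i.i.d. random A/C/G/T sequences. The pool is accepted only if
#' every pairwise identity (per [seq_identity()]) is below
#' `1 - min_divergence`; offending sequences are re-drawn a bounded number of
#' times.
#'
#' @param n_sources number of sources (>= 1).
#' @param length sequence length (>= 50).
#' @param min_divergence minimum pairwise divergence; the identity ceiling is
#'   `1 - min_divergence` (default ceiling 0.90).
#' @param seed integer seed; identical seeds give byte-identical pools.
#' @param max_retries redraw budget per sequence.
#' @return object of class `source_pool`: list with `sources` (named
#'   character vector, ids `src_01`, ...), `length`, `min_divergence`, `seed`.
#' @export
generate_source_pool <- function(n_sources, length, min_divergence = 0.10,
                                 seed = 1, max_retries = 20) {
  stopifnot(n_sources >= 1, length >= 50,
            min_divergence > 0, min_divergence < 1)
  ceiling_id <- 1 - min_divergence
  with_seed(seed, {
    draw <- function() paste(sample(c("A", "C", "G", "T"), length,
                                    replace = TRUE), collapse = "")
    seqs <- character(n_sources)
    for (i in seq_len(n_sources)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        cand <- draw()
        ok <- i == 1 ||
          all(vapply(seqs[seq_len(i - 1)], function(s)
            seq_identity(cand, s) < ceiling_id, logical(1)))
        if (ok) break
      }
      if (!ok) {
        stop("could not draw ", n_sources, " sources of length ", length,
             " at min_divergence ", min_divergence, " within ",
             max_retries, " retries", call. = FALSE)
      }
      seqs[i] <- cand
    }
    names(seqs) <- sprintf("src_%02d", seq_len(n_sources))
    structure(list(sources = seqs, length = length,
                   min_divergence = min_divergence, seed = seed),
              class = "source_pool")
  })
}

#' @export
print.source_pool <- function(x, ...) {
  cat("source_pool:", length(x$sources), "sources of length", x$length, "\n")
  invisible(x)
}

# mutate using the current RNG state; divergence*L changes total, a fraction
# of them 1-nt indels, the rest substitutions to a different base
.mutate_core <- function(seq, divergence, indel_fraction) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  n_mut <- round(divergence * L)
  n_indel <- round(n_mut * indel_fraction)
  n_sub <- n_mut - n_indel
  bases <- c("A", "C", "G", "T")
  if (n_sub > 0) {
    pos <- sample.int(L, n_sub)
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1)
    }
  }
  if (n_indel > 0) {
    for (k in seq_len(n_indel)) {
      if (runif(1) < 0.5 && length(chars) > 1) {  # deletion
        chars <- chars[-sample.int(length(chars), 1)]
      } else {  # insertion
        at <- sample.int(length(chars) + 1, 1)
        chars <- append(chars, sample(bases, 1), after = at - 1)
      }
    }
  }
  paste(chars, collapse = "")
}

#' Mutate a sequence to a controlled divergence
#'
#' Plants exactly `round(divergence * length)` changes, of which a fraction
#' `indel_fraction` are single-base insertions/deletions and the rest are
#' substitutions to a different base. The realized identity is measured back
#' with the alignment module.
#'
#' @param seq DNA sequence.
#' @param divergence target divergence in `[0, 0.5]`.
#' @param indel_fraction fraction of planted changes that are indels.
#' @param seed integer seed.
#' @return list with `sequence` and `realized_identity`.
#' @export
mutate_sequence <- function(seq, divergence, indel_fraction = 0, seed = 1) {
  stopifnot(divergence >= 0, divergence <= 0.5,
            indel_fraction >= 0, indel_fraction <= 1)
  seq <- check_dna(seq, "seq")
  mut <- with_seed(seed, .mutate_core(seq, divergence, indel_fraction))
  list(sequence = mut, realized_identity = seq_identity(mut, seq))
}

#' Specify a simulated amplicon survey
#'
#' @param body_sites character vector of body-site names.
#' @param samples_per_site samples per site.
#' @param reads_per_sample reads per sample.
#' @param prevalence_plan numeric matrix `sources x sites` of presence
#'   probabilities (row names = source ids, column names = body sites).
#' @param abundance_model `list(type = "geometric", p = 0.3)` or
#'   `list(type = "power_law", alpha = ...)`; rank weights over the pool.
#' @param error_rate per-base substitution probability.
#' @param indel_rate per-base indel probability.
#' @param chimera_rate fraction of reads that are two-parent chimeras
#'   (must be < 0.5).
#' @param chimera_copies expected reads per chimeric template; chimeras are
#'   modeled as templates formed once during PCR and then amplified, so the
#'   same bimera recurs in several reads of a sample.
#' @param region variable-region tag carried on every read.
#' @param seed integer seed.
#' @return object of class `simulation_design`.
#' @export
simulation_design <- function(body_sites, samples_per_site, reads_per_sample,
                              prevalence_plan,
                              abundance_model = list(type = "geometric",
                                                     p = 0.3),
                              error_rate = 0.01, indel_rate = 0.001,
                              chimera_rate = 0, chimera_copies = 5,
                              region = "V1-V3", seed = 1) {
  stopifnot(length(body_sites) >= 1, samples_per_site >= 1,
            reads_per_sample >= 1)
  if (!is.matrix(prevalence_plan) || is.null(rownames(prevalence_plan)) ||
      is.null(colnames(prevalence_plan))) {
    stop("prevalence_plan must be a matrix with source row names and site",
         " column names", call. = FALSE)
  }
  if (!setequal(colnames(prevalence_plan), body_sites)) {
    stop("prevalence_plan columns must match body_sites", call. = FALSE)
  }
  if (any(prevalence_plan < 0 | prevalence_plan > 1)) {
    stop("presence probabilities must be in [0, 1]", call. = FALSE)
  }
  stopifnot(error_rate >= 0, error_rate <= 1, indel_rate >= 0, indel_rate <= 1)
  if (chimera_rate < 0 || chimera_rate >= 0.5) {
    stop("chimera_rate must be in [0, 0.5)", call. = FALSE)
  }
  type <- match.arg(abundance_model$type, c("geometric", "power_law"))
  structure(list(body_sites = body_sites, samples_per_site = samples_per_site,
                 reads_per_sample = reads_per_sample,
                 prevalence_plan = prevalence_plan[, body_sites, drop = FALSE],
                 abundance_model = abundance_model, error_rate = error_rate,
                 indel_rate = indel_rate, chimera_rate = chimera_rate,
                 chimera_copies = chimera_copies, region = region,
                 seed = seed),
            class = "simulation_design")
}

# rank weights over n sources under the configured abundance model
abundance_weights <- function(model, n) {
  if (model$type == "geometric") {
    p <- if (is.null(model$p)) 0.3 else model$p
    stopifnot(p > 0, p < 1)
    w <- p * (1 - p)^(seq_len(n) - 1)
  } else {
    alpha <- if (is.null(model$alpha)) 1.5 else model$alpha
    w <- seq_len(n)^(-alpha)
  }
  w / sum(w)
}

# apply per-base noise to a character vector of bases
.noise_read <- function(chars, error_rate, indel_rate) {
  L <- length(chars)
  n_sub <- rbinom(1, L, error_rate)
  n_ind <- if (indel_rate > 0) rbinom(1, L, indel_rate) else 0
  if (n_sub > 0) {
    bases <- c("A", "C", "G", "T")
    pos <- sample.int(L, n_sub)
    for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1)
  }
  if (n_ind > 0) {
    bases <- c("A", "C", "G", "T")
    for (k in seq_len(n_ind)) {
      if (runif(1) < 0.5 && length(chars) > 1) {
        chars <- chars[-sample.int(length(chars), 1)]
      } else {
        at <- sample.int(length(chars) + 1, 1)
        chars <- append(chars, sample(bases, 1), after = at - 1)
      }
    }
  }
  chars
}

#' Simulate an amplicon survey from a source pool
#'
#' Per sample, sources are switched on by their per-site presence
#' probability, reads are drawn from the present sources with rank-abundance
#' weights, per-base noise is applied, and a configured fraction of reads are
#' two-parent single-breakpoint chimeras (bimeras). Chimeric templates are
#' formed from two present sources with a breakpoint uniform over the central
#' 60% of the read and are shared by several reads of the sample, mimicking
#' PCR amplification of an early chimeric molecule.
#'
#' @param pool a [generate_source_pool()] result.
#' @param design a [simulation_design()].
#' @return list with `reads` (named character vector), `metadata`
#'   (data.frame: `read_id`, `sample_id`, `subject_id`, `body_site`,
#'   `region`) and `truth` (list: per-read attribution, per-source planted
#'   prevalence and read tallies, design echo).
#' @export
simulate_samples <- function(pool, design) {
  stopifnot(inherits(pool, "source_pool"),
            inherits(design, "simulation_design"))
  src_ids <- names(pool$sources)
  n_src <- length(src_ids)
  if (n_src == 0) stop("empty source pool", call. = FALSE)
  plan <- design$prevalence_plan
  if (!setequal(rownames(plan), src_ids)) {
    stop("prevalence_plan rows must match pool sources", call. = FALSE)
  }
  plan <- plan[src_ids, , drop = FALSE]
  w_rank <- abundance_weights(design$abundance_model, n_src)
  src_chars <- lapply(pool$sources, function(s) strsplit(s, "")[[1]])
  L <- pool$length
  bp_lo <- ceiling(0.2 * L)
  bp_hi <- floor(0.8 * L)

  with_seed(design$seed, {
    reads <- list()
    meta <- list()
    truth_rows <- list()
    read_no <- 0L
    for (site in design$body_sites) {
      for (si in seq_len(design$samples_per_site)) {
        sample_id <- sprintf("%s_s%02d", site, si)
        subject_id <- sprintf("subj_%s_%02d", site, si)
        present <- which(runif(n_src) < plan[, site])
        tries <- 0
        while (length(present) == 0 && tries < 100) {
          present <- which(runif(n_src) < plan[, site])
          tries <- tries + 1
        }
        if (length(present) == 0) present <- 1L  # degenerate plan fallback
        w <- w_rank[present] / sum(w_rank[present])
        n_reads <- design$reads_per_sample
        n_chim <- if (design$chimera_rate > 0 && length(present) >= 2) {
          rbinom(1, n_reads, design$chimera_rate)
        } else 0L
        n_plain <- n_reads - n_chim

        # chimeric templates for this sample
        templ <- NULL
        if (n_chim > 0) {
          n_templ <- max(1L, round(n_chim / design$chimera_copies))
          templ <- lapply(seq_len(n_templ), function(tk) {
            par <- present[sample.int(length(present), 2, replace = FALSE,
                                      prob = w)]
            bp <- if (bp_hi >= bp_lo) sample(bp_lo:bp_hi, 1) else floor(L / 2)
            list(parent_a = src_ids[par[1]], parent_b = src_ids[par[2]],
                 breakpoint = bp,
                 chars = c(src_chars[[par[1]]][seq_len(bp)],
                           src_chars[[par[2]]][(bp + 1):L]),
                 id = sprintf("%s_chim%02d", sample_id, tk))
          })
        }

        plain_src <- if (n_plain > 0) {
          present[sample.int(length(present), n_plain, replace = TRUE,
                             prob = w)]
        } else integer(0)
        chim_templ <- if (n_chim > 0) {
          sample.int(length(templ), n_chim, replace = TRUE)
        } else integer(0)

        sample_reads <- character(n_reads)
        sample_truth <- vector("list", n_reads)
        for (k in seq_len(n_reads)) {
          read_no <- read_no + 1L
          rid <- sprintf("read_%06d", read_no)
          if (k <= n_plain) {
            src <- plain_src[k]
            chars <- .noise_read(src_chars[[src]], design$error_rate,
                                 design$indel_rate)
            sample_truth[[k]] <- data.frame(
              read_id = rid, sample_id = sample_id, body_site = site,
              source_id = src_ids[src], is_chimera = FALSE,
              parent_a = NA_character_, parent_b = NA_character_,
              breakpoint = NA_integer_, template_id = NA_character_,
              stringsAsFactors = FALSE)
          } else {
            tp <- templ[[chim_templ[k - n_plain]]]
            chars <- .noise_read(tp$chars, design$error_rate,
                                 design$indel_rate)
            sample_truth[[k]] <- data.frame(
              read_id = rid, sample_id = sample_id, body_site = site,
              source_id = NA_character_, is_chimera = TRUE,
              parent_a = tp$parent_a, parent_b = tp$parent_b,
              breakpoint = tp$breakpoint, template_id = tp$id,
              stringsAsFactors = FALSE)
          }
          sample_reads[k] <- paste(chars, collapse = "")
          names(sample_reads)[k] <- rid
        }
        reads[[sample_id]] <- sample_reads
        meta[[sample_id]] <- data.frame(
          read_id = names(sample_reads), sample_id = sample_id,
          subject_id = subject_id, body_site = site, region = design$region,
          stringsAsFactors = FALSE)
        truth_rows[[sample_id]] <- do.call(rbind, sample_truth)
      }
    }
    all_reads <- unlist(unname(reads))
    metadata <- do.call(rbind, unname(meta))
    rownames(metadata) <- NULL
    truth_reads <- do.call(rbind, unname(truth_rows))
    rownames(truth_reads) <- NULL

    tal <- table(factor(truth_reads$source_id, levels = src_ids))
    truth_sources <- data.frame(
      source_id = src_ids, rank = seq_len(n_src),
      abundance_weight = w_rank, planted_reads = as.integer(tal),
      stringsAsFactors = FALSE)
    truth_prev <- data.frame(
      source_id = rep(src_ids, times = ncol(plan)),
      body_site = rep(colnames(plan), each = nrow(plan)),
      presence_prob = as.vector(plan),
      stringsAsFactors = FALSE)

    list(reads = all_reads, metadata = metadata,
         truth = list(reads = truth_reads, sources = truth_sources,
                      prevalence = truth_prev, design = design))
  })
}

#' Build reference databases at planted divergence from the sources
#'
#' Each database holds a mutated copy of every source named in its plan
#' entry; sources omitted from a plan entry are absent from that database.
#' Realized identities (measured back with the alignment module) are
#' recorded so that planted priority classes can be derived.
#'
#' @param pool a [generate_source_pool()] result.
#' @param plan named list: db name -> `list(category =, divergence =)` where
#'   `divergence` is a named numeric vector (source id -> divergence) and
#'   `category` one of the [ref_db()] categories. At least one
#'   `sequenced_human` and one `cultured_named` database must be planned.
#' @param seed integer seed.
#' @param indel_fraction fraction of planted changes that are indels.
#' @return list with `dbs` (named list of [ref_db()]) and `identities`
#'   (data.frame: `db_name`, `category`, `source_id`, `ref_id`,
#'   `divergence`, `realized_identity`).
#' @export
generate_reference_databases <- function(pool, plan, seed = 1,
                                         indel_fraction = 0) {
  stopifnot(inherits(pool, "source_pool"), is.list(plan), length(plan) > 0)
  cats <- vapply(plan, `[[`, character(1), "category")
  for (need in c("sequenced_human", "cultured_named")) {
    if (!need %in% cats) {
      stop("plan must include a database of category '", need, "'",
           call. = FALSE)
    }
  }
  src_ids <- names(pool$sources)
  with_seed(seed, {
    dbs <- list()
    rows <- list()
    for (db_name in names(plan)) {
      entry <- plan[[db_name]]
      div <- entry$divergence
      if (is.null(names(div)) || !all(names(div) %in% src_ids)) {
        bad <- setdiff(names(div), src_ids)
        stop("unknown source id(s) in plan for '", db_name, "': ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      seqs <- character(length(div))
      ident <- numeric(length(div))
      for (i in seq_along(div)) {
        sid <- names(div)[i]
        mut <- .mutate_core(pool$sources[[sid]], div[[i]], indel_fraction)
        seqs[i] <- mut
        ident[i] <- seq_identity(mut, pool$sources[[sid]])
      }
      names(seqs) <- paste0(names(div), "|", db_name)
      dbs[[db_name]] <- ref_db(seqs, name = db_name,
                               category = entry$category)
      rows[[db_name]] <- data.frame(
        db_name = db_name, category = entry$category,
        source_id = names(div), ref_id = names(seqs),
        divergence = as.numeric(div), realized_identity = ident,
        stringsAsFactors = FALSE)
    }
    list(dbs = dbs, identities = do.call(rbind, unname(rows)))
  })
}

#' Planted priority classes implied by the generator's ground truth
#'
#' Applies the triage rules to the *planted* quantities: the realized
#' identity of each source to the sequenced-human databases and the planted
#' per-site presence probabilities. By construction this is the class the
#' pipeline should recover.
#'
#' @param identities the `identities` table from
#'   [generate_reference_databases()].
#' @param prevalence the `truth$prevalence` table from [simulate_samples()]
#'   (or any data.frame with `source_id`, `presence_prob`).
#' @param thresholds a [triage_thresholds()].
#' @return data.frame: `source_id`, `planted_seq_identity` (percent),
#'   `planted_cultured_identity` (percent), `planted_max_prevalence`,
#'   `planted_class`.
#' @export
planted_classes <- function(identities, prevalence,
                            thresholds = triage_thresholds()) {
  sh <- identities[identities$category == "sequenced_human", , drop = FALSE]
  cu <- identities[identities$category %in%
                     c("cultured_named", "cultured_unnamed"), , drop = FALSE]
  src <- sort(unique(identities$source_id))
  seq_id <- vapply(src, function(s) {
    v <- sh$realized_identity[sh$source_id == s]
    if (length(v) == 0) 0 else max(v)
  }, numeric(1)) * 100
  cul_id <- vapply(src, function(s) {
    v <- cu$realized_identity[cu$source_id == s]
    if (length(v) == 0) 0 else max(v)
  }, numeric(1)) * 100
  prev <- vapply(src, function(s) {
    v <- prevalence$presence_prob[prevalence$source_id == s]
    if (length(v) == 0) 0 else max(v)
  }, numeric(1))
  data.frame(source_id = src, planted_seq_identity = seq_id,
             planted_cultured_identity = cul_id,
             planted_max_prevalence = prev,
             planted_class = assign_priority(seq_id, prev, thresholds),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a simulated data set to disk
#'
#' Emits `reads.fasta`, `metadata.tsv`, one `refdb_<name>.fasta` per
#' database plus `db_manifest.tsv`, truth tables, and a JSON echo of all
#' generator parameters.
#'
#' @param sim result of [simulate_samples()].
#' @param refdbs result of [generate_reference_databases()] (optional).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, refdbs = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$reads, file.path(dir, "reads.fasta"))
  write_tsv(sim$metadata, file.path(dir, "metadata.tsv"))
  write_tsv(sim$truth$reads, file.path(dir, "truth_reads.tsv"))
  write_tsv(sim$truth$sources, file.path(dir, "truth_sources.tsv"))
  write_tsv(sim$truth$prevalence, file.path(dir, "truth_prevalence.tsv"))
  if (!is.null(refdbs)) {
    write_ref_dbs(refdbs$dbs, dir)
    write_tsv(refdbs$identities, file.path(dir, "truth_identities.tsv"))
  }
  d <- sim$truth$design
  cfg <- list(body_sites = d$body_sites,
              samples_per_site = d$samples_per_site,
              reads_per_sample = d$reads_per_sample,
              abundance_model = d$abundance_model,
              error_rate = d$error_rate, indel_rate = d$indel_rate,
              chimera_rate = d$chimera_rate,
              chimera_copies = d$chimera_copies,
              region = d$region, seed = d$seed)
  jsonlite::write_json(cfg, file.path(dir, "simulation_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
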