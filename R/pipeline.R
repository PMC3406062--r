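# End-to-end orchestration: cluster -> chimera screen -> reference search
# -> prevalence -> triage, in memory (most_wanted_pipeline) and as a
# file-based, re-entrant pipeline with a config (run_pipeline + the
# workbench CLI in cli.R).

#' Run the full prioritization pipeline in memory
#'
#' @param reads named character vector of amplicon reads.
#' @param metadata data.frame: `read_id`, `sample_id`, `subject_id`,
#'   `body_site`, `region`.
#' @param ref_dbs named list of [ref_db()] objects; must include at least
#'   one `sequenced_human` and one cultured category.
#' @param cluster [cluster_params()].
#' @param chimera [chimera_params()].
#' @param align [align_params()].
#' @param thresholds [triage_thresholds()].
#' @param presence_min minimum reads for presence in a sample.
#' @param non_hmp_mode if TRUE, chimera screening runs in reference mode
#'   only (the setting used for non-survey data sets).
#' @param chimera_ref_db name of the database used for reference-mode
#'   chimera screening; defaults to the first `comprehensive` database
#'   (else the first `sequenced_all`/`sequenced_human`).
#' @param use_prefilter k-mer prescreen inside clustering scans.
#' @return list: `clustering`, `verdicts`, `matches`, `otu_table`,
#'   `prevalence`, `mean_rel_abundance`, `records`, `table2`,
#'   `most_wanted`, `summary`.
#' @export
most_wanted_pipeline <- function(reads, metadata, ref_dbs,
                                 cluster = cluster_params(),
                                 chimera = chimera_params(),
                                 align = align_params(),
                                 thresholds = triage_thresholds(),
                                 presence_min = 1, non_hmp_mode = FALSE,
                                 chimera_ref_db = NULL,
                                 use_prefilter = TRUE) {
  manifest <- db_manifest(ref_dbs)
  if (is.null(chimera_ref_db)) {
    for (cat in c("comprehensive", "sequenced_all", "sequenced_human")) {
      hit <- manifest$db_name[manifest$category == cat]
      if (length(hit) > 0) { chimera_ref_db <- hit[1]; break }
    }
  }
  if (is.null(chimera_ref_db) || !chimera_ref_db %in% names(ref_dbs)) {
    stop("no usable reference database for chimera screening", call. = FALSE)
  }

  message("[cluster] ", length(reads), " reads")
  cl <- cluster_reads(reads, cluster, metadata, align, use_prefilter)
  message("[cluster] ", length(cl$otus), " OTUs, ",
          length(cl$unincorporated), " unincorporated reads")

  message("[chimera] screening ", length(cl$otus), " consensus sequences (",
          if (non_hmp_mode) "reference mode only" else "reference + de novo",
          ")")
  verdicts <- screen_chimeras(cl$otus, ref_dbs[[chimera_ref_db]], chimera,
                              align, denovo = !non_hmp_mode)
  nonchim <- !verdicts$chimeric
  message("[chimera] ", sum(!nonchim), " chimeric OTUs flagged")

  keep <- cl$otus[nonchim]
  cons <- setNames(vapply(keep, `[[`, character(1), "consensus"),
                   vapply(keep, `[[`, character(1), "otu_id"))
  message("[search] ", length(cons), " OTUs x ", length(ref_dbs),
          " databases")
  matches <- best_match_all(cons, ref_dbs, align)

  tab <- build_otu_table(cl$membership, metadata)
  prev <- prevalence_by_site(tab, presence_min)
  mra <- mean_relative_abundance(tab)

  regions <- setNames(vapply(cl$otus, `[[`, character(1), "region"),
                      vapply(cl$otus, `[[`, character(1), "otu_id"))
  records <- priority_records(matches, manifest, prev, regions, thresholds)
  records$mean_relative_abundance <- unname(mra[records$otu_id])
  t2 <- triage_table(records)
  mw <- most_wanted_report(records)
  message("[triage] high ", sum(records$priority_class == "high"),
          ", medium ", sum(records$priority_class == "medium"),
          ", low ", sum(records$priority_class == "low"))

  n_total <- length(reads)
  n_inc <- nrow(cl$membership)
  summary <- data.frame(
    metric = c("n_sequences", "n_incorporated", "pct_incorporated",
               "n_otus", "n_non_chimeric_otus"),
    value = c(n_total, n_inc, incorporation_summary(n_inc, n_total),
              length(cl$otus), sum(nonchim)),
    stringsAsFactors = FALSE)

  list(clustering = cl, verdicts = verdicts, matches = matches,
       otu_table = tab, prevalence = prev, mean_rel_abundance = mra,
       records = records, table2 = t2, most_wanted = mw, summary = summary,
       chimera_ref_db = chimera_ref_db)
}

#' Default pipeline configuration
#'
#' @return nested list of every tunable with its default; see the
#'   parameter constructors for meanings.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    output_dir = "mostwanted_out",
    simulate = NULL,   # list(preset="standard", n_sources=, ...) or NULL
    input = NULL,      # list(reads_fasta=, metadata_tsv=, db_manifest=)
    cluster = list(identity_threshold = 0.97, min_cluster_size = 2),
    chimera = list(top_k_parents = 4, min_divergence_gain = 0.02,
                   abskew = 2.0, min_model_identity = 0.90),
    alignment = list(match = 1, mismatch = -1, gap_open = -2,
                     gap_extend = -1, end_gaps_free = TRUE),
    thresholds = list(high_identity_max = 90, low_identity_min = 98,
                      prevalence_min = 0.20, cultured_identity_min = 98),
    presence_min = 1,
    non_hmp_mode = FALSE,
    chimera_ref_db = NULL)
}

# deep-merge user values over defaults
.merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]])) {
      base[[k]] <- .merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Read a pipeline configuration file (JSON)
#'
#' Missing fields take their defaults from [default_pipeline_config()].
#'
#' @param path JSON config file.
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  .merge_config(default_pipeline_config(), user)
}

.cfg_params <- function(config) {
  list(cluster = do.call(cluster_params, config$cluster),
       chimera = do.call(chimera_params, config$chimera),
       align = do.call(align_params, config$alignment),
       thresholds = do.call(triage_thresholds, config$thresholds))
}

# config echo used for hashing and the manifest: everything except paths
.cfg_echo <- function(config) {
  config$output_dir <- NULL
  config
}

.write_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl <- res$clustering
  cons <- setNames(vapply(cl$otus, `[[`, character(1), "consensus"),
                   vapply(cl$otus, `[[`, character(1), "otu_id"))
  write_fasta(cons, file.path(dir, "otus.fasta"))
  write_tsv(cl$membership, file.path(dir, "membership.tsv"))
  write_tsv(res$summary, file.path(dir, "summary.tsv"))
  write_tsv(res$verdicts, file.path(dir, "chimera_verdicts.tsv"))
  write_tsv(res$matches, file.path(dir, "matches.tsv"))
  tab <- as.data.frame(unclass(res$otu_table))
  tab <- cbind(data.frame(otu_id = rownames(res$otu_table),
                          stringsAsFactors = FALSE), tab)
  write_tsv(tab, file.path(dir, "otu_table.tsv"))
  prev <- res$prevalence
  prev$mean_relative_abundance <-
    unname(res$mean_rel_abundance[prev$otu_id])
  write_tsv(prev, file.path(dir, "prevalence.tsv"))
  write_tsv(res$records, file.path(dir, "triage.tsv"))
  write_tsv(res$table2, file.path(dir, "table2.tsv"))
  write_tsv(res$most_wanted, file.path(dir, "most_wanted.tsv"))

  # per-database identity vs prevalence (scatter-plot data)
  fig3 <- merge(res$matches,
                res$records[, c("otu_id", "max_prevalence",
                                "priority_class")],
                by.x = "query_id", by.y = "otu_id")
  fig3 <- fig3[order(fig3$db_name, fig3$query_id),
               c("query_id", "db_name", "identity", "max_prevalence",
                 "priority_class")]
  names(fig3)[1] <- "otu_id"
  write_tsv(fig3, file.path(dir, "fig3_data.tsv"))
  fig5 <- res$records[, c("otu_id", "region", "sequenced_identity",
                          "cultured_identity", "max_prevalence",
                          "priority_class")]
  write_tsv(fig5, file.path(dir, "fig5_data.tsv"))
  invisible(dir)
}

#' Run the pipeline from a configuration, writing all outputs
#'
#' Stages run in order simulate (optional) -> cluster -> chimera -> search
#' -> prevalence -> triage -> report. Every output file is listed in
#' `run_manifest.json` together with its MD5 digest and a hash of the
#' configuration; rerunning with an identical configuration reproduces
#' identical outputs.
#'
#' @param config a config list (see [default_pipeline_config()] /
#'   [read_pipeline_config()]).
#' @return invisibly, list with `result` (the in-memory pipeline result),
#'   `output_dir` and `manifest`.
#' @export
run_pipeline <- function(config) {
  config <- .merge_config(default_pipeline_config(), config)
  dir <- config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- .cfg_params(config)

  if (!is.null(config$simulate)) {
    s <- config$simulate
    message("[simulate] preset standard, seed ", config$seed)
    fx <- standard_fixture(
      seed = as.integer(config$seed),
      n_sources = if (is.null(s$n_sources)) 60 else s$n_sources,
      samples_per_site = if (is.null(s$samples_per_site)) 40
                         else s$samples_per_site,
      reads_per_sample = if (is.null(s$reads_per_sample)) 200
                         else s$reads_per_sample)
    sim_dir <- file.path(dir, "sim")
    write_simulation(list(reads = fx$reads, metadata = fx$metadata,
                          truth = fx$truth),
                     refdbs = list(dbs = fx$ref_dbs,
                                   identities = fx$truth$identities),
                     dir = sim_dir)
    reads <- fx$reads
    metadata <- fx$metadata
    ref_dbs <- fx$ref_dbs
  } else {
    inp <- config$input
    if (is.null(inp)) stop("config needs either simulate or input",
                           call. = FALSE)
    reads <- read_fasta(inp$reads_fasta)
    metadata <- read_tsv_strict(inp$metadata_tsv)
    ref_dbs <- read_ref_dbs(inp$db_manifest)
  }

  res <- most_wanted_pipeline(
    reads, metadata, ref_dbs, cluster = p$cluster, chimera = p$chimera,
    align = p$align, thresholds = p$thresholds,
    presence_min = config$presence_min,
    non_hmp_mode = isTRUE(config$non_hmp_mode),
    chimera_ref_db = config$chimera_ref_db)
  .write_results(res, dir)

  cfg_json <- jsonlite::toJSON(.cfg_echo(config), auto_unbox = TRUE,
                               digits = NA)
  cfg_path <- file.path(dir, "config_echo.json")
  writeLines(cfg_json, cfg_path)
  files <- c("otus.fasta", "membership.tsv", "summary.tsv",
             "chimera_verdicts.tsv", "matches.tsv", "otu_table.tsv",
             "prevalence.tsv", "triage.tsv", "table2.tsv",
             "most_wanted.tsv", "fig3_data.tsv", "fig5_data.tsv")
  md5 <- tools::md5sum(file.path(dir, files))
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   files = setNames(as.list(unname(md5)), files))
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(result = res, output_dir = dir, manifest = manifest))
}
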