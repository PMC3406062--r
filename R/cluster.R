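# Greedy abundance-ordered consensus clustering. Reads are dereplicated,
# unique sequences are visited in decreasing-abundance order (ties by
# lexicographic sequence order), each joins the first existing cluster whose
# representative it matches at >= the identity threshold, otherwise it
# founds a new cluster. Consensus sequences are rebuilt from the members,
# one re-recruitment pass against the updated consensus stabilizes
# membership, and clusters below the minimum size dissolve back to the
# unincorporated pool.

#' OTU clustering parameters
#'
#' @param identity_threshold identity for OTU inclusion (default 0.97, the
#'   conventional species-level cutoff).
#' @param min_cluster_size clusters with fewer reads dissolve to the
#'   unincorporated pool (default 2: singletons, which are error-enriched,
#'   never become OTUs).
#' @return object of class `cluster_params`.
#' @export
cluster_params <- function(identity_threshold = 0.97, min_cluster_size = 2) {
  if (!(identity_threshold > 0.5 && identity_threshold <= 1)) {
    stop("identity_threshold must be in (0.5, 1]", call. = FALSE)
  }
  stopifnot(min_cluster_size >= 1)
  structure(list(identity_threshold = identity_threshold,
                 min_cluster_size = min_cluster_size),
            class = "cluster_params")
}

#' Cluster amplicon reads into consensus OTUs
#'
#' @param reads named character vector (read id -> sequence), single
#'   variable region.
#' @param params a [cluster_params()].
#' @param metadata optional data.frame with `read_id`, `sample_id`,
#'   `body_site`, `region`; when given, per-sample counts are tracked and a
#'   mix of region tags is an error.
#' @param align [align_params()] used for all identity computations.
#' @param use_prefilter use the lossless k-mer prescreen inside the scans
#'   (identical results, much faster on unrelated pairs).
#' @return list with `otus` (list of OTU objects: `otu_id`, `region`,
#'   `consensus`, `n_reads`, `per_sample_counts`, `member_read_ids`),
#'   `membership` (data.frame `read_id`, `otu_id`), `unincorporated`
#'   (read ids), and `params`.
#' @export
cluster_reads <- function(reads, params = cluster_params(), metadata = NULL,
                          align = align_params(), use_prefilter = TRUE) {
  if (length(reads) == 0) stop("no reads supplied", call. = FALSE)
  if (is.null(names(reads))) stop("reads must be named", call. = FALSE)
  align <- .ap(align)
  region <- NA_character_
  if (!is.null(metadata)) {
    regions <- unique(metadata$region)
    if (length(regions) > 1) {
      stop("mixed region tags in metadata: ",
           paste(regions, collapse = ", "), call. = FALSE)
    }
    region <- regions[1]
  }

  # dereplicate; order by abundance desc, ties by lexicographic sequence
  derep <- table(reads)
  uniq <- names(derep)
  counts <- as.integer(derep)
  o <- order(-counts, uniq)
  uniq <- uniq[o]
  counts <- counts[o]

  t <- params$identity_threshold
  assign1 <- cpp_greedy_cluster(uniq, t, align$match, align$mismatch,
                                align$gap_open, align$gap_extend,
                                align$end_gaps_free, use_prefilter)

  # founder (seed) sequence of each cluster = first unique sequence assigned
  n_cl <- max(assign1)
  seed_of <- character(n_cl)
  for (c in seq_len(n_cl)) seed_of[c] <- uniq[match(c, assign1)]

  build_consensus <- function(assign) {
    vapply(seq_len(n_cl), function(c) {
      idx <- which(assign == c)
      if (length(idx) == 0) return(seed_of[c])
      cpp_consensus(seed_of[c], uniq[idx], as.numeric(counts[idx]),
                    align$match, align$mismatch, align$gap_open,
                    align$gap_extend, align$end_gaps_free)
    }, character(1))
  }
  cons <- build_consensus(assign1)

  # one re-recruitment pass against the updated consensus sequences
  assign2 <- vapply(uniq, function(s) {
    r <- cpp_first_match(s, cons, t, align$match, align$mismatch,
                         align$gap_open, align$gap_extend,
                         align$end_gaps_free, use_prefilter)
    as.integer(r$index)
  }, integer(1), USE.NAMES = FALSE)
  cons <- build_consensus(assign2)

  # dissolve small clusters
  cl_reads <- vapply(seq_len(n_cl), function(c)
    sum(counts[assign2 == c]), integer(1))
  keep <- which(cl_reads >= params$min_cluster_size)

  # final ids ordered by abundance (ties: creation order)
  keep <- keep[order(-cl_reads[keep], keep)]
  otu_ids <- sprintf("otu_%04d", seq_along(keep))

  read_seq <- unname(reads)
  read_uix <- match(read_seq, uniq)
  read_cl <- assign2[read_uix]
  read_otu <- rep(NA_character_, length(reads))
  otus <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    c <- keep[k]
    members <- which(read_cl == c)
    read_otu[members] <- otu_ids[k]
    member_ids <- names(reads)[members]
    if (!is.null(metadata)) {
      ms <- metadata$sample_id[match(member_ids, metadata$read_id)]
      per_sample <- table(ms)
      per_sample <- setNames(as.integer(per_sample), names(per_sample))
    } else {
      per_sample <- setNames(length(members), "all")
    }
    otus[[k]] <- structure(
      list(otu_id = otu_ids[k], region = region, consensus = cons[c],
           n_reads = length(members), per_sample_counts = per_sample,
           member_read_ids = member_ids),
      class = "mw_otu")
  }
  incorporated <- !is.na(read_otu)
  list(otus = otus,
       membership = data.frame(read_id = names(reads)[incorporated],
                               otu_id = read_otu[incorporated],
                               stringsAsFactors = FALSE),
       unincorporated = names(reads)[!incorporated],
       params = params)
}

#' @export
print.mw_otu <- function(x, ...) {
  cat(x$otu_id, ": ", x$n_reads, " reads, consensus ", nchar(x$consensus),
      " nt\n", sep = "")
  invisible(x)
}

#' Seed-anchored majority consensus of cluster members
#'
#' Members are aligned to the seed; per seed column the weighted-majority
#' base wins, ties go to the seed base, columns with a strict gap majority
#' are deleted, and insertion columns appear only with a strict majority.
#'
#' @param seed the cluster seed sequence (anchor for columns).
#' @param members character vector of member sequences.
#' @param weights per-member vote weights (e.g. dereplicated read counts).
#' @param align [align_params()].
#' @return the consensus sequence.
#' @export
consensus_sequence <- function(seed, members, weights = NULL,
                               align = align_params()) {
  if (length(members) == 0) stop("no members supplied", call. = FALSE)
  align <- .ap(align)
  seed <- check_dna(seed, "seed")
  members <- vapply(members, check_dna, character(1), what = "member",
                    USE.NAMES = FALSE)
  if (is.null(weights)) weights <- rep(1, length(members))
  stopifnot(length(weights) == length(members), all(weights > 0))
  cpp_consensus(seed, members, as.numeric(weights), align$match,
                align$mismatch, align$gap_open, align$gap_extend,
                align$end_gaps_free)
}

#' Percentage of reads incorporated into OTUs
#'
#' Reported the way survey summary tables print it: truncated (not rounded)
#' to one decimal place.
#'
#' @param n_incorporated reads assigned to an OTU.
#' @param n_total total reads.
#' @return percentage with one decimal.
#' @export
incorporation_summary <- function(n_incorporated, n_total) {
  if (length(n_total) != 1 || n_total <= 0) {
    stop("n_total must be a single positive count", call. = FALSE)
  }
  if (n_incorporated < 0 || n_incorporated > n_total) {
    stop("n_incorporated must be between 0 and n_total", call. = FALSE)
  }
  pct <- 100 * n_incorporated / n_total
  floor(pct * 10 + 1e-6) / 10
}

#' Cumulative rank-abundance curve over OTUs
#'
#' @param otus list of OTU objects from [cluster_reads()].
#' @param n_total_reads total reads in the data set (incorporated or not);
#'   the final cumulative fraction equals the incorporated fraction.
#' @return data.frame: `rank`, `otu_id`, `n_reads`, `cumulative_fraction`.
#' @export
rank_abundance <- function(otus, n_total_reads) {
  if (length(otus) == 0) stop("no OTUs supplied", call. = FALSE)
  stopifnot(n_total_reads > 0)
  n <- vapply(otus, `[[`, numeric(1), "n_reads")
  id <- vapply(otus, `[[`, character(1), "otu_id")
  o <- order(-n, id)
  data.frame(rank = seq_along(o), otu_id = id[o], n_reads = n[o],
             cumulative_fraction = cumsum(n[o]) / n_total_reads,
             stringsAsFactors = FALSE)
}
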