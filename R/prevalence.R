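# OTU x sample count table and the per-body-site prevalence statistics the
# triage step consumes: an OTU is "present" in a sample when at least
# `presence_min` reads were assigned to it, prevalence at a site is the
# fraction of that site's samples in which the OTU is present, and each OTU
# carries the site of its highest prevalence.

#' Build the OTU x sample count table
#'
#' @param membership data.frame with `read_id` and `otu_id`.
#' @param metadata data.frame with `read_id`, `sample_id`, `body_site`;
#'   every read in `membership` must appear here. All samples present in
#'   `metadata` become columns, even if no read was assigned.
#' @return an `otu_table`: integer matrix (OTUs x samples) with a
#'   `sample_sites` attribute mapping sample id -> body site.
#' @export
build_otu_table <- function(membership, metadata) {
  stopifnot(is.data.frame(membership), is.data.frame(metadata))
  samples <- unique(metadata$sample_id)
  sites <- metadata$body_site[match(samples, metadata$sample_id)]
  if (any(is.na(sites))) {
    stop("every sample must have a body_site", call. = FALSE)
  }
  mi <- match(membership$read_id, metadata$read_id)
  if (anyNA(mi)) {
    bad <- membership$read_id[which(is.na(mi))[1]]
    stop("read id not found in metadata: ", bad, call. = FALSE)
  }
  otus <- sort(unique(membership$otu_id))
  m <- matrix(0L, nrow = length(otus), ncol = length(samples),
              dimnames = list(otus, samples))
  if (nrow(membership) > 0) {
    tab <- table(factor(membership$otu_id, levels = otus),
                 factor(metadata$sample_id[mi], levels = samples))
    m[] <- as.integer(tab)
  }
  structure(m, sample_sites = setNames(sites, samples), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table: ", nrow(x), " OTUs x ", ncol(x), " samples, ",
      sum(x), " reads\n", sep = "")
  invisible(x)
}

.table_sites <- function(table) {
  sites <- attr(table, "sample_sites")
  if (is.null(sites)) stop("otu_table lacks sample site metadata",
                           call. = FALSE)
  sites[colnames(table)]
}

#' Per-body-site prevalence of each OTU
#'
#' @param table an `otu_table` from [build_otu_table()].
#' @param presence_min minimum read count for presence in a sample
#'   (default 1).
#' @param sites optional site set to report; sites with zero samples are
#'   excluded with a warning.
#' @return data.frame: `otu_id`, one `prev_<site>` column per site,
#'   `max_site` (ties: lexicographically first site), `max_prevalence`.
#' @export
prevalence_by_site <- function(table, presence_min = 1, sites = NULL) {
  stopifnot(inherits(table, "otu_table"), presence_min >= 1)
  sample_sites <- .table_sites(table)
  if (is.null(sites)) sites <- sort(unique(sample_sites))
  n_per_site <- vapply(sites, function(s) sum(sample_sites == s), numeric(1))
  if (any(n_per_site == 0)) {
    warning("excluding site(s) with zero samples: ",
            paste(sites[n_per_site == 0], collapse = ", "))
    sites <- sites[n_per_site > 0]
    n_per_site <- n_per_site[n_per_site > 0]
  }
  sites <- sort(sites)
  present <- table >= presence_min
  prev <- vapply(sites, function(s) {
    cols <- which(sample_sites == s)
    rowSums(present[, cols, drop = FALSE]) / length(cols)
  }, numeric(nrow(table)))
  prev <- matrix(prev, nrow = nrow(table),
                 dimnames = list(rownames(table), sites))
  max_i <- apply(prev, 1, which.max)  # first max = lexicographically first
  out <- data.frame(otu_id = rownames(table), stringsAsFactors = FALSE)
  for (s in sites) out[[paste0("prev_", s)]] <- prev[, s]
  out$max_site <- sites[max_i]
  out$max_prevalence <- prev[cbind(seq_len(nrow(prev)), max_i)]
  if (nrow(out) == 0) {
    out$max_site <- character(0)
    out$max_prevalence <- numeric(0)
  }
  rownames(out) <- NULL
  out
}

#' Mean relative abundance of each OTU
#'
#' Per retained sample, counts are normalized by the sample's column sum;
#' the mean over samples is reported. Empty samples are dropped with a
#' warning.
#'
#' @param table an `otu_table`.
#' @return named numeric vector (otu id -> mean relative abundance).
#' @export
mean_relative_abundance <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  cs <- colSums(table)
  if (all(cs == 0)) stop("all samples are empty", call. = FALSE)
  if (any(cs == 0)) {
    warning("dropping ", sum(cs == 0), " empty sample(s)")
  }
  keep <- cs > 0
  rel <- sweep(table[, keep, drop = FALSE], 2, cs[keep], "/")
  setNames(rowMeans(rel), rownames(table))
}
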