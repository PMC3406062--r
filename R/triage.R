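# Sequencing-priority triage. Identity bands are half-open: [0, 90) is
# high priority ("most wanted"), [90, 98) is medium, [98, 100] is low; any
# OTU below the prevalence floor in every body site is low priority
# regardless of identity. Only identity to *human-derived sequenced*
# collections can demote an OTU -- a close match in an environmental
# comprehensive database never does.

#' Triage thresholds
#'
#' @param high_identity_max identity (percent) below which an OTU is high
#'   priority.
#' @param low_identity_min identity (percent) at or above which an OTU is
#'   low priority.
#' @param prevalence_min minimum max-site prevalence for medium/high
#'   priority.
#' @param cultured_identity_min identity (percent) to a cultured collection
#'   at or above which an OTU counts as cultured.
#' @return object of class `triage_thresholds`.
#' @export
triage_thresholds <- function(high_identity_max = 90, low_identity_min = 98,
                              prevalence_min = 0.20,
                              cultured_identity_min = 98) {
  if (high_identity_max >= low_identity_min) {
    stop("high_identity_max must be below low_identity_min", call. = FALSE)
  }
  if (prevalence_min <= 0 || prevalence_min >= 1) {
    stop("prevalence_min must be in (0, 1)", call. = FALSE)
  }
  structure(list(high_identity_max = high_identity_max,
                 low_identity_min = low_identity_min,
                 prevalence_min = prevalence_min,
                 cultured_identity_min = cultured_identity_min),
            class = "triage_thresholds")
}

.cat_of <- function(matches, manifest) {
  manifest$category[match(matches$db_name, manifest$db_name)]
}

#' Identity to sequenced human-derived organisms
#'
#' The maximum best-match identity over databases of category
#' `sequenced_human` only; matches to comprehensive or environmental
#' collections are ignored so that they cannot demote an OTU.
#'
#' @param matches data.frame of best matches for one query (`db_name`,
#'   `identity` as fractions).
#' @param manifest data.frame mapping `db_name` to `category` (see
#'   [db_manifest()]).
#' @return identity in percent.
#' @export
sequenced_identity <- function(matches, manifest) {
  cat <- .cat_of(matches, manifest)
  keep <- which(cat == "sequenced_human")
  if (length(keep) == 0) {
    stop("no sequenced_human database among the matches", call. = FALSE)
  }
  100 * max(matches$identity[keep])
}

#' Assign a sequencing-priority class
#'
#' Rules, in order: below the prevalence floor -> low; identity below
#' `high_identity_max` -> high; below `low_identity_min` -> medium;
#' otherwise low. Vectorized over OTUs.
#'
#' @param seq_id identity (percent) to sequenced human-derived databases.
#' @param max_prev max per-site prevalence (fraction).
#' @param t a [triage_thresholds()].
#' @return character vector in `c("high", "medium", "low")`.
#' @export
assign_priority <- function(seq_id, max_prev, t = triage_thresholds()) {
  stopifnot(length(seq_id) == length(max_prev))
  ifelse(max_prev < t$prevalence_min, "low",
         ifelse(seq_id < t$high_identity_max, "high",
                ifelse(seq_id < t$low_identity_min, "medium", "low")))
}

#' Cultured status of an OTU
#'
#' @param matches data.frame of best matches for one query.
#' @param manifest database category manifest.
#' @param t a [triage_thresholds()].
#' @return list with `cultured` (logical: identity at or above
#'   `cultured_identity_min`) and `cultured_identity` (percent, max over
#'   the named and unnamed cultured collections).
#' @export
cultured_status <- function(matches, manifest, t = triage_thresholds()) {
  cat <- .cat_of(matches, manifest)
  keep <- which(cat %in% c("cultured_named", "cultured_unnamed"))
  if (length(keep) == 0) {
    stop("no cultured database among the matches", call. = FALSE)
  }
  ci <- 100 * max(matches$identity[keep])
  list(cultured = ci >= t$cultured_identity_min, cultured_identity = ci)
}

#' Assemble per-OTU priority records
#'
#' Joins best-match identities, prevalence and region labels into one
#' record per (non-chimeric) OTU and assigns the priority class.
#'
#' @param matches data.frame of best matches (`query_id`, `db_name`,
#'   `ref_id`, `identity`).
#' @param manifest database category manifest ([db_manifest()]).
#' @param prevalence data.frame from [prevalence_by_site()].
#' @param regions named character vector (otu id -> region tag).
#' @param thresholds a [triage_thresholds()].
#' @return data.frame: `otu_id`, `region`, `sequenced_identity`,
#'   `cultured_identity`, `cultured`, `comprehensive_identity`,
#'   `comprehensive_ref`, `max_site`, `max_prevalence`, `priority_class`.
#' @export
priority_records <- function(matches, manifest, prevalence, regions,
                             thresholds = triage_thresholds()) {
  ids <- unique(matches$query_id)
  rows <- lapply(ids, function(q) {
    m <- matches[matches$query_id == q, , drop = FALSE]
    sid <- sequenced_identity(m, manifest)
    cs <- cultured_status(m, manifest, thresholds)
    comp <- which(.cat_of(m, manifest) == "comprehensive")
    if (length(comp) > 0) {
      ci <- which.max(m$identity[comp])
      comp_id <- 100 * m$identity[comp][ci]
      comp_ref <- m$ref_id[comp][ci]
    } else {
      comp_id <- NA_real_
      comp_ref <- NA_character_
    }
    p <- prevalence[prevalence$otu_id == q, , drop = FALSE]
    if (nrow(p) == 0) {
      stop("no prevalence record for OTU ", q, call. = FALSE)
    }
    data.frame(otu_id = q,
               region = unname(regions[q]),
               sequenced_identity = sid,
               cultured_identity = cs$cultured_identity,
               cultured = cs$cultured,
               comprehensive_identity = comp_id,
               comprehensive_ref = comp_ref,
               max_site = p$max_site, max_prevalence = p$max_prevalence,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$priority_class <- assign_priority(out$sequenced_identity,
                                        out$max_prevalence, thresholds)
  rownames(out) <- NULL
  out
}

#' Priority class counts per region with a combined column
#'
#' @param records data.frame from [priority_records()] (needs
#'   `priority_class` and `region`).
#' @param regions optional region column order.
#' @return data.frame: `priority_class` rows (`high`, `medium`, `low`,
#'   `total`), one column per region, and `combined` (the row sum over
#'   regions).
#' @export
triage_table <- function(records, regions = NULL) {
  classes <- c("high", "medium", "low")
  if (is.null(regions)) {
    regions <- if (nrow(records) > 0) sort(unique(records$region))
               else character(0)
  }
  m <- matrix(0L, nrow = 3, ncol = length(regions),
              dimnames = list(classes, regions))
  if (nrow(records) > 0) {
    tab <- table(factor(records$priority_class, levels = classes),
                 factor(records$region, levels = regions))
    m[] <- as.integer(tab)
  }
  out <- data.frame(priority_class = c(classes, "total"),
                    stringsAsFactors = FALSE)
  for (r in regions) out[[r]] <- c(m[, r], sum(m[, r]))
  out$combined <- c(rowSums(m), sum(m))
  out
}

#' Ranked report of the high-priority ("most wanted") OTUs
#'
#' @param records data.frame from [priority_records()].
#' @return the high-priority rows sorted by max prevalence (descending),
#'   then sequenced identity (ascending), then OTU id.
#' @export
most_wanted_report <- function(records) {
  hi <- records[records$priority_class == "high", , drop = FALSE]
  cols <- c("otu_id", "region", "max_site", "max_prevalence",
            "sequenced_identity", "cultured", "comprehensive_identity",
            "comprehensive_ref")
  hi <- hi[order(-hi$max_prevalence, hi$sequenced_identity, hi$otu_id),
           cols, drop = FALSE]
  rownames(hi) <- NULL
  hi
}
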