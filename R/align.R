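#' Alignment scoring parameters
#'
#' Scoring scheme for the affine-gap global aligner. A gap of length `g`
#' costs `gap_open + (g - 1) * gap_extend`. With `end_gaps_free = TRUE`
#' (the default, a semi-global or "overlap" alignment) terminal gaps on
#' either sequence score zero, so a sub-region amplicon aligned against a
#' full-length reference is not penalized for the length difference.
#'
#' @param match match score (positive).
#' @param mismatch mismatch score (must be below `match`).
#' @param gap_open score of the first base of a gap (negative).
#' @param gap_extend score of each subsequent gap base (negative).
#' @param end_gaps_free logical; score terminal gaps as zero.
#' @return an object of class `align_params`.
#' @export
align_params <- function(match = 1, mismatch = -1, gap_open = -2,
                         gap_extend = -1, end_gaps_free = TRUE) {
  stopifnot(is.numeric(match), is.numeric(mismatch), is.numeric(gap_open),
            is.numeric(gap_extend), is.logical(end_gaps_free))
  if (gap_open >= 0 || gap_extend >= 0) {
    stop("gap penalties must be negative", call. = FALSE)
  }
  if (match <= mismatch) stop("match score must exceed mismatch", call. = FALSE)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, end_gaps_free = end_gaps_free),
            class = "align_params")
}

.ap <- function(params) {
  if (is.null(params)) params <- align_params()
  stopifnot(inherits(params, "align_params"))
  params
}

#' Global pairwise alignment with affine gaps
#'
#' Optimal global (Needleman-Wunsch/Gotoh) alignment of two nucleotide
#' sequences. Traceback ties prefer match/mismatch columns over gaps in the
#' second sequence over gaps in the first, so results are deterministic.
#'
#' @param a,b nucleotide sequences (IUPAC characters).
#' @param params an [align_params()] object.
#' @return an object of class `mw_alignment`: list with `aligned_a`,
#'   `aligned_b` (gapped strings of equal length), `score`, and the input
#'   lengths.
#' @examples
#' aln <- global_align("ACGTACGT", "ACGACGT")
#' percent_identity(aln)
#' @export
global_align <- function(a, b, params = align_params()) {
  params <- .ap(params)
  a <- check_dna(a, "a")
  b <- check_dna(b, "b")
  r <- cpp_align(a, b, params$match, params$mismatch, params$gap_open,
                 params$gap_extend, params$end_gaps_free)
  structure(list(aligned_a = r$aligned_a, aligned_b = r$aligned_b,
                 score = r$score, length_a = nchar(a), length_b = nchar(b),
                 params = params),
            class = "mw_alignment")
}

#' @export
print.mw_alignment <- function(x, ...) {
  cat("Global alignment (score ", x$score, ")\n", sep = "")
  cat(" a: ", x$aligned_a, "\n b: ", x$aligned_b, "\n", sep = "")
  invisible(x)
}

# terminal-gap spans: maximal prefix/suffix of columns containing a gap
.aln_core <- function(aln) {
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  L <- length(ca)
  gap <- ca == "-" | cb == "-"
  lead <- 0
  while (lead < L && gap[lead + 1]) lead <- lead + 1
  trail <- 0
  while (trail < L - lead && gap[L - trail]) trail <- trail + 1
  list(ca = ca, cb = cb, lead = lead, trail = trail, L = L)
}

#' Percent identity across a global alignment
#'
#' Fraction of identical-base columns among the columns outside the
#' terminal-gap spans; internal gap columns count as mismatches. The
#' denominator is never smaller than the shorter input sequence: with free
#' end gaps the score-optimal alignment of two unrelated sequences
#' degenerates to a short suffix/prefix overlap, and counting only its few
#' columns would report a spuriously high identity, so the uncovered bases
#' of the shorter sequence count as mismatches instead.
#'
#' @param aln an `mw_alignment` from [global_align()].
#' @return identity as a fraction in `[0, 1]`.
#' @export
percent_identity <- function(aln) {
  stopifnot(inherits(aln, "mw_alignment"))
  k <- .aln_core(aln)
  core <- seq_len(k$L - k$lead - k$trail) + k$lead
  if (length(core) == 0) {
    stop("alignment has no columns outside the terminal-gap spans",
         call. = FALSE)
  }
  denom <- max(length(core), min(aln$length_a, aln$length_b))
  sum(k$ca[core] != "-" & k$ca[core] == k$cb[core]) / denom
}

#' Aligning fraction of a query
#'
#' Fraction of the query's bases lying inside the aligned region (outside
#' the terminal-gap spans), capped at 1. The query is the first sequence of
#' the alignment.
#'
#' @param aln an `mw_alignment`.
#' @param query_length length of the original query read; defaults to the
#'   length of the first sequence.
#' @return a fraction in `[0, 1]`.
#' @export
aligning_fraction <- function(aln, query_length = aln$length_a) {
  stopifnot(inherits(aln, "mw_alignment"))
  if (!is.numeric(query_length) || query_length <= 0) {
    stop("query_length must be positive", call. = FALSE)
  }
  k <- .aln_core(aln)
  core <- seq_len(k$L - k$lead - k$trail) + k$lead
  min(1, sum(k$ca[core] != "-") / query_length)
}

#' Pairwise percent identity
#'
#' Convenience wrapper: align and return identity in one step. The result
#' is symmetric in its two arguments: when several alignments are
#' co-optimal the traceback choice depends on argument order, so the pair
#' is aligned in a canonical (lexicographic) order.
#'
#' @inheritParams global_align
#' @return identity fraction.
#' @export
seq_identity <- function(a, b, params = align_params()) {
  params <- .ap(params)
  a <- check_dna(a, "a")
  b <- check_dna(b, "b")
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  unname(cpp_align_stats(a, b, params$match, params$mismatch, params$gap_open,
                         params$gap_extend, params$end_gaps_free)["identity"])
}

# bulk identity/aligning-fraction scan of one query against many refs
.identity_scan <- function(query, refs, params) {
  cpp_identity_many(query, refs, params$match, params$mismatch,
                    params$gap_open, params$gap_extend, params$end_gaps_free)
}

#' Construct a categorized 16S reference database
#'
#' @param sequences named character vector (record id -> sequence). Record
#'   order is preserved and breaks best-hit ties (first record wins).
#' @param name database name.
#' @param category one of `comprehensive`, `sequenced_all`,
#'   `sequenced_human`, `cultured_named`, `cultured_unnamed`.
#' @return an object of class `ref_db`.
#' @export
ref_db <- function(sequences, name, category) {
  cats <- c("comprehensive", "sequenced_all", "sequenced_human",
            "cultured_named", "cultured_unnamed")
  category <- match.arg(category, cats)
  if (length(sequences) == 0) stop("reference database is empty", call. = FALSE)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must have unique names", call. = FALSE)
  }
  sequences <- vapply(sequences, check_dna, character(1), what = name)
  structure(list(name = name, category = category, sequences = sequences),
            class = "ref_db")
}

#' @export
print.ref_db <- function(x, ...) {
  cat("ref_db '", x$name, "' [", x$category, "]: ", length(x$sequences),
      " sequences\n", sep = "")
  invisible(x)
}

#' Best match of a query in a reference database
#'
#' Scans every record, computes percent identity across a global alignment,
#' and returns the best hit. Ties are broken by database record order.
#'
#' @param query nucleotide sequence.
#' @param db a [ref_db()].
#' @param params [align_params()].
#' @param query_id optional id carried into the result.
#' @return one-row data.frame: `query_id`, `db_name`, `ref_id`, `identity`,
#'   `aligning_fraction`.
#' @export
best_match <- function(query, db, params = align_params(),
                       query_id = NA_character_) {
  stopifnot(inherits(db, "ref_db"))
  params <- .ap(params)
  query <- check_dna(query, "query")
  m <- .identity_scan(query, db$sequences, params)
  i <- which.max(m[, "identity"])  # first maximum wins
  data.frame(query_id = query_id, db_name = db$name,
             ref_id = names(db$sequences)[i],
             identity = m[i, "identity"],
             aligning_fraction = m[i, "aligning_fraction"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Best matches of many queries against many databases
#'
#' @param queries named character vector of query sequences.
#' @param dbs list of [ref_db()] objects.
#' @param params [align_params()].
#' @return data.frame with one row per query x database.
#' @export
best_match_all <- function(queries, dbs, params = align_params()) {
  stopifnot(length(queries) > 0, length(dbs) > 0)
  if (inherits(dbs, "ref_db")) dbs <- list(dbs)
  params <- .ap(params)
  out <- vector("list", length(queries) * length(dbs))
  k <- 1
  for (qi in seq_along(queries)) {
    for (db in dbs) {
      out[[k]] <- best_match(queries[[qi]], db, params,
                             query_id = names(queries)[qi])
      k <- k + 1
    }
  }
  do.call(rbind, out)
}

#' Match single-cell 16S reads to OTU consensus sequences
#'
#' For each cell, every read is matched against the OTU database; the read
#' with the highest aligning fraction (alignment length / query read length)
#' represents the cell. Ties prefer higher identity, then read order. By
#' default both orientations of each read are tried and the better one kept.
#'
#' @param cell_reads named list: cell id -> character vector of reads.
#' @param otu_db a [ref_db()] of OTU consensus sequences.
#' @param id_threshold identity threshold for calling a confident assignment.
#' @param reverse_complement also try the reverse complement of each read.
#' @param params [align_params()].
#' @return data.frame: `cell_id`, `read_index`, `orientation`, `otu_id`,
#'   `identity`, `aligning_fraction`, `assigned` (identity >= threshold).
#' @export
match_single_cells <- function(cell_reads, otu_db, id_threshold = 0.97,
                               reverse_complement = TRUE,
                               params = align_params()) {
  stopifnot(inherits(otu_db, "ref_db"), is.list(cell_reads))
  if (length(cell_reads) == 0) stop("no cells supplied", call. = FALSE)
  params <- .ap(params)
  rows <- lapply(names(cell_reads), function(cid) {
    reads <- cell_reads[[cid]]
    if (length(reads) == 0) {
      stop("cell '", cid, "' has an empty read list", call. = FALSE)
    }
    per_read <- lapply(seq_along(reads), function(ri) {
      q <- check_dna(reads[[ri]], "read")
      cand <- list(fwd = q)
      if (reverse_complement) cand$rev <- revcomp(q)
      hits <- lapply(names(cand), function(ori) {
        h <- best_match(cand[[ori]], otu_db, params)
        h$orientation <- ori
        h
      })
      hits <- do.call(rbind, hits)
      h <- hits[which.max(hits$identity), , drop = FALSE]  # tie -> fwd
      data.frame(cell_id = cid, read_index = ri, orientation = h$orientation,
                 otu_id = h$ref_id, identity = h$identity,
                 aligning_fraction = h$aligning_fraction,
                 stringsAsFactors = FALSE)
    })
    per_read <- do.call(rbind, per_read)
    o <- order(-per_read$aligning_fraction, -per_read$identity,
               per_read$read_index)
    per_read[o[1], , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  out$assigned <- out$identity >= id_threshold
  rownames(out) <- NULL
  out
}
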