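# FASTA and TSV plumbing. FASTA goes through Biostrings; TSVs are plain
# UTF-8, tab-delimited, header row, '.' decimal.

#' Read a FASTA file into a named character vector
#'
#' Record names are truncated at the first whitespace.
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80)
  invisible(path)
}

#' @rdname read_tsv_strict
#' @param x data.frame to write.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read/write tab-separated tables
#'
#' @param path file path.
#' @return data.frame (strings kept as character).
#' @export
read_tsv_strict <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read reference databases listed in a manifest
#'
#' The manifest is a TSV with columns `db_name`, `category`, `fasta`
#' (path relative to the manifest's directory).
#'
#' @param manifest_path path to `db_manifest.tsv`.
#' @return named list of [ref_db()] objects.
#' @export
read_ref_dbs <- function(manifest_path) {
  man <- read_tsv_strict(manifest_path)
  need <- c("db_name", "category", "fasta")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  dbs <- lapply(seq_len(nrow(man)), function(i) {
    ref_db(read_fasta(file.path(base, man$fasta[i])),
           name = man$db_name[i], category = man$category[i])
  })
  names(dbs) <- man$db_name
  dbs
}

#' Write reference databases and their manifest
#'
#' @param dbs named list of [ref_db()] objects.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_ref_dbs <- function(dbs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- data.frame(
    db_name = vapply(dbs, `[[`, character(1), "name"),
    category = vapply(dbs, `[[`, character(1), "category"),
    fasta = paste0("refdb_", vapply(dbs, `[[`, character(1), "name"), ".fasta"),
    stringsAsFactors = FALSE)
  for (i in seq_along(dbs)) {
    write_fasta(dbs[[i]]$sequences, file.path(dir, man$fasta[i]))
  }
  path <- file.path(dir, "db_manifest.tsv")
  write_tsv(man, path)
  invisible(path)
}

#' Database category manifest from a list of databases
#'
#' @param dbs named list of [ref_db()] objects.
#' @return data.frame with `db_name` and `category`.
#' @export
db_manifest <- function(dbs) {
  data.frame(db_name = vapply(dbs, `[[`, character(1), "name"),
             category = vapply(dbs, `[[`, character(1), "category"),
             stringsAsFactors = FALSE, row.names = NULL)
}
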