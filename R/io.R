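.RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Extract the taxon at a rank from a semicolon-delimited taxonomy path
#'
#' SILVA-style taxonomy strings are ordered `domain;phylum;class;order;...`.
#' Records with no taxonomy, or whose path stops above the requested rank,
#' are assigned to `"Unclassified"`.
#'
#' @param taxonomy Character vector of semicolon-delimited paths.
#' @param rank Rank name (`"domain"`, `"phylum"`, ...) or a 1-based depth.
#' @return Character vector of taxon names.
#' @export
tax_at_rank <- function(taxonomy, rank = "phylum") {
  idx <- if (is.character(rank)) match(tolower(rank), .RANKS) else as.integer(rank)
  if (is.na(idx) || idx < 1L) stop("unknown taxonomic rank: ", rank, call. = FALSE)
  parts <- strsplit(ifelse(is.na(taxonomy), "", taxonomy), ";", fixed = TRUE)
  vapply(parts, function(p) {
    p <- trimws(p)
    p <- p[nzchar(p)]
    if (length(p) < idx) "Unclassified" else p[idx]
  }, character(1))
}

.rank_depth <- function(rank) {
  idx <- if (is.character(rank)) match(tolower(rank), .RANKS) else as.integer(rank)
  if (is.na(idx) || idx < 1L) stop("unknown taxonomic rank: ", rank, call. = FALSE)
  idx
}

#' Read a taxonomy-annotated FASTA reference set
#'
#' Reads FASTA in which each header carries a SILVA-style semicolon-delimited
#' taxonomy after the first whitespace (`>ID Domain;Phylum;...`). Sequences
#' are uppercased and RNA `U` is converted to `T`. A separate taxonomy table
#' (see [read_taxonomy_tsv()]) overrides header taxonomy when supplied.
#'
#' @param path FASTA file path.
#' @param taxonomy Optional tibble (`id`, `taxonomy`) to join by `id`.
#' @return Tibble with columns `id`, `sequence`, `taxonomy`.
#' @export
read_silva_fasta <- function(path, taxonomy = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("malformed FASTA '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  headers <- names(ss)
  id <- sub("\\s.*$", "", headers)
  tax <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), NA_character_)
  seqs <- as.character(ss)
  for (r in seq_along(seqs)) {
    seqs[r] <- tryCatch(clean_sequence(seqs[r]),
                        error = function(e) stop("record ", r, " ('", id[r], "'): ",
                                                 conditionMessage(e), call. = FALSE))
  }
  out <- tibble::tibble(id = id, sequence = unname(seqs), taxonomy = tax)
  if (anyDuplicated(out$id)) {
    stop("duplicated record ids in ", path, call. = FALSE)
  }
  if (!is.null(taxonomy)) {
    out$taxonomy <- taxonomy$taxonomy[match(out$id, taxonomy$id)]
  }
  out
}

#' Read a two-column taxonomy TSV
#'
#' @param path TSV with columns `id` and semicolon-delimited `taxonomy`
#'   (header optional; first two columns are used).
#' @return Tibble with columns `id`, `taxonomy`.
#' @export
read_taxonomy_tsv <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          header = FALSE, comment.char = "#")
  if (identical(tolower(as.character(df[1, 1])), "id")) df <- df[-1, , drop = FALSE]
  tibble::tibble(id = as.character(df[[1]]), taxonomy = as.character(df[[2]]))
}

#' Write a reference set as FASTA with SILVA-style headers
#'
#' @param records Tibble with `id`, `sequence` and optional `taxonomy`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(records, path) {
  ss <- Biostrings::DNAStringSet(records$sequence)
  names(ss) <- if ("taxonomy" %in% names(records) && any(!is.na(records$taxonomy))) {
    paste(records$id, records$taxonomy)
  } else {
    records$id
  }
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Write the id-to-taxonomy table as TSV
#'
#' @param records Tibble with `id` and `taxonomy`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_taxonomy_tsv <- function(records, path) {
  utils::write.table(records[, c("id", "taxonomy")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
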