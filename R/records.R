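#' Construct a set of protein records
#'
#' The atomic dataset unit is a data frame with columns `id`, `sequence` and
#' `label` (canonical class name or `NA` when unannotated). Sequences are
#' sanitized to the 21-letter alphabet; ids must be unique and contain no
#' whitespace.
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of residue strings.
#' @param label optional character vector of class names (or `NA`); tokens are
#'   normalized via [normalize_class()].
#' @return a `data.frame` of class `protein_records`.
#' @export
protein_records <- function(id, sequence, label = NA_character_) {
  id <- as.character(id)
  sequence <- as.character(sequence)
  label <- rep_len(as.character(label), length(id))
  if (length(sequence) != length(id)) {
    stop("id and sequence must have equal length")
  }
  if (any(grepl("[[:space:]]", id))) {
    stop("record ids must not contain whitespace: ",
         paste(id[grepl("[[:space:]]", id)], collapse = ", "))
  }
  if (anyDuplicated(id)) {
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(sequence))) {
    stop("empty sequence for record(s): ",
         paste(id[!nzchar(sequence)], collapse = ", "))
  }
  sequence <- mapply(sanitize_sequence, sequence, id, USE.NAMES = FALSE)
  has_lab <- !is.na(label)
  label[has_lab] <- normalize_class(label[has_lab])
  out <- data.frame(id = id, sequence = sequence, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

#' @export
print.protein_records <- function(x, ...) {
  cat("protein_records: ", nrow(x), " sequence(s), ",
      sum(!is.na(x$label)), " labeled\n", sep = "")
  if (nrow(x) > 0) {
    show <- utils::head(as.data.frame(x), 6)
    show$sequence <- ifelse(nchar(show$sequence) > 40,
                            paste0(substr(show$sequence, 1, 37), "..."),
                            show$sequence)
    print(show)
    if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more)\n", sep = "")
  }
  invisible(x)
}

#' Construct an alignment set (MSA) for one query
#'
#' Holds the aligned rows of a multiple sequence alignment for a single query
#' protein: row 1 is the query's own aligned representation, subsequent rows
#' are homologs. All rows have equal length over the 21-letter alphabet plus
#' `-` for gaps.
#'
#' @param query_id identifier of the query protein.
#' @param rows character vector of aligned strings (query first).
#' @return a list of class `alignment_set` with elements `query_id`, `rows`.
#' @export
alignment_set <- function(query_id, rows) {
  query_id <- as.character(query_id)
  rows <- toupper(as.character(rows))
  if (length(rows) < 1) stop("alignment must contain at least the query row")
  if (length(unique(nchar(rows))) != 1) {
    stop("ragged alignment for query '", query_id,
         "': rows differ in length")
  }
  ok <- paste0("[", paste(.AA21, collapse = ""), "-]")
  bad <- gsub(ok, "", rows)
  if (any(nzchar(bad))) {
    stop("alignment for query '", query_id,
         "' contains invalid characters: ",
         paste(unique(unlist(strsplit(bad, ""))), collapse = ""))
  }
  structure(list(query_id = query_id, rows = rows), class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat("alignment_set for '", x$query_id, "': ", length(x$rows),
      " row(s) x ", nchar(x$rows[1]), " column(s)\n", sep = "")
  invisible(x)
}
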