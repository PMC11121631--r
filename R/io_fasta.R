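#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and sanitized: the ambiguity / nonstandard codes
#' `B`, `Z`, `J`, `U`, `O` and `*` are mapped to `X`. File order is preserved
#' and ids (the first whitespace-delimited token of each header) must be
#' unique.
#'
#' @param path path to a FASTA file.
#' @param labels optional named character vector (id -> class), e.g. from
#'   [read_labels()], used to attach labels to the records.
#' @return a [protein_records] data frame.
#' @export
read_fasta <- function(path, labels = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("failed to parse FASTA file '", path, "': ",
                             conditionMessage(e))
  )
  if (length(aa) == 0) stop("FASTA file '", path, "' contains no sequences")
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- as.character(aa)
  if (any(!nzchar(ids))) {
    stop("malformed FASTA header (empty id) at entry ",
         which(!nzchar(ids))[1], " of '", path, "'")
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for FASTA entry: ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  lab <- NA_character_
  if (!is.null(labels)) lab <- unname(labels[ids])
  protein_records(ids, seqs, lab)
}

#' Write protein records to a FASTA file
#'
#' @param records a [protein_records] data frame.
#' @param path output path.
#' @param width line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- records$id
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

#' Read a tab-separated label file
#'
#' Two columns: id and class token. An optional header line is detected (a
#' first line whose second field is not a valid class token is skipped only
#' if it looks like a header, i.e. matches `id` / `label` / `class`
#' case-insensitively). Class tokens are matched case-insensitively with
#' spaces, underscores and hyphens interchangeable; anything else is an
#' error naming the token and line.
#'
#' @param path path to a TSV file.
#' @return named character vector mapping id to canonical class name.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("label file '", path, "' is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2)) {
    stop("label file '", path, "': line ", which(nf < 2)[1],
         " does not have two tab-separated fields")
  }
  first <- tolower(trimws(parts[[1]][2]))
  start <- if (first %in% c("label", "class", "location", "localization")) 2L else 1L
  if (start > length(parts)) stop("label file '", path, "' has a header but no rows")
  ids <- vapply(parts[start:length(parts)], function(p) trimws(p[1]), "")
  toks <- vapply(parts[start:length(parts)], function(p) trimws(p[2]), "")
  cls <- vapply(seq_along(toks), function(i) {
    tryCatch(normalize_class(toks[i]),
             error = function(e) stop("label file '", path, "', line ",
                                      i + start - 1L, ": ",
                                      conditionMessage(e), call. = FALSE))
  }, "")
  if (anyDuplicated(ids)) {
    stop("label file '", path, "': duplicate id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  stats::setNames(cls, ids)
}

#' Write per-protein class predictions to a TSV file
#'
#' Output columns: `id`, `predicted_class`, then one probability column per
#' class in the frozen class order, printed to 6 decimal places. The
#' predicted class is the argmax with lowest-index tie-break.
#'
#' @param records a [protein_records] data frame.
#' @param probs numeric matrix, one row per record, 8 columns summing to 1.
#' @param path output path.
#' @return a data frame of what was written, invisibly.
#' @export
write_predictions <- function(records, probs, path) {
  probs <- as.matrix(probs)
  if (nrow(probs) != nrow(records)) {
    stop("records (", nrow(records), ") and probs (", nrow(probs),
         ") differ in length")
  }
  if (ncol(probs) != length(.CLASSES)) {
    stop("probs must have ", length(.CLASSES), " columns")
  }
  sums <- rowSums(probs)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("probability rows must sum to 1 (row ",
         which(abs(sums - 1) > 1e-6)[1], " sums to ",
         format(sums[which(abs(sums - 1) > 1e-6)[1]]), ")")
  }
  pred <- .CLASSES[max.col(probs, ties.method = "first")]
  out <- data.frame(id = records$id, predicted_class = pred,
                    stringsAsFactors = FALSE)
  pm <- matrix(sprintf("%.6f", probs), nrow = nrow(probs))
  colnames(pm) <- .CLASSES
  out <- cbind(out, as.data.frame(pm, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read a predictions TSV written by [write_predictions()]
#'
#' @param path path to the predictions file.
#' @return data frame with `id`, `predicted_class` and per-class probability
#'   columns.
#' @export
read_predictions <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "predicted_class", .CLASSES)
  if (!all(need %in% names(out))) {
    stop("'", path, "' is not a scloc predictions file (missing columns: ",
         paste(setdiff(need, names(out)), collapse = ", "), ")")
  }
  out
}
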