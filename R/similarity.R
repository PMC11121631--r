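#' Similarity backends for redundancy reduction
#'
#' A similarity backend scores a pair of protein records with an e-value:
#' the expected number of chance alignments at least as good as the observed
#' one, given the size of the search space. Smaller means more similar.
#'
#' `similarity_backend_builtin()` computes a Smith-Waterman local alignment
#' (BLOSUM62, gap open 11, gap extend 1) via [Biostrings::pairwiseAlignment()]
#' and converts the raw score S to a Karlin-Altschul e-value
#' `E = K * m * n * exp(-lambda * S)` using the standard gapped
#' BLOSUM62(11,1) parameters lambda = 0.267, K = 0.041. `m` is the query
#' length and `n` is a database-size term, by default the number of
#' sequences in the set times their mean length (fixed once per set via
#' `prepare`).
#'
#' `similarity_backend_blast_tab()` wraps a tabular file produced by an
#' external BLAST run (`-outfmt 6` or equivalent: qseqid, sseqid and an
#' e-value column), looking pairs up instead of aligning. Pairs absent from
#' the table are treated as dissimilar (e-value `Inf`), which is how BLAST
#' itself reports no significant hit.
#'
#' @param lambda,K Karlin-Altschul parameters for the scoring system.
#' @param db_size database-size term n; if `NULL` it is computed from the
#'   record set at [redundancy_reduce()] time.
#' @return a list of class `similarity_backend` with an `evaluate(a, b)`
#'   function returning an e-value, and a `prepare(records)` hook.
#' @export
similarity_backend_builtin <- function(lambda = 0.267, K = 0.041,
                                       db_size = NULL) {
  env <- new.env(parent = emptyenv())
  env$n_term <- db_size
  evaluate <- function(a, b) {
    sc <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a$sequence), Biostrings::AAString(b$sequence),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, scoreOnly = FALSE))
    m <- nchar(a$sequence)
    n <- if (is.null(env$n_term)) nchar(b$sequence) else env$n_term
    K * m * n * exp(-lambda * sc)
  }
  prepare <- function(records) {
    if (is.null(db_size)) {
      env$n_term <- nrow(records) * mean(nchar(records$sequence))
    }
    invisible(NULL)
  }
  structure(list(evaluate = evaluate, prepare = prepare,
                 name = "builtin"), class = "similarity_backend")
}

#' @rdname similarity_backend_builtin
#' @param path path to a tab-separated BLAST hit table.
#' @param evalue_col 1-based column index of the e-value (11 for the
#'   standard 12-column `-outfmt 6` layout).
#' @export
similarity_backend_blast_tab <- function(path, evalue_col = 11L) {
  if (!file.exists(path)) stop("BLAST table not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < evalue_col) {
    stop("BLAST table '", path, "' has ", ncol(tab),
         " columns; e-value column ", evalue_col, " requested")
  }
  key <- paste(tab[[1]], tab[[2]], sep = "\r")
  ev <- suppressWarnings(as.numeric(tab[[evalue_col]]))
  if (anyNA(ev)) {
    stop("non-numeric e-value(s) in '", path, "' column ", evalue_col)
  }
  # keep the best (smallest) e-value per ordered pair
  best <- tapply(ev, key, min)
  evaluate <- function(a, b) {
    hit <- c(best[paste(a$id, b$id, sep = "\r")],
             best[paste(b$id, a$id, sep = "\r")])
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0) Inf else min(hit)
  }
  structure(list(evaluate = evaluate, prepare = function(records) invisible(NULL),
                 name = "blast-tab"), class = "similarity_backend")
}
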