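#' One-hot encode a protein sequence
#'
#' Each residue becomes a 21-dimensional indicator vector over the fixed
#' alphabet (20 standard amino acids + `X`), so a length-N sequence becomes an
#' N x 21 matrix with exactly one 1 per row.
#'
#' @param sequence a residue string (already sanitized, e.g. from
#'   [read_fasta()]), or a single-row [protein_records] entry.
#' @return N x 21 numeric matrix with `mode` attribute `"onehot"`.
#' @export
one_hot_encode <- function(sequence) {
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1)
    sequence <- sequence$sequence
  }
  chars <- strsplit(sequence, "")[[1]]
  idx <- match(chars, .AA21)
  if (anyNA(idx)) {
    stop("sequence contains characters outside the 21-letter alphabet: ",
         paste(unique(chars[is.na(idx)]), collapse = ""))
  }
  m <- matrix(0, nrow = length(idx), ncol = 21L)
  m[cbind(seq_along(idx), idx)] <- 1
  colnames(m) <- .AA21
  attr(m, "mode") <- "onehot"
  m
}

#' Build a clipped MSA profile for a query sequence
#'
#' For each query position, the 22-dimensional vector holds the frequency of
#' each of the 21 residue symbols plus the gap frequency, computed over all
#' alignment rows at that column. The column of the query's own residue is
#' then clipped to 1; no other entry is touched and nothing is renormalized.
#' Alignment columns where the query itself has a gap (insertions in
#' homologs) are dropped, so the profile is indexed by query positions.
#'
#' @param msa an [alignment_set] whose first row is the query.
#' @return N x 22 numeric matrix (N = ungapped query length) with `mode`
#'   attribute `"profile"`; columns are the 21 residues then `"-"`.
#' @export
build_profile <- function(msa) {
  stopifnot(inherits(msa, "alignment_set"))
  rows <- do.call(rbind, strsplit(msa$rows, ""))
  qry <- rows[1, ]
  keep <- which(qry != "-")
  if (length(keep) == 0) stop("query row of '", msa$query_id, "' is all gaps")
  symbols <- c(.AA21, "-")
  prof <- matrix(0, nrow = length(keep), ncol = 22L,
                 dimnames = list(NULL, symbols))
  nr <- nrow(rows)
  for (j in seq_along(keep)) {
    col <- rows[, keep[j]]
    tab <- tabulate(match(col, symbols), nbins = 22L)
    prof[j, ] <- tab / nr
  }
  # clip: the query's own residue column is forced to 1 at every position
  qidx <- match(qry[keep], symbols)
  prof[cbind(seq_along(keep), qidx)] <- 1
  attr(prof, "mode") <- "profile"
  prof
}

#' Encode a dataset of records into network input matrices
#'
#' Records with an MSA get profile encoding (22 columns); records without one
#' get one-hot encoding padded with a zero gap column to width 22, so every
#' matrix in one run has the same width and can feed the same network.
#'
#' @param records a [protein_records] data frame.
#' @param msas optional named list of [alignment_set] objects keyed by record
#'   id.
#' @param require_msa if `TRUE`, every record must have an MSA; missing ids
#'   are an error.
#' @return named list of N x 22 matrices, in record order.
#' @export
encode_dataset <- function(records, msas = NULL, require_msa = FALSE) {
  if (nrow(records) == 0) return(stats::setNames(list(), character(0)))
  if (require_msa) {
    missing <- setdiff(records$id, names(msas))
    if (length(missing) > 0) {
      stop("profile mode requested but no MSA for id(s): ",
           paste(missing, collapse = ", "))
    }
  }
  out <- lapply(seq_len(nrow(records)), function(i) {
    id <- records$id[i]
    if (!is.null(msas) && id %in% names(msas)) {
      m <- msas[[id]]
      qlen <- sum(strsplit(m$rows[1], "")[[1]] != "-")
      if (qlen != nchar(records$sequence[i])) {
        stop("MSA for '", id, "' has ungapped query length ", qlen,
             " but the record sequence has length ",
             nchar(records$sequence[i]))
      }
      build_profile(m)
    } else {
      oh <- one_hot_encode(records$sequence[i])
      m22 <- cbind(oh, `-` = 0)
      attr(m22, "mode") <- "onehot"
      m22
    }
  })
  stats::setNames(out, records$id)
}

#' Encode a labeled dataset for training
#'
#' Bundles input matrices with integer class targets in frozen class order.
#'
#' @inheritParams encode_dataset
#' @return list with elements `x` (list of matrices), `y` (integer vector of
#'   1-based class indices), `ids`.
#' @export
encode_labeled <- function(records, msas = NULL, require_msa = FALSE) {
  if (any(is.na(records$label))) {
    stop("all records must be labeled; unlabeled: ",
         paste(records$id[is.na(records$label)], collapse = ", "))
  }
  list(x = encode_dataset(records, msas, require_msa),
       y = class_index(records$label) + 1L,
       ids = records$id)
}
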