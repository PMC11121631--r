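#' Interleaved k-fold assignment
#'
#' A thin cross-validation driver companion to [interleaved_split()]: record
#' i (1-based) is assigned to fold `((i - 1) mod k) + 1`, so folds interleave
#' through the documented record order just like the 3:1:1 split does.
#'
#' @param records a [protein_records] data frame.
#' @param k number of folds (default 5).
#' @return integer vector of fold ids, one per record.
#' @export
make_folds <- function(records, k = 5L) {
  k <- as.integer(k)
  if (k < 2) stop("k must be at least 2")
  ((seq_len(nrow(records)) - 1L) %% k) + 1L
}
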