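#' Filter records for validity and minimum length
#'
#' Keeps records that carry a class label and are at least `min_len` residues
#' long (the boundary is inclusive: length 30 passes the default). Shorter
#' chains are conventionally peptides rather than proteins and follow
#' different organizing rules, so they are removed. Input order is preserved.
#'
#' @param records a [protein_records] data frame.
#' @param min_len minimum sequence length (default 30).
#' @return the surviving records, with a `report` attribute counting removals
#'   per reason (`no_location`, `too_short`).
#' @export
filter_valid <- function(records, min_len = 30L) {
  unlabeled <- is.na(records$label)
  short <- !unlabeled & nchar(records$sequence) < min_len
  keep <- !unlabeled & !short
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(records)
  attr(out, "report") <- c(input = nrow(records),
                           no_location = sum(unlabeled),
                           too_short = sum(short),
                           kept = sum(keep))
  out
}

#' Greedy redundancy reduction at an e-value threshold
#'
#' Scans records in input order: each surviving record is compared against
#' every later survivor, and later records similar to it at an e-value at or
#' below `threshold` are removed before moving on. Exact duplicates are
#' removed in the same sweep (a self-identical alignment always beats the
#' threshold). In the output no retained pair is similar at or below the
#' threshold under the backend.
#'
#' @param records a [protein_records] data frame with unique ids.
#' @param backend a `similarity_backend` (default: the built-in
#'   Smith-Waterman/Karlin-Altschul scorer).
#' @param threshold e-value threshold (default 0.001).
#' @return the surviving records; attribute `removed` lists removed ids and
#'   the id of the earlier record each was similar to.
#' @export
redundancy_reduce <- function(records, backend = similarity_backend_builtin(),
                              threshold = 0.001) {
  stopifnot(inherits(backend, "similarity_backend"))
  backend$prepare(records)
  n <- nrow(records)
  alive <- rep(TRUE, n)
  removed_by <- character(0)
  removed_id <- character(0)
  i <- 1L
  while (i <= n) {
    if (alive[i]) {
      a <- records[i, , drop = FALSE]
      js <- which(alive & seq_len(n) > i)
      for (j in js) {
        b <- records[j, , drop = FALSE]
        ev <- tryCatch(backend$evaluate(a, b), error = function(e) {
          stop("similarity backend failed on pair (", a$id, ", ", b$id,
               "): ", conditionMessage(e), call. = FALSE)
        })
        if (identical(a$sequence, b$sequence) || ev <= threshold) {
          alive[j] <- FALSE
          removed_id <- c(removed_id, b$id)
          removed_by <- c(removed_by, a$id)
        }
      }
    }
    i <- i + 1L
  }
  out <- records[alive, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(records)
  attr(out, "removed") <- data.frame(id = removed_id, similar_to = removed_by,
                                     stringsAsFactors = FALSE)
  out
}

#' Interleaved 3:1:1 train/test/validation split
#'
#' Walks the records in their given (documented) order: positions 1-3 of each
#' cycle of five go to training, position 4 to test, position 5 to
#' validation, and the cycle restarts. This spreads any listing bias in the
#' source file evenly over the three partitions. For n divisible by 5 the
#' sizes are exactly (3n/5, n/5, n/5).
#'
#' @param records a [protein_records] data frame in a fixed order.
#' @return a list of class `dataset_split` with elements `train`, `test`,
#'   `validation` ([protein_records] each).
#' @export
interleaved_split <- function(records) {
  pos <- (seq_len(nrow(records)) - 1L) %% 5L
  part <- ifelse(pos <= 2L, "train", ifelse(pos == 3L, "test", "validation"))
  mk <- function(p) {
    out <- records[part == p, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- class(records)
    out
  }
  structure(list(train = mk("train"), test = mk("test"),
                 validation = mk("validation")),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("dataset_split: train ", nrow(x$train), ", test ", nrow(x$test),
      ", validation ", nrow(x$validation), "\n", sep = "")
  invisible(x)
}

#' Per-class record counts for each partition
#'
#' @param split a `dataset_split`.
#' @return data frame with one row per class plus a `Total` row, and columns
#'   `train`, `test`, `validation`, `total`.
#' @export
class_summary <- function(split) {
  stopifnot(inherits(split, "dataset_split"))
  count_part <- function(recs) {
    if (any(is.na(recs$label))) {
      stop("class_summary requires all records to be labeled; unlabeled: ",
           paste(recs$id[is.na(recs$label)], collapse = ", "))
    }
    tab <- table(factor(recs$label, levels = .CLASSES))
    as.integer(tab)
  }
  m <- cbind(train = count_part(split$train),
             test = count_part(split$test),
             validation = count_part(split$validation))
  out <- data.frame(class = .CLASSES, m, stringsAsFactors = FALSE)
  out$total <- rowSums(m)
  totals <- data.frame(class = "Total", train = sum(m[, 1]),
                       test = sum(m[, 2]), validation = sum(m[, 3]),
                       total = sum(m), stringsAsFactors = FALSE)
  rbind(out, totals)
}

#' Run the full dataset-construction protocol
#'
#' Validity/length filtering, greedy e-value redundancy reduction and the
#' interleaved 3:1:1 split, with a stage-by-stage count report.
#'
#' @inheritParams filter_valid
#' @inheritParams redundancy_reduce
#' @return a list with `split` (a `dataset_split`), `records` (the reduced
#'   set, in split order) and `report` (named counts at each stage).
#' @export
prepare_dataset <- function(records, min_len = 30L,
                            backend = similarity_backend_builtin(),
                            threshold = 0.001) {
  filtered <- filter_valid(records, min_len = min_len)
  freport <- attr(filtered, "report")
  reduced <- redundancy_reduce(filtered, backend = backend,
                               threshold = threshold)
  split <- interleaved_split(reduced)
  list(split = split, records = reduced,
       report = c(freport, after_reduction = nrow(reduced),
                  train = nrow(split$train), test = nrow(split$test),
                  validation = nrow(split$validation)))
}
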