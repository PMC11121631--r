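#' Specification for synthetic labeled sequence datasets
#'
#' Generates protein-like sequences with a class-discriminative motif: each
#' class has a short residue motif planted at a random position in an
#' otherwise background-sampled sequence. The signal is positional (a
#' contiguous motif, not a compositional bias), so detecting it genuinely
#' requires convolutional context — a network with semi-context 0 sees only
#' single columns and cannot recognize a multi-residue motif pattern beyond
#' its residue composition.
#'
#' A single seed deterministically drives all sub-generators: child streams
#' are derived from it per purpose (sequences, per-record MSAs, duplicates)
#' via a fixed hash, so datasets, alignments and planted duplicates are all
#' reproducible independently of generation order.
#'
#' @param n_classes number of classes used (2-8; the first `n_classes` of
#'   the frozen class order).
#' @param motifs character vector of per-class motifs (lengths 3-8,
#'   default: built-in disjoint 5-mers).
#' @param n_per_class sequences per class.
#' @param length_range integer `c(min, max)` sequence length, min >= 30.
#' @param background length-21 residue probability vector (default: uniform
#'   over the 20 standard amino acids, 0 for `X`).
#' @param epsilon per-position motif substitution probability in `[0, 1)`.
#' @param msa_rows homolog rows per generated MSA.
#' @param mu per-position MSA mutation rate in `[0, 1)`; homolog positions
#'   are additionally gapped with probability `mu / 4`.
#' @param seed integer master seed.
#' @return list of class `generator_spec`.
#' @export
generator_spec <- function(n_classes = 4L,
                           motifs = NULL,
                           n_per_class = 50L,
                           length_range = c(30L, 50L),
                           background = NULL,
                           epsilon = 0,
                           msa_rows = 10L,
                           mu = 0.1,
                           seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2 || n_classes > 8) stop("n_classes must be in 2..8")
  if (is.null(motifs)) {
    motifs <- c("WYWKW", "HDHRH", "CPCNC", "EMEGE",
                "FQFAF", "RLRVR", "ITISI", "YGYPY")[seq_len(n_classes)]
  }
  motifs <- toupper(motifs)
  if (length(motifs) != n_classes) {
    stop("need one motif per class (", n_classes, ")")
  }
  if (any(nchar(motifs) < 3 | nchar(motifs) > 8)) {
    stop("motif lengths must be in 3..8")
  }
  length_range <- as.integer(length_range)
  if (length_range[1] < 30L) stop("minimum length must be at least 30")
  if (length_range[2] < length_range[1]) stop("invalid length range")
  if (any(nchar(motifs) > length_range[1])) {
    stop("motifs must fit in the shortest sequence")
  }
  if (is.null(background)) background <- c(rep(1 / 20, 20), 0)
  if (length(background) != 21 || abs(sum(background) - 1) > 1e-9 ||
      any(background < 0)) {
    stop("background must be 21 non-negative probabilities summing to 1")
  }
  if (epsilon < 0 || epsilon >= 1 || mu < 0 || mu >= 1) {
    stop("epsilon and mu must be in [0, 1)")
  }
  structure(list(n_classes = n_classes, motifs = motifs,
                 n_per_class = as.integer(n_per_class),
                 length_range = length_range, background = background,
                 epsilon = epsilon, msa_rows = as.integer(msa_rows),
                 mu = mu, seed = as.integer(seed)),
            class = "generator_spec")
}

sample_background <- function(n, background) {
  sample(.AA21, n, replace = TRUE, prob = background)
}

#' Generate a labeled synthetic dataset
#'
#' Each record is a background-sampled sequence with its class motif planted
#' at a random position; every motif position is independently substituted
#' by a background residue with probability `epsilon`. Class counts equal
#' `n_per_class` exactly; deterministic under the generator seed.
#'
#' @param spec a [generator_spec()].
#' @return a labeled [protein_records] data frame.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  classes <- .CLASSES[seq_len(spec$n_classes)]
  with_seed(derive_seed(spec$seed, "dataset"), {
    ids <- character(0); seqs <- character(0); labs <- character(0)
    for (ci in seq_along(classes)) {
      motif <- strsplit(spec$motifs[ci], "")[[1]]
      for (r in seq_len(spec$n_per_class)) {
        L <- sample(spec$length_range[1]:spec$length_range[2], 1L)
        s <- sample_background(L, spec$background)
        pos <- sample.int(L - length(motif) + 1L, 1L)
        planted <- motif
        hit <- stats::runif(length(motif)) < spec$epsilon
        if (any(hit)) {
          planted[hit] <- sample_background(sum(hit), spec$background)
        }
        s[pos:(pos + length(motif) - 1L)] <- planted
        ids <- c(ids, sprintf("syn_%s_%03d", tolower(classes[ci]), r))
        seqs <- c(seqs, paste(s, collapse = ""))
        labs <- c(labs, classes[ci])
      }
    }
    protein_records(ids, seqs, labs)
  })
}

#' Generate a mock MSA for one record
#'
#' Emulates a profile-search alignment: `msa_rows` homolog copies of the
#' query, each position independently substituted with probability `mu` and
#' replaced by a gap with probability `mu / 4`. Row 1 is the unmutated
#' query; all rows share the query's length (no insertions).
#'
#' @param record single-row [protein_records] entry (or list with `id`,
#'   `sequence`).
#' @param spec a [generator_spec()].
#' @return an [alignment_set].
#' @export
generate_msa <- function(record, spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    record <- as.list(record)
  }
  qry <- strsplit(record$sequence, "")[[1]]
  L <- length(qry)
  with_seed(derive_seed(spec$seed, paste0("msa:", record$id)), {
    rows <- vapply(seq_len(spec$msa_rows), function(r) {
      h <- qry
      sub <- stats::runif(L) < spec$mu
      if (any(sub)) h[sub] <- sample_background(sum(sub), spec$background)
      gap <- stats::runif(L) < spec$mu / 4
      h[gap] <- "-"
      paste(h, collapse = "")
    }, "")
    alignment_set(record$id, c(record$sequence, rows))
  })
}

#' Generate a dataset with planted near-duplicates
#'
#' Appends `n_dups` lightly mutated copies of randomly chosen members to a
#' generated dataset, to exercise redundancy reduction against a known
#' ground truth.
#'
#' @param spec a [generator_spec()].
#' @param n_dups number of near-duplicates to plant.
#' @param dup_mu per-position substitution rate of the copies (small).
#' @return a labeled [protein_records] data frame with attribute
#'   `duplicate_map`: named character vector, duplicate id -> source id.
#' @export
generate_redundant_pairs <- function(spec, n_dups, dup_mu = 0.03) {
  stopifnot(inherits(spec, "generator_spec"))
  base <- generate_dataset(spec)
  n_dups <- as.integer(n_dups)
  if (n_dups > nrow(base)) stop("n_dups exceeds dataset size")
  if (n_dups == 0) {
    attr(base, "duplicate_map") <- stats::setNames(character(0), character(0))
    return(base)
  }
  with_seed(derive_seed(spec$seed, "dups"), {
    src <- sample.int(nrow(base), n_dups, replace = FALSE)
    ids <- character(n_dups); seqs <- character(n_dups)
    labs <- character(n_dups)
    for (i in seq_len(n_dups)) {
      s <- strsplit(base$sequence[src[i]], "")[[1]]
      hit <- stats::runif(length(s)) < dup_mu
      if (any(hit)) s[hit] <- sample_background(sum(hit), spec$background)
      ids[i] <- paste0(base$id[src[i]], "_dup", i)
      seqs[i] <- paste(s, collapse = "")
      labs[i] <- base$label[src[i]]
    }
    out <- protein_records(c(base$id, ids), c(base$sequence, seqs),
                           c(base$label, labs))
    attr(out, "duplicate_map") <- stats::setNames(base$id[src], ids)
    out
  })
}
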