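#' Amino-acid alphabet and localization classes
#'
#' The package works over a fixed 21-letter residue alphabet: the 20 standard
#' amino acids plus `X` for any nonstandard or ambiguous residue. All ambiguity
#' codes (`B`, `Z`, `J`, `U`, `O`, `*`) collapse to `X` on input. Profile
#' encodings add a 22nd "gap" column on top of this alphabet.
#'
#' Localization classes are frozen in a fixed order; the integer index of a
#' class (0-based) defines the order of network output units, of probability
#' columns in prediction files, and the tie-break rule (lowest index wins).
#'
#' @format `aa_alphabet()` returns a character vector of 21 single letters;
#'   `localization_classes()` returns a character vector of 8 class names.
#' @examples
#' aa_alphabet()
#' localization_classes()
#' class_index("Secreted")
#' @name alphabet
NULL

.AA21 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

.CLASSES <- c("Other", "Cytoplasm", "GolgiApparatus", "Membrane",
              "Mitochondrion", "Nucleus", "Plastid", "Secreted")

#' @rdname alphabet
#' @export
aa_alphabet <- function() .AA21

#' @rdname alphabet
#' @export
localization_classes <- function() .CLASSES

#' @rdname alphabet
#' @param class character vector of canonical class names.
#' @return `class_index()`: the frozen 0-based integer index of each class.
#' @export
class_index <- function(class) {
  idx <- match(class, .CLASSES)
  if (anyNA(idx)) {
    stop("unknown localization class: ",
         paste(unique(class[is.na(idx)]), collapse = ", "))
  }
  idx - 1L
}

#' Normalize a localization class token
#'
#' Accepts the 8 canonical class names case-insensitively, with spaces,
#' underscores or hyphens used interchangeably (so `"Golgi_apparatus"`,
#' `"golgi apparatus"` and `"GolgiApparatus"` all normalize to
#' `"GolgiApparatus"`). Anything else is rejected.
#'
#' @param token character vector of raw class tokens.
#' @return character vector of canonical class names.
#' @export
normalize_class <- function(token) {
  squash <- function(x) gsub("[ _-]", "", tolower(x))
  idx <- match(squash(token), squash(.CLASSES))
  if (anyNA(idx)) {
    stop("unknown localization class token(s): ",
         paste(unique(token[is.na(idx)]), collapse = ", "),
         " (expected one of: ", paste(.CLASSES, collapse = ", "), ")")
  }
  .CLASSES[idx]
}

# Map ambiguity/nonstandard codes to X and uppercase; error on anything that
# is not a residue letter after that.
sanitize_sequence <- function(seq, id = "<sequence>") {
  s <- toupper(seq)
  s <- gsub("[BZJUO*]", "X", s)
  bad <- gsub(paste0("[", paste(.AA21, collapse = ""), "]"), "", s)
  if (any(nzchar(bad))) {
    stop("sequence '", id, "' contains non-amino-acid characters: ",
         paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]),
               collapse = ""))
  }
  s
}
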