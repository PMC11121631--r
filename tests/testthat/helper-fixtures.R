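# Shared fixtures: all built in code at test time.

tiny_config <- function(...) {
  defaults <- list(c = 1L, gamma = 1L, k = 1L, input_width = 22L,
                   kernel_hidden_units = 4L, state_units = 3L,
                   fc_hidden_units = 4L)
  args <- utils::modifyList(defaults, list(...))
  do.call(n1nn_config, args)
}

random_input <- function(n, d = 22L, seed = 1L) {
  set.seed(seed)
  matrix(stats::runif(n * d), n, d)
}

# Set every weight and bias of a parameter set to a constant.
constant_params <- function(params, value = 0) {
  fill <- function(p) { p[] <- value; p }
  params$input <- lapply(params$input, fill)
  params$hidden <- lapply(params$hidden, function(l) lapply(l, fill))
  params$fc <- lapply(params$fc, fill)
  class(params) <- "n1nn_params"
  params
}

# A deterministic similarity backend for unit tests: sequences are "similar"
# iff they share their first 10 residues.
prefix_backend <- function(sim_evalue = 1e-6, dis_evalue = 10) {
  structure(list(
    evaluate = function(a, b) {
      if (substr(a$sequence, 1, 10) == substr(b$sequence, 1, 10)) {
        sim_evalue
      } else {
        dis_evalue
      }
    },
    prepare = function(records) invisible(NULL),
    name = "prefix-mock"
  ), class = "similarity_backend")
}

# Random labeled records without any planted signal.
random_records <- function(n, len = 35L, seed = 1L, labeled = TRUE) {
  set.seed(seed)
  aa20 <- setdiff(aa_alphabet(), "X")
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(aa20, len, replace = TRUE), collapse = "")
  }, "")
  lab <- if (labeled) {
    sample(localization_classes(), n, replace = TRUE)
  } else {
    NA_character_
  }
  protein_records(sprintf("r%03d", seq_len(n)), seqs, lab)
}
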