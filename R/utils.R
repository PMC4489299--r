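# Shared helpers: residue alphabet, encoding, seeded RNG scopes.

# Canonical 20-letter amino-acid alphabet (alphabetical order); all
# emission vectors and encodings in the package index into this order.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Encode an amino-acid string as integer residue codes
#'
#' Residues outside the standard 20-letter alphabet (e.g. X, B, Z, U) are
#' mapped to 0, a wildcard that scores as the background distribution.
#'
#' @param sequence single character string of amino acids.
#' @return integer vector, one code per residue (1-20, or 0 for wildcard).
#' @keywords internal
aa_encode <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  codes <- match(chars, AA20)
  codes[is.na(codes)] <- 0L
  codes
}

#' Run code with a temporary RNG seed
#'
#' All stochastic steps in the package route their seed through this
#' wrapper so that the caller's RNG state is never disturbed and results
#' are reproducible.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Sample a random amino-acid sequence from the uniform background
#'
#' @param length sequence length.
#' @return character string of `length` residues drawn uniformly from the
#'   20-letter alphabet.
#' @keywords internal
random_aa <- function(length) {
  paste(sample(AA20, length, replace = TRUE), collapse = "")
}

# Mutate a sequence: each site independently substituted with the given
# per-site rate, drawing uniformly from the 19 other residues.
mutate_aa <- function(sequence, rate) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) {
      sample(setdiff(AA20, a), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

# Gap characters accepted in aligned input.
is_gap <- function(chars) chars == "-" | chars == "."
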