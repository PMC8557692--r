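#' Sequence alphabets
#'
#' Constructors for the two supported residue alphabets. An alphabet carries
#' its ordered residue letters and the designated "unknown" letter (`X` for
#' protein, `N` for DNA), which is never itself a residue of the alphabet and
#' can never be a biasing residue.
#'
#' @return A list of class `bias_alphabet` with elements `kind`
#'   (`"protein"` or `"dna"`), `letters` (character vector of residue
#'   letters) and `unknown` (single letter).
#' @examples
#' protein_alphabet()$unknown  # "X"
#' dna_alphabet()$letters      # A C G T
#' @export
protein_alphabet <- function() {
  structure(
    list(
      kind = "protein",
      letters = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
      unknown = "X"
    ),
    class = "bias_alphabet"
  )
}

#' @rdname protein_alphabet
#' @export
dna_alphabet <- function() {
  structure(
    list(kind = "dna", letters = c("A", "C", "G", "T"), unknown = "N"),
    class = "bias_alphabet"
  )
}

#' @rdname protein_alphabet
#' @param kind `"protein"` or `"dna"`.
#' @export
get_alphabet <- function(kind = c("protein", "dna")) {
  kind <- match.arg(kind)
  if (kind == "protein") protein_alphabet() else dna_alphabet()
}

is_alphabet <- function(x) inherits(x, "bias_alphabet")

# Letters that are tolerated on input and collapsed to the unknown letter
# (protein ambiguity/rare codes; DNA IUPAC ambiguity codes). Asterisks
# (stop codons) and gaps are treated the same way for protein input.
ambiguity_letters <- function(alphabet) {
  if (alphabet$kind == "protein") c("B", "Z", "U", "O", "J", "*")
  else c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U")
}

#' Guess the alphabet of a residue string
#'
#' Advisory only: an explicit user choice (for example the CLI `-n` flag)
#' always wins. A string whose letters all lie in `{A,C,G,T,N}` is reported
#' as DNA; anything else as protein. Sequences valid in both alphabets are
#' reported as DNA with a message, since short all-`ACGT` protein sequences
#' are rare while DNA is always all-`ACGT`.
#'
#' @param residues Non-empty character scalar of residue letters.
#' @param quiet Suppress the tie-case message.
#' @return `"protein"` or `"dna"`.
#' @examples
#' detect_alphabet("ACGTACGT")
#' detect_alphabet("MKLVWEED")
#' @export
detect_alphabet <- function(residues, quiet = FALSE) {
  stopifnot(is.character(residues), length(residues) == 1L, nzchar(residues))
  chars <- unique(strsplit(toupper(residues), "", fixed = TRUE)[[1]])
  if (all(chars %in% c("A", "C", "G", "T", "N"))) {
    if (!quiet) {
      message("sequence is valid in both alphabets; reporting 'dna' ",
              "(an explicit alphabet choice always overrides detection)")
    }
    "dna"
  } else {
    "protein"
  }
}
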