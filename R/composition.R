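#' Background residue compositions
#'
#' A `composition_table` is the binomial null: one background frequency per
#' residue of an alphabet. The unknown letter (`X`/`N`) never appears in the
#' table — how unknowns enter the calculation is decided at scan time by the
#' ignore-unknowns flag (CLI `-k`), not by the null.
#'
#' @param alphabet A [protein_alphabet()] or [dna_alphabet()].
#' @param freq Named numeric vector of frequencies covering every alphabet
#'   letter; must be non-negative and sum to 1 within 1e-9.
#' @param n_residues Number of residues tallied to build the table (0 for
#'   synthetic tables).
#' @param source Free-text provenance.
#' @param allow_deficit Permit the frequencies to sum to less than 1. Used
#'   by [compute_composition()] when unknown letters are kept in the
#'   denominator: the unknowns' share is deliberately left unassigned so
#'   that every known-letter frequency is a conservative (diluted)
#'   estimate.
#' @return An object of class `composition_table`.
#' @export
composition_table <- function(alphabet, freq, n_residues = 0L,
                              source = "user", allow_deficit = FALSE) {
  stopifnot(is_alphabet(alphabet))
  missing <- setdiff(alphabet$letters, names(freq))
  if (length(missing)) {
    stop("composition is missing letter(s): ", paste(missing, collapse = ", "))
  }
  freq <- freq[alphabet$letters]
  if (any(!is.finite(freq)) || any(freq < 0)) {
    stop("composition frequencies must be finite and non-negative")
  }
  dev <- sum(freq) - 1
  if (dev > 1e-9 || (!allow_deficit && dev < -1e-9)) {
    stop("composition frequencies must sum to 1 (got ", sum(freq), ")")
  }
  structure(
    list(alphabet = alphabet, freq = freq,
         n_residues = as.numeric(n_residues), source = source),
    class = "composition_table"
  )
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("<composition_table> %s, %s (n = %g)\n",
              x$alphabet$kind, x$source, x$n_residues))
  print(round(x$freq, 4))
  invisible(x)
}

#' Compute a background composition from sequence records
#'
#' The in-package equivalent of the CompositionMaker accessory: tallies
#' residues across all records. Unknown letters are never counted in the
#' numerator; with `ignore_unknown = FALSE` (default) they still contribute
#' to the denominator, so every reported frequency is conservative.
#'
#' @param records A `seq_record` or list of them, all on one alphabet.
#' @param ignore_unknown Drop unknown letters from the denominator as well.
#' @return A [composition_table()].
#' @export
compute_composition <- function(records, ignore_unknown = FALSE) {
  if (inherits(records, "seq_record")) records <- list(records)
  if (!length(records)) stop("need at least one record")
  kinds <- unique(vapply(records, function(r) r$alphabet$kind, ""))
  if (length(kinds) != 1L) {
    stop("all records must share one alphabet, found: ",
         paste(kinds, collapse = ", "))
  }
  alphabet <- records[[1L]]$alphabet
  chars <- unlist(strsplit(vapply(records, `[[`, "", "residues"), "",
                           fixed = TRUE), use.names = FALSE)
  counts <- table(factor(chars, levels = c(alphabet$letters,
                                           alphabet$unknown)))
  n_known <- sum(counts[alphabet$letters])
  denom <- if (ignore_unknown) n_known else sum(counts)
  if (n_known == 0L) stop("no countable residues (all unknown)")
  freq <- as.numeric(counts[alphabet$letters]) / denom
  names(freq) <- alphabet$letters
  composition_table(alphabet, freq, n_residues = denom,
                    source = "computed from records",
                    allow_deficit = !ignore_unknown)
}

#' Default background composition
#'
#' DNA: each of A, C, G and T with equal probability 0.25 — the null used
#' for DNA scans unless the user supplies a composition file. Protein: the
#' packaged Swiss-Prot-wide amino-acid frequency table shipped in
#' `extdata/protein_default.COMPOSITION` (documented there; override with
#' [read_composition_file()] / CLI `-c`).
#'
#' @param alphabet Alphabet object or `"protein"` / `"dna"`.
#' @return A [composition_table()].
#' @export
default_composition <- function(alphabet = protein_alphabet()) {
  if (is.character(alphabet)) alphabet <- get_alphabet(alphabet)
  if (alphabet$kind == "dna") {
    return(composition_table(alphabet,
                             c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                             source = "uniform DNA default"))
  }
  path <- system.file("extdata", "protein_default.COMPOSITION",
                      package = "flpsr", mustWork = TRUE)
  tab <- read_composition_file(path, alphabet)
  tab$source <- "packaged Swiss-Prot-wide default"
  tab
}

#' Read / write composition files
#'
#' Plain-text format: one `LETTER FREQUENCY` pair per line, whitespace
#' separated, `#` starts a comment. Frequencies off 1 by more than 1e-6 are
#' renormalized with a warning; off by more than 1% is an error, as is a
#' missing letter or a negative value. `write_composition_file()` writes at
#' full double precision so that read after write is the identity.
#'
#' @param path File path.
#' @param alphabet Alphabet the file must cover.
#' @return A [composition_table()] (reader); `path` invisibly (writer).
#' @export
read_composition_file <- function(path, alphabet = protein_alphabet()) {
  if (is.character(alphabet)) alphabet <- get_alphabet(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no composition entries in ", path)
  fields <- strsplit(lines, "\\s+")
  if (any(vapply(fields, length, integer(1)) != 2L)) {
    stop("each composition line must be 'LETTER FREQUENCY'")
  }
  letters <- toupper(vapply(fields, `[`, "", 1L))
  values <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  if (any(is.na(values))) stop("non-numeric frequency in ", path)
  if (any(values < 0)) stop("negative frequency in ", path)
  if (anyDuplicated(letters)) stop("duplicate letter in ", path)
  freq <- stats::setNames(values, letters)
  missing <- setdiff(alphabet$letters, letters)
  if (length(missing)) {
    stop("composition file is missing letter(s): ",
         paste(missing, collapse = ", "))
  }
  freq <- freq[alphabet$letters]
  s <- sum(freq)
  if (abs(s - 1) > 0.01) {
    stop("composition frequencies sum to ", s, "; expected 1 within 1%")
  }
  if (abs(s - 1) > 1e-6) {
    warning("composition frequencies sum to ", signif(s, 8),
            "; renormalizing")
  }
  composition_table(alphabet, freq / s, source = path)
}

#' @rdname read_composition_file
#' @param table A [composition_table()].
#' @export
write_composition_file <- function(table, path) {
  stopifnot(inherits(table, "composition_table"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("%s %.17g", names(table$freq), table$freq), con)
  invisible(path)
}
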