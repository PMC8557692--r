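#' Sequence records
#'
#' A `seq_record` is one FASTA entry: an id (first whitespace-delimited word
#' of the header), the remaining description, an uppercase residue string
#' over its alphabet plus the unknown letter, and an optional table of
#' filtered (excised or masked) domain intervals in ORIGINAL 1-based
#' inclusive coordinates. Filtered intervals ride along on the FASTA name
#' line in the dialect `#FILTERED start-end id[,start-end id...]#` so that a
#' domain-filtered file is self-describing.
#'
#' @param id Record identifier (no whitespace).
#' @param residues Residue string.
#' @param alphabet A [protein_alphabet()] / [dna_alphabet()], or `NULL` to
#'   detect.
#' @param description Free-text remainder of the header.
#' @param filtered_intervals `NULL` or a data.frame with columns
#'   `start`, `end`, `domain_id` (sorted, non-overlapping).
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, residues, alphabet = NULL, description = "",
                       filtered_intervals = NULL) {
  if (is.null(alphabet)) {
    alphabet <- get_alphabet(detect_alphabet(residues, quiet = TRUE))
  }
  residues <- normalize_residues(residues, alphabet, id = id)
  fi <- normalize_intervals(filtered_intervals)
  rec <- structure(
    list(id = id, description = description, residues = residues,
         alphabet = alphabet, filtered_intervals = fi),
    class = "seq_record"
  )
  validate_record(rec)
  rec
}

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$residues)
  cat(sprintf("<seq_record> %s (%s, %d residues)\n", x$id, x$alphabet$kind, n))
  shown <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(" ", shown, "\n")
  if (nrow(x$filtered_intervals)) {
    cat(sprintf("  %d filtered domain interval(s)\n",
                nrow(x$filtered_intervals)))
  }
  invisible(x)
}

empty_intervals <- function() {
  data.frame(start = integer(), end = integer(),
             domain_id = character(), stringsAsFactors = FALSE)
}

normalize_intervals <- function(fi) {
  if (is.null(fi) || NROW(fi) == 0L) return(empty_intervals())
  fi <- as.data.frame(fi, stringsAsFactors = FALSE)
  if (is.null(fi$domain_id)) fi$domain_id <- "."
  fi <- fi[order(fi$start), c("start", "end", "domain_id")]
  fi$start <- as.integer(fi$start)
  fi$end <- as.integer(fi$end)
  if (any(fi$start > fi$end)) stop("interval start exceeds end")
  if (nrow(fi) > 1L && any(fi$start[-1L] <= fi$end[-nrow(fi)])) {
    stop("filtered intervals must be non-overlapping")
  }
  rownames(fi) <- NULL
  fi
}

# Uppercase, map ambiguity codes to the unknown letter (with a message
# giving the count), reject anything else with its position.
normalize_residues <- function(residues, alphabet, id = "?") {
  stopifnot(is.character(residues), length(residues) == 1L)
  if (!nzchar(residues)) stop("record '", id, "' has an empty sequence")
  res <- toupper(residues)
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  legal <- c(alphabet$letters, alphabet$unknown)
  amb <- ambiguity_letters(alphabet)
  is_amb <- chars %in% amb
  if (any(is_amb)) {
    message(sum(is_amb), " ambiguity letter(s) in '", id,
            "' mapped to '", alphabet$unknown, "'")
    chars[is_amb] <- alphabet$unknown
    res <- paste(chars, collapse = "")
  }
  bad <- which(!(chars %in% legal))
  if (length(bad)) {
    stop("illegal character '", chars[bad[1L]], "' at position ", bad[1L],
         " in record '", id, "' for the ", alphabet$kind, " alphabet")
  }
  res
}

validate_record <- function(rec) {
  fi <- rec$filtered_intervals
  if (nrow(fi) && rec$alphabet$kind == "dna") return(invisible(rec))
  invisible(rec)
}

# --- name-line dialect for filtered domains ------------------------------

format_filtered_tag <- function(fi) {
  if (NROW(fi) == 0L) return("")
  paste0("#FILTERED ",
         paste(sprintf("%d-%d %s", fi$start, fi$end, fi$domain_id),
               collapse = ","),
         "#")
}

parse_filtered_tag <- function(description) {
  m <- regmatches(description,
                  regexec("#FILTERED ([^#]*)#", description))[[1]]
  if (length(m) < 2L) {
    return(list(description = description, intervals = empty_intervals()))
  }
  rest <- trimws(sub("\\s*#FILTERED [^#]*#\\s*", " ", description))
  parts <- strsplit(m[2L], ",", fixed = TRUE)[[1]]
  fields <- regmatches(parts, regexec("^\\s*(\\d+)-(\\d+)\\s*(.*)$", parts))
  ok <- vapply(fields, length, integer(1)) == 4L
  if (!all(ok)) stop("malformed #FILTERED annotation: ", m[1L])
  fi <- data.frame(
    start = as.integer(vapply(fields, `[`, "", 2L)),
    end = as.integer(vapply(fields, `[`, "", 3L)),
    domain_id = trimws(vapply(fields, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  fi$domain_id[!nzchar(fi$domain_id)] <- "."
  list(description = rest, intervals = normalize_intervals(fi))
}

# --- FASTA ---------------------------------------------------------------

#' Read a FASTA file
#'
#' Wraps `Biostrings::readBStringSet()` and layers on alphabet
#' normalization (uppercasing, ambiguity-code collapsing, strict rejection
#' of anything else) and parsing of the `#FILTERED ...#` name-line
#' annotation written by [apply_domain_filter()] / [write_fasta()].
#'
#' @param path FASTA file path.
#' @param alphabet A [protein_alphabet()] / [dna_alphabet()], the strings
#'   `"protein"` / `"dna"`, or `NULL` to detect from the first record
#'   (an explicit choice always wins over detection).
#' @return List of [seq_record()] objects, input order preserved.
#' @export
read_fasta <- function(path, alphabet = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  headers <- names(set)
  seqs <- as.character(set)
  if (is.character(alphabet)) alphabet <- get_alphabet(alphabet)
  if (is.null(alphabet)) {
    alphabet <- get_alphabet(detect_alphabet(seqs[[1L]], quiet = TRUE))
  }
  lapply(seq_along(seqs), function(i) {
    header <- headers[[i]]
    id <- sub("\\s.*$", "", header)
    if (!nzchar(id)) stop("record ", i, " has an empty id")
    desc <- if (grepl("\\s", header)) {
      trimws(sub("^\\S+\\s+", "", header))
    } else ""
    if (!nzchar(seqs[[i]])) stop("record '", id, "' has an empty sequence")
    tag <- parse_filtered_tag(desc)
    seq_record(id, seqs[[i]], alphabet = alphabet,
               description = tag$description,
               filtered_intervals = tag$intervals)
  })
}

#' Write records to a FASTA file
#'
#' The inverse of [read_fasta()] on normalized records: ids, residues and
#' filtered intervals round-trip exactly. Filtered intervals are emitted in
#' the `#FILTERED start-end id[,...]#` name-line dialect.
#'
#' @param records A `seq_record` or list of them.
#' @param path Output path.
#' @param width Residue line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "seq_record")) records <- list(records)
  lines <- unlist(lapply(records, function(rec) {
    tag <- format_filtered_tag(rec$filtered_intervals)
    desc <- paste(c(if (nzchar(rec$description)) rec$description,
                    if (nzchar(tag)) tag), collapse = " ")
    header <- if (nzchar(desc)) paste(rec$id, desc) else rec$id
    n <- nchar(rec$residues)
    starts <- seq(1L, n, by = width)
    c(paste0(">", header),
      substring(rec$residues, starts, pmin(starts + width - 1L, n)))
  }), use.names = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
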