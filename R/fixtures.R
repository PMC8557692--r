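#' Implant specification for synthetic sequences
#'
#' Describes one biased tract to plant into a background sequence: at each
#' implant position, a residue is drawn uniformly from `residue_set` with
#' probability `concentration`, otherwise from the background composition.
#' `concentration = 1` gives a pure tract.
#'
#' @param position 1-based start of the implant.
#' @param length Implant length in residues.
#' @param residue_set Letters the implant is biased for.
#' @param concentration Target biasing fraction, in (0, 1].
#' @return List of class `implant_spec`.
#' @export
implant_spec <- function(position, length, residue_set,
                         concentration = 0.8) {
  stopifnot(position >= 1, length >= 1,
            concentration > 0, concentration <= 1)
  residue_set <- unlist(strsplit(residue_set, "", fixed = TRUE))
  structure(list(position = as.integer(position),
                 length = as.integer(length),
                 residue_set = residue_set,
                 concentration = concentration),
            class = "implant_spec")
}

#' Generate a synthetic sequence with implanted biased tracts
#'
#' Ground-truth fixture generator: background positions are drawn i.i.d.
#' from the background composition; implant positions follow their
#' [implant_spec()]. The same seed always reproduces the same sequence.
#' The truth table of implanted tracts is attached for scoring recovery.
#'
#' @param length Sequence length.
#' @param background A [composition_table()]; defaults to a uniform table
#'   over the protein alphabet.
#' @param implants List of non-overlapping [implant_spec()]s.
#' @param seed Integer seed driving all randomness of this call.
#' @param id Record id.
#' @return A [seq_record()] with attribute `truth`: a data.frame of
#'   implant `start`, `end`, `residue_set` (collapsed letters),
#'   `concentration`.
#' @export
generate_sequence <- function(length, background = NULL, implants = list(),
                              seed = 1L, id = "synthetic") {
  if (is.null(background)) {
    alpha <- protein_alphabet()
    background <- composition_table(
      alpha, stats::setNames(rep(1 / 20, 20), alpha$letters),
      source = "uniform protein"
    )
  }
  alphabet <- background$alphabet
  if (inherits(implants, "implant_spec")) implants <- list(implants)
  if (length(implants)) {
    iv <- cbind(vapply(implants, `[[`, integer(1), "position"),
                vapply(implants, function(x) {
                  x$position + x$length - 1L
                }, integer(1)))
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(iv[, 2L] > length) || any(iv[, 1L] < 1L)) {
      stop("implant outside sequence bounds")
    }
    if (nrow(iv) > 1L && any(iv[-1L, 1L] <= iv[-nrow(iv), 2L])) {
      stop("implants must not overlap")
    }
  }
  p <- background$freq / sum(background$freq)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed))
  chars <- sample(names(p), length, replace = TRUE, prob = p)
  for (sp in implants) {
    pos <- sp$position:(sp$position + sp$length - 1L)
    use_bias <- stats::runif(sp$length) <= sp$concentration
    biased <- sample(sp$residue_set, sp$length, replace = TRUE)
    chars[pos] <- ifelse(use_bias, biased, chars[pos])
  }
  rec <- seq_record(id, paste(chars, collapse = ""), alphabet = alphabet)
  truth <- if (length(implants)) {
    data.frame(
      start = vapply(implants, `[[`, integer(1), "position"),
      end = vapply(implants, function(x) x$position + x$length - 1L,
                   integer(1)),
      residue_set = vapply(implants, function(x) {
        paste(x$residue_set, collapse = "")
      }, ""),
      concentration = vapply(implants, `[[`, numeric(1), "concentration"),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(start = integer(), end = integer(),
               residue_set = character(), concentration = numeric())
  }
  attr(rec, "truth") <- truth
  rec
}

#' Reciprocal-overlap coincidence of a feature and annotated regions
#'
#' The evaluation rule used for signal-peptide-style features: a feature
#' coincides with the annotation when some region shares at least 50% of
#' the feature's residues AND that shared span covers at least 50% of that
#' region's residues. Both thresholds are compared with `>=` on exact
#' residue counts, so an exact 50% tie qualifies.
#'
#' @param feature_start,feature_end 1-based inclusive feature interval.
#' @param regions An `lps_regions` data.frame (or any data.frame with
#'   `start`/`end`).
#' @return `TRUE` or `FALSE`.
#' @examples
#' regs <- data.frame(start = 5, end = 24)
#' coincides(1, 20, regs)   # TRUE: 16/20 and 16/20
#' coincides(1, 20, data.frame(start = 15, end = 100))  # FALSE
#' @export
coincides <- function(feature_start, feature_end, regions) {
  stopifnot(feature_start >= 1, feature_end >= feature_start)
  if (!NROW(regions)) return(FALSE)
  f_len <- feature_end - feature_start + 1
  for (i in seq_len(nrow(regions))) {
    ov <- min(feature_end, regions$end[i]) -
      max(feature_start, regions$start[i]) + 1
    if (ov <= 0) next
    r_len <- regions$end[i] - regions$start[i] + 1
    if (ov * 2 >= f_len && ov * 2 >= r_len) return(TRUE)
  }
  FALSE
}

#' Read a 3-column feature-interval table
#'
#' Tab-separated `seq_id  start  end` lines for use with [coincides()].
#'
#' @param path File path.
#' @return data.frame with `seq_id`, `start`, `end`.
#' @export
read_feature_table <- function(path) {
  df <- read_domain_table(path)
  df[, c("seq_id", "start", "end")]
}
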