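#' Read a domain-annotation table
#'
#' Tab-separated, one interval per line: `seq_id  start  end  domain_id`
#' (1-based inclusive), `#` comments allowed. Simple Pfam-style region
#' tables with these four leading columns are read by the same path.
#'
#' @param path File path.
#' @return data.frame with columns `seq_id`, `start`, `end`, `domain_id`.
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("no domain intervals in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < 3L)) stop("each line needs seq_id, start, end[, domain_id]")
  df <- data.frame(
    seq_id = vapply(fields, `[`, "", 1L),
    start = as.integer(vapply(fields, `[`, "", 2L)),
    end = as.integer(vapply(fields, `[`, "", 3L)),
    domain_id = ifelse(n >= 4L, vapply(fields, function(f) {
      if (length(f) >= 4L) f[4L] else "."
    }, ""), "."),
    stringsAsFactors = FALSE
  )
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop("non-integer coordinates in ", path)
  }
  df
}

# Merge overlapping/duplicated intervals; domain ids of merged spans are
# joined with "+".
merge_domain_intervals <- function(domains) {
  domains <- domains[order(domains$start), , drop = FALSE]
  out <- domains[0, , drop = FALSE]
  for (i in seq_len(nrow(domains))) {
    if (nrow(out) && domains$start[i] <= out$end[nrow(out)] + 0L) {
      if (domains$start[i] <= out$end[nrow(out)]) {
        out$end[nrow(out)] <- max(out$end[nrow(out)], domains$end[i])
        out$domain_id[nrow(out)] <- paste(out$domain_id[nrow(out)],
                                          domains$domain_id[i], sep = "+")
        next
      }
    }
    out <- rbind(out, domains[i, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Excise or mask annotated domains
#'
#' The domain-filter accessory: `excised` deletes each domain span so the
#' output sequence is shorter; `masked` replaces each span with the
#' unknown letter so length is preserved. Either way the original-
#' coordinate spans are recorded in the record's `filtered_intervals` (and
#' appear on the FASTA name line as `#FILTERED start-end id[,...]#` when
#' written), so that biased regions found on the filtered sequence can be
#' mapped back with [remap_region()].
#'
#' @param record A [seq_record()].
#' @param domains data.frame with `start`, `end` and optionally `seq_id`
#'   (rows for other sequences are ignored) and `domain_id`. Overlapping
#'   domains are merged first.
#' @param mode `"excised"` or `"masked"`.
#' @return The filtered [seq_record()].
#' @export
apply_domain_filter <- function(record, domains,
                                mode = c("excised", "masked")) {
  mode <- match.arg(mode)
  stopifnot(inherits(record, "seq_record"))
  domains <- as.data.frame(domains, stringsAsFactors = FALSE)
  if (!is.null(domains$seq_id)) {
    domains <- domains[domains$seq_id == record$id, , drop = FALSE]
  }
  if (!nrow(domains)) return(record)
  if (is.null(domains$domain_id)) domains$domain_id <- "."
  L <- nchar(record$residues)
  bad <- domains$start < 1L | domains$end > L | domains$start > domains$end
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("domain interval ", domains$start[i], "-", domains$end[i],
         " outside sequence '", record$id, "' (length ", L, ")")
  }
  domains <- merge_domain_intervals(
    domains[, c("start", "end", "domain_id")])
  chars <- seq_chars(record)
  span_pos <- unlist(mapply(seq.int, domains$start, domains$end,
                            SIMPLIFY = FALSE))
  residues <- if (mode == "excised") {
    paste(chars[-span_pos], collapse = "")
  } else {
    chars[span_pos] <- record$alphabet$unknown
    paste(chars, collapse = "")
  }
  rec <- record
  rec$residues <- residues
  rec$filtered_intervals <- normalize_intervals(domains)
  rec
}

# Original positions surviving excision, in filtered order: the map from
# filtered coordinate f to original coordinate is kept_positions[f].
.kept_positions <- function(filtered) {
  fi <- filtered$filtered_intervals
  L_orig <- nchar(filtered$residues) + sum(fi$end - fi$start + 1L)
  excised <- unlist(mapply(seq.int, fi$start, fi$end, SIMPLIFY = FALSE))
  setdiff(seq_len(L_orig), excised)
}

#' Map a region from filtered back to original coordinates
#'
#' After scanning an excised sequence, region coordinates refer to the
#' shortened sequence. Remapping restores original coordinates: the
#' region's outer extent is the original span of its first and last
#' position, and any excised domain falling strictly inside that extent is
#' reported in the region's `excluded` table — the region is then
#' discontinuous, its residues being those of the extent minus the
#' excluded spans. Masked sequences keep their length, so no remap is
#' needed there.
#'
#' @param region A region list (as built by [minimize_contig()]), with
#'   coordinates on the filtered sequence.
#' @param filtered The excised [seq_record()] the region was found on
#'   (must carry `filtered_intervals`).
#' @return The region in original coordinates, with an `excluded`
#'   data.frame of gap spans (possibly empty).
#' @export
remap_region <- function(region, filtered) {
  fi <- filtered$filtered_intervals
  if (!nrow(fi)) {
    region$excluded <- empty_intervals()
    return(region)
  }
  kept <- .kept_positions(filtered)
  s <- kept[region$start]
  e <- kept[region$end]
  inside <- fi[fi$start > s & fi$end < e, , drop = FALSE]
  rownames(inside) <- NULL
  region$start <- s
  region$end <- e
  region$excluded <- inside
  region
}

#' @rdname remap_region
#' @param regions An `lps_regions` data.frame from [annotate()] with
#'   coordinates on `filtered`.
#' @export
remap_regions <- function(regions, filtered) {
  if (!nrow(regions)) return(regions)
  fi <- filtered$filtered_intervals
  if (!nrow(fi)) return(regions)
  kept <- .kept_positions(filtered)
  for (i in seq_len(nrow(regions))) {
    s <- kept[regions$start[i]]
    e <- kept[regions$end[i]]
    regions$start[i] <- s
    regions$end[i] <- e
    regions$length[i] <- e - s + 1L
    inside <- fi[fi$start > s & fi$end < e, , drop = FALSE]
    rownames(inside) <- NULL
    regions$excluded[[i]] <- inside
  }
  regions
}
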