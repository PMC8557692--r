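#' Bias signature
#'
#' The biasing residues of a region, in bias-precedence order, wrapped in
#' curly brackets — e.g. `{PYQ}` for a region biased foremost for proline,
#' then tyrosine, then glutamine.
#'
#' @param residue_set Character vector of residue letters in precedence
#'   order.
#' @return Signature string.
#' @examples
#' bias_signature(c("P", "Y", "Q"))  # "{PYQ}"
#' @export
bias_signature <- function(residue_set) {
  stopifnot(length(residue_set) >= 1L)
  paste0("{", paste(residue_set, collapse = ""), "}")
}

#' Protein bias-class table
#'
#' Reads a class table: one `label residues` pair per line, `#` comments.
#' The packaged table (`extdata/protein_classes.txt`) encodes the Taylor
#' Venn property sets (hydrophobic, polar, small, tiny, aliphatic,
#' aromatic, charged, positive, negative) plus the extra intersection
#' categories glx, tiny_polar and polar_aromatic; `mixed` is the fallback
#' for sets no class contains.
#'
#' @param path Class-table file; default the packaged table.
#' @return A data.frame with columns `label`, `residues` (list column) and
#'   `size`, in file order.
#' @export
read_class_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "protein_classes.txt",
                        package = "flpsr", mustWork = TRUE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\\s+")
  if (any(vapply(fields, length, integer(1)) != 2L)) {
    stop("each class line must be 'label residues'")
  }
  residues <- lapply(fields, function(f) {
    strsplit(toupper(f[2L]), "", fixed = TRUE)[[1]]
  })
  data.frame(
    label = vapply(fields, `[`, "", 1L),
    size = lengths(residues),
    stringsAsFactors = FALSE
  ) -> df
  df$residues <- residues
  df
}

.class_table_cache <- new.env(parent = emptyenv())

default_class_table <- function() {
  if (is.null(.class_table_cache$tab)) {
    .class_table_cache$tab <- read_class_table()
  }
  .class_table_cache$tab
}

#' Physico-chemical class of a protein bias
#'
#' Among the classes whose residue set contains every biasing residue, the
#' one with the smallest membership is returned; ties break by table
#' order; when no class contains the set the label is `"mixed"`.
#'
#' @param residue_set Character vector of protein residue letters.
#' @param table A class table from [read_class_table()].
#' @return Class label.
#' @examples
#' protein_class(c("E", "D"))  # "negative"
#' protein_class(c("K", "R"))  # "positive"
#' @export
protein_class <- function(residue_set, table = default_class_table()) {
  stopifnot(length(residue_set) >= 1L)
  contains <- vapply(table$residues, function(set) {
    all(residue_set %in% set)
  }, logical(1))
  if (!any(contains)) return("mixed")
  cand <- which(contains)
  cand[which.min(table$size[cand])]
  table$label[cand[which.min(table$size[cand])]]
}

# The eight strand-paired DNA bias classes, keyed by the sorted member
# letters of either strand's residue set. Labels use an em dash between
# the two strands' signatures, e.g. "{A}—{T}".
.dna_pair <- function(a, b = NULL) {
  if (is.null(b)) paste0("{", a, "}")
  else paste0("{", a, "}", "\u2014", "{", b, "}")
}
.dna_class_map <- c(
  "A" = .dna_pair("A", "T"), "T" = .dna_pair("A", "T"),
  "G" = .dna_pair("G", "C"), "C" = .dna_pair("G", "C"),
  "AT" = .dna_pair("AT"), "CG" = .dna_pair("GC"),
  "AC" = .dna_pair("AC", "GT"), "GT" = .dna_pair("AC", "GT"),
  "AG" = .dna_pair("AG", "CT"), "CT" = .dna_pair("AG", "CT"),
  "ACT" = .dna_pair("ATC", "ATG"), "AGT" = .dna_pair("ATC", "ATG"),
  "ACG" = .dna_pair("ACG", "CGT"), "CGT" = .dna_pair("ACG", "CGT")
)

#' DNA bias class
#'
#' Every DNA bias maps to one of eight classes; a residue set and its
#' complementary-strand image (the base complement of each member) are the
#' same class — a bias for `{GT}` on one strand is a bias for `{CA}` on
#' the other. The two three-base classes are strand-specific depletions of
#' a single base: `{ATC}---{ATG}` marks a strand-specific lack of G or C.
#'
#' @param residue_set Non-empty subset of `A`, `C`, `G`, `T` of size at
#'   most 3 (all four bases admit no bias).
#' @return One of the eight class labels.
#' @examples
#' dna_class(c("G", "T"))       # "{AC}---{GT}"
#' dna_class("A")               # "{A}---{T}"
#' dna_class(c("A", "T", "C"))  # "{ATC}---{ATG}"
#' @export
dna_class <- function(residue_set) {
  residue_set <- unique(toupper(residue_set))
  if (!length(residue_set) || !all(residue_set %in% c("A", "C", "G", "T"))) {
    stop("residue_set must be a non-empty subset of A, C, G, T")
  }
  if (length(residue_set) == 4L) {
    stop("a bias for all four bases is not possible")
  }
  key <- paste(sort(residue_set), collapse = "")
  unname(.dna_class_map[key])
}

#' Enrichment of the biasing residues
#'
#' The proportion of biasing residues within the region divided by the
#' summed background frequency of those residues; > 1 for any region that
#' is biased under its own background.
#'
#' @param n_biased Residues of the biasing set inside the region.
#' @param length Region length in residues.
#' @param p_sum Summed background frequency of the biasing residues.
#' @return Dimensionless enrichment ratio.
#' @examples
#' bias_enrichment(15, 20, 0.115)  # ~6.52
#' @export
bias_enrichment <- function(n_biased, length, p_sum) {
  stopifnot(length >= 1)
  if (!is.finite(p_sum) || p_sum <= 0) {
    stop("biasing residues absent from the background composition")
  }
  (n_biased / length) / p_sum
}

#' @rdname bias_enrichment
#' @param region One row of an [annotate()] result (or a region list).
#' @param comp The background [composition_table()].
#' @export
region_enrichment <- function(region, comp) {
  set <- if (is.list(region$residue_set) && length(region$residue_set) == 1L)
    region$residue_set[[1L]] else region$residue_set
  bias_enrichment(sum(unlist(region$counts)),
                  region$end - region$start + 1L,
                  sum(comp$freq[set]))
}
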