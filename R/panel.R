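#' Define the lineage panel for a four-lineage marker analysis
#'
#' A lineage panel names the ingroup lineages whose diagnostic patterns are
#' tabulated, an optional annotation lineage that is scored but excluded from
#' the four-lineage statistics, and one or more outgroup taxa. The defaults
#' correspond to the Euarchontoglires setting: Primates, Dermoptera,
#' Scandentia and Glires as ingroup, Lagomorpha as annotation lineage and a
#' laurasiatherian outgroup.
#'
#' @param ingroup Character vector of 3 or 4 ingroup lineage names.
#' @param annotation Optional single annotation lineage name, or `NULL`.
#' @param outgroup Character vector of outgroup taxon names (non-empty).
#' @return An object of class `lineage_panel`.
#' @examples
#' lineage_panel()
#' @export
lineage_panel <- function(ingroup = c("Primates", "Dermoptera", "Scandentia", "Glires"),
                          annotation = "Lagomorpha",
                          outgroup = "Laurasiatheria") {
  ingroup <- as.character(ingroup)
  all_names <- c(ingroup, annotation, outgroup)
  if (anyDuplicated(all_names))
    stop("lineage names must be unique")
  if (length(ingroup) < 1L) stop("ingroup must not be empty")
  if (!length(ingroup) %in% c(3L, 4L))
    warning("ingroup has ", length(ingroup),
            " lineages; the lineage statistics require 3 or 4")
  if (length(outgroup) < 1L)
    stop("at least one outgroup taxon is required")
  structure(list(ingroup = ingroup,
                 annotation = if (is.null(annotation)) NULL else as.character(annotation),
                 outgroup = as.character(outgroup)),
            class = "lineage_panel")
}

#' @export
print.lineage_panel <- function(x, ...) {
  cat("Lineage panel\n")
  cat("  ingroup:   ", paste(x$ingroup, collapse = ", "), "\n")
  cat("  annotation:", if (is.null(x$annotation)) "(none)" else x$annotation, "\n")
  cat("  outgroup:  ", paste(x$outgroup, collapse = ", "), "\n")
  invisible(x)
}

panel_taxa <- function(panel) c(panel$ingroup, panel$annotation, panel$outgroup)

## The 10 diagnostic clade patterns for a 4-lineage ingroup: 6 presence pairs
## and 4 presence triples, in a fixed canonical order (pairs by index, then
## triples by index).
PATTERN_INDEX_SETS <- list(
  c(1L, 2L), c(1L, 3L), c(1L, 4L), c(2L, 3L), c(2L, 4L), c(3L, 4L),
  c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L)
)

#' Enumerate the diagnostic clade patterns of a panel
#'
#' For a four-lineage ingroup there are exactly ten diagnostic patterns: the
#' six presence pairs and four presence triples. A marker showing presence in
#' fewer than two or in all four ingroup lineages is uninformative.
#'
#' @param panel A [lineage_panel()].
#' @return A named list; each element is the character vector of present
#'   ingroup lineages, named by the `+`-joined pattern label.
#' @examples
#' names(clade_patterns(lineage_panel()))
#' @export
clade_patterns <- function(panel = lineage_panel()) {
  stopifnot(inherits(panel, "lineage_panel"), length(panel$ingroup) == 4L)
  sets <- lapply(PATTERN_INDEX_SETS, function(i) panel$ingroup[i])
  names(sets) <- vapply(sets, paste, "", collapse = "+")
  sets
}

pattern_labels <- function(panel) names(clade_patterns(panel))

## Positions (in canonical pattern order) corresponding to the published
## y11..y44 input order: y_ij (i<j) counts markers absent in lineages i and j,
## y_ii markers absent in lineage i only.  Order of labels:
## y11 y12 y13 y14 y22 y23 y24 y33 y34 y44.
Y_ORDER_SETS <- list(
  c(2L, 3L, 4L), c(3L, 4L), c(2L, 4L), c(2L, 3L),
  c(1L, 3L, 4L), c(1L, 4L), c(1L, 3L),
  c(1L, 2L, 4L), c(1L, 2L), c(1L, 2L, 3L)
)

y_order_index <- function() {
  match(vapply(Y_ORDER_SETS, paste, "", collapse = ","),
        vapply(PATTERN_INDEX_SETS, paste, "", collapse = ","))
}

#' Construct pattern counts
#'
#' Holds the per-pattern marker counts for the ten diagnostic clade patterns
#' of a four-lineage panel.
#'
#' @param counts Non-negative integer vector of length 10, either named by the
#'   pattern labels of `panel` or in canonical pattern order (the six pairs
#'   `12,13,14,23,24,34` then the four triples `123,124,134,234` of ingroup
#'   indices).
#' @param panel A [lineage_panel()].
#' @return An object of class `pattern_counts`: a named integer vector with
#'   the panel attached as an attribute.
#' @seealso [counts_from_y()] for the published y-vector input order.
#' @export
pattern_counts <- function(counts, panel = lineage_panel()) {
  labs <- pattern_labels(panel)
  if (length(counts) != 10L) stop("counts must have length 10")
  if (!is.null(names(counts))) {
    if (!setequal(names(counts), labs)) stop("count names do not match panel patterns")
    counts <- counts[labs]
  } else {
    names(counts) <- labs
  }
  counts <- as.integer(counts)
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be non-negative integers")
  names(counts) <- labs
  structure(counts, panel = panel, class = "pattern_counts")
}

#' Convert a y-ordered count vector to pattern counts
#'
#' Four-lineage web statistics take the ten counts in the order
#' `y11, y12, y13, y14, y22, y23, y24, y33, y34, y44`, where `y_ij` (`i < j`)
#' is the number of markers absent in lineages `i` and `j` (present in the
#' other two) and `y_ii` the number absent in lineage `i` only (present in the
#' other three), lineages indexed in panel ingroup order. This mapping is the
#' unique one consistent with the documented anchor counts of the
#' Euarchontoglires survey (132 for Primates+Dermoptera, 94 for
#' Primates+Dermoptera+Scandentia, 9 for Dermoptera+Scandentia).
#'
#' @param y Numeric vector of 10 counts in y order.
#' @param panel A [lineage_panel()].
#' @return A [pattern_counts()] object.
#' @examples
#' counts_from_y(c(16, 12, 9, 9, 16, 5, 13, 55, 132, 94))
#' @export
counts_from_y <- function(y, panel = lineage_panel()) {
  if (length(y) != 10L) stop("y must have length 10")
  out <- integer(10L)
  out[y_order_index()] <- as.integer(y)
  pattern_counts(out, panel)
}

#' Express pattern counts in y order
#'
#' @param counts A [pattern_counts()] object.
#' @return Integer vector of length 10 in `y11 .. y44` order.
#' @export
counts_to_y <- function(counts) {
  stopifnot(inherits(counts, "pattern_counts"))
  as.integer(unclass(counts)[y_order_index()])
}

#' Parse a comma-separated ten-count string
#'
#' Accepts the verbatim y-ordered input string used by the four-lineage web
#' statistics, e.g. `"16,12,9,9,16,5,13,55,132,94"`.
#'
#' @param string A single string of ten comma-separated non-negative integers.
#' @param panel A [lineage_panel()].
#' @return A [pattern_counts()] object.
#' @export
parse_count_string <- function(string, panel = lineage_panel()) {
  y <- suppressWarnings(as.numeric(strsplit(trimws(string), ",")[[1]]))
  if (length(y) != 10L || any(is.na(y)))
    stop("expected 10 comma-separated counts, got: ", string)
  counts_from_y(y, panel)
}

#' @export
print.pattern_counts <- function(x, ...) {
  cat("Pattern counts over", length(x), "diagnostic clade patterns (total",
      sum(x), "markers)\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Reference marker counts for the Euarchontoglires TE survey
#'
#' The per-pattern counts of the 361 diagnostic TE presence/absence markers
#' recovered by genome-wide screening of Primates, Dermoptera, Scandentia and
#' Glires: 132 markers support Primatomorpha (Primates+Dermoptera), 94 support
#' Euarchonta (Primates+Dermoptera+Scandentia), and 135 markers are
#' distributed over the eight conflicting patterns
#' (y order `16,12,9,9,16,5,13,55,132,94`).
#'
#' @param panel A [lineage_panel()].
#' @return A [pattern_counts()] object totalling 361 markers.
#' @examples
#' sum(euarchontoglires_counts())
#' @export
euarchontoglires_counts <- function(panel = lineage_panel()) {
  counts_from_y(c(16L, 12L, 9L, 9L, 16L, 5L, 13L, 55L, 132L, 94L), panel)
}
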