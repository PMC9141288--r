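#' Construct a TE presence/absence marker matrix
#'
#' A marker matrix holds one row per TE locus and one column per taxon, with
#' states coded `"1"` (presence), `"0"` (absence) and `"?"` (unknown: missing
#' sequence or a deletion spanning the insertion site).
#'
#' @param states Character matrix (markers x taxa) over `"0","1","?"`, with
#'   column names; or a matrix coercible to that coding (logical/numeric with
#'   `NA` for unknown).
#' @param panel A [lineage_panel()]; every ingroup lineage must be a column.
#' @param ids Optional character vector of unique marker ids; auto-generated
#'   as `"Euarch001"` style when absent.
#' @param te_family Optional character vector of TE family labels
#'   (e.g. `"MER57F#LTR/ERV1"`), recycled if length 1.
#' @param orientation Optional strand vector (`"+"`/`"-"`), recycled if length 1.
#' @return An object of class `marker_matrix`.
#' @export
marker_matrix <- function(states, panel = lineage_panel(), ids = NULL,
                          te_family = NA_character_, orientation = NA_character_) {
  if (is.logical(states) || is.numeric(states)) {
    m <- matrix(ifelse(is.na(states), "?", ifelse(states == 1, "1", "0")),
                nrow = nrow(states), dimnames = dimnames(states))
    states <- m
  }
  states <- as.matrix(states)
  if (is.null(colnames(states))) stop("states must have taxon column names")
  bad <- !states %in% c("0", "1", "?")
  if (any(bad)) stop("illegal state symbol(s): ", paste(unique(states[bad]), collapse = " "))
  missing_ingroup <- setdiff(panel$ingroup, colnames(states))
  if (length(missing_ingroup))
    stop("ingroup lineage(s) missing from matrix: ", paste(missing_ingroup, collapse = ", "))
  n <- nrow(states)
  if (is.null(ids)) ids <- sprintf("Euarch%03d", seq_len(n))
  if (anyDuplicated(ids)) stop("marker ids must be unique")
  structure(list(states = states,
                 ids = as.character(ids),
                 te_family = rep_len(as.character(te_family), n),
                 orientation = rep_len(as.character(orientation), n),
                 panel = panel),
            class = "marker_matrix")
}

n_markers <- function(x) nrow(x$states)

#' @export
print.marker_matrix <- function(x, ...) {
  cat("TE presence/absence marker matrix:", n_markers(x), "markers x",
      ncol(x$states), "taxa\n")
  cat("  taxa:", paste(colnames(x$states), collapse = ", "), "\n")
  tab <- table(factor(x$states, levels = c("1", "0", "?")))
  cat("  states: ", tab[["1"]], " present, ", tab[["0"]], " absent, ",
      tab[["?"]], " unknown\n", sep = "")
  invisible(x)
}

#' @export
summary.marker_matrix <- function(object, ...) {
  print(object)
  tp <- tabulate_patterns(object)
  print(tp)
  invisible(tp)
}

#' @export
as.data.frame.marker_matrix <- function(x, ...) {
  data.frame(id = x$ids, te_family = x$te_family, orientation = x$orientation,
             x$states, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Classify a marker into a diagnostic clade pattern
#'
#' A marker is informative when at least two ingroup lineages carry the
#' insertion and at least one lacks it. It contributes to the ten-pattern
#' tabulation only if every ingroup state is known, so that both the presence
#' set and its complement are fully determined; a marker with unknown ingroup
#' states that still shows two or more presences and one or more absences is
#' classified `"partial"` (usable for gene-tree export but not for counting),
#' and anything else is `"uninformative"`.
#'
#' @param states Named character vector of states (`"0"/"1"/"?"`) covering all
#'   ingroup lineages, or a single-row slice of a [marker_matrix()].
#' @param panel A [lineage_panel()].
#' @return The pattern label (e.g. `"Primates+Dermoptera"`), `"partial"`, or
#'   `"uninformative"`.
#' @examples
#' classify_marker(c(Primates = "0", Dermoptera = "1", Scandentia = "1",
#'                   Glires = "0"))
#' @export
classify_marker <- function(states, panel = lineage_panel()) {
  miss <- setdiff(panel$ingroup, names(states))
  if (length(miss)) stop("state missing for lineage(s): ", paste(miss, collapse = ", "))
  s <- states[panel$ingroup]
  pres <- sum(s == "1")
  abs_ <- sum(s == "0")
  if (pres < 2L || abs_ < 1L) return("uninformative")
  if (any(s == "?")) return("partial")
  if (pres > 3L) return("uninformative")
  paste(panel$ingroup[s == "1"], collapse = "+")
}

#' Tabulate diagnostic pattern counts of a marker matrix
#'
#' @param matrix A [marker_matrix()] with a four-lineage ingroup.
#' @return A [pattern_counts()] object with attributes `n_partial` and
#'   `n_uninformative` giving the markers excluded from the ten-pattern table.
#' @export
tabulate_patterns <- function(matrix) {
  stopifnot(inherits(matrix, "marker_matrix"))
  panel <- matrix$panel
  if (length(panel$ingroup) != 4L) stop("pattern tabulation requires 4 ingroup lineages")
  labs <- pattern_labels(panel)
  cls <- if (nrow(matrix$states) == 0L) character(0)
  else apply(matrix$states, 1L, classify_marker, panel = panel)
  counts <- pattern_counts(table(factor(cls, levels = labs)), panel)
  attr(counts, "n_partial") <- sum(cls == "partial")
  attr(counts, "n_uninformative") <- sum(cls == "uninformative")
  counts
}

#' Total markers conflicting with a set of supported patterns
#'
#' @param counts A [pattern_counts()] object.
#' @param supported Character vector of supported pattern labels (subset of
#'   `names(counts)`).
#' @return Integer: sum of counts outside `supported`.
#' @examples
#' conflicting_total(euarchontoglires_counts(),
#'                   c("Primates+Dermoptera", "Primates+Dermoptera+Scandentia"))
#' @export
conflicting_total <- function(counts, supported) {
  stopifnot(inherits(counts, "pattern_counts"))
  bad <- setdiff(supported, names(counts))
  if (length(bad)) stop("unknown pattern label(s): ", paste(bad, collapse = ", "))
  sum(counts[!names(counts) %in% supported])
}

#' Concordance of an annotation lineage with a reference lineage
#'
#' Counts how many markers have a known (non-`"?"`) state in the annotation
#' lineage, and how many of those match the state of a reference lineage —
#' e.g. lagomorphs versus rodents, whose shared Glires ancestry predicts
#' identical TE states.
#'
#' @param matrix A [marker_matrix()].
#' @param annotation_lineage Taxon column scored as annotation
#'   (default: the panel's annotation lineage).
#' @param reference_lineage Taxon column compared against (default: the last
#'   ingroup lineage).
#' @return Named integer vector `c(n_known, n_concordant)`.
#' @export
annotation_concordance <- function(matrix,
                                   annotation_lineage = matrix$panel$annotation,
                                   reference_lineage = matrix$panel$ingroup[length(matrix$panel$ingroup)]) {
  stopifnot(inherits(matrix, "marker_matrix"))
  if (is.null(annotation_lineage) || !annotation_lineage %in% colnames(matrix$states))
    stop("annotation lineage not present in matrix")
  if (!reference_lineage %in% colnames(matrix$states))
    stop("reference lineage not present in matrix")
  a <- matrix$states[, annotation_lineage]
  r <- matrix$states[, reference_lineage]
  known <- a != "?"
  c(n_known = sum(known), n_concordant = sum(known & a == r))
}
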