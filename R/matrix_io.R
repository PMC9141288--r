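## Binary (1/0/?) marker-matrix readers and writers.  These dialects are
## deliberately small: a NEXUS DATA block with datatype=standard,
## symbols="01", missing=?, one taxon per MATRIX line, plus an optional
## CHARLABELS block carrying marker ids; and a relaxed PHYLIP (names up to 50
## characters, whitespace-delimited, sequential).  Matrices are stored
## taxon-per-row in the files and marker-per-row in memory.

default_panel_for <- function(taxa, panel = NULL) {
  if (!is.null(panel)) return(panel)
  def <- lineage_panel()
  ingroup <- intersect(def$ingroup, taxa)
  if (length(ingroup) < 3L) ingroup <- taxa[seq_len(min(4L, length(taxa)))]
  annotation <- if (!is.null(def$annotation) && def$annotation %in% taxa) def$annotation
  rest <- setdiff(taxa, c(ingroup, annotation))
  outgroup <- if (length(rest)) rest else "Laurasiatheria"
  suppressWarnings(lineage_panel(ingroup, annotation, outgroup))
}

#' Read a TE presence/absence marker matrix
#'
#' Reads 1/0/`?` matrices in NEXUS (DATA block, `datatype=standard`,
#' `symbols="01"`, `missing=?`) or relaxed PHYLIP format (taxon names up to 50
#' characters, whitespace-delimited). Marker ids are recovered from a NEXUS
#' CHARLABELS block when present, otherwise auto-generated.
#'
#' @param path Path to the matrix file.
#' @param format `"nexus"` or `"phylip"` (default: guessed from the first line).
#' @param panel Optional [lineage_panel()]; by default inferred from the taxon
#'   names (known default lineage names, remaining taxa as outgroup).
#' @return A [marker_matrix()].
#' @export
read_marker_matrix <- function(path, format = c("auto", "nexus", "phylip"),
                               panel = NULL) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto")
    format <- if (length(lines) && grepl("^#NEXUS", lines[1], ignore.case = TRUE))
      "nexus" else "phylip"
  if (format == "nexus") read_matrix_nexus(lines, panel, path)
  else read_matrix_phylip(lines, panel, path)
}

parse_state_row <- function(chars, where) {
  bad <- !chars %in% c("0", "1", "?")
  if (any(bad))
    stop("illegal symbol '", chars[bad][1], "' at ", where)
  chars
}

read_matrix_phylip <- function(lines, panel, path) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PHYLIP file: ", path)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 2L || any(is.na(hdr)))
    stop("malformed PHYLIP header (line 1) in ", path)
  ntax <- hdr[1]; nchar_ <- hdr[2]
  if (length(lines) < ntax + 1L) stop("PHYLIP file truncated: ", path)
  taxa <- character(ntax)
  states <- matrix("?", nrow = ntax, ncol = nchar_)
  for (i in seq_len(ntax)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(parts) < 2L) stop("malformed PHYLIP row (line ", i + 1L, ") in ", path)
    taxa[i] <- parts[1]
    row <- strsplit(paste(parts[-1], collapse = ""), "")[[1]]
    if (length(row) != nchar_)
      stop("row length ", length(row), " != ", nchar_, " (line ", i + 1L, ") in ", path)
    states[i, ] <- parse_state_row(row, paste0("line ", i + 1L, " of ", path))
  }
  if (anyDuplicated(taxa)) stop("duplicate taxon name in ", path)
  rownames(states) <- taxa
  marker_matrix(t(states), default_panel_for(taxa, panel))
}

read_matrix_nexus <- function(lines, panel, path) {
  txt <- paste(lines, collapse = "\n")
  low <- tolower(txt)
  get_num <- function(key) {
    m <- regmatches(low, regexpr(paste0(key, "\\s*=\\s*[0-9]+"), low))
    if (!length(m)) stop("missing ", key, " in NEXUS dimensions: ", path)
    as.integer(sub(paste0(key, "\\s*=\\s*"), "", m))
  }
  ntax <- get_num("ntax"); nchar_ <- get_num("nchar")
  mstart <- regexpr("matrix", low)
  if (mstart < 0) stop("no MATRIX statement in ", path)
  rest <- substr(txt, mstart + attr(mstart, "match.length"), nchar(txt))
  body <- strsplit(rest, ";", fixed = TRUE)[[1]][1]
  rows <- trimws(strsplit(body, "\n")[[1]])
  rows <- rows[nzchar(rows) & !grepl("^\\[", rows)]
  taxa <- character(0)
  acc <- list()
  for (r in rows) {
    parts <- strsplit(r, "\\s+")[[1]]
    if (length(parts) < 2L) stop("malformed MATRIX row '", r, "' in ", path)
    tx <- parts[1]
    chars <- strsplit(paste(parts[-1], collapse = ""), "")[[1]]
    if (tx %in% taxa) acc[[tx]] <- c(acc[[tx]], chars)  # interleaved continuation
    else { taxa <- c(taxa, tx); acc[[tx]] <- chars }
  }
  if (length(taxa) != ntax) stop("expected ", ntax, " taxa, found ", length(taxa), " in ", path)
  states <- matrix("?", nrow = ntax, ncol = nchar_, dimnames = list(taxa, NULL))
  for (tx in taxa) {
    if (length(acc[[tx]]) != nchar_)
      stop("taxon ", tx, ": ", length(acc[[tx]]), " characters, expected ", nchar_, " in ", path)
    states[tx, ] <- parse_state_row(acc[[tx]], paste0("taxon ", tx, " of ", path))
  }
  ids <- NULL
  cl <- regexpr("charlabels", low)
  if (cl > 0) {
    rest <- substr(txt, cl + attr(cl, "match.length"), nchar(txt))
    lab <- strsplit(rest, ";", fixed = TRUE)[[1]][1]
    ids <- strsplit(trimws(lab), "\\s+")[[1]]
    if (length(ids) != nchar_) ids <- NULL
  }
  marker_matrix(t(states), default_panel_for(taxa, panel), ids = ids)
}

#' Write a TE presence/absence marker matrix
#'
#' The NEXUS writer emits a DATA block (`datatype=standard`, `symbols="01"`,
#' `missing=?`) directly usable by external network/Bayesian tools, plus a
#' CHARLABELS block with the marker ids; the PHYLIP writer emits the relaxed
#' dialect accepted by [read_marker_matrix()].
#'
#' @param matrix A [marker_matrix()].
#' @param path Output file path.
#' @param format `"nexus"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_marker_matrix <- function(matrix, path, format = c("nexus", "phylip")) {
  stopifnot(inherits(matrix, "marker_matrix"))
  format <- match.arg(format)
  if (n_markers(matrix) == 0L) stop("refusing to write an empty matrix")
  states <- t(matrix$states)  # taxa x markers
  taxa <- rownames(states)
  rows <- apply(states, 1L, paste, collapse = "")
  pad <- formatC(taxa, width = max(nchar(taxa)) + 2L, flag = "-")
  if (format == "phylip") {
    writeLines(c(paste(length(taxa), ncol(states)), paste0(pad, rows)), path)
  } else {
    writeLines(c(
      "#NEXUS",
      "BEGIN DATA;",
      paste0("  DIMENSIONS NTAX=", length(taxa), " NCHAR=", ncol(states), ";"),
      "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;",
      "  CHARLABELS",
      paste0("    ", paste(matrix$ids, collapse = " "), ";"),
      "  MATRIX",
      paste0("    ", pad, rows),
      "  ;",
      "END;"), path)
  }
  invisible(path)
}

#' Export pattern counts as CSV
#'
#' Writes the ten diagnostic pattern counts with their labels, canonical order
#' position and y-order position.
#'
#' @param counts A [pattern_counts()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pattern_counts <- function(counts, path) {
  stopifnot(inherits(counts, "pattern_counts"))
  ylab <- character(10L)
  ylab[y_order_index()] <- c("y11", "y12", "y13", "y14", "y22", "y23", "y24",
                             "y33", "y34", "y44")
  df <- data.frame(pattern = names(counts), count = as.integer(counts),
                   y_label = ylab)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
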