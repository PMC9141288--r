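#' TE annotation on a locus
#'
#' Coordinates are 0-based, half-open, in alignment columns (the package
#' converts 1-based RepeatMasker coordinates on input).
#'
#' @param family TE family label, e.g. `"MER57F#LTR/ERV1"` or `"L1MB5#LINE/L1"`.
#' @param strand `"+"` or `"-"`.
#' @param start,end Integer column coordinates, `start < end`.
#' @param truncation_3prime Nucleotides missing from the element's 3' end.
#' @return An object of class `te_annotation`.
#' @export
te_annotation <- function(family, strand = "+", start, end, truncation_3prime = 0L) {
  stopifnot(start >= 0, start < end, truncation_3prime >= 0,
            strand %in% c("+", "-"))
  structure(list(family = family, strand = strand,
                 start = as.integer(start), end = as.integer(end),
                 truncation_3prime = as.integer(truncation_3prime)),
            class = "te_annotation")
}

#' A per-locus multiple sequence alignment with a TE annotation
#'
#' @param sequences Named character vector of equal-length aligned sequences
#'   over `A,C,G,T,N,-` (case-insensitive).
#' @param te A [te_annotation()]; its span must lie within the alignment.
#' @param outgroup_taxa Taxa treated as outgroup for criterion 4.
#' @param taxon_families,taxon_strands Optional named vectors giving the
#'   per-taxon TE family/strand observed at the locus (used by criteria 2-3;
#'   taxa without an entry inherit the locus annotation).
#' @return An object of class `locus_alignment`.
#' @export
locus_alignment <- function(sequences, te, outgroup_taxa = character(0),
                            taxon_families = NULL, taxon_strands = NULL) {
  stopifnot(inherits(te, "te_annotation"))
  sequences <- toupper(unlist(sequences))
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique taxon names")
  len <- unique(nchar(sequences))
  if (length(len) != 1L)
    stop("taxon row lengths differ: ", paste(range(nchar(sequences)), collapse = " vs "))
  if (te$end > len) stop("TE span exceeds alignment length")
  structure(list(sequences = sequences, te = te,
                 outgroup_taxa = as.character(outgroup_taxa),
                 taxon_families = taxon_families, taxon_strands = taxon_strands),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("Locus alignment:", length(x$sequences), "taxa x",
      nchar(x$sequences[1]), "columns;", x$te$family,
      sprintf("[%d,%d) strand %s\n", x$te$start, x$te$end, x$te$strand))
  invisible(x)
}

locus_chars <- function(locus) {
  do.call(rbind, strsplit(unname(locus$sequences), ""))
}

## majority consensus over non-gap characters per column; "-" where all gap
column_consensus <- function(chars) {
  apply(chars, 2L, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (!length(col)) return("-")
    names(which.max(table(col)))
  })
}

#' Call per-taxon presence/absence/unknown states at a TE locus
#'
#' A taxon is called `present` when at least `coverage_threshold` of the TE
#' columns carry sequence; `absent` when the TE span is one contiguous gap
#' whose boundaries sit within 3 nt of the annotated insertion site and both
#' flanks are alignable (at least 20 nt of sequence each side with >= 60%
#' identity to the locus consensus); anything else (N-runs, partial elements,
#' flank deletions, boundary shifts above 3 nt) is `unknown`. A gap overhang
#' that exactly duplicates the opposite flank (a target-site duplication
#' alignment register) is not counted as a boundary shift.
#'
#' @param locus A [locus_alignment()].
#' @param coverage_threshold Fraction of TE columns that must be non-gap for a
#'   presence call (default 0.8).
#' @param max_shift Maximum tolerated insertion-boundary shift in nt
#'   (default 3).
#' @param min_flank Minimum alignable flank length in nt each side
#'   (default 20).
#' @param min_flank_identity Minimum flank identity to the consensus
#'   (default 0.6).
#' @return An object of class `diagnostic_call` with per-taxon `states`
#'   (`"1"/"0"/"?"`), `shift_nt`, and unset criteria flags (see
#'   [validate_marker()]).
#' @export
call_states <- function(locus, coverage_threshold = 0.8, max_shift = 3L,
                        min_flank = 20L, min_flank_identity = 0.6) {
  stopifnot(inherits(locus, "locus_alignment"))
  te <- locus$te
  if (te$end <= te$start) stop("empty TE span")
  chars <- locus_chars(locus)
  taxa <- names(locus$sequences)
  ncol_ <- ncol(chars)
  span <- (te$start + 1L):te$end
  cons <- column_consensus(chars)
  states <- stats::setNames(rep("?", length(taxa)), taxa)
  shifts <- stats::setNames(rep(NA_real_, length(taxa)), taxa)

  ## longest target-site duplication in the consensus: columns immediately 3'
  ## of the TE end duplicating those immediately 5' of the TE start.  A clean
  ## absence gap may span the TE plus either TSD copy, so boundary shifts are
  ## measured against the best of the three registrations.
  dup_len <- local({
    best <- 0L
    for (e in 1:25) {
      if (te$end + e > ncol_ || te$start - e + 1L < 1L) break
      a <- cons[(te$end + 1L):(te$end + e)]
      b <- cons[(te$start - e + 1L):te$start]
      if (any(a == "-") || any(b == "-")) break
      allow <- if (e <= 6L) 0L else ceiling(0.1 * e)
      if (sum(a != b) <= allow) best <- e
    }
    best
  })
  registrations <- rbind(c(te$start, te$end),
                         c(te$start, te$end + dup_len),
                         c(te$start - dup_len, te$end))

  for (i in seq_along(taxa)) {
    row <- chars[i, ]
    in_span <- row[span]
    n_seq <- sum(in_span %in% c("A", "C", "G", "T"))
    coverage <- n_seq / length(span)
    if (coverage >= coverage_threshold) {
      states[i] <- "1"
      ## boundary offset of the realized element against the annotation
      nz <- which(in_span != "-")
      shifts[i] <- max(nz[1L] - 1L, length(span) - nz[length(nz)])
      next
    }
    if (all(in_span == "-")) {
      g0 <- te$start + 1L
      while (g0 > 1L && row[g0 - 1L] == "-") g0 <- g0 - 1L
      g1 <- te$end
      while (g1 < ncol_ && row[g1 + 1L] == "-") g1 <- g1 + 1L
      shift <- min(apply(registrations, 1L, function(r)
        max(abs(g0 - (r[1] + 1L)), abs(g1 - r[2]))))
      shifts[i] <- shift
      if (shift > max_shift) next              # shifted boundary: unknown, never absent
      ## flank alignability each side of the gap run
      lf <- if (g0 > 1L) row[seq_len(g0 - 1L)] else character(0)
      rf <- if (g1 < ncol_) row[(g1 + 1L):ncol_] else character(0)
      lc <- if (g0 > 1L) cons[seq_len(g0 - 1L)] else character(0)
      rc <- if (g1 < ncol_) cons[(g1 + 1L):ncol_] else character(0)
      ok_flank <- function(fl, fc, from_end) {
        keep <- fl %in% c("A", "C", "G", "T")
        if (sum(keep) < min_flank) return(FALSE)
        idx <- which(keep)
        idx <- if (from_end) utils::tail(idx, min_flank) else utils::head(idx, min_flank)
        mean(fl[idx] == fc[idx]) >= min_flank_identity
      }
      if (ok_flank(lf, lc, TRUE) && ok_flank(rf, rc, FALSE)) states[i] <- "0"
    }
    ## everything else stays unknown
  }
  structure(list(states = states, shift_nt = shifts, tsd = NULL,
                 criteria = c(location = NA, family = NA, orientation = NA,
                              outgroup = NA),
                 accepted = NA, reason = NULL, locus_family = te$family),
            class = "diagnostic_call")
}

#' @export
print.diagnostic_call <- function(x, ...) {
  cat("Diagnostic call:",
      sum(x$states == "1"), "present /", sum(x$states == "0"), "absent /",
      sum(x$states == "?"), "unknown\n")
  if (!is.na(x$accepted)) {
    cat("  criteria:", paste(names(x$criteria), ifelse(is.na(x$criteria), "NA",
        ifelse(x$criteria, "ok", "FAIL")), collapse = ", "), "\n")
    cat("  accepted:", x$accepted,
        if (!is.null(x$reason)) paste0(" (", x$reason, ")") else "", "\n")
    if (!is.null(x$tsd))
      cat("  TSD:", x$tsd$length, "nt", x$tsd$left, "/", x$tsd$right, "\n")
  }
  invisible(x)
}

#' Detect a target-site duplication flanking a TE insertion
#'
#' Searches, on the taxon's ungapped sequence, for the longest direct repeat
#' whose copies sit immediately 5' of the TE start and immediately 3' of the
#' TE end, with length in `[min_len, max_len]` and at most `max_mismatch`
#' mismatching positions. TSDs arise during TE integration and are the
#' hallmark that insertions at an orthologous locus are shared.
#'
#' @param locus A [locus_alignment()].
#' @param taxon Taxon name; should carry the insertion (be called present).
#' @param min_len,max_len TSD length bounds (defaults 4 and 25 nt).
#' @param max_mismatch Allowed mismatches between the two copies (default 1).
#' @return `NULL`, or a list with `length`, `left`, `right` (the two copies).
#' @export
detect_tsd <- function(locus, taxon, min_len = 4L, max_len = 25L,
                       max_mismatch = 1L) {
  stopifnot(inherits(locus, "locus_alignment"))
  row <- strsplit(locus$sequences[[taxon]], "")[[1]]
  te <- locus$te
  keep <- row != "-"
  useq <- row[keep]
  ustart <- sum(keep[seq_len(te$start)])       # ungapped nt before TE start
  uend <- sum(keep[seq_len(te$end)])           # ungapped nt up to TE end
  n <- length(useq)
  hi <- min(max_len, ustart, n - uend)
  if (hi < min_len) return(NULL)
  for (len in seq(hi, min_len)) {
    left <- useq[(ustart - len + 1L):ustart]
    right <- useq[(uend + 1L):(uend + len)]
    valid <- left %in% c("A", "C", "G", "T") & right %in% c("A", "C", "G", "T")
    mism <- sum(left != right | !valid)
    if (mism <= max_mismatch)
      return(list(length = len, left = paste(left, collapse = ""),
                  right = paste(right, collapse = "")))
  }
  NULL
}

#' Validate a candidate TE marker against the four diagnostic criteria
#'
#' Sets the criteria flags on a [call_states()] result: (1) all realized
#' presence/absence boundaries lie within 3 nt of each other (ungapped
#' target-site coordinates); (2) all present taxa carry the same TE family;
#' (3) all present taxa carry it in the same orientation; (4) every outgroup
#' taxon with a known state is absent, with at least one known outgroup state.
#' The marker is accepted when all four hold and the pre-filter is met (at
#' least two ingroup presences and one ingroup absence). A TSD is attached
#' from the first present taxon that shows one.
#'
#' @param call A `diagnostic_call` from [call_states()].
#' @param locus The same [locus_alignment()].
#' @param max_shift Maximum boundary spread in nt (default 3).
#' @return The completed `diagnostic_call` (criteria flags, `accepted`,
#'   `reason`, `tsd`).
#' @export
validate_marker <- function(call, locus, max_shift = 3L) {
  stopifnot(inherits(call, "diagnostic_call"), inherits(locus, "locus_alignment"))
  te <- locus$te
  known <- call$states != "?"
  present <- names(call$states)[call$states == "1"]
  sh <- call$shift_nt[known]
  call$criteria[["location"]] <- length(sh) > 0 && all(sh <= max_shift, na.rm = TRUE)
  fam <- function(tx) {
    v <- locus$taxon_families
    if (!is.null(v) && tx %in% names(v)) v[[tx]] else te$family
  }
  str_ <- function(tx) {
    v <- locus$taxon_strands
    if (!is.null(v) && tx %in% names(v)) v[[tx]] else te$strand
  }
  call$criteria[["family"]] <- all(vapply(present, fam, "") == te$family)
  call$criteria[["orientation"]] <- all(vapply(present, str_, "") == te$strand)
  og <- intersect(locus$outgroup_taxa, names(call$states))
  if (!length(og)) {
    call$criteria[["outgroup"]] <- NA
    call$reason <- "no outgroup taxon in alignment"
  } else {
    og_states <- call$states[og]
    call$criteria[["outgroup"]] <- any(og_states != "?") && all(og_states %in% c("0", "?"))
  }
  ingroup_states <- call$states[setdiff(names(call$states), locus$outgroup_taxa)]
  prefilter <- sum(ingroup_states == "1") >= 2L && sum(ingroup_states == "0") >= 1L
  call$accepted <- isTRUE(all(call$criteria)) && prefilter
  if (!prefilter && is.null(call$reason))
    call$reason <- "fails pre-filter (needs >=2 present, >=1 absent)"
  for (tx in present) {
    t <- detect_tsd(locus, tx)
    if (!is.null(t)) { call$tsd <- t; break }
  }
  call
}

#' Keep only near-full-length LINE1 elements
#'
#' LINE1 insertions truncated by more than `max_truncation` nucleotides at the
#' 3' end are excluded from marker screening.
#'
#' @param te A [te_annotation()] for a LINE1 family.
#' @param max_truncation Maximum tolerated 3' truncation in nt (default 25,
#'   boundary inclusive).
#' @return `TRUE` if the element passes.
#' @export
line1_filter <- function(te, max_truncation = 25L) {
  stopifnot(inherits(te, "te_annotation"))
  te$truncation_3prime <= max_truncation
}

#' Read TE annotations from BED6 or RepeatMasker .out files
#'
#' BED coordinates are already 0-based half-open; RepeatMasker coordinates are
#' 1-based inclusive and converted, with orientation `"C"` mapped to `"-"`.
#' The 3' truncation of a RepeatMasker hit is taken from the parenthesized
#' "consensus remaining" field (position depends on strand).
#'
#' @param path Input file.
#' @param format `"bed"` or `"repeatmasker_out"`.
#' @return A list of [te_annotation()] objects, with `query` and `query_start`
#'   attributes preserved as element attributes.
#' @export
read_te_annotations <- function(path, format = c("bed", "repeatmasker_out")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    f <- strsplit(line, "\\s+")[[1]]
    if (format == "bed") {
      if (grepl("^(track|browser|#)", line)) next
      if (length(f) < 6L) stop("malformed BED row at line ", ln, " of ", path)
      start <- suppressWarnings(as.integer(f[2])); end <- suppressWarnings(as.integer(f[3]))
      if (is.na(start) || is.na(end) || !f[6] %in% c("+", "-"))
        stop("malformed BED row at line ", ln, " of ", path)
      te <- te_annotation(f[4], f[6], start, end)
      attr(te, "query") <- f[1]
    } else {
      if (grepl("^(SW|score|$)", line) || is.na(suppressWarnings(as.numeric(f[1])))) next
      if (length(f) < 14L) stop("malformed RepeatMasker row at line ", ln, " of ", path)
      begin <- suppressWarnings(as.integer(f[6])); end <- suppressWarnings(as.integer(f[7]))
      if (is.na(begin) || is.na(end)) stop("malformed RepeatMasker row at line ", ln, " of ", path)
      strand <- if (f[9] == "C") "-" else "+"
      paren <- function(x) as.integer(gsub("[()]", "", x))
      trunc3 <- if (strand == "+") paren(f[14]) else paren(f[12])
      te <- te_annotation(paste0(f[10], "#", f[11]), strand, begin - 1L, end,
                          truncation_3prime = trunc3)
      attr(te, "query") <- f[5]
    }
    out[[length(out) + 1L]] <- te
  }
  out
}

#' Read an aligned per-locus FASTA file
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @param te A [te_annotation()] for the locus.
#' @param outgroup_taxa Outgroup taxon names.
#' @param ... Passed to [locus_alignment()].
#' @return A [locus_alignment()].
#' @export
read_locus_alignment <- function(path, te, outgroup_taxa = character(0), ...) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(x) paste(toupper(x), collapse = ""), "")
  locus_alignment(seqs, te, outgroup_taxa, ...)
}

#' Write a locus alignment as FASTA
#'
#' @param locus A [locus_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locus_alignment <- function(locus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in names(locus$sequences))
    writeLines(c(paste0(">", tx), locus$sequences[[tx]]), con)
  invisible(path)
}

#' Write a per-locus diagnostic report as TSV
#'
#' @param calls A named list of completed `diagnostic_call` objects (one per
#'   locus).
#' @param path Output TSV path.
#' @return The report data frame, invisibly.
#' @export
write_diagnostic_report <- function(calls, path) {
  rows <- lapply(names(calls), function(id) {
    cl <- calls[[id]]
    data.frame(locus = id, taxon = names(cl$states), state = unname(cl$states),
               shift_nt = unname(cl$shift_nt),
               location_ok = cl$criteria[["location"]],
               family_ok = cl$criteria[["family"]],
               orientation_ok = cl$criteria[["orientation"]],
               outgroup_ok = cl$criteria[["outgroup"]],
               accepted = cl$accepted,
               tsd_length = if (is.null(cl$tsd)) NA_integer_ else cl$tsd$length)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
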