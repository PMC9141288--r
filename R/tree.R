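#' Convert a marker to an incompletely resolved gene tree
#'
#' Each informative marker defines one Newick "gene tree": the presence set as
#' the single non-trivial clade, all other known-state taxa attached to the
#' root polytomy, unknown-state taxa omitted.
#'
#' @param states Named character vector of `"0"/"1"/"?"` states over taxa.
#' @return A Newick string, or `NA` when fewer than two taxa are present or no
#'   other taxon has a known state.
#' @examples
#' marker_to_genetree(c(Primates = "1", Dermoptera = "1", Scandentia = "0",
#'                      Glires = "0", Laurasiatheria = "0"))
#' @export
marker_to_genetree <- function(states) {
  pres <- names(states)[states == "1"]
  rest <- names(states)[states == "0"]
  if (length(pres) < 2L || length(rest) < 1L) return(NA_character_)
  sprintf("((%s),%s);", paste(pres, collapse = ","), paste(rest, collapse = ","))
}

#' Build the gene-tree set of a marker matrix
#'
#' @param matrix A [marker_matrix()].
#' @return An object of class `genetree_set`: the Newick strings (markers with
#'   fewer than two present or no absent taxa are skipped and counted in
#'   attribute `n_skipped`), with the taxon list attached.
#' @export
genetree_set <- function(matrix) {
  stopifnot(inherits(matrix, "marker_matrix"))
  trees <- apply(matrix$states, 1L, marker_to_genetree)
  skipped <- sum(is.na(trees))
  if (skipped > 0L)
    message(skipped, " marker(s) skipped: fewer than two present taxa")
  structure(trees[!is.na(trees)], taxa = colnames(matrix$states),
            n_skipped = skipped, class = "genetree_set")
}

#' Write gene trees to a Newick file (one per line)
#'
#' @param genetrees A [genetree_set()] or character vector of Newick strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genetrees <- function(genetrees, path) {
  writeLines(unclass(genetrees), path)
  invisible(path)
}

## Marker signatures: unique (presence set | known set) combinations with
## multiplicities.  Quartet scores depend on markers only through these.
signatures_from_states <- function(states_mat) {
  key <- apply(states_mat, 1L, paste, collapse = "")
  tab <- table(key)
  taxa <- colnames(states_mat)
  sigs <- lapply(names(tab), function(k) {
    s <- strsplit(k, "")[[1]]
    list(A = taxa[s == "1"], K = taxa[s != "?"], n = as.integer(tab[[k]]))
  })
  sigs[vapply(sigs, function(s) length(s$A) >= 2L && length(s$K) > length(s$A), TRUE)]
}

signatures_from_newick <- function(trees) {
  taxa <- character(0)
  parsed <- lapply(trees, function(nwk) {
    tr <- ape::read.tree(text = nwk)
    tips <- tr$tip.label
    taxa <<- union(taxa, tips)
    root <- ape::Ntip(tr) + 1L
    inner <- setdiff(unique(tr$edge[, 1L]), root)
    if (length(inner) != 1L) return(NULL)
    kids <- ape::extract.clade(tr, inner)$tip.label
    list(A = kids, K = tips)
  })
  parsed <- parsed[!vapply(parsed, is.null, TRUE)]
  key <- vapply(parsed, function(p)
    paste(paste(sort(p$A), collapse = ","), paste(sort(p$K), collapse = ","), sep = "|"), "")
  tab <- table(key)
  sigs <- lapply(names(tab), function(k) {
    i <- match(k, key)
    c(parsed[[i]], list(n = as.integer(tab[[k]])))
  })
  list(sigs = sigs, taxa = taxa)
}

## Quartet machinery: candidate unrooted binary topologies on the taxon set,
## the induced pairing of every 4-subset, and the per-signature match counts.
quartet_engine <- function(taxa, sigs) {
  nt <- length(taxa)
  if (nt < 4L) stop("need at least 4 taxa for quartet scoring")
  cands <- phangorn::allTrees(nt, tip.label = taxa)
  quartets <- utils::combn(nt, 4L)
  nq <- ncol(quartets)
  code_of <- function(Q, pair) {
    pos <- sort(match(pair, Q))
    if (identical(pos, c(1L, 2L)) || identical(pos, c(3L, 4L))) 1L
    else if (identical(pos, c(1L, 3L)) || identical(pos, c(2L, 4L))) 2L
    else 3L
  }
  cand_codes <- vapply(cands, function(tr) {
    idx <- match(tr$tip.label, taxa)
    parts <- ape::prop.part(tr)
    out <- integer(nq)
    for (p in parts) {
      tipset <- idx[p]
      if (length(tipset) < 2L || length(tipset) > nt - 2L) next
      for (q in seq_len(nq)) {
        if (out[q] > 0L) next
        Q <- quartets[, q]
        inter <- intersect(tipset, Q)
        if (length(inter) == 2L) out[q] <- code_of(Q, inter)
      }
    }
    ## quartets not yet resolved: use complements of parts (rooting artifact)
    for (q in seq_len(nq)) {
      if (out[q] == 0L) {
        for (p in parts) {
          tipset <- setdiff(seq_len(nt), idx[p])
          inter <- intersect(tipset, quartets[, q])
          if (length(inter) == 2L && length(tipset) >= 2L) {
            out[q] <- code_of(quartets[, q], inter)
            break
          }
        }
      }
    }
    out
  }, integer(nq))
  sig_desired <- vapply(sigs, function(s) {
    Aidx <- match(s$A, taxa); Kidx <- match(s$K, taxa)
    out <- integer(nq)
    for (q in seq_len(nq)) {
      Q <- quartets[, q]
      if (!all(Q %in% Kidx)) next
      inter <- intersect(Aidx, Q)
      if (length(inter) == 2L) out[q] <- code_of(Q, inter)
    }
    out
  }, integer(nq))
  cand_codes <- matrix(cand_codes, nrow = nq)
  sig_desired <- matrix(sig_desired, nrow = nq)
  ## match-count matrix: candidates x signatures
  M <- matrix(0L, nrow = length(cands), ncol = length(sigs))
  for (s in seq_along(sigs)) {
    des <- sig_desired[, s]
    act <- des > 0L
    if (any(act))
      M[, s] <- colSums(cand_codes[act, , drop = FALSE] == des[act])
  }
  list(cands = cands, M = M, counts = vapply(sigs, `[[`, 0L, "n"))
}

root_candidate <- function(tr, outgroup) {
  og <- intersect(outgroup, tr$tip.label)
  if (!length(og)) return(tr)
  ape::root(tr, outgroup = og, resolve.root = TRUE)
}

rooted_clades <- function(tr, taxa_order) {
  parts <- ape::prop.part(tr)
  labs <- vapply(parts, function(p) {
    tips <- tr$tip.label[p]
    paste(taxa_order[sort(match(tips, taxa_order))], collapse = "+")
  }, "")
  setdiff(labs, paste(taxa_order[sort(match(tr$tip.label, taxa_order))], collapse = "+"))
}

#' Exhaustive quartet-scored species tree
#'
#' Enumerates every unrooted binary topology on the taxon set (exact for the
#' desk-scale taxon sets used here, up to 6-7 taxa), scores each by the number
#' of (gene tree, four-taxon subset) pairs whose induced resolved quartet it
#' matches — the same objective ASTRAL optimizes — and returns the argmax
#' rooted on the outgroup. Ties are broken lexicographically and reported.
#'
#' @param genetrees A [genetree_set()], a character vector of Newick strings,
#'   or a [marker_matrix()].
#' @param outgroup Outgroup taxon names for rooting (default: the panel
#'   outgroup when a matrix is given, else none).
#' @return An object of class `retro_species_tree`: `tree` (rooted `phylo`),
#'   `topology` (Newick), `quartet_score`, `ties`, `clades`, plus the scoring
#'   engine for reuse by [bootstrap_support()].
#' @export
quartet_species_tree <- function(genetrees, outgroup = NULL) {
  if (inherits(genetrees, "marker_matrix")) {
    if (is.null(outgroup)) outgroup <- genetrees$panel$outgroup
    taxa <- colnames(genetrees$states)
    sigs <- signatures_from_states(genetrees$states)
  } else {
    parsed <- signatures_from_newick(unclass(genetrees))
    sigs <- parsed$sigs
    taxa <- if (!is.null(attr(genetrees, "taxa"))) attr(genetrees, "taxa") else parsed$taxa
  }
  if (!length(sigs)) stop("no informative gene trees")
  eng <- quartet_engine(taxa, sigs)
  scores <- as.numeric(eng$M %*% eng$counts)
  best <- max(scores)
  tie_idx <- which(scores >= best)
  labels <- vapply(eng$cands[tie_idx], function(tr) ape::write.tree(tr), "")
  win <- tie_idx[order(labels)[1L]]
  if (length(tie_idx) > 1L)
    message("quartet-score tie between ", length(tie_idx),
            " topologies; lexicographic winner reported")
  rooted <- root_candidate(eng$cands[[win]], outgroup)
  structure(list(tree = rooted,
                 topology = ape::write.tree(rooted),
                 quartet_score = best,
                 scores = scores,
                 ties = vapply(eng$cands[tie_idx], ape::write.tree, ""),
                 clades = rooted_clades(rooted, taxa),
                 taxa = taxa, outgroup = outgroup, engine = eng),
            class = "retro_species_tree")
}

#' @export
print.retro_species_tree <- function(x, ...) {
  cat("Quartet species tree (exhaustive scoring over",
      length(x$scores), "topologies)\n")
  cat("  topology     :", x$topology, "\n")
  cat("  quartet score:", x$quartet_score, "\n")
  if (length(x$ties) > 1L)
    cat("  TIE between:", paste(x$ties, collapse = " ; "), "\n")
  if (!is.null(x$branch_lengths)) {
    cat("  internal branch lengths (coalescent units):\n")
    for (nm in names(x$branch_lengths))
      cat(sprintf("    %-45s %.3f\n", nm, x$branch_lengths[[nm]]))
  }
  if (!is.null(x$bootstrap)) {
    cat("  bootstrap support (%):\n")
    for (nm in names(x$bootstrap))
      cat(sprintf("    %-45s %.1f\n", nm, x$bootstrap[[nm]]))
  }
  invisible(x)
}

#' @export
plot.retro_species_tree <- function(x, ...) {
  tr <- x$tree
  if (is.null(tr$edge.length)) tr <- ape::compute.brlen(tr, 1)
  ape::plot.phylo(tr, ...)
  invisible(x)
}

#' Marker-resampling bootstrap support for species-tree clades
#'
#' Resamples markers with replacement, rebuilds the quartet species tree per
#' pseudoreplicate, and reports the percentage of replicates in which each
#' clade of interest is recovered in the rooted tree. Bit-reproducible given
#' `seed`.
#'
#' @param matrix A [marker_matrix()] (or anything [quartet_species_tree()]
#'   accepts).
#' @param replicates Number of pseudoreplicates (default 1000).
#' @param seed Integer seed.
#' @param outgroup Outgroup for rooting.
#' @return Named numeric vector: percentage support per clade observed in any
#'   replicate winner.
#' @examples
#' m <- euarchontoglires_markers(include_annotation = FALSE)
#' bootstrap_support(m, replicates = 50, seed = 1)["Primates+Dermoptera"]
#' @export
bootstrap_support <- function(matrix, replicates = 1000L, seed = 1L,
                              outgroup = NULL) {
  stopifnot(replicates >= 1L)
  res <- quartet_species_tree(matrix, outgroup)
  eng <- res$engine
  if (!is.null(seed)) set.seed(seed)
  clade_sets <- lapply(seq_along(eng$cands), function(i)
    rooted_clades(root_candidate(eng$cands[[i]], res$outgroup), res$taxa))
  n <- sum(eng$counts)
  p <- eng$counts / n
  tally <- new.env(parent = emptyenv())
  labels <- vapply(eng$cands, function(tr) ape::write.tree(tr), "")
  for (r in seq_len(replicates)) {
    cnt <- as.numeric(stats::rmultinom(1L, n, p))
    sc <- as.numeric(eng$M %*% cnt)
    win <- which(sc >= max(sc))
    win <- win[order(labels[win])[1L]]
    for (cl in clade_sets[[win]])
      assign(cl, (if (exists(cl, tally)) get(cl, tally) else 0L) + 1L, tally)
  }
  support <- unlist(as.list(tally)) / replicates * 100
  sort(support, decreasing = TRUE)
}

#' Attach coalescent-unit branch lengths to a species tree
#'
#' Each internal branch of the rooted ingroup topology gets the length
#' `max(0, -log((3/2) q_disc))` from [estimate_internal_branch()], applied to
#' the triplet counts around that branch: the two child units of the clade
#' against the nearest sibling unit, markers with mixed unit states or
#' presences outside the triplet excluded.
#'
#' @param result A `retro_species_tree` from [quartet_species_tree()].
#' @param counts A [pattern_counts()] object.
#' @param cap Maximum branch length (passed to [estimate_internal_branch()]).
#' @return `result` with `branch_lengths` (named by clade) filled in and edge
#'   lengths set on `tree`.
#' @export
annotate_branch_lengths <- function(result, counts, cap = 10) {
  stopifnot(inherits(result, "retro_species_tree"),
            inherits(counts, "pattern_counts"))
  panel <- attr(counts, "panel")
  ing <- panel$ingroup
  tr <- result$tree
  parts <- ape::prop.part(tr)
  ntip <- ape::Ntip(tr)
  bl <- list()
  tr$edge.length <- rep(0, nrow(tr$edge))
  for (node_i in seq_along(parts)) {
    tips <- tr$tip.label[parts[[node_i]]]
    clade_ing <- intersect(tips, ing)
    if (!setequal(tips, clade_ing)) next          # only pure ingroup clades
    if (!length(clade_ing) %in% c(2L, 3L) || length(clade_ing) == length(ing)) next
    node <- ntip + node_i
    ## child units of this clade
    kids <- tr$edge[tr$edge[, 1L] == node, 2L]
    units <- lapply(kids, function(k) {
      if (k <= ntip) tr$tip.label[k]
      else tr$tip.label[parts[[k - ntip]]]
    })
    units <- lapply(units, intersect, x = ing)
    units <- units[lengths(units) > 0L]
    if (length(units) != 2L) next
    ## sibling unit: the ingroup lineages nearest outside the clade
    parent <- tr$edge[tr$edge[, 2L] == node, 1L]
    sib_tips <- if (length(parent)) {
      sibs <- setdiff(tr$edge[tr$edge[, 1L] == parent, 2L], node)
      unlist(lapply(sibs, function(k)
        if (k <= ntip) tr$tip.label[k] else tr$tip.label[parts[[k - ntip]]]))
    } else character(0)
    sib <- intersect(sib_tips, ing)
    if (!length(sib)) sib <- setdiff(ing, clade_ing)
    trip <- triplet_counts(counts, units[[1L]], units[[2L]], sib)
    tau <- estimate_internal_branch(trip, cap = cap)
    lab <- paste(ing[sort(match(clade_ing, ing))], collapse = "+")
    bl[[lab]] <- tau
    edge <- which(tr$edge[, 2L] == node)
    if (length(edge)) tr$edge.length[edge] <- tau
  }
  result$branch_lengths <- unlist(bl)
  result$tree <- tr
  result$topology <- ape::write.tree(tr)
  result
}
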