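## Multispecies-coalescent marker simulator on the rooted four-lineage species
## tree (((L1,L2):tau1,L3):tau2,L4), one haploid lineage per species.  Markers
## are single-copy, homoplasy-free characters: an insertion lands uniformly on
## gene-tree branches lying within ancestral populations (weighted per
## population), its presence set is the insertion's descendant taxa, and
## uninformative draws (singletons, all four taxa) are rejected and redrawn.

## taxon bitmasks: L1=1, L2=2, L3=4, L4=8; canonical pattern index per mask
MASK2PAT <- local({
  m <- integer(15L)
  m[c(3L, 5L, 9L, 6L, 10L, 12L, 7L, 11L, 13L, 14L)] <- 1:10
  m
})

#' Simulation settings for coalescent marker generation
#'
#' @param tau1 Coalescent-unit duration of the cherry ancestral population
#'   (stem of lineages 1+2).
#' @param tau2 Duration of the three-lineage ancestral population (stem of
#'   lineages 1+2+3).
#' @param root_stem Length of the stem branch above the root coalescent
#'   population; insertions there are carried by all four lineages and always
#'   rejected as uninformative.
#' @param n_markers Number of informative markers to generate.
#' @param branch_weights Relative insertion-rate weights of the two internal
#'   ancestral populations and the root population.
#' @param missing_rate Probability that an ingroup state is masked to `"?"`.
#' @param seed Integer seed; all randomness flows from it.
#' @param panel A [lineage_panel()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(tau1 = 0.5, tau2 = 1, root_stem = 1, n_markers = 361L,
                       branch_weights = c(1, 1, 1), missing_rate = 0,
                       seed = NULL, panel = lineage_panel()) {
  stopifnot(tau1 >= 0, tau2 >= 0, root_stem >= 0, n_markers >= 1,
            length(branch_weights) == 3L, all(branch_weights > 0),
            missing_rate >= 0, missing_rate < 1)
  structure(list(tau1 = tau1, tau2 = tau2, root_stem = root_stem,
                 n_markers = as.integer(n_markers),
                 branch_weights = branch_weights,
                 missing_rate = missing_rate, seed = seed, panel = panel),
            class = "sim_config")
}

## Weighted gene-tree branch length per descendant mask (1..15) for one
## coalescent history.  Insertions land as a Poisson process along these
## segments, so across loci a pattern's frequency is proportional to its
## expected weighted branch length.
draw_branch_lengths <- function(tau1, tau2, root_stem, w) {
  L <- numeric(15L)
  t1 <- stats::rexp(1)
  c1 <- t1 < tau1
  a1 <- min(t1, tau1)
  L[1L] <- L[2L] <- w[1] * a1
  L[3L] <- w[1] * (tau1 - a1)
  if (c1) {
    t2 <- stats::rexp(1)
    a2 <- min(t2, tau2)
    L[3L] <- L[3L] + w[2] * a2
    L[4L] <- w[2] * a2
    L[7L] <- w[2] * (tau2 - a2)
    clusters <- if (t2 < tau2) 7L else c(3L, 4L)
  } else {
    u1 <- stats::rexp(1, 3)
    if (u1 >= tau2) {
      L[c(1L, 2L, 4L)] <- L[c(1L, 2L, 4L)] + w[2] * tau2
      clusters <- c(1L, 2L, 4L)
    } else {
      L[c(1L, 2L, 4L)] <- L[c(1L, 2L, 4L)] + w[2] * u1
      pair <- sample(c(3L, 5L, 6L), 1L)   # PD, PS or DS among lineages 1-3
      other <- bitwXor(7L, pair)
      u2 <- stats::rexp(1)
      seg <- min(u1 + u2, tau2) - u1
      L[pair] <- L[pair] + w[2] * seg
      L[other] <- L[other] + w[2] * seg
      if (u1 + u2 < tau2) {
        L[7L] <- L[7L] + w[2] * (tau2 - u1 - u2)
        clusters <- 7L
      } else clusters <- c(pair, other)
    }
  }
  clusters <- c(clusters, 8L)
  k <- length(clusters)
  w3 <- w[3]
  if (k == 2L) {
    v <- stats::rexp(1)
    L[clusters] <- L[clusters] + w3 * v
  } else if (k == 3L) {
    v1 <- stats::rexp(1, 3)
    L[clusters] <- L[clusters] + w3 * v1
    j <- sample.int(3L, 2L)
    merged <- sum(clusters[j])
    cl2 <- c(merged, clusters[-j])
    v2 <- stats::rexp(1)
    L[cl2] <- L[cl2] + w3 * v2
  } else {
    v1 <- stats::rexp(1, 6)
    L[clusters] <- L[clusters] + w3 * v1
    j <- sample.int(4L, 2L)
    cl2 <- c(sum(clusters[j]), clusters[-j])
    v2 <- stats::rexp(1, 3)
    L[cl2] <- L[cl2] + w3 * v2
    j2 <- sample.int(3L, 2L)
    cl3 <- c(sum(cl2[j2]), cl2[-j2])
    v3 <- stats::rexp(1)
    L[cl3] <- L[cl3] + w3 * v3
  }
  L[15L] <- w3 * root_stem
  L
}

#' Simulate an informative TE marker matrix under the coalescent
#'
#' Draws gene trees under the multispecies coalescent on
#' `(((L1,L2):tau1,L3):tau2,L4)` and plants insertions as a Poisson process
#' along the weighted gene-tree branch length inside ancestral populations, so
#' insertion opportunity is proportional to branch length both within and
#' across loci. Each insertion's presence set is its descendant taxa;
#' uninformative insertions (present in fewer than two or in all four
#' lineages) are rejected, and gene trees are drawn until `n_markers`
#' informative markers are collected. Ingroup states are then masked to `"?"`
#' independently at `missing_rate`. The outgroup column is `"0"` throughout.
#' Identical configs (including `seed`) give identical matrices.
#'
#' @param config A [sim_config()].
#' @return A [marker_matrix()] with `n_markers` rows.
#' @examples
#' m <- simulate_markers(sim_config(tau1 = 1, tau2 = 1, n_markers = 100, seed = 1))
#' tabulate_patterns(m)
#' @export
simulate_markers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_markers
  pat <- integer(n)
  got <- 0L
  while (got < n) {
    L <- draw_branch_lengths(config$tau1, config$tau2, config$root_stem,
                             config$branch_weights)
    tot <- sum(L)
    if (tot <= 0) stop("zero total insertable branch length")
    k <- stats::rpois(1L, tot)
    if (k == 0L) next
    masks <- sample.int(15L, k, replace = TRUE, prob = L)
    p <- MASK2PAT[masks]
    p <- p[p > 0L]
    if (!length(p)) next
    take <- min(length(p), n - got)
    pat[got + seq_len(take)] <- p[seq_len(take)]
    got <- got + take
  }
  panel <- config$panel
  sets <- PATTERN_INDEX_SETS
  states <- matrix("0", nrow = n, ncol = 4L)
  for (k in 1:10) {
    rows <- pat == k
    if (any(rows)) states[rows, sets[[k]]] <- "1"
  }
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n * 4L) < config$missing_rate, nrow = n)
    states[mask] <- "?"
  }
  colnames(states) <- panel$ingroup
  out <- matrix("0", nrow = n, ncol = length(panel$outgroup),
                dimnames = list(NULL, panel$outgroup))
  marker_matrix(cbind(states, out), panel, te_family = "simTE#LTR/ERV",
                orientation = "+")
}

#' Simulate one gene tree under the multispecies coalescent
#'
#' Coalesces one haploid lineage per species on the species tree
#' `(((L1,L2):tau1,L3):tau2,L4)`: exponential waiting times at rate
#' `k(k-1)/2` within each ancestral population, uncoalesced lineages passed
#' up. Tip branches are drawn to the first speciation at depth 1.
#'
#' @param config A [sim_config()]; `seed` is honoured when non-`NULL`.
#' @return An `ape` `phylo` gene tree with branch lengths in coalescent units
#'   and attribute `"triplet"`: the label pair among lineages 1-3 that
#'   coalesces first (the induced rooted triplet resolution).
#' @examples
#' tr <- simulate_gene_tree(sim_config(tau1 = 1, seed = 42))
#' attr(tr, "triplet")
#' @export
simulate_gene_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ing <- config$panel$ingroup
  t_pd <- 1                      # tip branch to first speciation
  t_pds <- t_pd + config$tau1
  t_root <- t_pds + config$tau2
  ## cluster state: newick string, mask, time at which lineage became available
  cl <- list(list(nwk = ing[1], mask = 1L, t = 0),
             list(nwk = ing[2], mask = 2L, t = 0))
  merges <- list()
  coalesce_in <- function(cl, start, end) {
    t <- start
    while (length(cl) > 1L) {
      k <- length(cl)
      t <- t + stats::rexp(1, k * (k - 1) / 2)
      if (t > end) break
      j <- sample.int(k, 2L)
      a <- cl[[j[1]]]; b <- cl[[j[2]]]
      merged <- list(
        nwk = sprintf("(%s:%.8f,%s:%.8f)", a$nwk, t - a$t, b$nwk, t - b$t),
        mask = a$mask + b$mask, t = t)
      merges[[length(merges) + 1L]] <<- c(a$mask, b$mask)
      cl <- c(cl[-j], list(merged))
    }
    cl
  }
  ## lineages of L1, L2 enter their ancestral population at depth t_pd
  cl <- coalesce_in(cl, t_pd, t_pds)
  cl <- c(cl, list(list(nwk = ing[3], mask = 4L, t = 0)))
  cl <- coalesce_in(cl, t_pds, t_root)
  cl <- c(cl, list(list(nwk = ing[4], mask = 8L, t = 0)))
  cl <- coalesce_in(cl, t_root, Inf)
  tree <- ape::read.tree(text = paste0(cl[[1]]$nwk, ";"))
  trip <- NA_character_
  for (m in merges) {
    if (bitwAnd(m[1], 7L) > 0 && bitwAnd(m[2], 7L) > 0) {
      pairmask <- bitwAnd(m[1] + m[2], 7L)
      trip <- paste(ing[which(bitwAnd(pairmask, c(1L, 2L, 4L)) > 0)], collapse = "+")
      break
    }
  }
  attr(tree, "triplet") <- trip
  tree
}

#' Simulate triplet marker counts at gene-tree discordance frequencies
#'
#' For a three-lineage species tree with internal branch `tau` (coalescent
#' units), gene trees are concordant with probability `1 - (2/3) exp(-tau)`
#' and each discordant resolution has probability `(1/3) exp(-tau)`. Each
#' locus contributes one marker from its gene-tree internal branch, so marker
#' counts follow the gene-tree frequencies; this is the sampling model under
#' which [estimate_internal_branch()] is consistent.
#'
#' @param tau Internal branch length in coalescent units.
#' @param n Number of markers (loci).
#' @param seed Optional integer seed.
#' @return Named integer vector `c(n1, n2, n3)`.
#' @export
simulate_triplet_counts <- function(tau, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conc <- stats::rexp(n) < tau
  k <- sum(!conc)
  pick <- if (k) sample.int(3L, k, replace = TRUE) else integer(0)
  c(n1 = sum(conc) + sum(pick == 1L), n2 = sum(pick == 2L), n3 = sum(pick == 3L))
}
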