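#' Three-lineage tree-versus-polytomy and hybridization test
#'
#' Exact binomial tests on triplet marker counts `(n1, n2, n3)`: markers
#' supporting a candidate clade and its two alternatives. Under a hard
#' polytomy the three resolutions are equiprobable, so the tree test is the
#' one-sided exact binomial tail `P(X >= n1)` with `X ~ Binomial(N, 1/3)`.
#' Under symmetric incomplete lineage sorting the two alternatives are
#' equiprobable, so the hybridization test is the two-sided exact binomial
#' test of `n2` against `n2 + n3` with success probability 1/2.
#'
#' @param counts Numeric vector `c(n1, n2, n3)` of non-negative marker counts;
#'   `n1` is the candidate clade.
#' @param alpha Significance level for `significant_tree`.
#' @return An object of class `kksc` with elements `p_topology`,
#'   `p_hybridization`, `significant_tree`, `counts`, `alpha`.
#' @examples
#' kksc_test(c(94, 55, 12))   # Euarchonta vs its two alternatives
#' kksc_test(c(5, 5, 5))      # star-like triplet, p ~ 0.60
#' @export
kksc_test <- function(counts, alpha = 0.05) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(is.na(counts)) || any(counts < 0))
    stop("counts must be three non-negative numbers (n1, n2, n3)")
  N <- sum(counts)
  if (N < 1) stop("no informative markers")
  n1 <- counts[1]; n2 <- counts[2]; n3 <- counts[3]
  p_top <- stats::pbinom(n1 - 1, N, 1 / 3, lower.tail = FALSE)
  p_hyb <- if (n2 + n3 == 0) 1 else stats::binom.test(n2, n2 + n3, 0.5)$p.value
  structure(list(p_topology = p_top,
                 p_hybridization = p_hyb,
                 significant_tree = p_top < alpha,
                 counts = stats::setNames(counts, c("n1", "n2", "n3")),
                 alpha = alpha),
            class = "kksc")
}

#' @export
print.kksc <- function(x, ...) {
  cat("Three-lineage tree-vs-polytomy test (exact binomial, null 1/3)\n")
  cat(sprintf("  counts: n1 = %g, n2 = %g, n3 = %g (N = %g)\n",
              x$counts[1], x$counts[2], x$counts[3], sum(x$counts)))
  cat(sprintf("  p(topology)      = %.4g  [%ssignificant at alpha = %g]\n",
              x$p_topology, if (x$significant_tree) "" else "not ", x$alpha))
  cat(sprintf("  p(hybridization) = %.4g  (two-sided, n2 vs n3)\n", x$p_hybridization))
  invisible(x)
}

#' Extract triplet counts around a branch from four-lineage pattern counts
#'
#' Collapses pattern counts to the triplet `(unit1 + unit2 | unit3)`: `n1`
#' counts markers present in all lineages of `unit1` and `unit2` and absent
#' elsewhere in the ingroup; `n2` joins `unit1` with `unit3`; `n3` joins
#' `unit2` with `unit3`. Units may be single lineages or clades (e.g.
#' Primatomorpha as one unit at the Euarchontoglires node).
#'
#' @param counts A [pattern_counts()] object.
#' @param unit1,unit2,unit3 Character vectors of ingroup lineage names.
#' @return Named integer vector `c(n1, n2, n3)`.
#' @examples
#' cc <- euarchontoglires_counts()
#' triplet_counts(cc, "Primates", "Dermoptera", "Scandentia")            # 132 13 9
#' triplet_counts(cc, c("Primates", "Dermoptera"), "Scandentia", "Glires") # 94 55 12
#' @export
triplet_counts <- function(counts, unit1, unit2, unit3) {
  stopifnot(inherits(counts, "pattern_counts"))
  panel <- attr(counts, "panel")
  units <- list(unit1, unit2, unit3)
  if (length(bad <- setdiff(unlist(units), panel$ingroup)))
    stop("not ingroup lineage(s): ", paste(bad, collapse = ", "))
  pats <- clade_patterns(panel)
  count_for <- function(a, b) {
    present <- sort(c(units[[a]], units[[b]]))
    hit <- vapply(pats, function(p) identical(sort(p), present), TRUE)
    if (any(hit)) as.integer(counts[[which(hit)]]) else 0L
  }
  c(n1 = count_for(1, 2), n2 = count_for(1, 3), n3 = count_for(2, 3))
}

#' Estimate an internal branch length in coalescent units
#'
#' From triplet counts, the fraction of markers conflicting with the candidate
#' clade estimates the gene-tree discordance `(2/3) exp(-tau)`, giving
#' `tau_hat = max(0, -log((3/2) (n2+n3) / N))`. A conflict-free triplet would
#' give infinite length and is capped at `cap`.
#'
#' @param counts Numeric `c(n1, n2, n3)` triplet counts.
#' @param cap Maximum reported branch length (coalescent units, default 10).
#' @return Branch length in coalescent units.
#' @examples
#' estimate_internal_branch(c(132, 13, 9))
#' @export
estimate_internal_branch <- function(counts, cap = 10) {
  counts <- as.numeric(counts)
  N <- sum(counts)
  if (N < 1) stop("no informative markers")
  disc <- (counts[2] + counts[3]) / N
  if (disc == 0) return(cap)
  min(cap, max(0, -log(1.5 * disc)))
}

## ---------------------------------------------------------------------------
## Expected insertion-opportunity intensities for the 10 informative patterns
## under the multispecies coalescent with uniform insertion along gene-tree
## branches inside ancestral populations.  Role order:
## AB AC AD BC BD CD ABC ABD ACD BCD, where for a caterpillar topology
## (((A,B):t1,C):t2,D) t1 is the cherry stem and t2 the triple stem, and for a
## balanced topology ((A,B):t1,(C,D):t2) the two cherry stems.  Weights
## w = (inner population 1, inner population 2, root population).

intensity_caterpillar <- function(t1, t2, w = c(1, 1, 1)) {
  e1 <- exp(-t1); p1 <- 1 - e1
  e2 <- exp(-t2); e3 <- exp(-3 * t2)
  I <- numeric(10)
  ## cherry ancestral population: coalesced (A,B) branch
  I[1] <- w[1] * (t1 - p1)
  ## triple ancestral population
  ## case A: (A,B) already coalesced -> 2 lineages {AB},{C}
  I[1] <- I[1] + w[2] * p1 * (1 - e2)
  I[7] <- w[2] * p1 * (t2 - (1 - e2))
  ## case B: 3 lineages {A},{B},{C}; first coalescence rate 3, pair uniform
  Lp <- (1 - e3) - 1.5 * e2 * (1 - e2^2)          # total expected pair-branch length
  L3 <- t2 - (3 * (1 - e2) - (1 - e3) / 3) / 2    # expected fully-coalesced length
  I[1] <- I[1] + w[2] * e1 * Lp / 3
  I[2] <- w[2] * e1 * Lp / 3                      # {A,C}
  I[4] <- w[2] * e1 * Lp / 3                      # {B,C}
  I[7] <- I[7] + w[2] * e1 * L3
  ## root population entry-state probabilities
  P1 <- 1.5 * e2 * (1 - e2^2)                     # exactly one coalescence in case B
  P2 <- 1 - e3 - P1                               # both coalescences in case B
  a   <- p1 * (1 - e2) + e1 * P2                  # enter as {ABC},{D}
  b   <- p1 * e2 + e1 * P1 / 3                    # enter as {AB},{C},{D}
  cAC <- e1 * P1 / 3                              # enter as {AC},{B},{D}
  cBC <- e1 * P1 / 3                              # enter as {BC},{A},{D}
  d   <- e1 * e3                                  # enter as 4 singletons
  w3 <- w[3]
  I[7] <- I[7] + w3 * a                                        # {ABC} branch, E[Exp(1)] = 1
  I[1] <- I[1] + w3 * b * 2 / 3                                # {AB} cluster branch
  I[7] <- I[7] + w3 * b / 3; I[8] <- w3 * b / 3; I[6] <- w3 * b / 3
  I[2] <- I[2] + w3 * cAC * 2 / 3
  I[7] <- I[7] + w3 * cAC / 3; I[9] <- w3 * cAC / 3; I[5] <- w3 * cAC / 3
  I[4] <- I[4] + w3 * cBC * 2 / 3
  I[7] <- I[7] + w3 * cBC / 3; I[10] <- w3 * cBC / 3; I[3] <- w3 * cBC / 3
  I <- I + w3 * d / 6
  I
}

intensity_balanced <- function(t1, t2, w = c(1, 1, 1)) {
  p <- 1 - exp(-t1); q <- 1 - exp(-t2)
  d <- (1 - p) * (1 - q)
  w3 <- w[3]
  I <- numeric(10)
  I[1] <- w[1] * (t1 - p) + w3 * (p * q + p * (1 - q) * 2 / 3 + (1 - p) * q / 3)
  I[6] <- w[2] * (t2 - q) + w3 * (p * q + (1 - p) * q * 2 / 3 + p * (1 - q) / 3)
  I[7] <- w3 * p * (1 - q) / 3        # {ABC}
  I[8] <- w3 * p * (1 - q) / 3        # {ABD}
  I[9] <- w3 * (1 - p) * q / 3        # {ACD}
  I[10] <- w3 * (1 - p) * q / 3       # {BCD}
  I + w3 * d / 6
}

#' Enumerate the 15 rooted four-lineage topologies
#'
#' Twelve caterpillar trees `(((A,B),C),D)` and three balanced trees
#' `((A,B),(C,D))` over the panel's four ingroup lineages.
#'
#' @param panel A [lineage_panel()] with four ingroup lineages.
#' @return A list of topology descriptors (kind, lineage roles, Newick label,
#'   role-to-pattern index map).
#' @export
all_topologies <- function(panel = lineage_panel()) {
  stopifnot(length(panel$ingroup) == 4L)
  key <- vapply(PATTERN_INDEX_SETS, paste, "", collapse = ",")
  role_map <- function(perm) {
    sets <- lapply(PATTERN_INDEX_SETS, function(i) sort(perm[i]))
    match(vapply(sets, paste, "", collapse = ","), key)
  }
  ing <- panel$ingroup
  topos <- list()
  for (pair in utils::combn(4L, 2L, simplify = FALSE)) {
    rest <- setdiff(1:4, pair)
    for (third in rest) {
      fourth <- setdiff(rest, third)
      perm <- c(pair, third, fourth)
      topos[[length(topos) + 1L]] <- list(
        kind = "caterpillar", roles = perm,
        label = sprintf("(((%s,%s),%s),%s)", ing[pair[1]], ing[pair[2]],
                        ing[third], ing[fourth]),
        map = role_map(perm))
    }
  }
  for (first in list(c(1L, 2L), c(1L, 3L), c(1L, 4L))) {
    pair2 <- setdiff(1:4, first)
    perm <- c(first, pair2)
    topos[[length(topos) + 1L]] <- list(
      kind = "balanced", roles = perm,
      label = sprintf("((%s,%s),(%s,%s))", ing[first[1]], ing[first[2]],
                      ing[pair2[1]], ing[pair2[2]]),
      map = role_map(perm))
  }
  names(topos) <- vapply(topos, `[[`, "", "label")
  topos
}

topology_probs <- function(t1, t2, topo, weights) {
  I <- if (topo$kind == "caterpillar") intensity_caterpillar(t1, t2, weights)
  else intensity_balanced(t1, t2, weights)
  p <- numeric(10)
  p[topo$map] <- I
  p / sum(p)
}

#' Exact informative-pattern probabilities under the coalescent
#'
#' Closed-form probabilities of the ten diagnostic patterns for a rooted
#' four-lineage topology with internal branch lengths `(tau1, tau2)` in
#' coalescent units, under the marker model: insertions land uniformly along
#' gene-tree branches inside ancestral populations (weighted per population),
#' conditioned on producing an informative pattern. This is the expectation of
#' the Monte-Carlo engine [pattern_probs()] and is used as the likelihood in
#' [fourlin()].
#'
#' @param tau1,tau2 Internal branch lengths in coalescent units (`>= 0`); for
#'   a caterpillar topology `tau1` is the cherry stem and `tau2` the
#'   three-lineage stem.
#' @param topology A topology descriptor from [all_topologies()], or its label;
#'   default the first caterpillar of the default panel,
#'   `(((Primates,Dermoptera),Scandentia),Glires)`.
#' @param weights Relative insertion-rate weights for the two internal
#'   ancestral populations and the root population.
#' @param panel A [lineage_panel()].
#' @return Named probability vector over the ten patterns (sums to 1).
#' @export
pattern_probs_exact <- function(tau1, tau2, topology = NULL,
                                weights = c(1, 1, 1), panel = lineage_panel()) {
  topos <- all_topologies(panel)
  topo <- resolve_topology(topology, topos)
  stats::setNames(topology_probs(tau1, tau2, topo, weights), pattern_labels(panel))
}

resolve_topology <- function(topology, topos) {
  if (is.null(topology)) return(topos[[1L]])
  if (is.character(topology)) {
    if (!topology %in% names(topos)) stop("unknown topology label: ", topology)
    return(topos[[topology]])
  }
  topology
}

#' Monte-Carlo informative-pattern probabilities
#'
#' Estimates the probability of each of the ten diagnostic patterns by
#' simulating markers under the multispecies coalescent with
#' [simulate_markers()] and tabulating their patterns. Deterministic given
#' `seed`; agrees with [pattern_probs_exact()] within Monte-Carlo error.
#'
#' @param tau1,tau2 Internal branch lengths in coalescent units.
#' @param weights Per-population insertion-rate weights (two internal
#'   populations, then root).
#' @param n_mc Number of informative markers to simulate.
#' @param seed Integer seed.
#' @param panel A [lineage_panel()].
#' @return Named probability vector over the ten patterns (sums to 1).
#' @export
pattern_probs <- function(tau1, tau2, weights = c(1, 1, 1), n_mc = 10000L,
                          seed = 1L, panel = lineage_panel()) {
  stopifnot(n_mc >= 1)
  cfg <- sim_config(tau1 = tau1, tau2 = tau2, n_markers = n_mc,
                    branch_weights = weights, seed = seed, panel = panel)
  tab <- tabulate_patterns(simulate_markers(cfg))
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

## ---------------------------------------------------------------------------
## Four-lineage likelihood-ratio test

fit_topology <- function(n, topo, weights, tau_max = 15) {
  nll <- function(par) {
    p <- topology_probs(par[1], par[2], topo, weights)
    -sum(n * log(pmax(p, 1e-300)))
  }
  grid <- c(0, 0.4, 1.2, 3)
  starts <- expand.grid(t1 = grid, t2 = grid)
  vals <- apply(starts, 1L, nll)
  st <- as.numeric(starts[which.min(vals), ])
  fit <- stats::optim(pmax(st, 1e-4), nll, method = "L-BFGS-B",
                      lower = c(0, 0), upper = c(tau_max, tau_max))
  ## profile null: cherry stem collapsed to zero
  null_fit <- stats::optimize(function(t2) nll(c(0, t2)), c(0, tau_max))
  list(tau = fit$par, logLik = -fit$value, logLik_null = -null_fit$objective,
       tau2_null = null_fit$minimum)
}

#' Four-lineage likelihood-ratio test for tree versus polytomy
#'
#' Fits the ten diagnostic pattern counts to every rooted four-lineage
#' topology by maximum likelihood over the two internal branch lengths
#' `(tau1, tau2)` in coalescent units, using the exact coalescent pattern
#' probabilities ([pattern_probs_exact()]). The best topology is the
#' likelihood argmax (ties broken lexicographically and reported). The
#' polytomy test compares the best fit against the same topology with its
#' cherry stem collapsed (`tau1 = 0`); because `tau1` sits on the boundary the
#' null distribution is the 50:50 mixture of a point mass at zero and
#' chi-square with 1 df, and the p-value carries a Bonferroni factor of 3 for
#' the selection among the three resolutions of the collapsed node.
#' Hybridization/introgression is screened by two-sided binomial tests between
#' mirrored conflict patterns — pattern pairs exchanged by the cherry
#' automorphisms of the best topology, which pure lineage sorting leaves
#' equiprobable — with Holm correction.
#'
#' @param counts A [pattern_counts()] object (or 10 counts in canonical order).
#' @param alpha Significance level.
#' @param weights Insertion-rate weights for the two internal populations and
#'   the root population.
#' @param tau_max Upper bound for branch-length optimization.
#' @param panel A [lineage_panel()] (taken from `counts` when available).
#' @return An object of class `fourlin`; see Details for fields.
#' @details Fields: `best_topology` (Newick label), `tau1_hat`, `tau2_hat`,
#' `lrt_stat`, `p_polytomy`, `symmetry_pvalues` (raw), `symmetry_holm`
#' (adjusted), `significant_hybridization`, `fits` (per-topology log-likelihood
#' table), `ties`, `fitted` (probabilities under the best fit), `counts`.
#' @examples
#' fourlin(euarchontoglires_counts())
#' @export
fourlin <- function(counts, alpha = 0.05, weights = c(1, 1, 1), tau_max = 15,
                    panel = NULL) {
  if (!inherits(counts, "pattern_counts")) {
    counts <- pattern_counts(counts, if (is.null(panel)) lineage_panel() else panel)
  }
  panel <- attr(counts, "panel")
  n <- as.numeric(counts)
  if (sum(n) < 10) stop("need at least 10 informative markers")
  if (all(n == 0)) stop("degenerate all-zero counts")
  topos <- all_topologies(panel)
  fits <- lapply(topos, fit_topology, n = n, weights = weights, tau_max = tau_max)
  ll <- vapply(fits, `[[`, 0, "logLik")
  best_ll <- max(ll)
  ties <- names(topos)[ll > best_ll - 1e-6]
  best_lab <- sort(ties)[1L]
  best <- fits[[best_lab]]
  topo <- topos[[best_lab]]
  lrt <- max(0, 2 * (best$logLik - best$logLik_null))
  p_poly <- min(1, 3 * 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE))
  sym <- symmetry_tests(counts, topo, panel)
  holm <- stats::p.adjust(sym, method = "holm")
  const <- lgamma(sum(n) + 1) - sum(lgamma(n + 1))
  structure(list(best_topology = best_lab,
                 tau1_hat = best$tau[1], tau2_hat = best$tau[2],
                 lrt_stat = lrt, p_polytomy = p_poly,
                 symmetry_pvalues = sym, symmetry_holm = holm,
                 significant_hybridization = any(holm < alpha),
                 ties = ties, alpha = alpha, weights = weights,
                 fits = data.frame(topology = names(topos), logLik = ll + const,
                                   row.names = NULL),
                 fitted = stats::setNames(
                   topology_probs(best$tau[1], best$tau[2], topo, weights),
                   names(counts)),
                 logLik = best$logLik + const,
                 counts = counts, panel = panel),
            class = "fourlin")
}

symmetry_tests <- function(counts, topo, panel) {
  ing <- panel$ingroup
  lab <- function(idx) paste(ing[sort(idx)], collapse = "+")
  r <- topo$roles  # A B C D
  pairs <- list(
    c(lab(r[c(1, 3)]), lab(r[c(2, 3)])),
    c(lab(r[c(1, 4)]), lab(r[c(2, 4)])),
    c(lab(r[c(1, 3, 4)]), lab(r[c(2, 3, 4)]))
  )
  if (topo$kind == "balanced")
    pairs <- c(pairs, list(c(lab(r[c(1, 2, 3)]), lab(r[c(1, 2, 4)]))))
  p <- vapply(pairs, function(pr) {
    x <- as.integer(counts[[pr[1]]]); m <- x + as.integer(counts[[pr[2]]])
    if (m == 0) 1 else stats::binom.test(x, m, 0.5)$p.value
  }, 0)
  stats::setNames(p, vapply(pairs, paste, "", collapse = " vs "))
}

#' @export
print.fourlin <- function(x, ...) {
  cat("Four-lineage coalescent likelihood-ratio test\n")
  cat("  best topology :", x$best_topology, "\n")
  if (length(x$ties) > 1L)
    cat("  NOTE: likelihood tie between:", paste(x$ties, collapse = "; "),
        "(lexicographic winner reported)\n")
  cat(sprintf("  tau1 = %.3f, tau2 = %.3f coalescent units\n", x$tau1_hat, x$tau2_hat))
  cat(sprintf("  LRT (cherry stem = 0) = %.2f, p(polytomy) = %.3g\n",
              x$lrt_stat, x$p_polytomy))
  cat(sprintf("  hybridization screen: min Holm-adjusted p = %.3g (%ssignificant at %g)\n",
              min(x$symmetry_holm), if (x$significant_hybridization) "" else "not ",
              x$alpha))
  invisible(x)
}

#' @export
summary.fourlin <- function(object, ...) {
  print(object)
  cat("\nSymmetry (hybridization) tests:\n")
  print(data.frame(p = object$symmetry_pvalues, holm = object$symmetry_holm))
  cat("\nObserved vs fitted pattern counts:\n")
  print(data.frame(observed = as.integer(object$counts),
                   fitted = round(object$fitted * sum(object$counts), 1),
                   row.names = names(object$counts)))
  invisible(object)
}

#' @export
coef.fourlin <- function(object, ...) {
  c(tau1 = object$tau1_hat, tau2 = object$tau2_hat)
}

#' @export
logLik.fourlin <- function(object, ...) {
  structure(object$logLik, df = 2L, nobs = sum(object$counts), class = "logLik")
}

#' @export
residuals.fourlin <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  N <- sum(object$counts)
  e <- object$fitted * N
  r <- as.numeric(object$counts) - e
  if (type == "pearson") r <- r / sqrt(pmax(e, .Machine$double.eps))
  stats::setNames(r, names(object$counts))
}

#' Simulate pattern count vectors from a fitted four-lineage model
#'
#' @param object A [fourlin()] fit.
#' @param nsim Number of count vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A 10 x `nsim` integer matrix of counts (same total as observed).
#' @export
simulate.fourlin <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  stats::rmultinom(nsim, sum(object$counts), object$fitted)
}

#' @export
plot.fourlin <- function(x, ...) {
  N <- sum(x$counts)
  m <- rbind(observed = as.numeric(x$counts), fitted = x$fitted * N)
  graphics::barplot(m, beside = TRUE, las = 2, cex.names = 0.6,
                    legend.text = rownames(m),
                    main = paste("Pattern counts:", x$best_topology), ...)
  invisible(x)
}
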