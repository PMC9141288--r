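# Independent oracles and small generators used across the suite.

# brute-force classification: enumerate the rule directly from the pre-filter
oracle_classify <- function(states, panel = lineage_panel()) {
  s <- states[panel$ingroup]
  np <- sum(s == "1"); na_ <- sum(s == "0")
  if (np < 2 || na_ < 1) return("uninformative")
  if (any(s == "?")) return("partial")
  if (np > 3) return("uninformative")
  paste(panel$ingroup[s == "1"], collapse = "+")
}

# brute-force binomial tail P(X >= k), X ~ Binomial(N, p)
oracle_binom_tail <- function(k, N, p = 1 / 3) {
  if (k <= 0) return(1)
  sum(vapply(k:N, function(x) choose(N, x) * p^x * (1 - p)^(N - x), 0))
}

# exhaustive direct-repeat search adjacent to the TE boundaries of a taxon's
# ungapped sequence (the detect_tsd contract, re-derived independently)
oracle_tsd <- function(locus, taxon, min_len = 4, max_len = 25, max_mismatch = 1) {
  row <- strsplit(locus$sequences[[taxon]], "")[[1]]
  keep <- row != "-"
  useq <- row[keep]
  ustart <- sum(keep[seq_len(locus$te$start)])
  uend <- sum(keep[seq_len(locus$te$end)])
  best <- NULL
  for (len in min_len:min(max_len, ustart, length(useq) - uend)) {
    a <- useq[(ustart - len + 1):ustart]
    b <- useq[(uend + 1):(uend + len)]
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    if (sum(a != b | !ok) <= max_mismatch) best <- len
  }
  best
}

random_marker_matrix <- function(n, seed, missing = 0.15) {
  set.seed(seed)
  panel <- lineage_panel()
  taxa <- c(panel$ingroup, panel$annotation, panel$outgroup)
  states <- matrix(sample(c("0", "1", "?"), n * length(taxa), replace = TRUE,
                          prob = c(0.45, 0.45, missing)),
                   nrow = n, dimnames = list(NULL, taxa))
  marker_matrix(states, panel)
}

ALL_STATE_VECTORS <- local({
  g <- expand.grid(rep(list(c("0", "1", "?")), 4), stringsAsFactors = FALSE)
  colnames(g) <- lineage_panel()$ingroup
  g
})
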