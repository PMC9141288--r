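#' Settings for simulating a TE locus alignment
#'
#' @param flank_length Flank length each side of the insertion site, nt.
#' @param te_length Element length, nt.
#' @param tsd_length Target-site duplication length, nt (0 for none).
#' @param shift_nt Planted boundary shift applied to taxa listed in the
#'   `shift_taxa` argument of [simulate_locus()] (gap extended into the left
#'   flank by this many nt).
#' @param substitution_rate Per-site substitution probability applied
#'   independently per taxon.
#' @param seed Optional integer seed.
#' @return An object of class `locus_sim_config`.
#' @export
locus_sim_config <- function(flank_length = 150L, te_length = 300L,
                             tsd_length = 12L, shift_nt = 0L,
                             substitution_rate = 0.02, seed = NULL) {
  stopifnot(flank_length > 0, te_length > 0, tsd_length >= 0, shift_nt >= 0,
            substitution_rate >= 0, substitution_rate < 1)
  structure(list(flank_length = as.integer(flank_length),
                 te_length = as.integer(te_length),
                 tsd_length = as.integer(tsd_length),
                 shift_nt = as.integer(shift_nt),
                 substitution_rate = substitution_rate, seed = seed),
            class = "locus_sim_config")
}

random_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

#' Simulate a per-locus alignment with a planted TE insertion
#'
#' Generates a shared flank sequence, plants the TE with a duplicated
#' target-site (TSD) for presence-planned taxa, gaps the TE plus the second
#' TSD copy for absence-planned taxa (the single remaining target site stays
#' aligned to the left TSD columns), applies an optional boundary shift (gap
#' extended `shift_nt` into the left flank) to designated taxa, and mutates
#' each taxon's sequence independently at `substitution_rate`. The planted TSD
#' avoids homopolymers so its length is recovered exactly by [detect_tsd()]
#' with `max_mismatch = 0` on noise-free data.
#'
#' @param config A [locus_sim_config()].
#' @param plan Named character vector over taxa with values `"1"`/`"present"`
#'   or `"0"`/`"absent"`.
#' @param outgroup_taxa Taxa to mark as outgroup in the returned alignment.
#' @param shift_taxa Absent taxa receiving the planted boundary shift.
#' @return A list with `locus` (a [locus_alignment()]) and `truth` (the plan,
#'   TSD length and per-taxon planted shifts).
#' @examples
#' sim <- simulate_locus(locus_sim_config(seed = 7),
#'                       plan = c(Primates = "1", Dermoptera = "1",
#'                                Scandentia = "0", Glires = "0",
#'                                Laurasiatheria = "0"),
#'                       outgroup_taxa = "Laurasiatheria")
#' call_states(sim$locus)$states
#' @export
simulate_locus <- function(config, plan, outgroup_taxa = character(0),
                           shift_taxa = character(0)) {
  stopifnot(inherits(config, "locus_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  taxa <- names(plan)
  if (is.null(taxa)) stop("plan must be a named vector covering all taxa")
  present <- plan %in% c("1", "present")
  names(present) <- taxa
  fl <- config$flank_length; tl <- config$te_length; td <- config$tsd_length
  left <- random_bases(fl)
  right <- random_bases(fl)
  tsd <- random_bases(td)
  while (td > 1L && length(unique(tsd)) == 1L) tsd <- random_bases(td)
  te <- random_bases(tl)
  te_start <- fl + td                 # 0-based half-open TE span
  te_end <- te_start + tl
  ncol_ <- fl + td + tl + td + fl
  mutate <- function(v) {
    if (config$substitution_rate == 0) return(v)
    hit <- which(v %in% c("A", "C", "G", "T") &
                   stats::runif(length(v)) < config$substitution_rate)
    for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
    v
  }
  shifts <- stats::setNames(rep(0L, length(taxa)), taxa)
  rows <- lapply(taxa, function(tx) {
    if (present[[tx]]) {
      row <- c(left, tsd, te, tsd, right)
    } else {
      row <- c(left, tsd, rep("-", tl + td), right)
      if (tx %in% shift_taxa && config$shift_nt > 0L) {
        ## delete the last shift_nt nt of the left flank region (incl. TSD tail)
        cut <- (fl + td - config$shift_nt + 1L):(fl + td)
        row[cut] <- "-"
        shifts[[tx]] <<- config$shift_nt
      }
    }
    paste(mutate(row), collapse = "")
  })
  names(rows) <- taxa
  locus <- locus_alignment(unlist(rows),
                           te_annotation("simTE#LTR/ERV", "+", te_start, te_end),
                           outgroup_taxa = outgroup_taxa)
  list(locus = locus,
       truth = list(states = stats::setNames(ifelse(present, "1", "0"), taxa),
                    tsd_length = td, shifts = shifts))
}
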