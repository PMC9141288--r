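# hand-built locus: 30 nt left flank | 6 nt TSD | 12 nt TE | 6 nt TSD | 30 nt
# right flank; absent taxa gap the TE plus the right TSD copy
build_locus <- function(shift = 0, outgroup_state = "absent",
                        strands = NULL, families = NULL) {
  set.seed(501)
  left <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  tsd <- "ACGTGA"
  te <- "TTTTCCCCGGGG"
  gap <- strrep("-", nchar(te) + nchar(tsd))
  present <- paste0(left, tsd, te, tsd, right)
  absent <- paste0(left, tsd, gap, right)
  if (shift > 0) {
    pre <- nchar(left) + nchar(tsd)
    absent <- paste0(substr(absent, 1, pre - shift), strrep("-", shift),
                     substr(absent, pre + 1, nchar(absent)))
  }
  seqs <- c(Primates = present, Dermoptera = present,
            Scandentia = absent, Glires = absent,
            Laurasiatheria = if (outgroup_state == "present") present else absent)
  locus_alignment(seqs,
                  te_annotation("MER57F#LTR/ERV1", "+", 36, 48),
                  outgroup_taxa = "Laurasiatheria",
                  taxon_strands = strands, taxon_families = families)
}

test_that("state calling separates present, absent and shifted rows", {
  loc <- build_locus()
  call <- call_states(loc)
  expect_equal(unname(call$states),
               c("1", "1", "0", "0", "0"))
  expect_equal(unname(call$shift_nt), rep(0, 5))

  # absence gap shifted 5 nt into the flank violates the <=3 nt criterion
  loc5 <- build_locus(shift = 5)
  call5 <- call_states(loc5)
  expect_equal(unname(call5$states[c("Scandentia", "Glires")]), c("?", "?"))
  expect_equal(unname(call5$shift_nt[["Scandentia"]]), 5)

  # shifts within tolerance remain absent, with the shift recorded
  loc2 <- build_locus(shift = 2)
  call2 <- call_states(loc2)
  expect_equal(unname(call2$states[["Scandentia"]]), "0")
  expect_equal(unname(call2$shift_nt[["Scandentia"]]), 2)

  # a taxon row of the wrong length is rejected up front
  seqs <- loc$sequences
  seqs[["Primates"]] <- substr(seqs[["Primates"]], 1, 10)
  expect_error(locus_alignment(seqs, loc$te), "lengths differ")
})

test_that("unknown calls cover N-runs and missing flanks", {
  loc <- build_locus()
  seqs <- loc$sequences
  # TE span replaced by Ns: neither covered nor cleanly deleted
  s <- strsplit(seqs[["Primates"]], "")[[1]]
  s[37:48] <- "N"
  seqs[["Primates"]] <- paste(s, collapse = "")
  # flank deleted on an absent taxon: gap run reaches the alignment edge
  s2 <- strsplit(seqs[["Scandentia"]], "")[[1]]
  s2[1:36] <- "-"
  seqs[["Scandentia"]] <- paste(s2, collapse = "")
  call <- call_states(locus_alignment(seqs, loc$te,
                                      outgroup_taxa = "Laurasiatheria"))
  expect_equal(unname(call$states[["Primates"]]), "?")
  expect_equal(unname(call$states[["Scandentia"]]), "?")
})

test_that("validation enforces the four diagnostic criteria", {
  loc <- build_locus()
  call <- validate_marker(call_states(loc), loc)
  expect_true(all(call$criteria))
  expect_true(call$accepted)

  # criterion 4: outgroup presence rejects the locus
  loc_og <- build_locus(outgroup_state = "present")
  call_og <- validate_marker(call_states(loc_og), loc_og)
  expect_false(call_og$criteria[["outgroup"]])
  expect_false(call_og$accepted)

  # criterion 3: opposite strands among present taxa
  loc_str <- build_locus(strands = c(Dermoptera = "-"))
  call_str <- validate_marker(call_states(loc_str), loc_str)
  expect_false(call_str$criteria[["orientation"]])
  expect_false(call_str$accepted)

  # criterion 2: a different element at the orthologous position
  loc_fam <- build_locus(families = c(Dermoptera = "L1MB5#LINE/L1"))
  call_fam <- validate_marker(call_states(loc_fam), loc_fam)
  expect_false(call_fam$criteria[["family"]])

  # no outgroup row: criterion 4 unknown, rejected with a reason
  seqs <- loc$sequences[setdiff(names(loc$sequences), "Laurasiatheria")]
  loc_no <- locus_alignment(seqs, loc$te, outgroup_taxa = "Laurasiatheria")
  call_no <- validate_marker(call_states(loc_no), loc_no)
  expect_true(is.na(call_no$criteria[["outgroup"]]))
  expect_false(call_no$accepted)
  expect_match(call_no$reason, "outgroup")
})

test_that("accepted markers always satisfy the pre-filter", {
  taxa <- c("Primates", "Dermoptera", "Scandentia", "Glires")
  for (i in 1:20) {
    set.seed(700 + i)
    plan <- c(setNames(sample(c("1", "0"), 4, TRUE), taxa),
              Laurasiatheria = "0")
    sim <- simulate_locus(locus_sim_config(substitution_rate = 0), plan,
                          outgroup_taxa = "Laurasiatheria")
    call <- validate_marker(call_states(sim$locus), sim$locus)
    ing <- call$states[taxa]
    if (call$accepted)
      expect_true(sum(ing == "1") >= 2 && sum(ing == "0") >= 1)
    else if (all(call$criteria, na.rm = TRUE) && !anyNA(call$criteria))
      expect_false(sum(ing == "1") >= 2 && sum(ing == "0") >= 1)
  }
})

test_that("TSD detection matches an exhaustive oracle", {
  plan <- c(Primates = "1", Dermoptera = "1", Scandentia = "0",
            Laurasiatheria = "0")
  for (i in 1:15) {
    td <- sample(4:20, 1)
    sim <- simulate_locus(locus_sim_config(seed = 800 + i, tsd_length = td,
                                           substitution_rate = 0.02),
                          plan, outgroup_taxa = "Laurasiatheria")
    got <- detect_tsd(sim$locus, "Primates")
    want <- oracle_tsd(sim$locus, "Primates")
    expect_equal(got$length, want, info = i)
  }
  # one mismatch is tolerated when allowed, not otherwise
  loc <- build_locus()
  s <- strsplit(loc$sequences[["Primates"]], "")[[1]]
  s[33] <- setdiff(c("A", "C", "G", "T"), s[33])[1]   # mutate left TSD copy
  loc$sequences[["Primates"]] <- paste(s, collapse = "")
  expect_equal(detect_tsd(loc, "Primates", max_mismatch = 1)$length, 6)
  got0 <- detect_tsd(loc, "Primates", max_mismatch = 0)
  expect_true(is.null(got0) || got0$length < 6)
})

test_that("LINE1 truncation filter is boundary inclusive", {
  mk <- function(tr) te_annotation("L1MB5#LINE/L1", "+", 0, 100,
                                   truncation_3prime = tr)
  expect_true(line1_filter(mk(0)))
  expect_true(line1_filter(mk(25)))
  expect_false(line1_filter(mk(26)))
})

test_that("annotation readers normalize coordinates and strand", {
  bed <- withr::local_tempfile(lines = c(
    "chr1\t100\t400\tL1MB5#LINE/L1\t0\t+",
    "chr2\t10\t50\tMER57F#LTR/ERV1\t0\t-"))
  tes <- read_te_annotations(bed, "bed")
  expect_equal(tes[[1]]$start, 100L)
  expect_equal(tes[[1]]$end, 400L)
  expect_equal(tes[[2]]$strand, "-")

  rm_out <- withr::local_tempfile(lines = c(
    "   SW  perc perc perc  query      position in query     matching repeat",
    "score  div. del. ins.  sequence   begin end (left)      repeat class/family begin end (left) ID",
    "",
    "  463  12.5  0.0  0.0  chr1       101  400 (5000)   +   L1MB5    LINE/L1     1  300  (12)  1",
    "  512  10.1  0.0  0.0  chr1       900 1100 (4300)   C   MER57F   LTR/ERV1  (0)  201    1   2"))
  rms <- read_te_annotations(rm_out, "repeatmasker_out")
  expect_equal(rms[[1]]$start, 100L)            # 1-based begin 101 -> 0-based 100
  expect_equal(rms[[1]]$end, 400L)
  expect_equal(rms[[1]]$family, "L1MB5#LINE/L1")
  expect_equal(rms[[1]]$truncation_3prime, 12L) # (left) on + strand
  expect_equal(rms[[2]]$strand, "-")            # orientation C
  expect_equal(rms[[2]]$truncation_3prime, 0L)  # (left) swaps to begin on C

  bad <- withr::local_tempfile(lines = "chr1\t100")
  expect_error(read_te_annotations(bad, "bed"), "line 1")
})

test_that("locus FASTA and report round-trips work", {
  loc <- build_locus()
  f <- withr::local_tempfile(fileext = ".fa")
  write_locus_alignment(loc, f)
  loc2 <- read_locus_alignment(f, loc$te, outgroup_taxa = "Laurasiatheria")
  expect_equal(loc2$sequences, loc$sequences)
  call <- validate_marker(call_states(loc2), loc2)
  rep_f <- withr::local_tempfile(fileext = ".tsv")
  df <- write_diagnostic_report(list(locus1 = call), rep_f)
  expect_equal(nrow(df), 5L)
  expect_true(all(df$accepted))
  expect_equal(unique(df$tsd_length), 6L)
})
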