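test_that("classification follows the informativeness pre-filter", {
  panel <- lineage_panel()
  expect_equal(
    classify_marker(c(Primates = "0", Dermoptera = "1", Scandentia = "1",
                      Glires = "0")),
    "Dermoptera+Scandentia")
  expect_equal(
    classify_marker(c(Primates = "1", Dermoptera = "1", Scandentia = "1",
                      Glires = "1")),
    "uninformative")
  expect_equal(
    classify_marker(c(Primates = "1", Dermoptera = "0", Scandentia = "0",
                      Glires = "0")),
    "uninformative")
  # unknown states block the 10-pattern tabulation but keep partial markers
  expect_equal(
    classify_marker(c(Primates = "1", Dermoptera = "1", Scandentia = "0",
                      Glires = "?")),
    "partial")
  expect_error(classify_marker(c(Primates = "1", Dermoptera = "1")), "missing")
})

test_that("classification agrees with a brute-force oracle on all 3^4 state vectors", {
  for (i in seq_len(nrow(ALL_STATE_VECTORS))) {
    s <- unlist(ALL_STATE_VECTORS[i, ])
    expect_equal(classify_marker(s), oracle_classify(s), info = paste(s, collapse = ""))
  }
})

test_that("tabulation conserves markers and reproduces hand counts", {
  m <- euarchontoglires_markers()
  tab <- tabulate_patterns(m)
  expect_equal(sum(tab), 361L)
  expect_equal(tab[["Primates+Dermoptera"]], 132L)
  expect_equal(tab[["Primates+Dermoptera+Scandentia"]], 94L)
  expect_equal(sum(tab) + attr(tab, "n_partial") + attr(tab, "n_uninformative"),
               nrow(m$states))

  ds <- c(Primates = "0", Dermoptera = "1", Scandentia = "1", Glires = "0",
          Laurasiatheria = "0")
  m3 <- marker_matrix(matrix(rep(ds, 3), nrow = 3, byrow = TRUE,
                             dimnames = list(NULL, names(ds))))
  t3 <- tabulate_patterns(m3)
  expect_equal(t3[["Dermoptera+Scandentia"]], 3L)
  expect_equal(sum(t3), 3L)

  empty <- marker_matrix(matrix(character(0), nrow = 0, ncol = 5,
                                dimnames = list(NULL, names(ds))))
  expect_equal(sum(tabulate_patterns(empty)), 0L)
})

test_that("conflicting totals sum counts outside the supported patterns", {
  cc <- euarchontoglires_counts()
  expect_equal(conflicting_total(cc, c("Primates+Dermoptera",
                                       "Primates+Dermoptera+Scandentia")), 135L)
  expect_equal(sum(cc) - cc[["Primates+Dermoptera"]] -
                 cc[["Primates+Dermoptera+Scandentia"]],
               conflicting_total(cc, c("Primates+Dermoptera",
                                       "Primates+Dermoptera+Scandentia")))
  zero <- pattern_counts(rep(0L, 10))
  expect_equal(conflicting_total(zero, "Primates+Dermoptera"), 0L)
  small <- pattern_counts(c(2L, 1L, rep(0L, 8)))  # PD = 2, PS = 1
  expect_equal(conflicting_total(small, "Primates+Dermoptera"), 1L)
  expect_error(conflicting_total(cc, "NotAPattern"), "unknown pattern")
})

test_that("y-vector order maps counts onto the anchored patterns", {
  y <- c(16, 12, 9, 9, 16, 5, 13, 55, 132, 94)
  cc <- counts_from_y(y)
  expect_equal(cc[["Primates+Dermoptera"]], 132L)          # y34
  expect_equal(cc[["Primates+Dermoptera+Scandentia"]], 94L) # y44
  expect_equal(cc[["Dermoptera+Scandentia"]], 9L)           # y14
  expect_equal(counts_to_y(cc), as.integer(y))
  expect_equal(as.integer(parse_count_string("16,12,9,9,16,5,13,55,132,94")),
               as.integer(cc))
  expect_error(parse_count_string("1,2,3"), "10")
})

test_that("annotation concordance counts known and matching states", {
  m <- euarchontoglires_markers()
  expect_equal(annotation_concordance(m),
               c(n_known = 299L, n_concordant = 289L))

  sts <- matrix(c("1", "1", "0", "0", "?",
                  "1", "1", "0", "0", "?",
                  "1", "0", "1", "0", "1",
                  "1", "0", "1", "0", "0",
                  "0", "1", "1", "0", "1"),
                nrow = 5, byrow = TRUE,
                dimnames = list(NULL, c("Primates", "Dermoptera", "Scandentia",
                                        "Glires", "Lagomorpha")))
  m2 <- marker_matrix(sts)
  # 2 unknown, rows 3-5 known: states 1,0,1 vs Glires 0,0,0 -> 1 concordant
  expect_equal(annotation_concordance(m2),
               c(n_known = 3L, n_concordant = 1L))

  all_unknown <- marker_matrix(matrix(c("1", "1", "0", "0", "?"), nrow = 1,
                                      dimnames = list(NULL, colnames(sts))))
  expect_equal(annotation_concordance(all_unknown),
               c(n_known = 0L, n_concordant = 0L))
})

test_that("NEXUS and PHYLIP round-trips are lossless", {
  for (seed in 1:5) {
    m <- random_marker_matrix(40, seed)
    for (fmt in c("nexus", "phylip")) {
      f <- withr::local_tempfile()
      write_marker_matrix(m, f, fmt)
      m2 <- read_marker_matrix(f)
      expect_identical(m$states, m2$states, info = paste(fmt, seed))
      if (fmt == "nexus") expect_identical(m$ids, m2$ids)
      # write(read(f)) is byte-identical to the first write
      f2 <- withr::local_tempfile()
      write_marker_matrix(m2, f2, fmt)
      expect_identical(readLines(f), readLines(f2))
    }
  }
})

test_that("matrix readers validate their dialects", {
  f <- withr::local_tempfile(lines = c("2 1", "A 1", "B 0"))
  m <- read_marker_matrix(f, "phylip")
  expect_equal(unname(m$states[1, c("A", "B")]), c("1", "0"))

  f2 <- withr::local_tempfile(lines = c("#NEXUS", "BEGIN DATA;",
    "DIMENSIONS NTAX=3 NCHAR=1;",
    "FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
    "MATRIX", "A 1", "B 1", "C ?", ";", "END;"))
  m2 <- read_marker_matrix(f2, "nexus")
  expect_equal(unname(m2$states[1, "C"]), "?")

  bad <- withr::local_tempfile(lines = c("2 1", "A 2", "B 0"))
  expect_error(read_marker_matrix(bad, "phylip"), "illegal symbol")
  dup <- withr::local_tempfile(lines = c("2 1", "A 1", "A 0"))
  expect_error(read_marker_matrix(dup, "phylip"), "duplicate")
  hdr <- withr::local_tempfile(lines = c("not a header", "A 1"))
  expect_error(read_marker_matrix(hdr, "phylip"), "header")
  empty <- marker_matrix(matrix(character(0), 0, 5,
    dimnames = list(NULL, c("Primates", "Dermoptera", "Scandentia", "Glires",
                            "Laurasiatheria"))))
  expect_error(write_marker_matrix(empty, withr::local_tempfile(), "phylip"),
               "empty")
})

test_that("pattern-count CSV export carries labels and y positions", {
  f <- withr::local_tempfile()
  write_pattern_counts(euarchontoglires_counts(), f)
  df <- read.csv(f)
  expect_equal(df$count[df$y_label == "y34"], 132)
  expect_equal(sum(df$count), 361)
})
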