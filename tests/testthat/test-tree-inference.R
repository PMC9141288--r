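test_that("markers convert to incompletely resolved gene trees", {
  expect_equal(
    marker_to_genetree(c(Primates = "1", Dermoptera = "1", Scandentia = "0",
                         Glires = "0", Laurasiatheria = "0")),
    "((Primates,Dermoptera),Scandentia,Glires,Laurasiatheria);")
  # unknown-state taxa are omitted
  expect_equal(
    marker_to_genetree(c(Primates = "0", Dermoptera = "1", Scandentia = "1",
                         Glires = "0", Laurasiatheria = "?")),
    "((Dermoptera,Scandentia),Primates,Glires);")
  expect_equal(
    marker_to_genetree(c(Primates = "1", Dermoptera = "1", Scandentia = "1",
                         Glires = "0", Laurasiatheria = "0")),
    "((Primates,Dermoptera,Scandentia),Glires,Laurasiatheria);")
  # fewer than two present taxa: skipped
  expect_true(is.na(marker_to_genetree(c(A = "1", B = "0", C = "0"))))
  m <- euarchontoglires_markers()
  gt <- genetree_set(m)
  expect_length(gt, 361L)
  expect_equal(attr(gt, "n_skipped"), 0L)
})

test_that("a single gene tree fixes its clade in the species tree", {
  st <- quartet_species_tree(c("((A,B),C,D);"))
  # without an outgroup the tree is unrooted: the AB|CD split may be labelled
  # by either side
  expect_true(any(c("A+B", "C+D") %in% st$clades))
  expect_gt(st$quartet_score, 0)
})

test_that("perfectly conflicting gene trees tie and the tie is reported", {
  trees <- c("((A,B),C,D);", "((A,C),B,D);", "((A,D),B,C);")
  expect_message(st <- quartet_species_tree(trees), "tie")
  expect_length(st$ties, 3L)
})

test_that("the winner's quartet score dominates every enumerated alternative", {
  m <- simulate_markers(sim_config(tau1 = 0.6, tau2 = 0.6, n_markers = 150,
                                   seed = 31, missing_rate = 0.1))
  st <- quartet_species_tree(m)
  expect_true(all(st$quartet_score >= st$scores))
})

test_that("plurality pattern support decides the quartet winner", {
  # one pattern strictly dominating -> its clade in the species tree
  for (seed in 1:5) {
    set.seed(seed)
    y <- sample(0:5, 10, replace = TRUE)
    winner <- sample(1:6, 1)              # a pair pattern
    y[winner] <- 50
    cc <- pattern_counts(y)
    m <- matrix_from_counts(cc)
    st <- quartet_species_tree(m)
    expect_true(names(cc)[winner] %in% st$clades, info = seed)
  }
})

test_that("the survey fixture yields the Euarchonta topology with full support", {
  m <- euarchontoglires_markers()
  st <- quartet_species_tree(m)
  expect_true(all(c("Primates+Dermoptera", "Primates+Dermoptera+Scandentia")
                  %in% st$clades))
  expect_false("Primates+Scandentia" %in% st$clades)
  # rooting on the declared outgroup
  expect_match(st$topology, "Laurasiatheria\\);$")

  bs <- bootstrap_support(m, replicates = 200, seed = 17)
  expect_equal(unname(bs[["Primates+Dermoptera"]]), 100)
  expect_equal(unname(bs[["Primates+Dermoptera+Scandentia"]]), 100)
  # bit-reproducible given the seed
  expect_identical(bs, bootstrap_support(m, replicates = 200, seed = 17))
})

test_that("bootstrap support reflects marker conflict", {
  one <- marker_matrix(matrix(c("1", "1", "0", "0", "0"), 1,
                              dimnames = list(NULL, c("Primates", "Dermoptera",
                                                      "Scandentia", "Glires",
                                                      "Laurasiatheria"))))
  bs1 <- bootstrap_support(one, replicates = 50, seed = 3)
  expect_equal(unname(bs1[["Primates+Dermoptera"]]), 100)

  # 20 vs 20 conflicting markers: clade support near 50% (the tie replicates,
  # ~12% mass, fall to the lexicographic winner)
  conf <- pattern_counts(c(20L, 20L, rep(0L, 8)))
  m <- matrix_from_counts(conf)
  bs <- bootstrap_support(m, replicates = 400, seed = 5)
  expect_gt(bs[["Primates+Dermoptera"]], 30)
  expect_lt(bs[["Primates+Dermoptera"]], 70)
})

test_that("branch lengths in coalescent units land on the internal branches", {
  m <- euarchontoglires_markers(include_annotation = FALSE)
  st <- quartet_species_tree(m)
  cc <- euarchontoglires_counts()
  st <- annotate_branch_lengths(st, cc)
  bl <- st$branch_lengths
  expect_equal(unname(bl[["Primates+Dermoptera"]]),
               estimate_internal_branch(c(132, 13, 9)))
  expect_equal(unname(bl[["Primates+Dermoptera+Scandentia"]]),
               estimate_internal_branch(c(94, 55, 12)))
  expect_true(all(bl > 0 & bl < 10))

  # conflict-free counts: capped maximum; star counts: zero length
  clean <- pattern_counts(c(100L, 0L, 0L, 0L, 0L, 0L, 80L, 0L, 0L, 0L))
  st_clean <- annotate_branch_lengths(quartet_species_tree(matrix_from_counts(clean)),
                                      clean)
  expect_true(all(st_clean$branch_lengths == 10))
  star <- pattern_counts(rep(10L, 10))
  st_star <- suppressMessages(quartet_species_tree(matrix_from_counts(star)))
  st_star <- annotate_branch_lengths(st_star, star)
  expect_true(all(st_star$branch_lengths == 0))
})

test_that("gene trees written to Newick parse back", {
  m <- euarchontoglires_markers()
  gt <- genetree_set(m)
  f <- withr::local_tempfile()
  write_genetrees(gt, f)
  trees <- ape::read.tree(f)
  expect_length(trees, 361L)
  expect_setequal(trees[[1]]$tip.label,
                  c(lineage_panel()$ingroup, "Lagomorpha", "Laurasiatheria"))
})
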