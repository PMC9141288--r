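Package: retroils
Title: Retroposon Presence/Absence Phylogenetics under Incomplete Lineage Sorting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for retrophylogenomic analysis of transposed-element (TE)
    presence/absence markers across four lineages, developed around the
    Euarchontoglires radiation (Primates, Dermoptera, Scandentia, Glires).
    Classifies markers into the ten diagnostic clade patterns, tests pattern
    counts for tree-versus-polytomy and hybridization under incomplete lineage
    sorting with exact binomial and likelihood-ratio statistics, estimates
    internal branch lengths in coalescent units, builds exhaustive quartet-based
    species trees with marker bootstrap, validates candidate TE loci on per-locus
    alignments (insertion-boundary shifts, target-site duplications, outgroup
    states), and simulates markers and loci under the multispecies coalescent.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
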