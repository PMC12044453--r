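test_that("exactly eleven rules exist with the expected names", {
  rules <- recap_rules()
  expect_equal(nrow(rules), 11L)
  expect_setequal(rules$name,
                  c("amine", "amide", "ester", "urea", "olefin", "ether",
                    "aromatic_N_aliphatic_C", "lactam_N_aliphatic_C",
                    "aromatic_C_aromatic_C", "quaternary_N",
                    "sulfonamide"))
})

test_that("cleavable-bond detection matches hand application", {
  expect_equal(nrow(find_cleavable_bonds("c1ccccc1")), 0L)
  b <- find_cleavable_bonds("CC(=O)Nc1ccccc1")
  expect_equal(nrow(b), 1L)
  expect_equal(b$rule, "amide")
  b2 <- find_cleavable_bonds("c1ccc(-c2ccccc2)cc1")
  expect_equal(b2$rule, "aromatic_C_aromatic_C")
  # no rule ever reports a ring bond: a cyclic ester/amide is untouched
  expect_equal(nrow(find_cleavable_bonds("O=C1CCCCO1")), 0L)
})

test_that("leaf decomposition matches hand application of each rule", {
  for (nm in names(recap_rule_fixtures())) {
    fx <- recap_rule_fixtures()[[nm]]
    bonds <- find_cleavable_bonds(fx$smiles)
    expect_setequal(unique(bonds$rule), fx$rules)
    leaves <- recap_decompose(fx$smiles)[[1]]
    expect_equal(sort(leaves), sort(fx$leaves), label = nm)
  }
})

test_that("undecomposable molecules yield no fragments", {
  out <- recap_decompose(c("c1ccccc1", "C1CCOCC1", "CC(=O)O"))
  expect_equal(lengths(out), c(0L, 0L, 0L))
})

test_that("decomposition is invariant to bond-breaking order", {
  toys <- c("CN(C)C(=O)Nc1ccccc1", "c1ccccc1COCc1ccccc1",
            "C1CCOCC1OC1CCOC1C(=O)NCC=Cc1ccccc1",
            "C[N+](C)(C)Cc1ccc(-c2ccccc2)cc1")
  ref <- recap_decompose(toys, unique_leaves = FALSE)
  for (s in c(1L, 7L, 23L)) {
    perm <- recap_decompose(toys, unique_leaves = FALSE, order_seed = s)
    for (i in seq_along(toys)) {
      expect_equal(sort(perm[[i]]), sort(ref[[i]]))
    }
  }
})

test_that("leaves conserve heavy atoms and pass the element whitelist", {
  lib <- generate_library(generator_params(40L, "np_like", seed = 21L,
                                           min_blocks = 2L))
  std <- standardize_library(lib)$records
  leaves <- recap_decompose(std$canonical_smiles, unique_leaves = FALSE)
  heavy <- function(s) descriptor_profile(s)$n_heavy
  parents_heavy <- heavy(std$canonical_smiles)
  for (i in seq_along(leaves)) {
    if (length(leaves[[i]]) == 0L) next
    expect_equal(sum(heavy(leaves[[i]])), parents_heavy[i])
  }
  all_leaves <- unique(unlist(leaves))
  expect_true(all(check_elements(all_leaves)))
  # every multi-block generated molecule yields at least 2 leaves
  expect_true(all(lengths(leaves) >= 2L))
})

test_that("fragment_library aggregates occurrences and applies the MW cutoff", {
  fl <- fragment_library(c("c1ccc(-c2ccccc2)cc1", "CC(=O)Nc1ccccc1"))
  expect_s3_class(fl, "fragment_library")
  expect_setequal(fl$canonical_smiles, c("c1ccccc1", "CC=O", "Nc1ccccc1"))
  expect_equal(fl$occurrence[fl$canonical_smiles == "c1ccccc1"], 1L)
  expect_true(all(fl$occurrence == fl$n_parents))

  # a parent at the cutoff is skipped and counted
  big <- paste(rep("C1CCC2CCCCC2C1", 8), collapse = "C(=O)O")  # MW >> 1000
  fl2 <- fragment_library(c(big, "c1ccc(-c2ccccc2)cc1"),
                          mw_cutoff = 1000)
  expect_equal(attr(fl2, "n_skipped_mw"), 1L)
  expect_equal(fl2$canonical_smiles, "c1ccccc1")

  # shared fragments accumulate occurrence across parents
  fl3 <- fragment_library(c("c1ccc(-c2ccccc2)cc1",
                            "c1ccccc1Cc1ccccc1OCc1ccccc1"))
  expect_gte(fl3$occurrence[fl3$canonical_smiles == "c1ccccc1"], 1L)
  expect_true(all(grepl("\\S", fl3$rules_applied)))
})

test_that("site multiplicity counting is available as a switch", {
  # biphenyl yields benzene twice with site counting, once without
  fl1 <- fragment_library("c1ccc(-c2ccccc2)cc1")
  fl2 <- fragment_library("c1ccc(-c2ccccc2)cc1", count_sites = TRUE)
  expect_equal(fl1$occurrence, 1L)
  expect_equal(fl2$occurrence, 2L)
})
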