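test_that("overlap handles identical, disjoint and partial cases", {
  a <- c("CCO", "c1ccccc1", "C1CCOCC1")
  same <- overlap(a, a)
  expect_equal(same$n_shared, 3L)
  expect_equal(same$unique_a, 0L)
  expect_equal(same$pct_shared_a, 100)

  disj <- overlap(a, c("CCN", "CCS"))
  expect_equal(disj$n_shared, 0L)
  expect_equal(disj$unique_b, 2L)

  part <- overlap(a, c("CCO", "CCN"))
  expect_equal(part$n_shared, 1L)
  expect_equal(part$unique_a, 2L)
  expect_equal(part$pct_shared_b, 50)
  # symmetry of the intersection size
  expect_equal(part$n_shared, overlap(c("CCO", "CCN"), a)$n_shared)
})

test_that("union size identity holds on generated library pairs", {
  std <- bench_std()
  for (pair in list(c("np_gen", "sy_gen"), c("np_gen", "vd_gen"))) {
    ov <- overlap(std[[pair[1]]], std[[pair[2]]])
    un <- length(union(std[[pair[1]]]$canonical_smiles,
                       std[[pair[2]]]$canonical_smiles))
    expect_equal(un, ov$n_a + ov$n_b - ov$n_shared)
  }
})

test_that("stereo-insensitive matching merges enantiomer spellings", {
  a <- "C[C@H](N)C(=O)O"
  b <- "C[C@@H](N)C(=O)O"
  expect_equal(overlap(a, b)$n_shared, 0L)
  expect_equal(overlap(a, b, stereo = FALSE)$n_shared, 1L)
})

test_that("frequency tables rank by percentage under both denominators", {
  fl <- structure(data.frame(
    canonical_smiles = c("c1ccccc1", "Oc1ccccc1"),
    occurrence = c(3L, 1L), stringsAsFactors = FALSE),
    class = c("fragment_library", "data.frame"))
  ft <- frequency_table(fl, denominator = "occurrences")
  expect_equal(ft$percentage, c(75, 25))
  ftu <- frequency_table(fl, denominator = "unique_fragments")
  expect_equal(ftu$percentage, c(150, 50))

  single <- frequency_table(fl[1, , drop = FALSE],
                            denominator = "occurrences")
  expect_equal(single$percentage, 100)
})

test_that("mw windows restrict entries and keep the library denominator", {
  fl <- structure(data.frame(
    canonical_smiles = c("c1ccccc1", "C", "O=Cc1ccc(O)cc1"),
    occurrence = c(2L, 5L, 3L), stringsAsFactors = FALSE),
    class = c("fragment_library", "data.frame"))
  ft <- frequency_table(fl, mw_window = c(70, 300),
                        denominator = "occurrences")
  # methane (MW 16) is outside the window
  expect_false("C" %in% ft$canonical_smiles)
  # percentages stay relative to all 10 occurrences, so they sum <= 100
  expect_equal(ft$percentage, c(20, 30)[order(-c(20, 30))])
  expect_lte(sum(ft$percentage), 100)
})

test_that("common-fragment tables pair the two libraries' percentages", {
  fa <- structure(data.frame(canonical_smiles = c("c1ccccc1", "CCO"),
                             occurrence = c(3L, 1L),
                             stringsAsFactors = FALSE),
                  class = c("fragment_library", "data.frame"))
  fb <- structure(data.frame(canonical_smiles = c("c1ccccc1", "CCN"),
                             occurrence = c(1L, 1L),
                             stringsAsFactors = FALSE),
                  class = c("fragment_library", "data.frame"))
  ct <- common_frequency_table(fa, fb)
  expect_equal(ct$canonical_smiles, "c1ccccc1")
  expect_equal(ct$percentage_a, 75)
  expect_equal(ct$percentage_b, 50)

  expect_equal(nrow(common_frequency_table(fa, structure(
    data.frame(canonical_smiles = "CO", occurrence = 1L,
               stringsAsFactors = FALSE),
    class = c("fragment_library", "data.frame")))), 0L)
})

test_that("a planted high-multiplicity fragment ranks first", {
  lib <- generate_library(generator_params(
    40L, "np_like", seed = 17L, min_blocks = 2L,
    planted_duplicates = rep("c1ccccc1-c1ccccc1", 10L)))
  fl <- fragment_library(standardize_library(lib)$records)
  # the ten planted biphenyls collapse to one parent after dedup, so rank
  # benzene via occurrences across all parents instead: it must be
  # present and carried by at least the planted parent
  expect_true("c1ccccc1" %in% fl$canonical_smiles)

  # plant at distinct parents to exercise multiplicity ranking
  lib2 <- generate_library(generator_params(
    30L, "synthetic_like", seed = 18L, min_blocks = 2L))
  extra <- sprintf("c1ccc(-c2ccccc2)cc1%s", c("", "C", "CC", "CCC"))
  fl2 <- fragment_library(c(standardize_library(lib2)$records$canonical_smiles,
                            standardize_molecule(extra)$canonical_smiles))
  # mini fragments (water, methane, ammonia) dominate raw occurrence
  # counts; the 70-300 Da window is what makes ring fragments visible
  ft <- frequency_table(fl2, top_k = 1, mw_window = c(70, 300),
                        denominator = "occurrences")
  expect_equal(ft$canonical_smiles, "c1ccccc1")
})

test_that("scaffold census matches known cases", {
  sc <- scaffold_summary(c("c1ccccc1", "CCO", "C1CC2CCC1C2",
                           "c1ccc(CCCC2CCCCC2)cc1"))
  expect_equal(sc$n_acyclic, 1L)
  expect_equal(sc$n_distinct, 3L)
  benz <- sc$frequency[sc$frequency$scaffold == "c1ccccc1", ]
  expect_false(benz$heterocyclic)
  expect_false(benz$fused)
  # norbornane is fused (bridged) but not ortho-fused
  nb <- sc$frequency[sc$frequency$scaffold == "C1CC2CCC1C2", ]
  expect_true(nb$fused)
  expect_false(nb$ortho_fused)
  # the linker-connected two-ring scaffold keeps its linker
  expect_true(any(grepl("CCC", sc$frequency$scaffold)))
})

test_that("scaffold extraction is idempotent and side chains drop", {
  sc1 <- scaffold_summary("CCc1ccccc1O")   # side chains removed
  expect_equal(sc1$frequency$scaffold, "c1ccccc1")
  again <- scaffold_summary(sc1$frequency$scaffold)
  expect_equal(again$frequency$scaffold, sc1$frequency$scaffold)

  # nitrogen classification counts ring or linker N within the scaffold
  sc2 <- scaffold_summary("c1ccncc1CC")
  expect_equal(sc2$n_nitrogen_containing, 1L)
  expect_equal(sc2$n_nonheterocyclic, 0L)
  # census partition: heterocyclic + non-heterocyclic = distinct
  std <- bench_std()$sy_gen
  sc3 <- scaffold_summary(std)
  expect_equal(sc3$n_nonheterocyclic +
                 sum(sc3$frequency$heterocyclic), sc3$n_distinct)
})
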