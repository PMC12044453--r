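test_that("generation is deterministic for a fixed seed", {
  p <- generator_params(15L, "np_like", seed = 77L)
  a <- generate_library(p)
  b <- generate_library(p)
  expect_identical(a$raw_smiles, b$raw_smiles)
  c <- generate_library(generator_params(15L, "np_like", seed = 78L))
  expect_false(identical(a$raw_smiles, c$raw_smiles))
})

test_that("block metadata matches the descriptor engine", {
  blocks <- fragcompare:::generator_blocks()
  d <- descriptor_profile(blocks$smiles)
  expect_equal(d$n_C, blocks$nC)
  expect_equal(d$n_N, blocks$nN)
  expect_equal(d$n_O, blocks$nO)
  expect_equal(round(d$frac_sp3_C * d$n_C), blocks$sp3)
})

test_that("every generated molecule is valid, whitelisted and pre-clean", {
  lib <- generate_library(generator_params(60L, "np_like", seed = 19L))
  std <- standardize_molecule(lib$raw_smiles)
  expect_true(all(std$status == "standardized"))
  expect_true(all(check_elements(lib$raw_smiles)))
  # the generator emits structures the curation protocol leaves unchanged
  canon <- vapply(fragcompare:::call_chemtools("parse", lib$raw_smiles),
                  function(r) r$canonical, "")
  expect_equal(std$canonical_smiles, canon)
})

test_that("composition targets are recovered on the generated output", {
  for (prof in c("np_like", "synthetic_like")) {
    p <- generator_params(200L, prof, seed = 101L)
    lib <- generate_library(p)
    d <- descriptor_profile(lib$raw_smiles)
    expect_lt(abs(mean(d$frac_O) - p$target_frac_O), 0.03)
    expect_lt(abs(mean(d$frac_N) - p$target_frac_N), 0.03)
    expect_lt(abs(mean(d$frac_sp3_C) - p$target_frac_sp3), 0.03)
  }
})

test_that("the two profiles separate as NP-like vs synthetic-like", {
  np <- descriptor_profile(generate_library(
    generator_params(120L, "np_like", seed = 55L))$raw_smiles)
  sy <- descriptor_profile(generate_library(
    generator_params(120L, "synthetic_like", seed = 56L))$raw_smiles)
  expect_gt(mean(np$frac_O), mean(sy$frac_O))
  expect_lt(mean(np$frac_N), mean(sy$frac_N))
  expect_gt(mean(np$frac_sp3_C), mean(sy$frac_sp3_C))
  expect_gt(mean(np$frac_chiral_C), mean(sy$frac_chiral_C))
  expect_lt(mean(np$n_aromatic_rings), mean(sy$n_aromatic_rings))
})

test_that("planted duplicates appear verbatim and drive overlap", {
  a <- generate_library(generator_params(
    20L, "np_like", seed = 1L, planted_duplicates = "c1ccccc1"))
  b <- generate_library(generator_params(
    20L, "synthetic_like", seed = 2L, planted_duplicates = "c1ccccc1"))
  expect_true("c1ccccc1" %in% a$raw_smiles)
  ov <- overlap(standardize_library(a)$records,
                standardize_library(b)$records)
  expect_gte(ov$n_shared, 1L)
  expect_error(generator_params(2L, "np_like",
                                planted_duplicates = rep("C", 3L)) |>
                 generate_library(), "planted")
})

test_that("infeasible constraints fail loudly", {
  p <- generator_params(5L, "custom", target_frac_O = 0.9,
                        target_frac_N = 0, target_frac_sp3 = 1,
                        block_weights = c(aromatic_carbocycle = 1,
                                          aromatic_N_het = 0,
                                          sat_O_het = 0, fused_bicycle = 0,
                                          bridged_bicycle = 0,
                                          spiro_pair = 0, chain = 0),
                        linker_weights = c(amide = 0, ester = 0,
                                           ether = 0, amine = 0,
                                           sulfonamide = 0, urea = 0,
                                           olefin = 0, biaryl = 1),
                        block_subset = "benzene")
  # benzene-only with biaryl links is feasible structurally, so this runs;
  # an empty vocabulary is the hard failure mode
  expect_error(generate_library(
    generator_params(5L, "np_like", block_subset = "no_such_block")),
    "block_subset")
  expect_error(generator_params(5L, "np_like",
                                block_weights = c(aromatic_carbocycle = -1)))
})

test_that("the benchmark suite ships its ground truth", {
  suite <- bench_suite()
  expect_gte(length(suite$libraries), 3L)
  gt <- suite$ground_truth
  expect_true(all(c("planted_overlaps", "composition_targets",
                    "recap_audit") %in% names(gt)))
  expect_equal(nrow(gt$recap_audit), 10L)

  # the hand-audited decompositions match the engine exactly
  got <- recap_decompose(gt$recap_audit$smiles)
  for (i in seq_len(nrow(gt$recap_audit))) {
    expected <- sort(strsplit(gt$recap_audit$expected_leaves[i], "|",
                              fixed = TRUE)[[1]])
    expect_equal(sort(got[[i]]), expected,
                 label = gt$recap_audit$id[i])
  }

  # RO3-enriched vendor-like library
  vd <- bench_std()$vd_gen
  expect_gte(attr(filter_ro3(vd$canonical_smiles), "pass_rate"), 50)
})

test_that("suite files round trip through the registry", {
  dir <- withr::local_tempdir()
  suite <- generate_benchmark_suite(seed = 3L, n_np = 12L, n_synth = 12L,
                                    n_vendor = 10L, dir = dir)
  reg <- read_registry(suite$registry_path)
  expect_named(reg, c("np_gen", "sy_gen", "vd_gen"))
  lib <- read_library(reg$np_gen)
  expect_equal(nrow(lib), 12L)
  expect_true(file.exists(file.path(dir, "ground_truth_recap.csv")))
})
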