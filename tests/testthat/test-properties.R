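test_that("ro3 boundary pairs pass/fail on exactly the intended property", {
  pairs <- ro3_boundary_pairs()
  for (prop in names(pairs)) {
    p <- ro3_profile(c(pairs[[prop]]$pass, pairs[[prop]]$fail))
    expect_true(p$passes[1], label = paste(prop, "pass molecule"))
    expect_false(p$passes[2], label = paste(prop, "fail molecule"))
    exceeded <- c(mw = p$mw[2] > 300, rb = p$rb[2] > 3,
                  tpsa = p$tpsa[2] > 60, logp = p$logp[2] > 3,
                  hba = p$hba[2] > 3, hbd = p$hbd[2] > 3)
    expect_equal(names(which(exceeded)), prop)
  }
})

test_that("ro3 profiles match reference descriptor values", {
  p <- ro3_profile(c("c1ccccc1", "CCCCCCCCCCCCCCCCCCCCCCCCC"))
  expect_true(p$passes[1])
  expect_equal(p$mw[1], 78.11, tolerance = 1e-3)
  expect_equal(p$hba[1], 0L)
  # the C25 alkane fails on MW regardless of anything else
  expect_false(p$passes[2])
  expect_gt(p$mw[2], 300)
  # a triol has hbd = 3 (boundary value is compliant for that property)
  triol <- ro3_profile("OCC(O)CO")
  expect_equal(triol$hbd, 3L)
  expect_lte(triol$hbd, 3)
})

test_that("filter_ro3 preserves occurrence data and is idempotent", {
  fl <- fragment_library(c("c1ccc(-c2ccccc2)cc1", "CC(=O)Nc1ccccc1"))
  sub <- filter_ro3(fl)
  expect_true(all(sub$canonical_smiles %in% fl$canonical_smiles))
  expect_true(all(c("occurrence", "n_parents") %in% names(sub)))
  again <- filter_ro3(sub)
  expect_equal(again$canonical_smiles, sub$canonical_smiles)
  expect_equal(attr(again, "pass_rate"), 100)

  five <- filter_ro3(rep("c1ccccc1", 5L))
  expect_equal(attr(five, "n_pass"), 5L)
  expect_equal(attr(five, "pass_rate"), 100)

  none <- filter_ro3(character())
  expect_identical(attr(none, "pass_rate"), NA_real_)
})

test_that("descriptor panel matches known structures", {
  d <- descriptor_profile(c("c1ccccc1", "C1CCC2(CC1)CCCC2",
                            "C1CC2CCC1C2", "c1ccc2c(c1)OCO2"))
  # benzene
  expect_equal(d$n_rings[1], 1)
  expect_equal(d$n_aromatic_rings[1], 1)
  expect_equal(d$n_heterocycles[1], 0)
  expect_equal(d$frac_sp3_C[1], 0)
  expect_equal(d$n_spiro_atoms[1], 0)
  # spiro[4.5]decane
  expect_equal(d$n_spiro_atoms[2], 1)
  expect_equal(d$n_rings[2], 2)
  expect_equal(d$n_aliphatic_rings[2], 2)
  # norbornane
  expect_equal(d$n_bridgehead_atoms[3], 2)
  # benzodioxole: one aromatic carbocycle + one aliphatic O-heterocycle
  expect_equal(d$n_heterocycles[4], 1)
  expect_equal(d$n_aliphatic_heterocycles[4], 1)
  expect_equal(d$n_aromatic_heterocycles[4], 0)
})

test_that("descriptor invariants hold on a generated battery", {
  lib <- generate_library(generator_params(80L, "np_like", seed = 5L))
  d <- descriptor_profile(lib$raw_smiles)
  expect_true(all(d$frac_C + d$frac_O + d$frac_N <= 1 + 1e-12))
  expect_true(all(d$frac_sp3_C >= 0 & d$frac_sp3_C <= 1))
  expect_true(all(d$frac_chiral_C >= 0 & d$frac_chiral_C <= 1))
  expect_equal(d$n_aliphatic_rings + d$n_aromatic_rings, d$n_rings)
  expect_true(all(d$n_aromatic_heterocycles <= d$n_aromatic_rings))
  expect_true(all(d$n_aliphatic_heterocycles <= d$n_aliphatic_rings))
  expect_true(all(d$n_heterocycles <= d$n_rings))
})

test_that("adding carbons never decreases mw or heavy-atom count", {
  series <- c("C", "CC", "CCC", "CCCC", "CCCCC")
  d <- descriptor_profile(series)
  expect_true(all(diff(d$mw) > 0))
  expect_true(all(diff(d$n_heavy) == 1))
})

test_that("library summaries are plain means over unique structures", {
  one <- library_descriptor_summary("c1ccccc1")
  d <- descriptor_profile("c1ccccc1")
  expect_equal(one$mean, unname(unlist(d[1, one$descriptor])))

  two <- library_descriptor_summary(c("c1ccccc1", "C1CCCCC1"))
  expect_equal(two$mean[two$descriptor == "n_rings"], 1)
  expect_equal(two$mean[two$descriptor == "frac_sp3_C"], 0.5)

  # duplicates do not weight the mean
  three <- library_descriptor_summary(c("c1ccccc1", "c1ccccc1",
                                        "C1CCCCC1"))
  expect_equal(three$mean, two$mean)
  expect_error(library_descriptor_summary(character()), "empty")
})
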