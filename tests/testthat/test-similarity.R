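test_that("fingerprints have the right length and canonical invariance", {
  f1 <- fingerprint(c("c1ccccc1", "C1=CC=CC=C1"), "maccs166")
  expect_equal(f1$nbits, 166L)
  expect_identical(f1$bits[[1]], f1$bits[[2]])

  f2 <- fingerprint("C", "morgan2_1024")
  expect_equal(f2$nbits, 1024L)
  expect_gte(length(f2$bits[[1]]), 1L)

  # aromatic vs saturated ring differ under MACCS
  f3 <- fingerprint(c("c1ccccc1", "C1CCCCC1"), "maccs166")
  expect_false(identical(f3$bits[[1]], f3$bits[[2]]))

  f4 <- fingerprint("c1ccccc1", "morgan3_1024")
  expect_equal(f4$nbits, 1024L)
})

test_that("tanimoto matches its definition and edge cases", {
  expect_equal(tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1)), 0.5)
  expect_equal(tanimoto(c(1, 0), c(1, 0)), 1)
  expect_equal(tanimoto(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(tanimoto(numeric(4), numeric(4)), 1)  # all-zero convention
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length")
})

test_that("tanimoto agrees with a set-based oracle on random vectors", {
  withr::local_seed(99)
  for (i in 1:200) {
    n <- sample(8:64, 1)
    a <- rbinom(n, 1, runif(1, 0.1, 0.9))
    b <- rbinom(n, 1, runif(1, 0.1, 0.9))
    on_a <- which(a == 1); on_b <- which(b == 1)
    un <- length(union(on_a, on_b))
    oracle <- if (un == 0) 1 else length(intersect(on_a, on_b)) / un
    expect_equal(tanimoto(a, b), oracle)
    expect_equal(tanimoto(b, a), tanimoto(a, b))  # symmetry
  }
})

test_that("exhaustive mode conserves the pair count", {
  smi <- unique(generate_library(
    generator_params(25L, "synthetic_like", seed = 4L))$raw_smiles)
  d <- diversity_distribution(smi, "morgan2_1024")
  n <- d$n_molecules
  expect_equal(d$n_pairs, n * (n - 1) / 2)
  expect_equal(d$mode, "exhaustive")
  expect_true(all(d$values >= 0 & d$values <= 1))
  expect_true(all(diff(d$cdf$cumulative) >= 0))
  expect_equal(d$cdf$cumulative[201], 1)
})

test_that("identical molecules give similarity 1 and median 1", {
  d <- diversity_distribution(rep("c1ccccc1", 3), "maccs166",
                              subsample_scheme())
  expect_equal(d$values, rep(1, 3))
  expect_equal(d$median, 1)
  expect_error(diversity_distribution("CCO"), "at least 2")
})

test_that("pairwise values agree with a brute-force loop", {
  smi <- c("c1ccccc1", "Cc1ccccc1", "C1CCOCC1", "CCO", "CCN")
  fps <- fingerprint(smi, "morgan2_1024")
  d <- diversity_distribution(fps)
  dense <- lapply(fps$bits, function(b) {
    v <- numeric(fps$nbits); v[b + 1] <- 1; v
  })
  brute <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    brute <- c(brute, tanimoto(dense[[i]], dense[[j]]))
  }
  expect_equal(sort(d$values), sort(brute))
})

test_that("subsampled and exhaustive medians agree at reduced scale", {
  smi <- unique(generate_library(
    generator_params(150L, "np_like", seed = 13L))$raw_smiles)
  fps <- fingerprint(smi, "morgan2_1024")
  ex <- diversity_distribution(fps)
  sub <- diversity_distribution(
    fps, scheme = subsample_scheme(n_subsets = 10L, subset_size = 60L,
                                   seed = 7L, trigger_size = 100L))
  expect_equal(sub$mode, "subsampled")
  expect_length(sub$subset_medians, 10L)
  expect_lt(abs(sub$median - ex$median), 0.05)

  # determinism under a fixed scheme seed
  sub2 <- diversity_distribution(
    fps, scheme = subsample_scheme(n_subsets = 10L, subset_size = 60L,
                                   seed = 7L, trigger_size = 100L))
  expect_identical(sub$values, sub2$values)
})

test_that("a planted two-cluster library gives a bimodal distribution", {
  suite <- bench_suite()
  np <- standardize_library(suite$libraries$np_gen)$records
  sy <- standardize_library(suite$libraries$sy_gen)$records
  both <- unique(c(np$canonical_smiles[1:50], sy$canonical_smiles[1:50]))
  d_all <- diversity_distribution(both, "morgan2_1024")
  d_np <- diversity_distribution(unique(np$canonical_smiles[1:50]),
                                 "morgan2_1024")
  # pooled similarities sit below the within-cluster level
  expect_lt(d_all$median, d_np$median)
})
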