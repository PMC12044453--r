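# Shared fixtures, computed once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = fixture_env, inherits = FALSE)) {
    assign(name, fn(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# small benchmark suite shared across overlap / pipeline / generator tests
bench_suite <- function() {
  fixture("bench_suite", function() {
    generate_benchmark_suite(seed = 42L, n_np = 60L, n_synth = 60L,
                             n_vendor = 50L)
  })
}

bench_std <- function() {
  fixture("bench_std", function() {
    lapply(bench_suite()$libraries,
           function(l) standardize_library(l)$records)
  })
}

# eleven hand-constructed rule fixtures: for each rule one molecule whose
# cleavable-bond rule set and leaf-fragment set were derived by manual
# application of the cleavage rules
recap_rule_fixtures <- function() {
  list(
    amine = list(smiles = "CCN(CC)CC", rules = "amine",
                 leaves = c("CC", "N")),
    amide = list(smiles = "CC(=O)Nc1ccccc1", rules = "amide",
                 leaves = c("CC=O", "Nc1ccccc1")),
    ester = list(smiles = "CCOC(=O)c1ccccc1", rules = "ester",
                 leaves = c("CCO", "O=Cc1ccccc1")),
    urea = list(smiles = "CN(C)C(=O)Nc1ccccc1", rules = "urea",
                leaves = c("C", "C=O", "N", "Nc1ccccc1")),
    olefin = list(smiles = "C(=Cc1ccccc1)c1ccccc1", rules = "olefin",
                  leaves = "Cc1ccccc1"),
    ether = list(smiles = "c1ccccc1COCc1ccccc1", rules = "ether",
                 leaves = c("Cc1ccccc1", "O")),
    aromatic_N_aliphatic_C = list(smiles = "Cn1cccc1",
                                  rules = "aromatic_N_aliphatic_C",
                                  leaves = c("C", "c1cc[nH]c1")),
    lactam_N_aliphatic_C = list(smiles = "CCN1CCCC1=O",
                                rules = "lactam_N_aliphatic_C",
                                leaves = c("CC", "O=C1CCCN1")),
    aromatic_C_aromatic_C = list(smiles = "c1ccc(-c2ccccc2)cc1",
                                 rules = "aromatic_C_aromatic_C",
                                 leaves = "c1ccccc1"),
    quaternary_N = list(smiles = "C[N+](C)(C)Cc1ccccc1",
                        rules = "quaternary_N",
                        leaves = c("C", "Cc1ccccc1", "[NH4+]")),
    sulfonamide = list(smiles = "CNS(=O)(=O)c1ccccc1",
                       rules = "sulfonamide",
                       leaves = c("CN", "O=[SH](=O)c1ccccc1")))
}

# rule-of-three boundary pairs: each "fail" molecule exceeds exactly one
# property (verified in test-properties.R)
ro3_boundary_pairs <- function() {
  list(
    mw = list(pass = "IC1CCOCC1", fail = "IC1CCOC(I)C1"),
    rb = list(pass = "c1ccccc1OCCO", fail = "c1ccccc1OCCCO"),
    tpsa = list(pass = "COC1CC(O)CC(O)C1", fail = "OC1CC(O)CC(O)C1"),
    logp = list(pass = "CC(C)(C)c1ccccc1", fail = "c1ccc(-c2ccccc2)cc1"),
    hba = list(pass = "C1COCCOCCO1", fail = "C1COCCOCCOCCO1"),
    hbd = list(pass = "CNC1CCC(N)CC1", fail = "NC1CCC(N)CC1"))
}

# 50-molecule battery spanning acyclic, macrocyclic, spiro, bridged and
# stereocentre-rich structures, for the SA-score equivalence check
sa_battery <- function() {
  fixed <- c(
    "CCO", "CC(=O)O", "c1ccccc1", "c1ccncc1", "CC(C)CO",
    "C1CCCCCCCCCCC1", "O=C1CCCCCCCCCCO1", "C1CCC2(CC1)CCCC2",
    "C1CC2CCC1C2", "CC12CCC(CC1)C2(C)C", "C[C@@H](O)[C@H](C)O",
    "N[C@@H](C)C(=O)O", "OC[C@H]1O[C@@H](O)[C@H](O)[C@@H]1O",
    "CC(=O)Nc1ccccc1", "CN1CCC[C@H]1c1cccnc1", "c1ccc2c(c1)OCO2",
    "C1CCC2(CC1)OCCO2", "CC(C)(C)OC(=O)N1CCC(N)CC1",
    "O=S(=O)(N)c1ccccc1", "Clc1ccc(Cl)cc1")
  gen <- generate_library(generator_params(45L, "np_like", seed = 7L))
  head(unique(c(fixed, gen$raw_smiles)), 50L)
}
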