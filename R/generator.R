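# Synthetic library generator: block-and-linker grammar producing
# NP-like and synthetic-like populations with controllable elemental
# composition, sp3 content, ring systems and planted duplicates.
#
# Blocks are SMILES written so that the first atom (head) bonds to the
# previous unit and the last written atom (tail) bonds to the next; both
# are carbons with a free valence, so concatenating
#   block1 + linker1 + block2 + ...
# is always a valid molecule.  Linkers are the RECAP-cleavable bond
# environments, so every multi-block molecule is decomposable by
# construction.  Composition targets are reached by reweighting the block
# and linker choice towards the target at every sampling step.

# name, smiles, class, and heavy-atom bookkeeping used for steering
# (nC/nN/nO/nS: heavy-atom counts; sp3: sp3 carbons; arom: aromatic
# head/tail).  The metadata is cross-checked against descriptor_profile
# in the test suite.
generator_blocks <- function() {
  df <- function(...) data.frame(..., stringsAsFactors = FALSE)
  rbind(
    df(name = "benzene", smiles = "c1ccccc1", class = "aromatic_carbocycle",
       nC = 6L, nN = 0L, nO = 0L, nS = 0L, sp3 = 0L, arom = TRUE),
    df(name = "naphthalene", smiles = "c1ccc2ccccc2c1",
       class = "aromatic_carbocycle",
       nC = 10L, nN = 0L, nO = 0L, nS = 0L, sp3 = 0L, arom = TRUE),
    df(name = "pyridine", smiles = "c1ccncc1", class = "aromatic_N_het",
       nC = 5L, nN = 1L, nO = 0L, nS = 0L, sp3 = 0L, arom = TRUE),
    df(name = "pyrimidine", smiles = "c1ncncc1", class = "aromatic_N_het",
       nC = 4L, nN = 2L, nO = 0L, nS = 0L, sp3 = 0L, arom = TRUE),
    df(name = "quinoline", smiles = "c1ccc2ncccc2c1",
       class = "aromatic_N_het",
       nC = 9L, nN = 1L, nO = 0L, nS = 0L, sp3 = 0L, arom = TRUE),
    df(name = "thp", smiles = "C1CCOCC1", class = "sat_O_het",
       nC = 5L, nN = 0L, nO = 1L, nS = 0L, sp3 = 5L, arom = FALSE),
    df(name = "thf", smiles = "C1CCOC1", class = "sat_O_het",
       nC = 4L, nN = 0L, nO = 1L, nS = 0L, sp3 = 4L, arom = FALSE),
    df(name = "dioxolane", smiles = "C1OCOC1", class = "sat_O_het",
       nC = 3L, nN = 0L, nO = 2L, nS = 0L, sp3 = 3L, arom = FALSE),
    df(name = "thp_ol", smiles = "C1CC(O)OCC1", class = "sat_O_het",
       nC = 5L, nN = 0L, nO = 2L, nS = 0L, sp3 = 5L, arom = FALSE),
    df(name = "decalin", smiles = "C1CCC2CCCCC2C1", class = "fused_bicycle",
       nC = 10L, nN = 0L, nO = 0L, nS = 0L, sp3 = 10L, arom = FALSE),
    df(name = "oxadecalin", smiles = "C1CCC2OCCCC2C1",
       class = "fused_bicycle",
       nC = 9L, nN = 0L, nO = 1L, nS = 0L, sp3 = 9L, arom = FALSE),
    df(name = "norbornane", smiles = "C1CC2CCC1C2", class = "bridged_bicycle",
       nC = 7L, nN = 0L, nO = 0L, nS = 0L, sp3 = 7L, arom = FALSE),
    df(name = "oxaspiro", smiles = "C1CCC2(C1)CCOC2", class = "spiro_pair",
       nC = 8L, nN = 0L, nO = 1L, nS = 0L, sp3 = 8L, arom = FALSE),
    df(name = "spirononane", smiles = "C1CCC2(C1)CCCC2", class = "spiro_pair",
       nC = 9L, nN = 0L, nO = 0L, nS = 0L, sp3 = 9L, arom = FALSE),
    df(name = "isopropanol_u", smiles = "CC(O)C", class = "chain",
       nC = 3L, nN = 0L, nO = 1L, nS = 0L, sp3 = 3L, arom = FALSE),
    df(name = "glycol_u", smiles = "CC(O)C(O)C", class = "chain",
       nC = 4L, nN = 0L, nO = 2L, nS = 0L, sp3 = 4L, arom = FALSE),
    df(name = "isobutane_u", smiles = "CC(C)C", class = "chain",
       nC = 4L, nN = 0L, nO = 0L, nS = 0L, sp3 = 4L, arom = FALSE))
}

generator_linkers <- function() {
  df <- function(...) data.frame(..., stringsAsFactors = FALSE)
  rbind(
    df(name = "amide", smiles = "C(=O)N", nC = 1L, nN = 1L, nO = 1L,
       nS = 0L, sp3 = 0L, needs_arom = FALSE),
    df(name = "ester", smiles = "C(=O)O", nC = 1L, nN = 0L, nO = 2L,
       nS = 0L, sp3 = 0L, needs_arom = FALSE),
    df(name = "ether", smiles = "O", nC = 0L, nN = 0L, nO = 1L,
       nS = 0L, sp3 = 0L, needs_arom = FALSE),
    df(name = "amine", smiles = "N", nC = 0L, nN = 1L, nO = 0L,
       nS = 0L, sp3 = 0L, needs_arom = FALSE),
    df(name = "sulfonamide", smiles = "S(=O)(=O)N", nC = 0L, nN = 1L,
       nO = 2L, nS = 1L, sp3 = 0L, needs_arom = FALSE),
    df(name = "urea", smiles = "NC(=O)N", nC = 1L, nN = 2L, nO = 1L,
       nS = 0L, sp3 = 0L, needs_arom = FALSE),
    df(name = "olefin", smiles = "C=C", nC = 2L, nN = 0L, nO = 0L,
       nS = 0L, sp3 = 0L, needs_arom = FALSE),
    df(name = "biaryl", smiles = "", nC = 0L, nN = 0L, nO = 0L,
       nS = 0L, sp3 = 0L, needs_arom = TRUE))
}

profile_defaults <- function(profile) {
  switch(profile,
    np_like = list(
      target_frac_O = 0.21, target_frac_N = 0.01, target_frac_sp3 = 0.65,
      block_weights = c(aromatic_carbocycle = 0.22, aromatic_N_het = 0.01,
                        sat_O_het = 0.30, fused_bicycle = 0.12,
                        bridged_bicycle = 0.06, spiro_pair = 0.06,
                        chain = 0.23),
      linker_weights = c(amide = 0.02, ester = 0.30, ether = 0.38,
                         amine = 0.02, sulfonamide = 0.00, urea = 0.00,
                         olefin = 0.18, biaryl = 0.10),
      mean_blocks = 3),
    synthetic_like = list(
      target_frac_O = 0.10, target_frac_N = 0.14, target_frac_sp3 = 0.30,
      block_weights = c(aromatic_carbocycle = 0.28, aromatic_N_het = 0.38,
                        sat_O_het = 0.10, fused_bicycle = 0.04,
                        bridged_bicycle = 0.01, spiro_pair = 0.01,
                        chain = 0.18),
      linker_weights = c(amide = 0.28, ester = 0.05, ether = 0.10,
                         amine = 0.20, sulfonamide = 0.12, urea = 0.08,
                         olefin = 0.02, biaryl = 0.15),
      mean_blocks = 2.5),
    stop("unknown profile: ", profile))
}

#' Parameters for the synthetic library generator
#'
#' The built-in profiles state the populations the generator emulates:
#' `"np_like"` (oxygen-rich, nitrogen-poor, high sp3 fraction, saturated
#' O-heterocycles and fused/bridged/spiro ring systems, ester/ether
#' linkages) and `"synthetic_like"` (nitrogen-rich, aromatic-ring-rich,
#' low sp3, amide/amine/sulfonamide/urea linkages). Composition targets
#' default to heavy-atom fractions O ~ 0.21 / N ~ 0.01 / sp3 ~ 0.65 for
#' the NP-like profile and O ~ 0.10 / N ~ 0.14 / sp3 ~ 0.30 for the
#' synthetic-like profile.
#'
#' @param n library size.
#' @param profile `"np_like"`, `"synthetic_like"` or `"custom"`.
#' @param seed integer seed; the same parameters and seed give an
#'   identical library.
#' @param target_frac_O,target_frac_N heavy-atom fraction targets.
#' @param target_frac_sp3 target fraction of sp3 carbons.
#' @param block_weights named non-negative weights over the block classes.
#' @param linker_weights named non-negative weights over the linkers.
#' @param mean_blocks mean building blocks per molecule (>= 1; block
#'   count is 1 + Poisson(mean_blocks - 1)).
#' @param min_blocks lower bound on blocks per molecule.
#' @param planted_duplicates optional character vector of SMILES inserted
#'   verbatim (replacing the tail of the sampled set).
#' @param block_subset,linker_subset optional character vectors of block /
#'   linker names restricting the vocabulary (see `generator_blocks()`).
#' @param steer steering strength of the composition reweighting.
#' @return A `generator_params` list.
#' @export
generator_params <- function(n, profile = c("np_like", "synthetic_like",
                                            "custom"),
                             seed = 1L,
                             target_frac_O = NULL, target_frac_N = NULL,
                             target_frac_sp3 = NULL,
                             block_weights = NULL, linker_weights = NULL,
                             mean_blocks = NULL, min_blocks = 1L,
                             planted_duplicates = character(),
                             block_subset = NULL, linker_subset = NULL,
                             steer = 12) {
  profile <- match.arg(profile)
  base <- if (profile == "custom") {
    stopifnot(!is.null(target_frac_O), !is.null(target_frac_N),
              !is.null(target_frac_sp3), !is.null(block_weights),
              !is.null(linker_weights))
    list(target_frac_O = target_frac_O, target_frac_N = target_frac_N,
         target_frac_sp3 = target_frac_sp3, block_weights = block_weights,
         linker_weights = linker_weights,
         mean_blocks = if (is.null(mean_blocks)) 2.5 else mean_blocks)
  } else {
    profile_defaults(profile)
  }
  override <- function(cur, new) if (is.null(new)) cur else new
  p <- list(n = as.integer(n), profile = profile, seed = as.integer(seed),
            target_frac_O = override(base$target_frac_O, target_frac_O),
            target_frac_N = override(base$target_frac_N, target_frac_N),
            target_frac_sp3 = override(base$target_frac_sp3,
                                       target_frac_sp3),
            block_weights = override(base$block_weights, block_weights),
            linker_weights = override(base$linker_weights, linker_weights),
            mean_blocks = override(base$mean_blocks, mean_blocks),
            min_blocks = as.integer(min_blocks),
            planted_duplicates = planted_duplicates,
            block_subset = block_subset, linker_subset = linker_subset,
            steer = steer)
  stopifnot(p$n >= 1L, all(p$block_weights >= 0),
            all(p$linker_weights >= 0), sum(p$block_weights) > 0,
            sum(p$linker_weights) > 0)
  structure(p, class = "generator_params")
}

# sample index by weight (deterministic under the current RNG state)
wsample <- function(w) {
  if (all(w <= 0)) stop("infeasible constraints: all candidate weights zero")
  sample.int(length(w), 1L, prob = w)
}

# `lib_state` accumulates the per-molecule composition fractions of the
# library generated so far (the quantity the targets are stated for is
# the library mean of per-molecule fractions).  Each block/linker draw is
# reweighted by how close the projected library mean would land to the
# targets if the current molecule ended with that unit: a negative
# feedback loop whose mean converges onto the targets while per-molecule
# composition keeps its natural variance.
new_lib_state <- function() c(sum_fo = 0, sum_fn = 0, sum_fs = 0, n = 0)

params_blocks <- function(params) {
  b <- generator_blocks()
  if (!is.null(params$block_subset)) {
    b <- b[b$name %in% params$block_subset, , drop = FALSE]
    if (nrow(b) == 0L) stop("block_subset matches no blocks")
  }
  b
}

params_linkers <- function(params) {
  l <- generator_linkers()
  if (!is.null(params$linker_subset)) {
    l <- l[l$name %in% params$linker_subset, , drop = FALSE]
    if (nrow(l) == 0L) stop("linker_subset matches no linkers")
  }
  l
}

assemble_molecule <- function(params, blocks, linkers,
                              lib_state = new_lib_state()) {
  tgt <- c(O = params$target_frac_O, N = params$target_frac_N,
           sp3 = params$target_frac_sp3)
  n_blocks <- max(params$min_blocks,
                  1L + stats::rpois(1L, max(0, params$mean_blocks - 1)))
  bw <- params$block_weights[blocks$class]
  lw <- params$linker_weights[linkers$name]

  mol <- c(C = 0, N = 0, O = 0, S = 0, sp3 = 0, heavy = 0)
  pieces <- character(0)
  prev_arom <- FALSE
  for (b in seq_len(n_blocks)) {
    if (b > 1L) {
      ok <- !linkers$needs_arom | prev_arom
      w <- lw * steer_weight(mol, lib_state, linkers, tgt,
                             params$steer) * ok
      # a biaryl bond also needs the NEXT block aromatic; enforced on
      # the block draw below
      li <- wsample(w)
      lk <- linkers[li, ]
      mol <- mol + c(lk$nC, lk$nN, lk$nO, lk$nS, lk$sp3,
                     lk$nC + lk$nN + lk$nO + lk$nS)
      pieces <- c(pieces, lk$smiles)
      need_arom <- lk$needs_arom
    } else {
      need_arom <- FALSE
    }
    wb <- bw * steer_weight(mol, lib_state, blocks, tgt, params$steer)
    if (need_arom) wb <- wb * blocks$arom
    bi <- wsample(wb)
    bl <- blocks[bi, ]
    mol <- mol + c(bl$nC, bl$nN, bl$nO, bl$nS, bl$sp3,
                   bl$nC + bl$nN + bl$nO + bl$nS)
    pieces <- c(pieces, bl$smiles)
    prev_arom <- bl$arom
  }
  lib_state <- lib_state + c(mol[["O"]] / mol[["heavy"]],
                             mol[["N"]] / mol[["heavy"]],
                             mol[["sp3"]] / max(mol[["C"]], 1), 1)
  list(smiles = paste(pieces, collapse = ""), state = lib_state)
}

# multiplicative reweighting towards the composition targets: project the
# library mean as if the molecule ended right after the candidate unit
steer_weight <- function(mol, lib_state, units, tgt, steer) {
  heavy <- mol[["heavy"]] + units$nC + units$nN + units$nO + units$nS
  fo <- (mol[["O"]] + units$nO) / pmax(heavy, 1)
  fn <- (mol[["N"]] + units$nN) / pmax(heavy, 1)
  cc <- mol[["C"]] + units$nC
  fs <- (mol[["sp3"]] + units$sp3) / pmax(cc, 1)
  n1 <- lib_state[["n"]] + 1
  proj_fo <- (lib_state[["sum_fo"]] + fo) / n1
  proj_fn <- (lib_state[["sum_fn"]] + fn) / n1
  proj_fs <- (lib_state[["sum_fs"]] + fs) / n1
  # early in the library the projection is noisy; anneal the strength
  lam <- steer * min(1, n1 / 10)
  dist <- abs(proj_fo - tgt[["O"]]) + abs(proj_fn - tgt[["N"]]) +
    abs(proj_fs - tgt[["sp3"]])
  exp(-lam * n1 * dist)
}

#' Generate a synthetic compound library
#'
#' Molecules are assembled by sampling ring/chain blocks joined through
#' RECAP-cleavable linker bonds, with the block and linker choice
#' reweighted at every step towards the composition targets. All
#' structures are valid, element-whitelist compliant and already in their
#' standardized form (the blocks and linkers are tautomer- and
#' charge-stable). Planted duplicates are inserted verbatim at the end of
#' the library.
#'
#' @param params a [generator_params()] object.
#' @param prefix identifier prefix for `source_id`s.
#' @return A `molecule_library` of `params$n` pending records.
#' @examples
#' \dontrun{
#' lib <- generate_library(generator_params(50, "np_like", seed = 7))
#' }
#' @export
generate_library <- function(params, prefix = NULL) {
  stopifnot(inherits(params, "generator_params"))
  blocks <- params_blocks(params)
  linkers <- params_linkers(params)
  if (is.null(prefix)) {
    prefix <- switch(params$profile, np_like = "NP",
                     synthetic_like = "SY", custom = "GN")
  }
  n_plant <- length(params$planted_duplicates)
  if (n_plant > params$n) stop("more planted duplicates than n")
  n_sampled <- params$n - n_plant
  smiles <- with_seed(params$seed, {
    state <- new_lib_state()
    out <- character(n_sampled)
    for (i in seq_len(n_sampled)) {
      res <- assemble_molecule(params, blocks, linkers, state)
      out[i] <- res$smiles
      state <- res$state
    }
    out
  })
  smiles <- c(smiles, as.character(params$planted_duplicates))
  new_molecule_library(sprintf("%s%05d", prefix, seq_len(params$n)),
                       smiles, name = paste0(tolower(prefix), "_gen"),
                       role = "generated")
}

#' Generate the benchmark suite of paired libraries
#'
#' Emits an NP-like, a synthetic-like and a small RO3-enriched
#' "vendor-like" library, with planted duplicate structures across
#' libraries, plus a machine-readable ground-truth sheet: the planted
#' overlaps per library pair, the composition targets, and the manually
#' derived RECAP leaf sets for a ten-molecule audit battery. Organic
#' (non-planted) cross-library duplicates are resampled away so the
#' pairwise overlaps equal the planted counts exactly.
#'
#' @param seed master seed; the three libraries use `seed`, `seed + 1`,
#'   `seed + 2`.
#' @param n_np,n_synth,n_vendor library sizes.
#' @param dir optional directory; when given, the libraries, a registry
#'   file and the ground-truth CSVs are written there.
#' @return A list with `libraries` (named list of `molecule_library`),
#'   `ground_truth` (list: `planted_overlaps`, `composition_targets`,
#'   `recap_audit`) and, if `dir` was given, `registry_path`.
#' @export
generate_benchmark_suite <- function(seed = 42L, n_np = 300L,
                                     n_synth = 300L, n_vendor = 150L,
                                     dir = NULL) {
  planted <- list(
    np = c("c1ccccc1C(=O)OC1CCOCC1", "C1CCOCC1OC1CCOC1"),
    synth = c("c1ccccc1C(=O)OC1CCOCC1", "c1ccncc1NC(=O)c1ccccc1"),
    vendor = c("C1CCOCC1OC1CCOC1", "c1ccncc1NC(=O)c1ccccc1"))
  # pairwise planted intersections implied by the lists above:
  planted_overlaps <- data.frame(
    lib_a = c("np_gen", "np_gen", "sy_gen"),
    lib_b = c("sy_gen", "vd_gen", "vd_gen"),
    n_planted = c(1L, 1L, 1L), stringsAsFactors = FALSE)

  p_np <- generator_params(n_np, "np_like", seed = seed,
                           min_blocks = 2L,
                           planted_duplicates = planted$np)
  p_sy <- generator_params(n_synth, "synthetic_like", seed = seed + 1L,
                           min_blocks = 2L,
                           planted_duplicates = planted$synth)
  p_vd <- generator_params(
    n_vendor, "custom", seed = seed + 2L,
    target_frac_O = 0.08, target_frac_N = 0.10, target_frac_sp3 = 0.35,
    block_weights = c(aromatic_carbocycle = 0.45, aromatic_N_het = 0.20,
                      sat_O_het = 0.25, fused_bicycle = 0,
                      bridged_bicycle = 0, spiro_pair = 0, chain = 0.10),
    linker_weights = c(amide = 0.45, ester = 0.05, ether = 0.20,
                       amine = 0.25, sulfonamide = 0, urea = 0,
                       olefin = 0, biaryl = 0.05),
    mean_blocks = 1.3, min_blocks = 2L,
    block_subset = c("benzene", "pyridine", "thp", "thf",
                     "isopropanol_u", "isobutane_u"),
    linker_subset = c("amide", "ester", "ether", "amine", "biaryl"),
    planted_duplicates = planted$vendor)

  libs <- list(np_gen = generate_library(p_np, "NP"),
               sy_gen = generate_library(p_sy, "SY"),
               vd_gen = generate_library(p_vd, "VD"))

  libs <- deduplicate_across(libs, planted, seed + 100L,
                             list(np_gen = p_np, sy_gen = p_sy,
                                  vd_gen = p_vd))

  gt <- list(planted_overlaps = planted_overlaps,
             composition_targets = data.frame(
               library = c("np_gen", "sy_gen", "vd_gen"),
               frac_O = c(p_np$target_frac_O, p_sy$target_frac_O,
                          p_vd$target_frac_O),
               frac_N = c(p_np$target_frac_N, p_sy$target_frac_N,
                          p_vd$target_frac_N),
               frac_sp3 = c(p_np$target_frac_sp3, p_sy$target_frac_sp3,
                            p_vd$target_frac_sp3),
               stringsAsFactors = FALSE),
             recap_audit = recap_audit_sheet())

  out <- list(libraries = libs, ground_truth = gt)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    entries <- list()
    for (nm in names(libs)) {
      path <- file.path(dir, paste0(nm, ".smi"))
      write_library(libs[[nm]], path)
      entries[[nm]] <- library_entry(nm, "generated", path)
    }
    reg <- file.path(dir, "registry.dcf")
    write_registry(entries, reg)
    utils::write.table(gt$planted_overlaps,
                       file.path(dir, "ground_truth_overlaps.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    utils::write.table(gt$composition_targets,
                       file.path(dir, "ground_truth_targets.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    utils::write.table(gt$recap_audit,
                       file.path(dir, "ground_truth_recap.csv"),
                       sep = ",", row.names = FALSE, quote = TRUE)
    out$registry_path <- reg
  }
  out
}

# resample organically colliding structures so cross-library overlaps
# equal the planted counts exactly
deduplicate_across <- function(libs, planted, seed, params) {
  planted_set <- unique(unlist(planted))
  canon <- lapply(libs, function(l) {
    vapply(call_chemtools("parse", l$raw_smiles),
           function(r) null2na(r$canonical), NA_character_)
  })
  planted_canon <- vapply(call_chemtools("parse", planted_set),
                          function(r) null2na(r$canonical), NA_character_)
  nm <- names(libs)
  for (round in 1:20) {
    all_canon <- data.frame(
      lib = rep(nm, vapply(canon, length, 0L)),
      idx = unlist(lapply(canon, seq_along), use.names = FALSE),
      smi = unlist(canon, use.names = FALSE), stringsAsFactors = FALSE)
    planted_rows <- all_canon$smi %in% planted_canon
    dup_tab <- table(unique(all_canon[!planted_rows,
                                      c("lib", "smi")])$smi)
    organic_dups <- names(dup_tab)[dup_tab > 1]
    # also: an organic copy of a planted structure inflates the overlap
    bad <- all_canon$smi %in% organic_dups & !planted_rows
    n_planted_per_lib <- vapply(nm, function(l)
      length(planted[[match(l, nm)]]), 0L)
    for (l in nm) {
      is_plant_slot <- seq_along(canon[[l]]) >
        (length(canon[[l]]) - length(planted[[match(l, nm)]]))
      organic_of_planted <- canon[[l]] %in% planted_canon & !is_plant_slot
      bad[all_canon$lib == l] <- bad[all_canon$lib == l] |
        organic_of_planted
    }
    if (!any(bad)) break
    # keep the first library's copy, resample the others
    fix <- all_canon[bad, , drop = FALSE]
    keep_first <- !duplicated(fix$smi) & !(fix$smi %in% planted_canon)
    fix <- fix[!keep_first, , drop = FALSE]
    if (nrow(fix) == 0L) break
    for (r in seq_len(nrow(fix))) {
      l <- fix$lib[r]
      i <- fix$idx[r]
      new_smi <- with_seed(seed + round * 1000L + r, {
        assemble_molecule(params[[l]], params_blocks(params[[l]]),
                          params_linkers(params[[l]]))$smiles
      })
      libs[[l]]$raw_smiles[i] <- new_smi
      canon[[l]][i] <- call_chemtools("parse", new_smi)[[1]]$canonical
    }
  }
  libs
}

# Ten-molecule RECAP audit battery with manually derived leaf sets
# (fragments listed as canonical SMILES, '|'-separated, sorted).
recap_audit_sheet <- function() {
  data.frame(
    id = sprintf("audit%02d", 1:10),
    smiles = c(
      "c1ccccc1-c1ccccc1",             # biaryl bond
      "CC(=O)Nc1ccccc1",               # amide
      "CCOC(=O)c1ccccc1",              # ester
      "C1CCOCC1OC1CCOC1",              # ether between two O-heterocycles
      "C1CCOCC1C=CC1CCOC1",            # olefin bridge
      "CCN1CCCC1=O",                   # lactam N - aliphatic C
      "Cn1cccc1",                      # aromatic N - aliphatic C
      "CNS(=O)(=O)c1ccccc1",           # sulfonamide
      "C[N+](C)(C)Cc1ccccc1",          # quaternary nitrogen
      "CNC(=O)Nc1ccccc1"),             # urea (with amine follow-up)
    expected_leaves = c(
      "c1ccccc1",
      "CC=O|Nc1ccccc1",
      "CCO|O=Cc1ccccc1",
      "C1CCOC1|C1CCOCC1|O",
      "CC1CCCOC1|CC1CCOC1",
      "CC|O=C1CCCN1",
      "C|c1cc[nH]c1",
      "CN|O=[SH](=O)c1ccccc1",
      "C|Cc1ccccc1|[NH4+]",
      "C=O|CN|Nc1ccccc1"),
    stringsAsFactors = FALSE)
}
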