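# Rule-of-three profiling and the constitutional/complexity descriptor
# panel.

#' Default rule-of-three thresholds
#'
#' MW <= 300 Da, rotatable bonds <= 3, TPSA <= 60 A^2, logP <= 3,
#' hydrogen-bond acceptors <= 3 (N+O count) and donors <= 3 (N-H/O-H
#' hydrogen count). All thresholds are inclusive.
#' @export
RO3_THRESHOLDS <- c(mw = 300, rb = 3, tpsa = 60, logp = 3, hba = 3, hbd = 3)

DESCRIPTOR_PANEL <- c("n_C", "n_O", "n_N", "frac_C", "frac_O", "frac_N",
                      "frac_sp3_C", "frac_chiral_C", "mw", "n_heavy",
                      "n_rings", "n_aliphatic_rings", "n_aromatic_rings",
                      "n_heterocycles", "n_aliphatic_heterocycles",
                      "n_aromatic_heterocycles", "n_spiro_atoms",
                      "n_bridgehead_atoms")

descriptor_table <- function(smiles) {
  res <- call_chemtools("descriptors", smiles)
  bad <- vapply(res, is.null, TRUE)
  if (any(bad)) {
    stop("unparsable SMILES at position(s) ",
         paste(which(bad), collapse = ", "))
  }
  cols <- names(res[[1]])
  df <- as.data.frame(lapply(setNames(cols, cols), function(cn) {
    vapply(res, function(r) as.numeric(r[[cn]]), 0)
  }))
  df
}

#' Rule-of-three property profile
#'
#' Computes the six fragment-likeness properties for each molecule:
#' molecular weight (average atomic masses, implicit hydrogens included),
#' rotatable bonds (acyclic single bonds between non-terminal heavy atoms,
#' amide C-N excluded), topological polar surface area (classic Ertl
#' parametrization, no S/P contributions), Crippen logP, hydrogen-bond
#' acceptors (N+O count) and donors (N-H/O-H hydrogen count).
#'
#' @param smiles character vector of standardized SMILES.
#' @param thresholds named vector of inclusive upper bounds (see
#'   [RO3_THRESHOLDS]).
#' @return Data frame with `mw`, `rb`, `tpsa`, `logp`, `hba`, `hbd` and
#'   logical `passes` (the conjunction of all six bounds).
#' @examples
#' \dontrun{
#' ro3_profile(c("c1ccccc1", "CCCCCCCCCCCCCCCCCCCCCCCCC"))
#' }
#' @export
ro3_profile <- function(smiles, thresholds = RO3_THRESHOLDS) {
  if (inherits(smiles, "fragment_library") ||
      inherits(smiles, "molecule_library")) {
    smiles <- smiles$canonical_smiles
  }
  df <- descriptor_table(smiles)[, c("mw", "rb", "tpsa", "logp",
                                     "hba", "hbd")]
  df$rb <- as.integer(df$rb)
  df$hba <- as.integer(df$hba)
  df$hbd <- as.integer(df$hbd)
  df$passes <- df$mw <= thresholds[["mw"]] & df$rb <= thresholds[["rb"]] &
    df$tpsa <= thresholds[["tpsa"]] & df$logp <= thresholds[["logp"]] &
    df$hba <= thresholds[["hba"]] & df$hbd <= thresholds[["hbd"]]
  df
}

#' Filter a fragment collection by the rule of three
#'
#' @param fragments a `fragment_library` (occurrence data preserved) or a
#'   character vector of SMILES.
#' @param thresholds see [ro3_profile()].
#' @return The passing subset, with attributes `n_input`, `n_pass` and
#'   `pass_rate` (percentage to one decimal; `NA` for empty input).
#' @export
filter_ro3 <- function(fragments, thresholds = RO3_THRESHOLDS) {
  smiles <- if (is.character(fragments)) fragments
            else fragments$canonical_smiles
  if (length(smiles) == 0L) {
    out <- fragments
    attr(out, "n_input") <- 0L
    attr(out, "n_pass") <- 0L
    attr(out, "pass_rate") <- NA_real_
    return(out)
  }
  prof <- ro3_profile(smiles, thresholds)
  out <- if (is.character(fragments)) fragments[prof$passes]
         else fragments[prof$passes, , drop = FALSE]
  if (is.data.frame(out)) rownames(out) <- NULL
  attr(out, "n_input") <- length(smiles)
  attr(out, "n_pass") <- sum(prof$passes)
  attr(out, "pass_rate") <- round(100 * sum(prof$passes) / length(smiles),
                                  1)
  # keep library metadata
  for (a in c("class", "name")) {
    if (!is.null(attr(fragments, a))) attr(out, a) <- attr(fragments, a)
  }
  out
}

#' Constitutional and complexity descriptor profile
#'
#' The 18-descriptor panel: C/O/N atom counts and heavy-atom fractions,
#' fraction of sp3 carbons, fraction of carbons that are (assigned or
#' unassigned) tetrahedral stereocentres, molecular weight, heavy atoms,
#' and ring counts (SSSR; a ring is aromatic when every bond is aromatic;
#' a heterocycle contains at least one non-carbon ring atom) plus spiro and
#' bridgehead atom counts.
#'
#' @param smiles character vector of standardized SMILES.
#' @return Data frame with one row per molecule and the 18 panel columns.
#' @examples
#' \dontrun{
#' descriptor_profile("C1CC2CCC1C2")  # norbornane: 2 bridgehead atoms
#' }
#' @export
descriptor_profile <- function(smiles) {
  if (inherits(smiles, "fragment_library") ||
      inherits(smiles, "molecule_library")) {
    smiles <- smiles$canonical_smiles
  }
  descriptor_table(smiles)[, DESCRIPTOR_PANEL]
}

#' Per-library descriptor means
#'
#' Arithmetic mean of each panel descriptor over unique structures (not
#' occurrence-weighted), mirroring a library-comparison summary table.
#'
#' @param molecules character vector of SMILES, or a library object.
#' @return Data frame with columns `descriptor` and `mean`, in panel order.
#' @export
library_descriptor_summary <- function(molecules) {
  if (inherits(molecules, "fragment_library") ||
      inherits(molecules, "molecule_library")) {
    molecules <- molecules$canonical_smiles
  }
  molecules <- unique(molecules)
  if (length(molecules) == 0L) stop("empty collection")
  prof <- descriptor_profile(molecules)
  data.frame(descriptor = DESCRIPTOR_PANEL,
             mean = vapply(prof, mean, 0)[DESCRIPTOR_PANEL],
             row.names = NULL, stringsAsFactors = FALSE)
}
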