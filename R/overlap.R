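# Inter-library overlap, frequency tables, and Bemis-Murcko scaffold
# censuses.

library_keys <- function(x) {
  if (is.character(x)) unique(x)
  else unique(x$canonical_smiles)
}

library_name <- function(x, default) {
  nm <- attr(x, "name", exact = TRUE)
  if (is.null(nm) || !nzchar(nm)) default else nm
}

#' Unique and overlapping structures between two libraries
#'
#' Libraries are intersected on their standardized, stereochemistry-aware
#' canonical SMILES. Percentages are computed against the owning library's
#' unique-structure count.
#'
#' @param lib_a,lib_b standardized libraries (`fragment_library`,
#'   `molecule_library` or character vectors of canonical SMILES).
#' @param name_a,name_b display names (default: library attributes).
#' @param stereo if `FALSE`, keys are compared after stripping stereo
#'   annotations (reported separately, never mixed with the default).
#' @return An `overlap_result` list: `name_a`, `name_b`, `n_a`, `n_b`,
#'   `n_shared`, `unique_a`, `unique_b`, `pct_unique_a`, `pct_unique_b`,
#'   `pct_shared_a`, `pct_shared_b`, `shared` (the intersection keys).
#' @export
overlap <- function(lib_a, lib_b, name_a = NULL, name_b = NULL,
                    stereo = TRUE) {
  a <- library_keys(lib_a)
  b <- library_keys(lib_b)
  if (!stereo) {
    a <- unique(strip_stereo(a))
    b <- unique(strip_stereo(b))
  }
  shared <- intersect(a, b)
  res <- list(
    name_a = if (is.null(name_a)) library_name(lib_a, "A") else name_a,
    name_b = if (is.null(name_b)) library_name(lib_b, "B") else name_b,
    n_a = length(a), n_b = length(b), n_shared = length(shared),
    unique_a = length(a) - length(shared),
    unique_b = length(b) - length(shared),
    pct_unique_a = 100 * (length(a) - length(shared)) / max(length(a), 1L),
    pct_unique_b = 100 * (length(b) - length(shared)) / max(length(b), 1L),
    pct_shared_a = 100 * length(shared) / max(length(a), 1L),
    pct_shared_b = 100 * length(shared) / max(length(b), 1L),
    stereo = stereo,
    shared = shared)
  structure(res, class = "overlap_result")
}

strip_stereo <- function(smiles) {
  plain <- gsub("\\[([A-Za-z][a-z]?)@+H?\\]", "\\1", smiles)
  plain <- gsub("[/\\\\]", "", plain)
  res <- call_chemtools("parse", plain)
  vapply(seq_along(res), function(i) {
    if (isTRUE(res[[i]]$ok)) res[[i]]$canonical else smiles[[i]]
  }, "")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Overlap %s (n=%d) vs %s (n=%d)%s\n", x$name_a, x$n_a,
              x$name_b, x$n_b, if (x$stereo) "" else " [stereo-insensitive]"))
  cat(sprintf("  shared     : %d (%.2f%% of %s, %.2f%% of %s)\n",
              x$n_shared, x$pct_shared_a, x$name_a, x$pct_shared_b,
              x$name_b))
  cat(sprintf("  unique %-4s: %d (%.2f%%)\n", x$name_a, x$unique_a,
              x$pct_unique_a))
  cat(sprintf("  unique %-4s: %d (%.2f%%)\n", x$name_b, x$unique_b,
              x$pct_unique_b))
  invisible(x)
}

fragment_mw <- function(smiles) {
  desc <- call_chemtools("descriptors", smiles)
  vapply(desc, function(d) d$mw, 0)
}

#' Most-frequent-fragment table
#'
#' Ranks fragments by their percentage under the chosen denominator,
#' optionally restricted to a molecular-weight window. With denominator
#' `"occurrences"` a fragment's percentage is its occurrence count over
#' the library's total occurrences (so windowed percentages sum to at
#' most 100); with `"unique_fragments"` the denominator is the number of
#' unique fragments in the library. Ties are broken by canonical-string
#' order.
#'
#' @param fragments a `fragment_library` (or data frame with
#'   `canonical_smiles` and `occurrence`).
#' @param top_k keep the `top_k` most frequent entries (`NULL` = all).
#' @param mw_window optional `c(low, high)` daltons (inclusive).
#' @param denominator `"occurrences"` or `"unique_fragments"`.
#' @return A `frequency_table` data frame with `canonical_smiles`,
#'   `occurrence`, `percentage`; attributes record the denominator and
#'   window.
#' @export
frequency_table <- function(fragments, top_k = NULL, mw_window = NULL,
                            denominator = c("occurrences",
                                            "unique_fragments")) {
  denominator <- match.arg(denominator)
  df <- as.data.frame(fragments)[, c("canonical_smiles", "occurrence")]
  denom <- if (denominator == "occurrences") sum(df$occurrence)
           else nrow(df)
  if (!is.null(mw_window)) {
    stopifnot(length(mw_window) == 2L, mw_window[1] <= mw_window[2])
    if (nrow(df)) {
      mw <- fragment_mw(df$canonical_smiles)
      df <- df[mw >= mw_window[1] & mw <= mw_window[2], , drop = FALSE]
    }
  }
  df$percentage <- if (denom > 0) 100 * df$occurrence / denom else numeric(nrow(df))
  ord <- order(-df$percentage, df$canonical_smiles)
  df <- df[ord, , drop = FALSE]
  if (!is.null(top_k)) df <- head(df, top_k)
  rownames(df) <- NULL
  structure(df, class = c("frequency_table", "data.frame"),
            denominator = denominator, mw_window = mw_window)
}

#' Common-fragment frequency table for two libraries
#'
#' Restricts both collections to their intersection and reports each
#' shared fragment with its percentage in either library (same
#' denominator convention as [frequency_table()]). Entries are ranked by
#' the first library's percentage.
#'
#' @param frags_a,frags_b `fragment_library` objects.
#' @inheritParams frequency_table
#' @return Data frame with `canonical_smiles`, `percentage_a`,
#'   `percentage_b`, `occurrence_a`, `occurrence_b`.
#' @export
common_frequency_table <- function(frags_a, frags_b, top_k = NULL,
                                   mw_window = NULL,
                                   denominator = c("occurrences",
                                                   "unique_fragments")) {
  denominator <- match.arg(denominator)
  ta <- frequency_table(frags_a, top_k = NULL, mw_window = mw_window,
                        denominator = denominator)
  tb <- frequency_table(frags_b, top_k = NULL, mw_window = mw_window,
                        denominator = denominator)
  shared <- intersect(ta$canonical_smiles, tb$canonical_smiles)
  ia <- match(shared, ta$canonical_smiles)
  ib <- match(shared, tb$canonical_smiles)
  df <- data.frame(canonical_smiles = shared,
                   percentage_a = ta$percentage[ia],
                   percentage_b = tb$percentage[ib],
                   occurrence_a = ta$occurrence[ia],
                   occurrence_b = tb$occurrence[ib],
                   stringsAsFactors = FALSE)
  ord <- order(-df$percentage_a, df$canonical_smiles)
  df <- df[ord, , drop = FALSE]
  if (!is.null(top_k)) df <- head(df, top_k)
  rownames(df) <- NULL
  df
}

#' Bemis-Murcko scaffold census
#'
#' Extracts the atom-typed Bemis-Murcko scaffold (ring systems plus the
#' linkers connecting them, side chains removed) of every molecule;
#' acyclic molecules contribute no scaffold. Scaffolds are classified as
#' non-heterocyclic (no ring heteroatom), nitrogen-containing (any
#' nitrogen in the scaffold, ring or linker) and fused (at least two
#' rings sharing an atom, which includes ortho-fused, bridged and spiro
#' systems; a strict ortho-fused count — sharing a bond — is also
#' reported).
#'
#' @param molecules SMILES vector or library object.
#' @return A `scaffold_summary` list: `n_molecules`, `n_acyclic`,
#'   `n_distinct`, `frequency` (data frame scaffold/count),
#'   `n_nonheterocyclic`, `n_nitrogen_containing`, `n_fused`,
#'   `n_ortho_fused`.
#' @export
scaffold_summary <- function(molecules) {
  if (inherits(molecules, "fragment_library") ||
      inherits(molecules, "molecule_library")) {
    molecules <- molecules$canonical_smiles
  }
  molecules <- unique(molecules)
  res <- call_chemtools("scaffolds", molecules)
  bad <- vapply(res, is.null, TRUE)
  if (any(bad)) stop("unparsable SMILES in scaffold input")
  scaf <- vapply(res, function(r) null2na(r$scaffold), NA_character_)
  has <- !is.na(scaf)
  rows <- res[has]
  tab <- table(scaf[has])
  uniq <- names(tab)
  first <- rows[match(uniq, scaf[has])]
  info <- data.frame(
    scaffold = uniq,
    count = as.integer(tab),
    heterocyclic = vapply(first, `[[`, TRUE, "has_ring_heteroatom"),
    nitrogen = vapply(first, `[[`, TRUE, "has_nitrogen"),
    fused = vapply(first, `[[`, TRUE, "fused"),
    ortho_fused = vapply(first, `[[`, TRUE, "ortho_fused"),
    stringsAsFactors = FALSE)
  info <- info[order(-info$count, info$scaffold), , drop = FALSE]
  rownames(info) <- NULL
  structure(list(
    n_molecules = length(molecules),
    n_acyclic = sum(!has),
    n_distinct = nrow(info),
    frequency = info,
    n_nonheterocyclic = sum(!info$heterocyclic),
    n_nitrogen_containing = sum(info$nitrogen),
    n_fused = sum(info$fused),
    n_ortho_fused = sum(info$ortho_fused)),
    class = "scaffold_summary")
}

#' @export
print.scaffold_summary <- function(x, ...) {
  cat(sprintf("Scaffold census: %d molecules -> %d distinct scaffolds (%d acyclic inputs)\n",
              x$n_molecules, x$n_distinct, x$n_acyclic))
  cat(sprintf("  non-heterocyclic    : %d\n", x$n_nonheterocyclic))
  cat(sprintf("  nitrogen-containing : %d\n", x$n_nitrogen_containing))
  cat(sprintf("  fused (incl. bridged/spiro): %d (ortho-fused %d)\n",
              x$n_fused, x$n_ortho_fused))
  invisible(x)
}
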