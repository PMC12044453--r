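# RECAP retrosynthetic decomposition.

#' The eleven RECAP cleavage rules
#'
#' Returns the rule table used by the decomposition engine: rule name and
#' the bond-environment pattern (SMARTS with the cleavable bond between the
#' atoms mapped `:1` and `:2`). Rules never cleave ring bonds.
#'
#' @return Data frame with columns `name` and `pattern`.
#' @export
recap_rules <- function() {
  res <- call_chemtools("recap_rules")
  data.frame(name = vapply(res, `[[`, "", "name"),
             pattern = vapply(res, `[[`, "", "pattern"),
             stringsAsFactors = FALSE)
}

#' Find RECAP-cleavable bonds
#'
#' Lists every acyclic bond of each molecule that matches the environment
#' of one of the eleven cleavage rules. A bond matched by several rules is
#' reported once per rule. Atom indices are 0-based positions in the
#' canonical atom order of the parsed input.
#'
#' @param smiles character vector of standardized SMILES.
#' @return A data frame with columns `molecule` (input index), `bond`
#'   (bond index), `a1`, `a2` (atom indices) and `rule`.
#' @examples
#' \dontrun{
#' find_cleavable_bonds("CC(=O)Nc1ccccc1")  # one amide bond
#' }
#' @export
find_cleavable_bonds <- function(smiles) {
  res <- call_chemtools("recap_bonds", smiles)
  rows <- lapply(seq_along(res), function(i) {
    ri <- res[[i]]
    if (is.null(ri)) stop("unparsable SMILES at position ", i)
    if (length(ri) == 0L) return(NULL)
    data.frame(molecule = i,
               bond = vapply(ri, `[[`, 0L, "bond"),
               a1 = vapply(ri, `[[`, 0L, "a1"),
               a2 = vapply(ri, `[[`, 0L, "a2"),
               rule = vapply(ri, `[[`, "", "rule"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(molecule = integer(), bond = integer(),
                      a1 = integer(), a2 = integer(), rule = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' RECAP-decompose molecules into leaf fragments
#'
#' Hierarchical decomposition: in each round all rule-matching bonds of a
#' fragment are cleaved simultaneously, the broken ends are capped with
#' hydrogen, and the resulting pieces are decomposed further until no rule
#' applies. Only the leaves are returned; a molecule with no cleavable bond
#' yields an empty set (the intact parent is not a fragment). Breaking all
#' matched bonds of a round at once makes the result independent of
#' cleavage order and conserves heavy atoms across the leaves.
#'
#' @param smiles character vector of standardized SMILES.
#' @param unique_leaves drop per-parent duplicate leaves (default `TRUE`,
#'   the "set" semantics; `FALSE` keeps site multiplicity).
#' @param order_seed optional integer; shuffles the internal bond-breaking
#'   order (the result must not depend on it — used by invariance tests).
#' @return A list (one element per input) of character vectors of canonical
#'   leaf SMILES.
#' @examples
#' \dontrun{
#' recap_decompose("c1ccc(-c2ccccc2)cc1")  # list("c1ccccc1")
#' }
#' @export
recap_decompose <- function(smiles, unique_leaves = TRUE,
                            order_seed = NULL) {
  res <- call_chemtools("recap", smiles,
                        options = list(order_seed = order_seed))
  lapply(seq_along(res), function(i) {
    ri <- res[[i]]
    if (is.null(ri)) stop("unparsable SMILES at position ", i)
    leaves <- as.character(unlist(ri))
    if (unique_leaves) unique(leaves) else leaves
  })
}

#' Fragment a standardized library
#'
#' Applies [recap_decompose()] to every parent below the molecular-weight
#' cutoff, re-standardizes each leaf with the curation protocol, and
#' aggregates leaves by canonical SMILES with occurrence counts.
#'
#' @param records a deduplicated `molecule_library` (standardized), or a
#'   character vector of canonical SMILES.
#' @param mw_cutoff parents with molecular weight `>= mw_cutoff` daltons
#'   are skipped (default 1000, strict less-than is fragmented).
#' @param count_sites if `TRUE`, a parent containing a fragment at several
#'   sites contributes that many occurrences; default counts each parent
#'   once per unique fragment.
#' @return A `fragment_library` data frame with columns `canonical_smiles`,
#'   `occurrence`, `n_parents`, `parents` (comma-separated source ids) and
#'   `rules_applied`; attributes `n_parents_total`, `n_skipped_mw`,
#'   `n_parents_fragmented` and `name` record the attrition.
#' @export
fragment_library <- function(records, mw_cutoff = 1000,
                             count_sites = FALSE) {
  if (is.character(records)) {
    records <- new_molecule_library(sprintf("mol%05d", seq_along(records)),
                                    records, canonical_smiles = records,
                                    status = "standardized")
  }
  smiles <- records$canonical_smiles
  ids <- records$source_id
  desc <- call_chemtools("descriptors", smiles)
  mw <- vapply(desc, function(d) d$mw, 0)
  keep <- mw < mw_cutoff
  n_skip <- sum(!keep)

  leaves <- if (any(keep)) {
    recap_decompose(smiles[keep], unique_leaves = !count_sites)
  } else list()
  bonds <- if (any(keep)) find_cleavable_bonds(smiles[keep]) else NULL

  raw <- unlist(leaves, use.names = FALSE)
  if (is.null(raw) || length(raw) == 0L) {
    out <- data.frame(canonical_smiles = character(),
                      occurrence = integer(), n_parents = integer(),
                      parents = character(), rules_applied = character(),
                      stringsAsFactors = FALSE)
    return(structure(out, class = c("fragment_library", "data.frame"),
                     n_parents_total = nrow(records),
                     n_skipped_mw = n_skip,
                     n_parents_fragmented = sum(lengths(leaves) > 0),
                     name = attr(records, "name", exact = TRUE)))
  }

  # re-standardize the unique leaf strings once, then map back
  uniq <- unique(raw)
  std <- standardize_molecule(uniq)
  ok <- std$status == "standardized"
  leaf_map <- setNames(std$canonical_smiles, uniq)

  kept_ids <- ids[keep]
  parent_rules <- if (!is.null(bonds) && nrow(bonds)) {
    tapply(bonds$rule, bonds$molecule,
           function(r) paste(sort(unique(r)), collapse = "|"))
  } else NULL

  rows <- lapply(seq_along(leaves), function(i) {
    lv <- leaf_map[leaves[[i]]]
    lv <- lv[!is.na(lv)]
    if (length(lv) == 0L) return(NULL)
    if (!count_sites) lv <- unique(lv)
    data.frame(canonical_smiles = as.character(lv),
               parent = kept_ids[i],
               rules = if (!is.null(parent_rules))
                 parent_rules[[as.character(i)]] else "",
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)

  agg_occ <- tapply(long$parent, long$canonical_smiles, length)
  agg_par <- tapply(long$parent, long$canonical_smiles,
                    function(p) paste(unique(p), collapse = ","))
  agg_rul <- tapply(long$rules, long$canonical_smiles, function(r) {
    paste(sort(unique(unlist(strsplit(r, "|", fixed = TRUE)))),
          collapse = "|")
  })
  key <- sort(names(agg_occ))
  out <- data.frame(canonical_smiles = key,
                    occurrence = as.integer(agg_occ[key]),
                    n_parents = vapply(strsplit(agg_par[key], ","),
                                       function(p) length(unique(p)), 0L),
                    parents = as.character(agg_par[key]),
                    rules_applied = as.character(agg_rul[key]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("fragment_library", "data.frame"),
            n_parents_total = nrow(records),
            n_skipped_mw = n_skip,
            n_parents_fragmented = sum(lengths(leaves) > 0),
            n_leaf_rejected = sum(!ok),
            name = attr(records, "name", exact = TRUE))
}

#' @export
print.fragment_library <- function(x, ...) {
  cat(sprintf("<fragment_library%s: %d unique fragments from %s parents (%s skipped by MW cutoff)>\n",
              if (!is.null(attr(x, "name", exact = TRUE))) paste0(" ", attr(x, "name", exact = TRUE))
              else "",
              nrow(x), null2na(attr(x, "n_parents_total")),
              null2na(attr(x, "n_skipped_mw"))))
  print.data.frame(head(as.data.frame(x)[, c("canonical_smiles",
                                             "occurrence", "n_parents")],
                        10L))
  invisible(x)
}
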