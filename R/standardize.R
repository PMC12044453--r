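# Curation protocol: element whitelist, largest component, reionization,
# neutralization, canonical tautomer, deduplication.

#' The 13-element whitelist used by the curation protocol
#'
#' Structures are kept only if every atom is H, B, C, N, O, F, Si, P, S,
#' Cl, Se, Br or I.
#' @export
ELEMENT_WHITELIST <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                       "Cl", "Se", "Br", "I")

#' Check a structure against the element whitelist
#'
#' The check is applied to the molecule as read, before any multi-component
#' splitting, so a non-whitelisted counterion rejects the whole input.
#'
#' @param smiles character vector of SMILES strings.
#' @return Logical vector; `NA` for unparsable input.
#' @examples
#' \dontrun{
#' check_elements(c("CCO", "CC(=O)[O-].[Na+]", "C[Si](C)(C)O"))
#' }
#' @export
check_elements <- function(smiles) {
  res <- call_chemtools("elements", smiles)
  vapply(res, function(el) {
    if (is.null(el)) return(NA)
    all(unlist(el) %in% ELEMENT_WHITELIST)
  }, logical(1))
}

#' Standardize molecules
#'
#' Applies the curation protocol to each structure, in order: (1) element
#' whitelist check, (2) split multi-component inputs and keep the component
#' with the most heavy atoms (ties: higher molecular weight, then smallest
#' canonical string), (3) reionize, (4) neutralize charges (quaternary
#' nitrogens keep their charge), (5) generate a canonical tautomer from a
#' deterministic scored enumeration capped at `max_tautomers`, (6) emit the
#' stereochemistry-aware canonical SMILES. If tautomer enumeration fails or
#' exceeds its cap, the pre-tautomer canonical form is kept and flagged.
#'
#' @param smiles character vector (or a `molecule_library`, whose raw
#'   strings are used).
#' @param element_stage apply the element filter before (`"pre_split"`,
#'   default) or after (`"post_split"`) component splitting.
#' @param max_tautomers cap on the tautomer enumeration.
#' @return A data frame with columns `canonical_smiles`, `status`
#'   (`"standardized"`/`"rejected"`), `rejection_reason` and
#'   `tautomer_fallback`.
#' @examples
#' \dontrun{
#' standardize_molecule(c("CCO", "CCO.Cl", "CC(=O)[O-]"))
#' }
#' @export
standardize_molecule <- function(smiles, element_stage = c("pre_split",
                                                           "post_split"),
                                 max_tautomers = 1000L) {
  element_stage <- match.arg(element_stage)
  if (inherits(smiles, "molecule_library")) smiles <- smiles$raw_smiles
  res <- call_chemtools("standardize", smiles,
                        options = list(element_stage = element_stage,
                                       max_tautomers = max_tautomers))
  data.frame(
    canonical_smiles = vapply(res, function(r) null2na(r$canonical),
                              NA_character_),
    status = vapply(res, `[[`, "", "status"),
    rejection_reason = vapply(res, function(r) null2na(r$reason),
                              NA_character_),
    tautomer_fallback = vapply(res, `[[`, FALSE, "tautomer_fallback"),
    stringsAsFactors = FALSE)
}

#' Standardize and deduplicate a library
#'
#' Runs [standardize_molecule()] over all records, then retains unique
#' structures keyed on the canonical SMILES. The occurrence multiplicity
#' before deduplication is recorded on each surviving record (first
#' occurrence wins; its `source_id` is kept).
#'
#' @param records a `molecule_library` from [read_library()] or a character
#'   vector of SMILES.
#' @param ... passed to [standardize_molecule()].
#' @return A list with `records` (deduplicated `molecule_library`) and
#'   `report` (a `standardization_report`).
#' @export
standardize_library <- function(records, ...) {
  if (is.character(records)) {
    records <- new_molecule_library(sprintf("mol%05d", seq_along(records)),
                                    records)
  }
  stopifnot(inherits(records, "molecule_library"))
  n_input <- nrow(records)
  todo <- records$status != "rejected"
  std <- if (any(todo)) standardize_molecule(records$raw_smiles[todo], ...)
         else standardize_molecule(character())

  out <- records
  out$canonical_smiles[todo] <- std$canonical_smiles
  out$status[todo] <- std$status
  out$rejection_reason[todo] <- std$rejection_reason

  stage_log <- data.frame(source_id = records$source_id,
                          status = out$status,
                          reason = out$rejection_reason,
                          stringsAsFactors = FALSE)

  keep <- out$status == "standardized"
  acc <- out[keep, , drop = FALSE]
  mult <- table(acc$canonical_smiles)
  first <- !duplicated(acc$canonical_smiles)
  dedup <- acc[first, , drop = FALSE]
  dedup$multiplicity <- as.integer(mult[dedup$canonical_smiles])
  rownames(dedup) <- NULL
  dedup <- structure(dedup, class = class(records),
                     name = attr(records, "name", exact = TRUE),
                     role = attr(records, "role"))

  report <- structure(list(
    n_input = n_input,
    n_rejected_parse = sum(out$rejection_reason %in% "parse_error"),
    n_rejected_elements = sum(out$rejection_reason %in% "element_violation"),
    n_rejected_other = sum(out$status == "rejected" &
                             !out$rejection_reason %in%
                             c("parse_error", "element_violation")),
    n_standardized = sum(keep),
    n_after_dedup = nrow(dedup),
    n_tautomer_fallback = sum(std$tautomer_fallback),
    stage_log = stage_log), class = "standardization_report")

  list(records = dedup, report = report)
}

#' @export
print.standardization_report <- function(x, ...) {
  cat("Standardization report\n")
  cat(sprintf("  input records        : %d\n", x$n_input))
  cat(sprintf("  rejected (parse)     : %d\n", x$n_rejected_parse))
  cat(sprintf("  rejected (elements)  : %d\n", x$n_rejected_elements))
  cat(sprintf("  rejected (other)     : %d\n", x$n_rejected_other))
  cat(sprintf("  standardized         : %d\n", x$n_standardized))
  cat(sprintf("  unique after dedup   : %d\n", x$n_after_dedup))
  if (x$n_tautomer_fallback > 0) {
    cat(sprintf("  tautomer fallbacks   : %d\n", x$n_tautomer_fallback))
  }
  invisible(x)
}
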