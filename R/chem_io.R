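# Reading/writing compound libraries and the named-library registry.

LIBRARY_ROLES <- c("natural_product", "synthetic_fragment",
                   "vendor_fragment", "generated")
LIBRARY_FORMATS <- c("smiles_table", "sdf")

#' Describe one named library
#'
#' A registry entry names a compound library, assigns it a role in the
#' comparative analysis and records where and in which format it is stored.
#'
#' @param name short unique identifier.
#' @param role one of `"natural_product"`, `"synthetic_fragment"`,
#'   `"vendor_fragment"`, `"generated"`.
#' @param path file location.
#' @param format `"smiles_table"` (delimited text, structure column first
#'   unless a header names the columns) or `"sdf"` (V2000).
#' @return A `library_entry` object.
#' @export
library_entry <- function(name, role, path, format = "smiles_table") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  role <- match.arg(role, LIBRARY_ROLES)
  format <- match.arg(format, LIBRARY_FORMATS)
  structure(list(name = name, role = role, path = path, format = format),
            class = "library_entry")
}

#' Read or write a registry of named libraries
#'
#' The registry is a plain key-value (DCF) file with one block per library
#' holding the `library_entry` fields. Names must be unique.
#'
#' @param path registry file.
#' @param entries list of [library_entry()] objects (for writing).
#' @return `read_registry()` returns a named list of `library_entry`
#'   objects; `write_registry()` returns `path` invisibly.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  blocks <- read.dcf(path)
  entries <- lapply(seq_len(nrow(blocks)), function(i) {
    row <- as.list(blocks[i, ])
    library_entry(row$name, row$role, row$path,
                  if (is.null(row$format) || is.na(row$format))
                    "smiles_table" else row$format)
  })
  names(entries) <- vapply(entries, `[[`, "", "name")
  if (anyDuplicated(names(entries))) {
    stop("duplicate library names in registry: ",
         paste(unique(names(entries)[duplicated(names(entries))]),
               collapse = ", "))
  }
  entries
}

#' @rdname read_registry
#' @export
write_registry <- function(entries, path) {
  if (inherits(entries, "library_entry")) entries <- list(entries)
  nm <- vapply(entries, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate library names")
  mat <- do.call(rbind, lapply(entries, function(e) {
    c(name = e$name, role = e$role, path = e$path, format = e$format)
  }))
  write.dcf(mat, path)
  invisible(path)
}

new_molecule_library <- function(source_id, raw_smiles,
                                 canonical_smiles = NA_character_,
                                 status = "pending",
                                 rejection_reason = NA_character_,
                                 multiplicity = NA_integer_,
                                 name = NULL, role = NULL) {
  n <- length(source_id)
  df <- data.frame(source_id = as.character(source_id),
                   raw_smiles = as.character(raw_smiles),
                   canonical_smiles = rep_len(canonical_smiles, n),
                   status = rep_len(status, n),
                   rejection_reason = rep_len(rejection_reason, n),
                   multiplicity = rep_len(multiplicity, n),
                   stringsAsFactors = FALSE)
  structure(df, class = c("molecule_library", "data.frame"),
            name = name, role = role)
}

#' @export
print.molecule_library <- function(x, ...) {
  nm <- attr(x, "name", exact = TRUE)
  cat(sprintf("<molecule_library%s: %d records (%d standardized, %d rejected, %d pending)>\n",
              if (!is.null(nm)) paste0(" ", nm) else "", nrow(x),
              sum(x$status == "standardized"), sum(x$status == "rejected"),
              sum(x$status == "pending")))
  print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

detect_delimiter <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  probe <- head(lines, 50L)
  counts <- vapply(c(tab = "\t", comma = ","), function(d) {
    sum(vapply(probe, function(l) lengths(regmatches(l, gregexpr(d, l, fixed = TRUE))), 1L))
  }, numeric(1))
  if (counts[["tab"]] > 0) "\t" else if (counts[["comma"]] > 0) "," else " "
}

read_smiles_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty library file: ", path)
    return(data.frame(id = character(), smiles = character(),
                      stringsAsFactors = FALSE))
  }
  delim <- detect_delimiter(lines)
  tab <- utils::read.table(text = lines, sep = delim, header = FALSE,
                           quote = "", comment.char = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE, fill = TRUE)
  smi_col <- 1L
  id_col <- if (ncol(tab) >= 2L) 2L else NA_integer_
  hdr <- tolower(trimws(as.character(tab[1L, ])))
  named_smi <- match(TRUE, hdr %in% c("smiles", "structure", "canonical_smiles"))
  if (!is.na(named_smi)) {
    smi_col <- named_smi
    named_id <- match(TRUE, hdr %in% c("id", "name", "identifier", "source_id"))
    id_col <- if (!is.na(named_id)) named_id else id_col
    if (identical(id_col, smi_col)) id_col <- NA_integer_
    tab <- tab[-1L, , drop = FALSE]
  }
  smiles <- trimws(tab[[smi_col]])
  ids <- if (!is.na(id_col)) trimws(tab[[id_col]]) else rep("", nrow(tab))
  blank <- !nzchar(ids)
  ids[blank] <- sprintf("mol%05d", which(blank))
  data.frame(id = ids, smiles = smiles, stringsAsFactors = FALSE)
}

#' Read a compound library
#'
#' Reads a library into a collection of molecule records. Every input
#' row/molecule yields exactly one record, in input order: parsable
#' structures come back with status `"pending"`, unparsable ones with
#' status `"rejected"` and reason `"parse_error"` (never silently dropped).
#'
#' @param entry a [library_entry()], or a path (read as a SMILES table).
#' @return A `molecule_library` data frame with columns `source_id`,
#'   `raw_smiles`, `canonical_smiles`, `status`, `rejection_reason`,
#'   `multiplicity`.
#' @examples
#' \dontrun{
#' tf <- tempfile(fileext = ".smi")
#' writeLines(c("CCO eth-1", "c1ccccc1 bz-1"), tf)
#' read_library(library_entry("demo", "generated", tf))
#' }
#' @export
read_library <- function(entry) {
  if (is.character(entry)) {
    entry <- library_entry(basename(entry), "generated", entry)
  }
  stopifnot(inherits(entry, "library_entry"))
  if (!file.exists(entry$path)) {
    stop("library file not found: ", entry$path)
  }
  if (entry$format == "smiles_table") {
    tab <- read_smiles_table(entry$path)
    ids <- tab$id
    smiles <- tab$smiles
    ok <- if (nrow(tab)) {
      vapply(call_chemtools("parse", smiles), `[[`, TRUE, "ok")
    } else logical(0)
  } else {
    res <- call_chemtools("sdf_read", options = list(path = entry$path))
    if (length(res) == 0L) warning("empty library file: ", entry$path)
    ids <- vapply(res, `[[`, "", "id")
    smiles <- vapply(res, function(r) null2na(r$smiles), NA_character_)
    ok <- vapply(res, `[[`, TRUE, "ok")
    smiles[!ok] <- ""
  }
  new_molecule_library(
    source_id = ids, raw_smiles = smiles,
    status = ifelse(ok, "pending", "rejected"),
    rejection_reason = ifelse(ok, NA_character_, "parse_error"),
    name = entry$name, role = entry$role)
}

#' Write a compound library
#'
#' Writes records to a SMILES table (tab-separated, with header) or an SDF
#' file. Standardized records are written with their canonical string, other
#' records with the raw input string, so that a read/write round trip
#' preserves canonical structures. Tabs and newlines in identifiers are
#' escaped in the tabular format.
#'
#' @param records a `molecule_library` (or data frame with `source_id` and
#'   a structure column).
#' @param path output file.
#' @param format `"smiles_table"` or `"sdf"`.
#' @return `path`, invisibly.
#' @export
write_library <- function(records, path, format = "smiles_table") {
  format <- match.arg(format, LIBRARY_FORMATS)
  smi <- ifelse(!is.na(records$canonical_smiles),
                records$canonical_smiles, records$raw_smiles)
  ids <- gsub("[\t\r\n]", " ", records$source_id)
  if (format == "smiles_table") {
    df <- data.frame(smiles = smi, id = ids, stringsAsFactors = FALSE)
    if ("multiplicity" %in% names(records) &&
        any(!is.na(records$multiplicity))) {
      df$multiplicity <- records$multiplicity
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    call_chemtools("sdf_write", smi,
                   options = list(path = path, ids = as.list(ids)))
  }
  invisible(path)
}
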