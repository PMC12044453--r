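#' @keywords internal
"_PACKAGE"

#' @importFrom jsonlite fromJSON toJSON write_json read_json
#' @importFrom stats median quantile rbinom rpois runif setNames
#' @importFrom utils read.table write.table head packageVersion
NULL

the <- new.env(parent = emptyenv())

#' Locate the Python interpreter used by the chemistry backend
#'
#' The backend requires a Python 3 interpreter with RDKit (and scikit-learn
#' for t-SNE). The interpreter is resolved once per session from, in order,
#' `options(fragcompare.python = ...)`, the `FRAGCOMPARE_PYTHON` environment
#' variable, and `python`/`python3` on the PATH.
#'
#' @return Path to the interpreter (character scalar).
#' @export
find_python <- function() {
  if (!is.null(the$python)) {
    return(the$python)
  }
  cand <- c(getOption("fragcompare.python", ""),
            Sys.getenv("FRAGCOMPARE_PYTHON", ""),
            Sys.which("python"), Sys.which("python3"))
  cand <- cand[nzchar(cand)]
  if (length(cand) == 0L) {
    stop("no python interpreter found; set options(fragcompare.python=)",
         call. = FALSE)
  }
  the$python <- cand[[1L]]
  the$python
}

chemtools_script <- function() {
  path <- system.file("python", "chemtools.py", package = "fragcompare")
  if (!nzchar(path)) {
    # running from a source checkout (e.g. pkgload)
    path <- file.path("inst", "python", "chemtools.py")
  }
  path
}

#' Call the chemistry backend
#'
#' Low-level JSON bridge to the bundled RDKit helper script. One process is
#' started per call, so callers batch all molecules of an operation into a
#' single invocation.
#'
#' @param cmd backend command name.
#' @param smiles character vector of SMILES strings (may be empty).
#' @param options named list of command options.
#' @param payload optional full payload overriding `smiles`/`options`.
#' @return Parsed JSON result (lists, not simplified).
#' @keywords internal
call_chemtools <- function(cmd, smiles = character(), options = list(),
                           payload = NULL) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  if (is.null(payload)) {
    payload <- list(smiles = as.list(as.character(smiles)),
                    options = options)
  }
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  err <- tempfile(fileext = ".txt")
  on.exit(unlink(err), add = TRUE)
  status <- system2(find_python(),
                    c(shQuote(chemtools_script()), cmd, shQuote(infile),
                      shQuote(outfile)),
                    stdout = FALSE, stderr = err)
  if (!identical(status, 0L)) {
    msg <- tryCatch(paste(readLines(err, warn = FALSE), collapse = "\n"),
                    error = function(e) "")
    stop(sprintf("chemistry backend '%s' failed (status %s):\n%s",
                 cmd, status, msg), call. = FALSE)
  }
  jsonlite::read_json(outfile, simplifyVector = FALSE)
}

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

null2na <- function(x) {
  if (is.null(x)) NA_character_ else as.character(x)
}
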