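# Ertl-Schuffenhauer synthetic accessibility score.

#' Score boundary conventionally separating "easy to synthesize"
#' structures (SA score <= 6) from difficult ones.
#' @export
SA_EASY_THRESHOLD <- 6

#' Synthetic accessibility score with its breakdown
#'
#' The score combines a fragment-contribution term (occurrence-weighted
#' mean of log-frequency contributions of radius-2 circular substructures,
#' looked up in the reference frequency table; substructures absent from
#' the table contribute the published default) and a complexity penalty
#' (molecular size, stereocentres, spiro atoms, bridgehead atoms,
#' macrocycles, less a symmetry correction for repeated environments).
#' The raw difference is mapped onto the 1-10 scale with the published
#' piecewise smoothing; 1 means easy to synthesize.
#'
#' @param smiles character vector of standardized SMILES.
#' @return Data frame with `fragment_score`, the individual penalty terms,
#'   `complexity_penalty`, `raw` (= `fragment_score - complexity_penalty`)
#'   and `score` in `[1, 10]`.
#' @examples
#' \dontrun{
#' sa_breakdown(c("CCO", "C1CC2(CCC1)CCC1(CCC2)CC1"))
#' }
#' @export
sa_breakdown <- function(smiles) {
  if (inherits(smiles, "fragment_library") ||
      inherits(smiles, "molecule_library")) {
    smiles <- smiles$canonical_smiles
  }
  res <- call_chemtools("sascore", smiles)
  bad <- vapply(res, is.null, TRUE)
  if (any(bad)) {
    stop("unparsable SMILES at position(s) ",
         paste(which(bad), collapse = ", "))
  }
  cols <- c("fragment_score", "size_penalty", "stereo_penalty",
            "spiro_penalty", "bridge_penalty", "macrocycle_penalty",
            "symmetry_correction", "complexity_penalty", "raw", "score")
  as.data.frame(lapply(setNames(cols, cols), function(cn) {
    vapply(res, function(r) as.numeric(r[[cn]]), 0)
  }))
}

#' Library-level synthetic accessibility summary
#'
#' @param molecules character vector of SMILES or a library object; only
#'   unique structures are scored.
#' @param threshold boundary for the "hard to synthesize" fraction
#'   (default [SA_EASY_THRESHOLD]).
#' @param bins number of histogram bins on `[1, 10]`.
#' @return A list of class `sa_summary`: `mean`, `n`, `n_above_threshold`,
#'   `fraction_above_threshold`, `threshold` and `histogram` (data frame of
#'   bin midpoints, counts and densities).
#' @export
library_sa_summary <- function(molecules, threshold = SA_EASY_THRESHOLD,
                               bins = 36L) {
  if (inherits(molecules, "fragment_library") ||
      inherits(molecules, "molecule_library")) {
    molecules <- molecules$canonical_smiles
  }
  molecules <- unique(molecules)
  if (length(molecules) == 0L) stop("empty collection")
  sc <- sa_breakdown(molecules)$score
  breaks <- seq(1, 10, length.out = bins + 1L)
  h <- graphics::hist(sc, breaks = breaks, plot = FALSE)
  structure(list(
    mean = mean(sc),
    n = length(sc),
    n_above_threshold = sum(sc > threshold),
    fraction_above_threshold = mean(sc > threshold),
    threshold = threshold,
    histogram = data.frame(mid = h$mids, count = h$counts,
                           density = h$density)),
    class = "sa_summary")
}

#' @export
print.sa_summary <- function(x, ...) {
  cat(sprintf("SA score summary: n = %d, mean = %.2f, %d (%.1f%%) above %s\n",
              x$n, x$mean, x$n_above_threshold,
              100 * x$fraction_above_threshold, format(x$threshold)))
  invisible(x)
}
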