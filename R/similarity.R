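# Fingerprints, Tanimoto similarity, and library diversity distributions.

FINGERPRINT_KINDS <- c("maccs166", "morgan2_1024", "morgan3_1024")

#' Compute binary fingerprints
#'
#' Supported kinds: `"maccs166"` (166 predefined substructure keys),
#' `"morgan2_1024"` and `"morgan3_1024"` (hashed circular environments of
#' radius 2/3 folded to 1024 bits). Fingerprints depend only on the
#' molecular graph, so two spellings of the same molecule give identical
#' bit vectors.
#'
#' @param smiles character vector of standardized SMILES.
#' @param kind fingerprint kind.
#' @return A `fingerprint_set`: list with `bits` (per-molecule integer
#'   vectors of 0-based on-bit positions), `nbits` and `kind`.
#' @export
fingerprint <- function(smiles, kind = FINGERPRINT_KINDS) {
  kind <- match.arg(kind)
  if (inherits(smiles, "fragment_library") ||
      inherits(smiles, "molecule_library")) {
    smiles <- smiles$canonical_smiles
  }
  res <- call_chemtools("fingerprints", smiles,
                        options = list(kind = kind))
  bits <- lapply(res$bits, function(b) {
    if (is.null(b)) stop("unparsable SMILES in fingerprint input")
    as.integer(unlist(b))
  })
  structure(list(bits = bits, nbits = as.integer(res$nbits), kind = kind),
            class = "fingerprint_set")
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat(sprintf("<fingerprint_set: %d molecules, %s (%d bits)>\n",
              length(x$bits), x$kind, x$nbits))
  invisible(x)
}

#' @export
length.fingerprint_set <- function(x) length(x$bits)

fp_subset <- function(fps, idx) {
  structure(list(bits = fps$bits[idx], nbits = fps$nbits, kind = fps$kind),
            class = "fingerprint_set")
}

#' Tanimoto similarity of two bit vectors
#'
#' `|a AND b| / |a OR b|` over the on-bits; defined as 1 when both vectors
#' are all-zero. Inputs are dense 0/1 (or logical) vectors of equal
#' length.
#'
#' @param a,b bit vectors.
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1))  # 2 shared / 4 union = 0.5
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("bit vectors differ in length")
  a <- as.logical(a)
  b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0L) return(1.0)
  sum(a & b) / un
}

# All pairwise Tanimoto similarities of a fingerprint set (upper triangle,
# column-major pair order), via sparse cross-products.
tanimoto_pairwise <- function(fps) {
  n <- length(fps$bits)
  if (n < 2L) stop("need at least 2 molecules")
  i <- rep.int(seq_len(n), lengths(fps$bits))
  j <- unlist(fps$bits, use.names = FALSE) + 1L
  x <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(n, fps$nbits))
  inter <- as.matrix(Matrix::tcrossprod(x))
  pop <- lengths(fps$bits)
  un <- outer(pop, pop, `+`) - inter
  sim <- ifelse(un == 0, 1, inter / pmax(un, 1))
  sim[upper.tri(sim)]
}

#' Subsampling scheme for large-library diversity
#'
#' Libraries larger than `trigger_size` are summarized from `n_subsets`
#' independent random subsets of `subset_size` structures (drawn without
#' replacement within a subset); pairwise similarities are computed within
#' each subset. Subset `i` uses seed `seed + i`.
#'
#' @param n_subsets number of subsets (default 10).
#' @param subset_size structures per subset (default 5000).
#' @param seed master seed.
#' @param trigger_size library size above which sampling replaces the
#'   exhaustive computation.
#' @return A `subsample_scheme` list.
#' @export
subsample_scheme <- function(n_subsets = 10L, subset_size = 5000L,
                             seed = 42L, trigger_size = 20000L) {
  structure(list(n_subsets = as.integer(n_subsets),
                 subset_size = as.integer(subset_size),
                 seed = as.integer(seed),
                 trigger_size = as.integer(trigger_size)),
            class = "subsample_scheme")
}

#' Pairwise Tanimoto diversity distribution of a library
#'
#' For libraries of at most `scheme$trigger_size` molecules all
#' `n (n - 1) / 2` pairwise similarities are computed; larger libraries
#' are summarized by the subsampling protocol of [subsample_scheme()].
#' The cumulative distribution is evaluated on a fixed 201-point grid.
#'
#' @param molecules SMILES vector, library object or `fingerprint_set`.
#' @param kind fingerprint kind (ignored if `molecules` is already a
#'   `fingerprint_set`).
#' @param scheme a [subsample_scheme()].
#' @return A `similarity_distribution`: `values` (pooled similarities),
#'   `median`, `quartiles`, `min`, `max`, `cdf` (grid data frame),
#'   `subset_medians` (`NULL` in exhaustive mode), `mode`, `n_molecules`,
#'   `n_pairs`, `fingerprint`.
#' @export
diversity_distribution <- function(molecules, kind = "morgan2_1024",
                                   scheme = subsample_scheme()) {
  fps <- if (inherits(molecules, "fingerprint_set")) molecules
         else fingerprint(molecules, kind)
  n <- length(fps$bits)
  if (n < 2L) stop("need at least 2 molecules")
  if (n <= scheme$trigger_size) {
    values <- tanimoto_pairwise(fps)
    mode <- "exhaustive"
    subset_medians <- NULL
  } else {
    values <- numeric(0)
    subset_medians <- numeric(scheme$n_subsets)
    for (i in seq_len(scheme$n_subsets)) {
      idx <- with_seed(scheme$seed + i,
                       sample.int(n, scheme$subset_size))
      vals_i <- tanimoto_pairwise(fp_subset(fps, idx))
      subset_medians[i] <- stats::median(vals_i)
      values <- c(values, vals_i)
    }
    mode <- "subsampled"
  }
  grid <- seq(0, 1, length.out = 201L)
  cdf <- stats::ecdf(values)(grid)
  structure(list(
    values = values,
    median = stats::median(values),
    quartiles = stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE),
    min = min(values), max = max(values),
    cdf = data.frame(similarity = grid, cumulative = cdf),
    subset_medians = subset_medians,
    mode = mode, n_molecules = n, n_pairs = length(values),
    fingerprint = fps$kind), class = "similarity_distribution")
}

#' @export
print.similarity_distribution <- function(x, ...) {
  cat(sprintf("<similarity_distribution: %s, %d molecules, %d pairs (%s), median %.3f>\n",
              x$fingerprint, x$n_molecules, x$n_pairs, x$mode, x$median))
  invisible(x)
}
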