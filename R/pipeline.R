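# End-to-end comparative pipeline: standardize -> fragment -> RO3 ->
# descriptors -> SA -> diversity -> overlap -> scaffolds -> embeddings.

#' Pipeline configuration
#'
#' All defaults equal the analysis' stated parameters: MW prefilter
#' 1000 Da, inclusive rule-of-three thresholds, ten subsets of 5000 for
#' large-library diversity, Morgan2/MACCS fingerprints, tree-map k = 50 /
#' kc = 10, t-SNE perplexity 40 with 300 iterations. The master seed fans
#' out to per-stage seeds by fixed offsets (+100 diversity, +200
#' embeddings).
#'
#' @param registry path to a registry file, or a named list of
#'   [library_entry()] objects.
#' @param out_dir output directory for the report bundle.
#' @param mw_cutoff parent molecular-weight cutoff (Da).
#' @param ro3 named thresholds, see [RO3_THRESHOLDS].
#' @param scheme a [subsample_scheme()].
#' @param fingerprints fingerprint kinds to use for diversity.
#' @param embedding_fingerprint fingerprint for the chemical-space maps.
#' @param tmap_k,tmap_kc tree-map neighbour parameters.
#' @param tsne_perplexity,tsne_n_iter t-SNE parameters.
#' @param sa_threshold "hard to synthesize" boundary.
#' @param mw_window window for the common-fragment tables (Da).
#' @param seed master seed.
#' @param embed run the embedding stage (the slowest part) or skip it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(registry, out_dir,
                            mw_cutoff = 1000,
                            ro3 = RO3_THRESHOLDS,
                            scheme = subsample_scheme(),
                            fingerprints = c("morgan2_1024", "maccs166"),
                            embedding_fingerprint = "maccs166",
                            tmap_k = 50L, tmap_kc = 10L,
                            tsne_perplexity = 40, tsne_n_iter = 300L,
                            sa_threshold = SA_EASY_THRESHOLD,
                            mw_window = c(70, 300),
                            seed = 42L, embed = TRUE) {
  if (is.character(registry)) registry <- read_registry(registry)
  structure(list(registry = registry, out_dir = out_dir,
                 mw_cutoff = mw_cutoff, ro3 = ro3, scheme = scheme,
                 fingerprints = fingerprints,
                 embedding_fingerprint = embedding_fingerprint,
                 tmap_k = tmap_k, tmap_kc = tmap_kc,
                 tsne_perplexity = tsne_perplexity,
                 tsne_n_iter = tsne_n_iter,
                 sa_threshold = sa_threshold, mw_window = mw_window,
                 seed = as.integer(seed), embed = embed),
            class = "pipeline_config")
}

write_csv <- function(df, path) {
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE)
  path
}

#' Run the comparative fragment-library pipeline
#'
#' Executes every stage for every registered library and writes a report
#' bundle to `config$out_dir`: per-library fragment files and RO3
#' subsets, an attrition table, pairwise overlap tables (fragments and
#' RO3 subsets), per-library descriptor means, SA summaries and
#' histograms, diversity CDFs with medians, scaffold censuses, embedding
#' coordinates and a JSON run manifest. Reruns with the same
#' configuration and seed produce byte-identical CSVs (timestamps appear
#' only in the manifest). Any stage failure aborts with the stage and
#' library name and leaves a `FAILED` marker in the bundle.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the per-library objects and the paths
#'   of the written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out, "FAILED")
  if (file.exists(marker)) unlink(marker)
  stage <- function(name, lib, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage=%s library=%s error=%s", name, lib,
                         conditionMessage(e)), marker)
      stop(sprintf("pipeline stage '%s' failed for library '%s': %s",
                   name, lib, conditionMessage(e)), call. = FALSE)
    })
  }
  logline <- function(...) message(sprintf(...))

  libs <- names(config$registry)
  std <- list(); frags <- list(); ro3 <- list()
  attrition <- list()
  artifacts <- character(0)

  for (nm in libs) {
    rec <- stage("read", nm, read_library(config$registry[[nm]]))
    s <- stage("standardize", nm, standardize_library(rec))
    std[[nm]] <- s$records
    logline("[%s] standardized: %d/%d", nm, nrow(s$records), nrow(rec))
    f <- stage("fragment", nm,
               fragment_library(s$records, mw_cutoff = config$mw_cutoff))
    frags[[nm]] <- f
    r3 <- stage("ro3", nm, filter_ro3(f, config$ro3))
    ro3[[nm]] <- r3
    attrition[[nm]] <- data.frame(
      library = nm,
      n_input = s$report$n_input,
      n_standardized = s$report$n_after_dedup,
      n_skipped_mw = attr(f, "n_skipped_mw"),
      n_fragments = nrow(f),
      n_fragments_ro3 = attr(r3, "n_pass"),
      ro3_pass_rate = attr(r3, "pass_rate"),
      stringsAsFactors = FALSE)
    fr_path <- file.path(out, paste0(nm, "_fragments.csv"))
    write_csv(as.data.frame(f)[, c("canonical_smiles", "occurrence",
                                   "n_parents")], fr_path)
    ro3_path <- file.path(out, paste0(nm, "_fragments_ro3.csv"))
    write_csv(as.data.frame(r3)[, c("canonical_smiles", "occurrence",
                                    "n_parents")], ro3_path)
    artifacts <- c(artifacts, fr_path, ro3_path)
  }

  attr_path <- write_csv(do.call(rbind, attrition),
                         file.path(out, "attrition.csv"))

  # descriptor means (fragments and RO3 subsets), table rows = descriptors
  desc_tab <- NULL
  for (nm in libs) {
    for (set in c("fragments", "ro3")) {
      obj <- if (set == "fragments") frags[[nm]] else ro3[[nm]]
      if (nrow(obj) == 0L) next
      ds <- stage("descriptors", nm, library_descriptor_summary(obj))
      col <- paste(nm, set, sep = ".")
      if (is.null(desc_tab)) {
        desc_tab <- ds
        names(desc_tab)[2] <- col
      } else {
        desc_tab[[col]] <- ds$mean
      }
    }
  }
  desc_path <- write_csv(desc_tab, file.path(out, "descriptor_means.csv"))

  sa_rows <- list()
  for (nm in libs) {
    if (nrow(frags[[nm]]) == 0L) next
    ss <- stage("sa_score", nm,
                library_sa_summary(frags[[nm]],
                                   threshold = config$sa_threshold))
    hist_path <- write_csv(ss$histogram,
                           file.path(out, paste0(nm, "_sa_hist.csv")))
    artifacts <- c(artifacts, hist_path)
    sa_rows[[nm]] <- data.frame(library = nm, n = ss$n,
                                mean_sa = ss$mean,
                                n_above = ss$n_above_threshold,
                                fraction_above = ss$fraction_above_threshold,
                                threshold = ss$threshold,
                                stringsAsFactors = FALSE)
  }
  sa_path <- write_csv(do.call(rbind, sa_rows),
                       file.path(out, "sa_summary.csv"))

  div_rows <- list()
  for (nm in libs) {
    if (nrow(frags[[nm]]) < 2L) next
    for (fpk in config$fingerprints) {
      scheme <- config$scheme
      scheme$seed <- config$seed + 100L
      dd <- stage("diversity", nm,
                  diversity_distribution(frags[[nm]], fpk, scheme))
      cdf_path <- write_csv(dd$cdf,
                            file.path(out, sprintf("%s_%s_cdf.csv", nm,
                                                   fpk)))
      artifacts <- c(artifacts, cdf_path)
      div_rows[[paste(nm, fpk)]] <- data.frame(
        library = nm, fingerprint = fpk, n = dd$n_molecules,
        n_pairs = dd$n_pairs, mode = dd$mode, median = dd$median,
        q1 = dd$quartiles[1], q3 = dd$quartiles[3],
        stringsAsFactors = FALSE)
    }
  }
  div_path <- write_csv(do.call(rbind, div_rows),
                        file.path(out, "diversity_medians.csv"))

  ov_rows <- list()
  for (set in c("fragments", "ro3")) {
    pool <- if (set == "fragments") frags else ro3
    for (a in seq_along(libs)) {
      for (b in seq_along(libs)) {
        if (a >= b) next
        ov <- stage("overlap", paste(libs[a], libs[b]),
                    overlap(pool[[libs[a]]], pool[[libs[b]]],
                            name_a = libs[a], name_b = libs[b]))
        ov_rows[[paste(set, a, b)]] <- data.frame(
          set = set, lib_a = ov$name_a, lib_b = ov$name_b,
          n_a = ov$n_a, n_b = ov$n_b, n_shared = ov$n_shared,
          unique_a = ov$unique_a, unique_b = ov$unique_b,
          pct_unique_a = round(ov$pct_unique_a, 1),
          pct_unique_b = round(ov$pct_unique_b, 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  ov_path <- write_csv(do.call(rbind, ov_rows),
                       file.path(out, "overlap.csv"))

  sc_rows <- list()
  for (nm in libs) {
    if (nrow(frags[[nm]]) == 0L) next
    sc <- stage("scaffolds", nm, scaffold_summary(frags[[nm]]))
    sc_rows[[nm]] <- data.frame(
      library = nm, n_distinct = sc$n_distinct,
      n_nonheterocyclic = sc$n_nonheterocyclic,
      n_nitrogen_containing = sc$n_nitrogen_containing,
      n_fused = sc$n_fused, n_ortho_fused = sc$n_ortho_fused,
      stringsAsFactors = FALSE)
  }
  sc_path <- write_csv(do.call(rbind, sc_rows),
                       file.path(out, "scaffolds.csv"))

  emb_paths <- character(0)
  if (isTRUE(config$embed)) {
    pool_smi <- unlist(lapply(libs, function(nm)
      ro3[[nm]]$canonical_smiles), use.names = FALSE)
    pool_lib <- rep(libs, vapply(libs, function(nm)
      nrow(ro3[[nm]]), 0L))
    keep <- !duplicated(pool_smi)
    pool_smi <- pool_smi[keep]; pool_lib <- pool_lib[keep]
    if (length(pool_smi) >= 5L) {
      fps <- stage("embed", "all",
                   fingerprint(pool_smi, config$embedding_fingerprint))
      g <- stage("embed", "all",
                 knn_graph(fps, k = config$tmap_k, kc = config$tmap_kc,
                           seed = config$seed + 200L))
      tm <- stage("embed", "all", tmap_layout(g))
      tm$coords$library <- pool_lib
      tm$coords$smiles <- pool_smi
      emb_paths <- c(emb_paths,
                     write_csv(tm$coords,
                               file.path(out, "tmap_coords.csv")),
                     write_csv(tm$edges,
                               file.path(out, "tmap_edges.csv")))
      ts <- stage("embed", "all",
                  suppressWarnings(
                    tsne_embed(fps, perplexity = config$tsne_perplexity,
                               n_iter = config$tsne_n_iter,
                               seed = config$seed + 200L)))
      ts$coords$library <- pool_lib
      ts$coords$smiles <- pool_smi
      emb_paths <- c(emb_paths,
                     write_csv(ts$coords,
                               file.path(out, "tsne_coords.csv")))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("fragcompare")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    stage_seeds = list(diversity = config$seed + 100L,
                       embedding = config$seed + 200L),
    parameters = list(mw_cutoff = config$mw_cutoff,
                      ro3 = as.list(config$ro3),
                      subsample = unclass(config$scheme),
                      fingerprints = config$fingerprints,
                      tmap = list(k = config$tmap_k, kc = config$tmap_kc),
                      tsne = list(perplexity = config$tsne_perplexity,
                                  n_iter = config$tsne_n_iter),
                      sa_threshold = config$sa_threshold),
    libraries = lapply(attrition, as.list))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(standardized = std, fragments = frags, ro3 = ro3,
                 artifacts = c(artifacts, attr_path, desc_path, sa_path,
                               div_path, ov_path, sc_path, emb_paths,
                               file.path(out, "manifest.json"))))
}
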