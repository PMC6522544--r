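#' Run the full TSS-centric methylation-expression analysis
#'
#' Orchestrates every stage on in-memory inputs (typically a
#' [simulate_cohort()] bundle or tables read with the package's readers):
#' window scoring, tumor and normal correlation maps, significant-
#' coordinate density profiles, the AUC-ratio permutation test, gene
#' selection with direction of methylation change, Ward subtype
#' clustering, and expression-quartile methylation meta-profiles. All
#' randomness flows from `seed`; reruns with identical inputs and seed
#' are bit-identical, and a manifest records the configuration hash and
#' per-stage row counts.
#'
#' @param genes,cgi,segments,expr,samples Input tables (see the reader
#'   and simulator documentation); `cgi` may be NULL to skip CGI
#'   stratification.
#' @param chrom_sizes Optional named chromosome lengths.
#' @param q_sig Significance threshold for density maps (default 0.05).
#' @param q_select Threshold for subtype gene selection (default 0.001).
#' @param n_perm Permutations for the shift test (default 1000).
#' @param k Number of methylation subtypes (default 3).
#' @param seed Integer seed.
#' @param ... Further arguments passed to [tss_shift_test()].
#' @return A `tss_pipeline` list: `windows`, `cm_tumor`, `cm_normal`,
#'   `densities`, `shift_test`, `selection`, `subtypes`, `quartiles`,
#'   `meta_profiles`, `manifest`.
#' @export
run_tss_pipeline <- function(genes, segments, expr, samples, cgi = NULL,
                             chrom_sizes = NULL, q_sig = 0.05,
                             q_select = 0.001, n_perm = 1000, k = 3,
                             seed = 1, ...) {
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  if (!is.null(cgi) && is.null(genes$is_cgi_gene)) {
    genes$is_cgi_gene <- classify_cgi_genes(genes, cgi)
  }
  windows <- stage("score", window_scores(segments, genes, chrom_sizes))
  cm_tumor <- stage("correlate-tumor",
                    build_correlation_map(windows, expr, samples, "tumor"))
  cm_normal <- stage("correlate-normal",
                     build_correlation_map(windows, expr, samples, "normal"))
  densities <- stage("density", {
    out <- list()
    for (arm in c("tumor", "normal")) {
      cm <- if (arm == "tumor") cm_tumor else cm_normal
      coords <- significant_coordinates(cm, q_max = q_sig)
      if (length(unique(coords)) >= 2) out[[arm]] <- density_profile(coords)
    }
    out
  })
  shift <- stage("shift-test",
                 tss_shift_test(windows, expr, samples, n_perm = n_perm,
                                seed = seed, genes = genes, ...))
  selection <- stage("select", {
    sel <- select_genes(cm_tumor, q_max = q_select)
    if (nrow(sel)) methylation_change(sel, windows, samples) else sel
  })
  subtypes <- stage("cluster", {
    if (nrow(selection) >= 2 &&
        sum(samples$group == "tumor") >= k) {
      ward_cluster(selection, windows, samples, k = k)
    } else {
      NULL
    }
  })
  quartiles <- stage("quartiles", assign_quartiles(expr, samples, "tumor"))
  meta <- stage("profiles", {
    parts <- if (is.null(cgi)) "all" else c("within_cgi", "outside_cgi")
    setNames(lapply(parts, function(p) {
      methylation_meta_profile(segments, samples, genes, quartiles,
                               group = "tumor", cgi = cgi, partition = p)
    }), parts)
  })
  manifest <- list(
    config_hash = rlang::hash(list(q_sig = q_sig, q_select = q_select,
                                   n_perm = n_perm, k = k, seed = seed)),
    input_hash = rlang::hash(list(genes, segments, expr, samples, cgi)),
    seed = as.integer(seed),
    n_genes = nrow(genes), n_samples = nrow(samples),
    rows = list(windows = nrow(windows), cm_tumor = nrow(cm_tumor),
                cm_normal = nrow(cm_normal), selection = nrow(selection)),
    package_version = as.character(utils::packageVersion("tssmeth"))
  )
  structure(
    list(windows = windows, cm_tumor = cm_tumor, cm_normal = cm_normal,
         densities = densities, shift_test = shift, selection = selection,
         subtypes = subtypes, quartiles = quartiles, meta_profiles = meta,
         manifest = manifest),
    class = "tss_pipeline"
  )
}

#' @export
print.tss_pipeline <- function(x, ...) {
  cat("TSS methylation-expression pipeline result\n")
  cat(sprintf("  %d genes, %d samples; config %s\n", x$manifest$n_genes,
              x$manifest$n_samples, substr(x$manifest$config_hash, 1, 8)))
  cat(sprintf("  correlation records: %d tumor, %d normal\n",
              nrow(x$cm_tumor), nrow(x$cm_normal)))
  cat(sprintf("  selected genes (q < threshold, negative): %d\n",
              nrow(x$selection)))
  print(x$shift_test)
  invisible(x)
}

#' Write pipeline outputs as TSV/JSON files
#'
#' @param result A `tss_pipeline` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(result$cm_tumor, file.path(dir, "correlation_tumor.tsv"))
  readr::write_tsv(result$cm_normal, file.path(dir, "correlation_normal.tsv"))
  for (arm in names(result$densities)) {
    readr::write_tsv(as_tibble(result$densities[[arm]]),
                     file.path(dir, sprintf("density_%s.tsv", arm)))
  }
  readr::write_tsv(result$selection, file.path(dir, "gene_selection.tsv"))
  if (!is.null(result$subtypes)) {
    readr::write_tsv(tidy(result$subtypes), file.path(dir, "subtypes.tsv"))
  }
  readr::write_tsv(tidy(result$shift_test), file.path(dir, "null_ratios.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    st <- result$shift_test
    jsonlite::write_json(
      list(auc_tumor = st$auc_tumor, auc_normal = st$auc_normal,
           ratio = st$ratio, p_value = st$p_value, n_perm = st$n_perm,
           seed = st$seed, degenerate_permutations = st$n_degenerate,
           manifest = result$manifest),
      file.path(dir, "shift_test.json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
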