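#' Density mass within a TSS-relative region
#'
#' Trapezoidal integral of a density profile over a region, a value in
#' `[0, 1]` for unit-mass profiles.
#'
#' @param profile A `tss_density` tibble from [density_profile()].
#' @param region Numeric length-2 vector of TSS-relative bounds in bp
#'   (default `c(-500, 500)`).
#' @return The integrated density mass.
#' @export
auc_in_region <- function(profile, region = c(-500, 500)) {
  stopifnot(length(region) == 2, region[1] < region[2])
  keep <- profile$position >= region[1] & profile$position <= region[2]
  if (sum(keep) < 2) abort("region covers fewer than 2 grid points")
  pracma::trapz(profile$position[keep], profile$density[keep])
}

#' Tumor/normal AUC ratio at the TSS
#'
#' Ratio of tumor to normal density mass within a TSS-relative region;
#' values above 1 indicate that significant methylation-expression coupling
#' is more concentrated at the TSS in tumors.
#'
#' @param tumor,normal `tss_density` profiles.
#' @param region TSS-relative bounds in bp.
#' @return Positive real ratio.
#' @export
auc_ratio <- function(tumor, normal, region = c(-500, 500)) {
  a_t <- auc_in_region(tumor, region)
  a_n <- auc_in_region(normal, region)
  if (a_n <= 0) abort("degenerate null arm: normal AUC is zero in region")
  a_t / a_n
}

# One pass of the statistic pipeline for prepared arm data. Returns the
# coordinates (window midpoints) passing the selection rule for one arm.
arm_coordinates <- function(prep, perm = NULL, alpha, measure, sign) {
  rho <- cor_map_rho(prep$meth_rs, prep$expr_rs, prep$gene_row, perm)
  ok <- !is.na(rho)
  p <- spearman_p(rho[ok], prep$n)
  stat <- if (measure == "q") bh_fdr(p) else p
  keep <- stat < alpha
  if (sign == "negative") keep <- keep & rho[ok] < 0
  if (sign == "positive") keep <- keep & rho[ok] > 0
  prep$midpoint[ok][keep]
}

prepare_arm <- function(wsm, expr, samples, arm, expressed_frac,
                        genes = NULL, gene_set = "all") {
  ids <- intersect(samples$sample_id[samples$group == arm], names(expr))
  ids <- intersect(ids, names(wsm))
  if (length(ids) < 5) {
    abort(sprintf("arm '%s' has %d usable samples; need >= 5", arm, length(ids)))
  }
  gene_ids <- intersect(unique(wsm$gene_id), expr$gene_id)
  if (gene_set != "all") {
    if (is.null(genes) || is.null(genes$is_cgi_gene)) {
      abort("gene_set filtering needs a gene tibble with is_cgi_gene")
    }
    cgi_ids <- genes$gene_id[genes$is_cgi_gene]
    gene_ids <- if (gene_set == "CGI") {
      intersect(gene_ids, cgi_ids)
    } else {
      setdiff(gene_ids, cgi_ids)
    }
  }
  E <- as.matrix(expr[match(gene_ids, expr$gene_id), ids, drop = FALSE])
  expressed <- rowMeans(E > 0) >= expressed_frac
  gene_ids <- gene_ids[expressed]
  if (length(gene_ids) == 0) abort(sprintf("no expressed genes in arm '%s'", arm))
  E <- E[expressed, , drop = FALSE]
  w <- wsm[wsm$gene_id %in% gene_ids, c("gene_id", "window_start", ids)]
  list(
    meth_rs = row_rank_scale(as.matrix(w[, ids, drop = FALSE])),
    expr_rs = row_rank_scale(E),
    gene_row = match(w$gene_id, gene_ids),
    midpoint = as.integer(w$window_start + WINDOW_BP / 2L),
    n = length(ids)
  )
}

#' Permutation test for a tumorward shift of methylation-expression
#' coupling to the TSS
#'
#' The observed statistic is the tumor/normal ratio of significant-
#' coordinate density mass within TSS +/- 500 bp. Each permutation breaks
#' the methylation-expression pairing by shuffling expression columns
#' against methylation columns independently within each arm (arm sizes
#' fixed), then recomputes the full pipeline: window-wise Spearman
#' correlation, coordinate selection, kernel density per arm, and the AUC
#' ratio. The one-sided empirical p-value uses the add-one estimator
#' `(1 + #(null >= observed)) / (1 + n_perm)` and so is never exactly 0.
#'
#' A permutation (or the observed data) yielding fewer than 2 distinct
#' coordinates in an arm contributes the neutral ratio 1 and is counted in
#' the `n_degenerate` tally.
#'
#' @param wsm Window-score tibble from [window_scores()].
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param samples Sample manifest (`sample_id`, `group` with levels
#'   `tumor`/`normal`).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; the result is bit-identical given the seed.
#' @param alpha Coordinate-selection threshold (default 0.05).
#' @param measure `"p"` (default) selects coordinates on the raw Spearman
#'   p-value, which keeps the statistic populated and calibrated at
#'   moderate cohort sizes; `"q"` applies the threshold to BH-adjusted
#'   q-values, the rule used for display density maps.
#' @param sign Correlation sign filter for selected coordinates.
#' @param gene_set `"all"`, `"CGI"`, or `"noCGI"` (needs `genes`).
#' @param genes Optional gene tibble with `is_cgi_gene`.
#' @param region TSS-relative integration bounds in bp.
#' @param bandwidth KDE bandwidth in bp or `"auto"`.
#' @param expressed_frac Expression filter passed to the correlation step.
#' @param scheme `"pairing"` (default) permutes expression against
#'   methylation within each arm; `"labels"` permutes the tumor/normal arm
#'   labels across samples instead.
#' @return A `tss_shift_test` object: list with `auc_tumor`, `auc_normal`,
#'   `ratio`, `null_ratios`, `p_value`, `n_perm`, `seed`, `n_degenerate`,
#'   `degenerate_observed`, `densities` (named list of `tss_density`), and
#'   the call parameters.
#' @export
tss_shift_test <- function(wsm, expr, samples, n_perm = 1000, seed = 1,
                           alpha = 0.05, measure = c("p", "q"),
                           sign = c("any", "negative", "positive"),
                           gene_set = c("all", "CGI", "noCGI"),
                           genes = NULL, region = c(-500, 500),
                           bandwidth = "auto", expressed_frac = 0.2,
                           scheme = c("pairing", "labels")) {
  measure <- match.arg(measure)
  sign <- match.arg(sign)
  gene_set <- match.arg(gene_set)
  scheme <- match.arg(scheme)
  set.seed(as.integer(seed))

  prep <- list(
    tumor = prepare_arm(wsm, expr, samples, "tumor", expressed_frac,
                        genes, gene_set),
    normal = prepare_arm(wsm, expr, samples, "normal", expressed_frac,
                         genes, gene_set)
  )

  ratio_of <- function(coords_t, coords_n) {
    if (length(unique(coords_t)) < 2 || length(unique(coords_n)) < 2) {
      return(NA_real_)
    }
    auc_ratio(density_profile(coords_t, bandwidth),
              density_profile(coords_n, bandwidth), region)
  }

  obs_t <- arm_coordinates(prep$tumor, NULL, alpha, measure, sign)
  obs_n <- arm_coordinates(prep$normal, NULL, alpha, measure, sign)
  observed <- ratio_of(obs_t, obs_n)
  degenerate_observed <- is.na(observed)
  if (degenerate_observed) {
    warn("observed data yield < 2 distinct significant coordinates in an arm; neutral ratio 1 used")
    observed <- 1
  }

  # All permutation indices are drawn up front from the single seeded
  # stream, so permutation i is a pure function of (seed, i).
  perm_t <- replicate(n_perm, sample.int(prep$tumor$n), simplify = FALSE)
  perm_n <- replicate(n_perm, sample.int(prep$normal$n), simplify = FALSE)
  if (scheme == "labels") {
    n_all <- nrow(samples)
    perm_lab <- replicate(n_perm, sample.int(n_all), simplify = FALSE)
  }

  null_ratios <- numeric(n_perm)
  n_degenerate <- 0L
  for (i in seq_len(n_perm)) {
    if (scheme == "pairing") {
      ct <- arm_coordinates(prep$tumor, perm_t[[i]], alpha, measure, sign)
      cn <- arm_coordinates(prep$normal, perm_n[[i]], alpha, measure, sign)
    } else {
      samp_i <- samples
      samp_i$group <- samples$group[perm_lab[[i]]]
      prep_i <- list(
        tumor = prepare_arm(wsm, expr, samp_i, "tumor", expressed_frac,
                            genes, gene_set),
        normal = prepare_arm(wsm, expr, samp_i, "normal", expressed_frac,
                             genes, gene_set)
      )
      ct <- arm_coordinates(prep_i$tumor, NULL, alpha, measure, sign)
      cn <- arm_coordinates(prep_i$normal, NULL, alpha, measure, sign)
    }
    r <- ratio_of(ct, cn)
    if (is.na(r)) {
      r <- 1
      n_degenerate <- n_degenerate + 1L
    }
    null_ratios[i] <- r
  }

  p_value <- (1 + sum(null_ratios >= observed)) / (1 + n_perm)

  densities <- list()
  if (length(unique(obs_t)) >= 2) densities$tumor <- density_profile(obs_t, bandwidth)
  if (length(unique(obs_n)) >= 2) densities$normal <- density_profile(obs_n, bandwidth)
  auc_t <- if (!is.null(densities$tumor)) auc_in_region(densities$tumor, region) else NA_real_
  auc_n <- if (!is.null(densities$normal)) auc_in_region(densities$normal, region) else NA_real_

  structure(
    list(auc_tumor = auc_t, auc_normal = auc_n, ratio = observed,
         null_ratios = null_ratios, p_value = p_value,
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         n_degenerate = n_degenerate,
         degenerate_observed = degenerate_observed,
         densities = densities,
         params = list(alpha = alpha, measure = measure, sign = sign,
                       gene_set = gene_set, region = region,
                       bandwidth = bandwidth, scheme = scheme,
                       expressed_frac = expressed_frac)),
    class = "tss_shift_test"
  )
}

#' @export
print.tss_shift_test <- function(x, ...) {
  cat("TSS shift permutation test (AUC ratio, tumor/normal)\n")
  cat(sprintf("  region: [%d, %d] bp; selection: %s < %g (%s correlation, %s genes)\n",
              x$params$region[1], x$params$region[2], x$params$measure,
              x$params$alpha, x$params$sign, x$params$gene_set))
  cat(sprintf("  AUC tumor = %.4f, AUC normal = %.4f\n", x$auc_tumor, x$auc_normal))
  cat(sprintf("  observed ratio = %.3f, p = %.4g (%d permutations, %d degenerate)\n",
              x$ratio, x$p_value, x$n_perm, x$n_degenerate))
  invisible(x)
}

#' @describeIn tss_shift_test One row per permutation (`permutation`,
#'   `null_ratio`).
#' @param x A `tss_shift_test` object.
#' @param ... Unused.
#' @export
tidy.tss_shift_test <- function(x, ...) {
  tibble(permutation = seq_len(x$n_perm), null_ratio = x$null_ratios)
}

#' @describeIn tss_shift_test One-row summary of the test.
#' @export
glance.tss_shift_test <- function(x, ...) {
  tibble(auc_tumor = x$auc_tumor, auc_normal = x$auc_normal,
         ratio = x$ratio, p_value = x$p_value, n_perm = x$n_perm,
         n_degenerate = x$n_degenerate, seed = x$seed)
}

#' @describeIn tss_shift_test Null-ratio histogram with the observed ratio
#'   marked.
#' @param object A `tss_shift_test` object.
#' @export
autoplot.tss_shift_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_ratio)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$ratio, colour = "red") +
    ggplot2::labs(x = "null AUC ratio (tumor/normal)", y = "permutations",
                  subtitle = sprintf("observed ratio %.3f, p = %.4g",
                                     object$ratio, object$p_value)) +
    ggplot2::theme_minimal()
}
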