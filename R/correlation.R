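#' Spearman rank correlation with large-sample p-value
#'
#' Average ranks are used for ties; the p-value comes from the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom (two-sided). Constant vectors have no defined rank
#' correlation and raise an error; callers exclude such windows as
#' degenerate.
#'
#' @param x,y Numeric vectors of equal length, n >= 5.
#' @return Named list with `rho` and `p`.
#' @export
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5)) # rho = 0.8
spearman_rho <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort("x and y must have equal length")
  if (n < 5) abort("need at least 5 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("degenerate: constant vector")
  rho <- cor(rank(x), rank(y))
  list(rho = rho, p = spearman_p(rho, n))
}

spearman_p <- function(rho, n) {
  r2 <- pmin(rho^2, 1)
  tstat <- abs(rho) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * pt(-tstat, df = n - 2)
  ifelse(r2 >= 1, 0, p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (`q = min over p_(j) >= p of p_(j) * m / j`,
#' capped at 1), applied jointly over all tests handed in.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

# Rank every row, then center and scale to unit norm so that rho between a
# methylation row and an expression row is a plain dot product. Rows with
# zero variance come back as NA and are treated as degenerate.
row_rank_scale <- function(M) {
  R <- t(apply(M, 1, rank))
  R <- R - rowMeans(R)
  nrm <- sqrt(rowSums(R^2))
  R / ifelse(nrm > 0, nrm, NA_real_)
}

# Internal engine shared by the observed map and the permutation loop.
# meth_rs: rank-scaled methylation matrix (rows = gene x window records);
# expr_rs: rank-scaled expression matrix (rows = genes); gene_row: row of
# expr_rs backing each meth row; perm: permutation of the sample columns
# applied to expression.
cor_map_rho <- function(meth_rs, expr_rs, gene_row, perm = NULL) {
  E <- expr_rs[gene_row, , drop = FALSE]
  if (!is.null(perm)) E <- E[, perm, drop = FALSE]
  rowSums(meth_rs * E)
}

#' Per-gene, per-window methylation-expression correlation map
#'
#' For one cohort arm, correlates each gene's expression with its
#' methylation window scores across samples (Spearman), and adjusts all
#' retained tests jointly by Benjamini-Hochberg. Windows with zero
#' methylation variance across the arm and genes with (near-)constant
#' expression are excluded before the FDR step so that only testable
#' hypotheses count.
#'
#' @param wsm Window-score tibble from [window_scores()].
#' @param expr Expression tibble: `gene_id` plus one nonnegative numeric
#'   column per sample (normalized, RSEM-style).
#' @param samples Sample manifest (`sample_id`, `group`).
#' @param arm Group label selecting the samples to correlate over.
#' @param expressed_frac Genes must have nonzero expression in at least
#'   this fraction of the arm's samples to enter the map (default 0.2).
#' @return A correlation-map tibble: `gene_id`, `window_start`, `rho`,
#'   `p`, `q`, `n`, with attribute `n_degenerate` counting excluded
#'   windows.
#' @export
build_correlation_map <- function(wsm, expr, samples, arm,
                                  expressed_frac = 0.2) {
  ids <- intersect(samples$sample_id[samples$group == arm], names(expr))
  ids <- intersect(ids, names(wsm))
  if (length(ids) == 0) abort("no overlapping samples between arms and matrices")
  if (length(ids) < 5) {
    abort(sprintf("arm '%s' has %d usable samples; need >= 5", arm, length(ids)))
  }
  genes <- intersect(unique(wsm$gene_id), expr$gene_id)
  E <- as.matrix(expr[match(genes, expr$gene_id), ids, drop = FALSE])
  expressed <- rowMeans(E > 0) >= expressed_frac
  genes <- genes[expressed]
  if (length(genes) == 0) abort("no expressed genes in this arm")
  E <- E[expressed, , drop = FALSE]
  w <- wsm[wsm$gene_id %in% genes, c("gene_id", "window_start", ids)]
  M <- as.matrix(w[, ids, drop = FALSE])
  meth_rs <- row_rank_scale(M)
  expr_rs <- row_rank_scale(E)
  gene_row <- match(w$gene_id, genes)
  rho <- cor_map_rho(meth_rs, expr_rs, gene_row)
  ok <- !is.na(rho)
  n_deg <- sum(!ok)
  out <- tibble(
    gene_id = w$gene_id[ok],
    window_start = w$window_start[ok],
    rho = rho[ok],
    p = spearman_p(rho[ok], length(ids)),
    n = length(ids)
  )
  out$q <- bh_fdr(out$p)
  out <- out[, c("gene_id", "window_start", "rho", "p", "q", "n")]
  attr(out, "n_degenerate") <- n_deg
  attr(out, "arm") <- arm
  out
}

#' Extract TSS-relative coordinates of significant windows
#'
#' Filters a correlation map by significance, correlation sign, and gene
#' class, returning the midpoints (window start + 250 bp) of the retained
#' windows — the coordinates profiled by [density_profile()].
#'
#' @param cm Correlation map from [build_correlation_map()].
#' @param q_max Significance threshold (default 0.05).
#' @param sign `"any"`, `"negative"`, or `"positive"` correlation.
#' @param genes Optional gene tibble with `is_cgi_gene`, required when
#'   `gene_set` is not `"all"`.
#' @param gene_set `"all"`, `"CGI"`, or `"noCGI"`.
#' @param measure Column the threshold applies to: `"q"` (BH-adjusted,
#'   default) or `"p"` (raw).
#' @return Integer vector of TSS-relative window midpoints (possibly with
#'   repeats across genes).
#' @export
significant_coordinates <- function(cm, q_max = 0.05,
                                    sign = c("any", "negative", "positive"),
                                    genes = NULL,
                                    gene_set = c("all", "CGI", "noCGI"),
                                    measure = c("q", "p")) {
  sign <- match.arg(sign)
  gene_set <- match.arg(gene_set)
  measure <- match.arg(measure)
  keep <- cm[[measure]] < q_max
  if (sign == "negative") keep <- keep & cm$rho < 0
  if (sign == "positive") keep <- keep & cm$rho > 0
  if (gene_set != "all") {
    if (is.null(genes) || is.null(genes$is_cgi_gene)) {
      abort("gene_set filtering needs a gene tibble with is_cgi_gene")
    }
    cgi_ids <- genes$gene_id[genes$is_cgi_gene]
    in_cgi <- cm$gene_id %in% cgi_ids
    keep <- keep & (if (gene_set == "CGI") in_cgi else !in_cgi)
  }
  as.integer(cm$window_start[keep] + WINDOW_BP / 2L)
}

#' Kernel density profile of significant coordinates around the TSS
#'
#' Gaussian KDE of TSS-relative coordinates, evaluated on a 10-bp grid
#' over `[-5000, 5000]`, truncated to that domain and renormalized so the
#' trapezoidal integral equals 1 exactly — the y-axis is a probability
#' density over the domain.
#'
#' @param coords Integer/numeric vector of TSS-relative coordinates
#'   (window midpoints); needs at least 2 distinct values.
#' @param bandwidth Kernel bandwidth in bp, or `"auto"` for Silverman's
#'   rule (`stats::bw.nrd0`).
#' @param span Domain half-width in bp.
#' @return A `tss_density` tibble with columns `position`, `density` and
#'   attributes `bandwidth` and `n_points`.
#' @export
density_profile <- function(coords, bandwidth = "auto", span = 5000L) {
  coords <- as.numeric(coords)
  if (length(unique(coords)) < 2) {
    abort("insufficient coordinates: need >= 2 distinct positions")
  }
  bw <- if (identical(bandwidth, "auto")) bw.nrd0(coords) else as.numeric(bandwidth)
  d <- density(coords, bw = bw, from = -span, to = span, n = span / 5 + 1)
  y <- pmax(d$y, 0)
  total <- pracma::trapz(d$x, y)
  if (total <= 0) abort("degenerate density (no mass on the domain)")
  out <- tibble(position = d$x, density = y / total)
  attr(out, "bandwidth") <- bw
  attr(out, "n_points") <- length(coords)
  class(out) <- c("tss_density", class(out))
  out
}

#' Plot tumor/normal density profiles
#'
#' @param profiles Named list of `tss_density` tibbles (e.g.
#'   `list(tumor = ..., normal = ...)`).
#' @param region Optional numeric length-2 region to shade (bp).
#' @return A ggplot object.
#' @export
plot_density_profiles <- function(profiles, region = c(-500, 500)) {
  df <- purrr::imap(profiles, ~ mutate(as_tibble(.x), arm = .y)) |>
    purrr::list_rbind()
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$density,
                                        colour = .data$arm))
  if (!is.null(region)) {
    p <- p + ggplot2::annotate("rect", xmin = region[1], xmax = region[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.1)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "distance to TSS (bp)", y = "density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
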