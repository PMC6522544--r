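#' Assign genes to expression quartiles
#'
#' Genes are ranked by their mean normalized expression across one arm's
#' samples and split into four near-equal groups, Q1 lowest to Q4 highest.
#' When the gene count is not divisible by 4 the remainder is assigned
#' from Q1 upward (10 genes give sizes 3, 3, 2, 2); ties in mean
#' expression are broken by gene id, so the assignment is deterministic.
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param samples Sample manifest.
#' @param arm Group whose samples define the ranking.
#' @param stat `"mean"` (default) or `"median"` summary across samples.
#' @return Tibble `gene_id`, `summary_expr`, `quartile` (factor Q1-Q4).
#' @export
assign_quartiles <- function(expr, samples, arm, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  ids <- intersect(samples$sample_id[samples$group == arm], names(expr))
  if (length(ids) == 0) abort(sprintf("no samples in arm '%s'", arm))
  if (nrow(expr) < 4) abort("need at least 4 genes to form quartiles")
  E <- as.matrix(expr[, ids, drop = FALSE])
  val <- if (stat == "mean") rowMeans(E) else apply(E, 1, stats::median)
  ord <- order(val, expr$gene_id)
  n <- length(ord)
  base <- n %/% 4L
  sizes <- rep(base, 4) + c(rep(1L, n %% 4L), rep(0L, 4L - n %% 4L))
  q <- rep(paste0("Q", 1:4), times = sizes)
  tibble(gene_id = expr$gene_id[ord],
         summary_expr = val[ord],
         quartile = factor(q, levels = paste0("Q", 1:4))) |>
    arrange(.data$gene_id)
}

# 100-bp TSS-relative bin of each grid segment, strand-aware (same
# genomic-side half-open binning as the 500-bp windows).
gene_segment_bins <- function(genes) {
  purrr::pmap(
    list(genes$gene_id, genes$chrom, genes$tss, genes$strand),
    function(g, ch, t, st) {
      first <- 100L * as.integer(ceiling((t - SPAN - 50L) / 100))
      seg_start <- seq.int(first, by = 100L, length.out = 100L)
      u <- seg_start + 50L - t
      b <- as.integer(floor(u / 100))
      rel <- if (st == "+") 100L * b else -100L * (b + 1L)
      tibble(gene_id = g, chrom = ch, seg_start = seg_start,
             position = as.integer(rel))
    }
  ) |>
    purrr::list_rbind()
}

#' Expression-quartile methylation meta-profile
#'
#' Mean methylation ratio per 100-bp TSS-relative bin, averaged over the
#' genes of each expression quartile, optionally restricted to segments
#' within or outside CpG islands. Bins with no eligible segment in a
#' quartile are absent from the output.
#'
#' @param segments Segment-call tibble.
#' @param samples Sample manifest.
#' @param genes Gene tibble.
#' @param quartiles Quartile assignment from [assign_quartiles()].
#' @param group Arm whose samples define the methylation ratio.
#' @param cgi Optional CpG island tibble, required for partitioning.
#' @param partition `"all"`, `"within_cgi"`, or `"outside_cgi"`.
#' @return A `meta_profile` tibble: `position`, `quartile`, `mean_signal`,
#'   `n_genes`.
#' @export
methylation_meta_profile <- function(segments, samples, genes, quartiles,
                                     group = "tumor", cgi = NULL,
                                     partition = c("all", "within_cgi",
                                                   "outside_cgi")) {
  partition <- match.arg(partition)
  ratio <- methylation_ratio(segments, samples, group)
  if (partition != "all") {
    if (is.null(cgi)) abort("partitioning requires CpG island intervals")
    ratio <- partition_by_cgi(ratio, cgi)
  }
  bins <- gene_segment_bins(genes) |>
    inner_join(ratio, by = c("chrom", "seg_start" = "start")) |>
    inner_join(quartiles[, c("gene_id", "quartile")], by = "gene_id")
  if (partition == "within_cgi") bins <- bins[bins$within_cgi, ]
  if (partition == "outside_cgi") bins <- bins[!bins$within_cgi, ]
  out <- bins |>
    group_by(.data$position, .data$quartile) |>
    summarise(mean_signal = mean(.data$ratio),
              n_genes = dplyr::n_distinct(.data$gene_id), .groups = "drop") |>
    arrange(.data$quartile, .data$position)
  class(out) <- c("meta_profile", class(out))
  out
}

#' Read a 4-column bedGraph coverage track
#'
#' @param path Path to a bedGraph file (chrom, start, end, value; 0-based
#'   half-open). `track` and comment lines are skipped.
#' @return Tibble `chrom`, `start`, `end`, `value`, sorted.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4)) abort("bedGraph requires 4 columns")
  out <- tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = as.integer(vapply(fields, `[[`, "", 2)),
    end   = as.integer(vapply(fields, `[[`, "", 3)),
    value = as.numeric(vapply(fields, `[[`, "", 4))
  )
  if (any(is.na(out$value)) || any(out$start >= out$end)) {
    abort("malformed bedGraph record")
  }
  arrange(out, .data$chrom, .data$start)
}

# Per-chromosome cumulative-integral lookup for step-function coverage;
# intervals must be non-overlapping. Returns F(x) = integral of coverage
# over (-inf, x], vectorized in x.
coverage_integral <- function(cov_chrom) {
  starts <- cov_chrom$start
  ends <- cov_chrom$end
  vals <- cov_chrom$value
  cum <- c(0, cumsum(vals * (ends - starts)))
  function(x) {
    i <- findInterval(x, starts)
    j <- pmax(i, 1)
    inside <- pmax(0, pmin(x - starts[j], (ends - starts)[j]))
    ifelse(i == 0, 0, cum[j] + vals[j] * inside)
  }
}

# Strand-aware binned mean coverage per gene: matrix genes x bins with
# TSS-relative bin starts as column names.
gene_coverage_matrix <- function(coverage, genes, bin = 10L, span = SPAN) {
  rel_edges <- seq(-span, span, by = bin)
  n_bins <- length(rel_edges) - 1L
  out <- matrix(NA_real_, nrow = nrow(genes), ncol = n_bins,
                dimnames = list(genes$gene_id, rel_edges[-length(rel_edges)]))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    Fc <- coverage_integral(coverage[coverage$chrom == ch, ])
    for (g in gi) {
      edges <- if (genes$strand[g] == "+") {
        genes$tss[g] + rel_edges
      } else {
        genes$tss[g] - rel_edges
      }
      vals <- Fc(edges)
      out[g, ] <- abs(diff(vals)) / bin
    }
  }
  out
}

#' Expression-quartile ChIP coverage meta-profile
#'
#' Strand-aware mean ChIP coverage in 10-bp TSS-relative bins per gene,
#' averaged over the genes of each expression quartile. Genes running past
#' a declared chromosome end are dropped with a message.
#'
#' @param coverage bedGraph-style coverage tibble (one track), e.g. from
#'   [read_bedgraph()]; values must be nonnegative.
#' @param genes Gene tibble.
#' @param quartiles Quartile assignment from [assign_quartiles()].
#' @param bin Bin width in bp (default 10).
#' @param span Domain half-width in bp.
#' @param chrom_sizes Optional named chromosome lengths for bounds checks.
#' @return A `meta_profile` tibble: `position`, `quartile`, `mean_signal`,
#'   `n_genes`.
#' @export
chip_meta_profile <- function(coverage, genes, quartiles, bin = 10L,
                              span = SPAN, chrom_sizes = NULL) {
  if (any(coverage$value < 0)) abort("coverage must be nonnegative")
  if (!is.null(chrom_sizes)) {
    limit <- chrom_sizes[genes$chrom]
    ok <- genes$tss - span >= 0 & genes$tss + span <= limit & !is.na(limit)
    if (any(!ok)) {
      inform(sprintf("dropping %d gene(s) extending past contig end", sum(!ok)))
      genes <- genes[ok, ]
    }
  }
  genes <- genes[genes$gene_id %in% quartiles$gene_id, ]
  M <- gene_coverage_matrix(coverage, genes, bin, span)
  q <- quartiles$quartile[match(rownames(M), quartiles$gene_id)]
  out <- purrr::map(levels(q), function(lev) {
    rows <- which(q == lev)
    tibble(position = as.integer(colnames(M)),
           quartile = factor(lev, levels = levels(q)),
           mean_signal = colMeans(M[rows, , drop = FALSE]),
           n_genes = length(rows))
  }) |>
    purrr::list_rbind()
  class(out) <- c("meta_profile", class(out))
  out
}

#' Randomized gene-list background band for ChIP meta-profiles
#'
#' Draws `n_lists` gene lists of size `list_size` without replacement from
#' a universe, computes each list's mean coverage profile, and returns the
#' per-bin envelope — the genomic background against which a target gene
#' set's profile is judged.
#'
#' @param coverage Coverage tibble.
#' @param genes Gene tibble.
#' @param universe Character vector of candidate gene ids (must contain at
#'   least `list_size` genes present in `genes`).
#' @param list_size Genes per random list (default 407).
#' @param n_lists Number of random lists (default 1000).
#' @param seed Integer seed; the band is deterministic given the seed.
#' @param band `"minmax"` (default) or `"central95"` envelope.
#' @param bin,span Binning as in [chip_meta_profile()].
#' @return Tibble `position`, `lower`, `upper` with attributes `n_lists`,
#'   `list_size`, `seed`, `band`.
#' @export
randomized_background <- function(coverage, genes, universe,
                                  list_size = 407L, n_lists = 1000L,
                                  seed = 1, band = c("minmax", "central95"),
                                  bin = 10L, span = SPAN) {
  band <- match.arg(band)
  universe <- intersect(universe, genes$gene_id)
  if (length(universe) < list_size) {
    abort(sprintf("universe (%d genes) smaller than list_size (%d)",
                  length(universe), list_size))
  }
  set.seed(as.integer(seed))
  M <- gene_coverage_matrix(coverage, genes[match(universe, genes$gene_id), ],
                            bin, span)
  profiles <- matrix(NA_real_, nrow = n_lists, ncol = ncol(M))
  for (i in seq_len(n_lists)) {
    rows <- sample.int(length(universe), list_size)
    profiles[i, ] <- colMeans(M[rows, , drop = FALSE])
  }
  bounds <- if (band == "minmax") {
    list(lower = apply(profiles, 2, min), upper = apply(profiles, 2, max))
  } else {
    list(lower = apply(profiles, 2, quantile, probs = 0.025),
         upper = apply(profiles, 2, quantile, probs = 0.975))
  }
  out <- tibble(position = as.integer(colnames(M)),
                lower = bounds$lower, upper = bounds$upper)
  attr(out, "n_lists") <- n_lists
  attr(out, "list_size") <- list_size
  attr(out, "seed") <- as.integer(seed)
  attr(out, "band") <- band
  out
}

#' Plot a meta-profile, optionally over a background band
#'
#' @param profile A `meta_profile` tibble.
#' @param background Optional band from [randomized_background()].
#' @return A ggplot object.
#' @export
plot_meta_profile <- function(profile, background = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(background)) {
    p <- p + ggplot2::geom_ribbon(
      data = background,
      ggplot2::aes(x = .data$position, ymin = .data$lower, ymax = .data$upper),
      fill = "grey85"
    )
  }
  p +
    ggplot2::geom_line(
      data = as_tibble(profile),
      ggplot2::aes(x = .data$position, y = .data$mean_signal,
                   colour = .data$quartile)
    ) +
    ggplot2::labs(x = "distance to TSS (bp)", y = "mean signal",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
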