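#' Genomic 100-bp segment grid covering each gene's TSS +/- 5 kb
#'
#' Segments are anchored on the genomic 100-bp lattice (start divisible by
#' 100); a segment belongs to a gene's territory when its midpoint falls in
#' `[tss - 5000, tss + 5000)`. Every territory contains exactly 100
#' segments.
#'
#' @param genes Gene tibble (see [read_gene_bed()]).
#' @return A tibble with columns `chrom`, `start` (unique, sorted).
#' @export
segment_grid <- function(genes) {
  purrr::map2(genes$chrom, genes$tss, function(ch, t) {
    first <- 100L * as.integer(ceiling((t - SPAN - 50L) / 100))
    tibble(chrom = ch, start = seq.int(first, by = 100L, length.out = 100L))
  }) |>
    purrr::list_rbind() |>
    distinct() |>
    arrange(.data$chrom, .data$start)
}

#' Binarize per-sample methylation peak calls onto a segment grid
#'
#' A segment scores 1 for a sample iff any of that sample's peaks overlaps
#' it by at least 1 bp (half-open interval semantics), the presence/absence
#' abstraction of MACS peak calls on MBD-seq data.
#'
#' @param peaks Long tibble of peak calls: `sample_id`, `chrom`, `start`,
#'   `end` (0-based half-open). Extra columns are ignored.
#' @param grid Segment grid from [segment_grid()].
#' @param sample_ids Optional character vector fixing column order (and
#'   including samples with zero peaks). Defaults to samples present in
#'   `peaks`.
#' @return A segment-call tibble: `chrom`, `start`, then one 0/1 integer
#'   column per sample. Peaks on chromosomes absent from the grid are
#'   skipped with a warning.
#' @export
binarize_segments <- function(peaks, grid, sample_ids = NULL) {
  stopifnot(all(c("sample_id", "chrom", "start", "end") %in% names(peaks)))
  if (any(peaks$start >= peaks$end)) abort("peak with start >= end")
  sample_ids <- sample_ids %||% unique(peaks$sample_id)
  key <- paste(grid$chrom, grid$start)
  unknown <- setdiff(unique(peaks$chrom), unique(grid$chrom))
  if (length(unknown)) {
    n_skip <- sum(peaks$chrom %in% unknown)
    warn(sprintf("skipping %d peak(s) on chromosome(s) outside the grid: %s",
                 n_skip, paste(unknown, collapse = ", ")))
    peaks <- peaks[!peaks$chrom %in% unknown, ]
  }
  out <- grid
  for (s in sample_ids) {
    p <- peaks[peaks$sample_id == s, ]
    col <- integer(nrow(grid))
    if (nrow(p)) {
      first <- 100L * (p$start %/% 100L)
      last <- 100L * ((p$end - 1L) %/% 100L)
      touched <- unlist(purrr::pmap(
        list(p$chrom, first, last),
        function(ch, a, b) paste(ch, seq.int(a, b, by = 100L))
      ))
      col[key %in% touched] <- 1L
    }
    out[[s]] <- col
  }
  out
}

sample_cols <- function(x, ids) {
  missing <- setdiff(ids, names(x))
  if (length(missing)) {
    abort(paste("sample column(s) absent:", paste(missing, collapse = ", ")))
  }
  as.matrix(x[, ids, drop = FALSE])
}

# Per-gene map from grid segments to strand-aware 500-bp TSS-relative
# windows. Segments are binned half-open on the genomic side
# (floor(u/500) with u the plus-strand offset of the segment midpoint) and
# the bin label is strand-flipped, so every gene gets exactly 20 windows of
# 5 segments and mirrored fixtures score identically.
gene_segment_map <- function(genes) {
  purrr::pmap(
    list(genes$gene_id, genes$chrom, genes$tss, genes$strand),
    function(g, ch, t, st) {
      first <- 100L * as.integer(ceiling((t - SPAN - 50L) / 100))
      seg_start <- seq.int(first, by = 100L, length.out = 100L)
      u <- seg_start + 50L - t                # plus-strand midpoint offset
      w <- as.integer(floor(u / 500))         # genomic window index
      rel <- if (st == "+") 500L * w else -500L * (w + 1L)
      tibble(gene_id = g, chrom = ch, seg_start = seg_start,
             window_start = as.integer(rel))
    }
  ) |>
    purrr::list_rbind()
}

#' Sum binary segment calls into 500-bp TSS-relative window scores
#'
#' Each gene's TSS +/- 5 kb territory is divided into 20 non-overlapping
#' 500-bp windows at TSS-relative starts -5000, -4500, ..., +4500
#' (strand-aware; negative = upstream). A window's score for a sample is
#' the sum of its five binary 100-bp segment calls, an integer in 0..5.
#'
#' @param segments Segment-call tibble from [binarize_segments()] (or the
#'   simulator).
#' @param genes Gene tibble.
#' @param chrom_sizes Optional named vector of chromosome lengths; genes
#'   whose territory runs off a chromosome are dropped with a message.
#' @return A window-score tibble: `gene_id`, `window_start`, then one
#'   integer column per sample, 20 rows per gene ordered upstream to
#'   downstream.
#' @export
window_scores <- function(segments, genes, chrom_sizes = NULL) {
  if (!is.null(chrom_sizes)) {
    limit <- chrom_sizes[genes$chrom]
    ok <- genes$tss - SPAN - 50L >= 0 & genes$tss + SPAN + 50L <= limit &
      !is.na(limit)
    if (any(!ok)) {
      inform(sprintf("dropping %d gene(s) whose TSS +/- 5 kb exceeds chromosome bounds",
                     sum(!ok)))
      genes <- genes[ok, ]
    }
  }
  smap <- gene_segment_map(genes)
  idx <- match(paste(smap$chrom, smap$seg_start),
               paste(segments$chrom, segments$start))
  if (anyNA(idx)) {
    bad_genes <- unique(smap$gene_id[is.na(idx)])
    abort(sprintf("segment grid does not cover %d gene(s), e.g. %s",
                  length(bad_genes), bad_genes[1]))
  }
  ids <- setdiff(names(segments), c("chrom", "start"))
  M <- sample_cols(segments, ids)[idx, , drop = FALSE]
  grp <- factor(paste(smap$gene_id, smap$window_start),
                levels = unique(paste(
                  rep(genes$gene_id, each = N_WINDOWS),
                  rep(seq(-SPAN, SPAN - WINDOW_BP, by = WINDOW_BP),
                      times = nrow(genes))
                )))
  W <- rowsum(M, grp)
  out <- tibble(
    gene_id = rep(genes$gene_id, each = N_WINDOWS),
    window_start = rep(as.integer(seq(-SPAN, SPAN - WINDOW_BP, by = WINDOW_BP)),
                       times = nrow(genes))
  )
  W <- W[match(paste(out$gene_id, out$window_start), rownames(W)), ,
         drop = FALSE]
  for (i in seq_along(ids)) out[[ids[i]]] <- as.integer(W[, i])
  out
}

#' Across-sample methylation ratio per segment
#'
#' The fraction of samples in a group whose binary call is 1, per 100-bp
#' segment.
#'
#' @param segments Segment-call tibble.
#' @param samples Sample manifest tibble (`sample_id`, `group`).
#' @param group Group label to average over (e.g. `"tumor"` or `"normal"`).
#' @return Tibble `chrom`, `start`, `ratio`.
#' @export
methylation_ratio <- function(segments, samples, group) {
  ids <- samples$sample_id[samples$group == group]
  if (length(ids) == 0) abort(sprintf("no samples in group '%s'", group))
  M <- sample_cols(segments, ids)
  tibble(chrom = segments$chrom, start = segments$start,
         ratio = rowMeans(M))
}

#' Partition segments by CpG-island overlap
#'
#' A segment is `within_cgi` iff it overlaps any CpG island by at least
#' 1 bp (segments straddling an island boundary count as within).
#'
#' @param segments Segment-call (or grid) tibble with `chrom`, `start`.
#' @param cgi CpG island tibble.
#' @return The input with a logical `within_cgi` column appended.
#' @export
partition_by_cgi <- function(segments, cgi) {
  within <- logical(nrow(segments))
  for (ch in unique(segments$chrom)) {
    si <- which(segments$chrom == ch)
    ci <- cgi[cgi$chrom == ch, ]
    if (nrow(ci) == 0) next
    segs <- IRanges::IRanges(start = segments$start[si] + 1L,
                             end = segments$start[si] + 100L)
    isl <- IRanges::IRanges(start = ci$start + 1L, end = ci$end)
    within[si] <- IRanges::overlapsAny(segs, isl)
  }
  segments$within_cgi <- within
  segments
}

#' Probe-density-weighted gene methylation (array mode)
#'
#' Summarizes per-probe beta values into one methylation level per gene
#' over TSS +/- 5 kb, correcting the platform's probe-design bias: each
#' probe is weighted by the width of its TSS-relative Voronoi cell (half
#' the distance to its flanking probes, clipped at the domain edges), so
#' dense probe clusters near the promoter are not over-counted. Cell widths
#' sum to the 10 kb domain before normalization.
#'
#' @param probes Tibble `probe_id`, `chrom`, `pos`.
#' @param betas Tibble with `probe_id` plus one numeric beta column in
#'   `[0, 1]` per sample.
#' @param genes Gene tibble.
#' @param span Half-width of the TSS-relative domain in bp (default 5000).
#' @return Tibble `gene_id`, `n_probes`, then one weighted-mean column per
#'   sample. Genes with no probe in the domain are omitted (with a
#'   message), matching their exclusion downstream.
#' @export
probe_weighted_methylation <- function(probes, betas, genes, span = 5000L) {
  ids <- setdiff(names(betas), "probe_id")
  B <- as.matrix(betas[, ids, drop = FALSE])
  if (any(B < 0 | B > 1, na.rm = TRUE)) abort("beta values must lie in [0, 1]")
  rownames(B) <- betas$probe_id
  rows <- purrr::pmap(
    list(genes$gene_id, genes$chrom, genes$tss, genes$strand),
    function(g, ch, t, st) {
      p <- probes[probes$chrom == ch, ]
      rel <- tss_relative(p$pos, t, st)
      keep <- abs(rel) <= span
      if (!any(keep)) return(NULL)
      rel <- rel[keep]
      pid <- p$probe_id[keep]
      o <- order(rel)
      rel <- rel[o]; pid <- pid[o]
      bounds <- c(-span, (head(rel, -1) + tail(rel, -1)) / 2, span)
      w <- diff(bounds)
      w <- w / sum(w)
      vals <- colSums(B[pid, , drop = FALSE] * w)
      tibble(gene_id = g, n_probes = length(pid), !!!as.list(vals))
    }
  )
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0) {
    inform(sprintf("%d gene(s) with no probe within +/- %d bp omitted",
                   dropped, span))
  }
  purrr::list_rbind(rows)
}
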