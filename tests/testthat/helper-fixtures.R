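# Shared fixture builders (all generated in code; no files on disk).

# A one-gene annotation row at a given TSS/strand on chromosome `chrom`.
fixture_gene <- function(gene_id, tss, strand = "+", chrom = "chr1") {
  g <- tibble::tibble(
    gene_id = gene_id, chrom = chrom,
    start = if (strand == "+") tss else tss - 1999L,
    end = if (strand == "+") tss + 2000L else tss + 1L,
    strand = strand, tss = as.integer(tss)
  )
  prom <- make_promoter(g$tss, g$strand)
  g$promoter_start <- prom$start
  g$promoter_end <- prom$end
  g
}

# A plus-strand gene and its minus-strand twin whose segment methylation
# is the exact mirror image around the TSS. Both TSSs are multiples of
# 100 so mirrored segment midpoints land back on the grid.
mirror_fixture <- function(n_samples = 8, seed = 42, tss = 20000L) {
  set.seed(seed)
  gp <- fixture_gene("plus", tss, "+", chrom = "chrP")
  gm <- fixture_gene("minus", tss, "-", chrom = "chrM")
  genes <- dplyr::bind_rows(gp, gm)
  grid_p <- segment_grid(gp)
  vals <- matrix(rbinom(nrow(grid_p) * n_samples, 1, 0.35),
                 nrow = nrow(grid_p))
  samples <- paste0("s", seq_len(n_samples))
  seg_p <- grid_p
  for (j in seq_len(n_samples)) seg_p[[samples[j]]] <- vals[, j]
  # mirror: segment with midpoint tss + u maps to midpoint tss - u,
  # i.e. start tss + u - 50 -> start tss - u - 50
  u <- grid_p$start + 50L - tss
  seg_m <- tibble::tibble(chrom = "chrM", start = tss - u - 50L)
  o <- order(seg_m$start)
  seg_m <- seg_m[o, ]
  for (j in seq_len(n_samples)) seg_m[[samples[j]]] <- vals[o, j]
  list(genes = genes, segments = dplyr::bind_rows(seg_p, seg_m),
       sample_ids = samples)
}

# Small cohort presets used across tests (kept small for speed).
small_cohort <- function(seed = 3, ...) {
  simulate_cohort(cohort_config(n_genes = 80, n_tumor = 15, n_normal = 15,
                                seed = seed, ...))
}
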