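quartile_fixture <- function(n_genes = 8, n_samples = 6, seed = 1) {
  set.seed(seed)
  expr <- tibble::tibble(gene_id = sprintf("g%02d", seq_len(n_genes)))
  ids <- paste0("s", seq_len(n_samples))
  for (s in ids) expr[[s]] <- runif(n_genes, 0, 100)
  samples <- tibble::tibble(sample_id = ids, group = "tumor")
  list(expr = expr, samples = samples)
}

test_that("quartile sizes follow the remainder-from-Q1 rule", {
  fx <- quartile_fixture(8)
  qa <- assign_quartiles(fx$expr, fx$samples, "tumor")
  expect_equal(as.vector(table(qa$quartile)), rep(2L, 4))
  fx10 <- quartile_fixture(10)
  qa10 <- assign_quartiles(fx10$expr, fx10$samples, "tumor")
  expect_equal(as.vector(table(qa10$quartile)), c(3L, 3L, 2L, 2L))
  # Q4 holds the highest expression
  top <- fx10$expr$gene_id[which.max(rowMeans(as.matrix(fx10$expr[, -1])))]
  expect_equal(as.character(qa10$quartile[qa10$gene_id == top]), "Q4")
})

test_that("quartile assignment is deterministic under ties", {
  expr <- tibble::tibble(gene_id = sprintf("g%02d", 1:8),
                         s1 = rep(5, 8), s2 = rep(5, 8))
  samples <- tibble::tibble(sample_id = c("s1", "s2"), group = "tumor")
  qa1 <- assign_quartiles(expr, samples, "tumor")
  qa2 <- assign_quartiles(expr[sample(8), ], samples, "tumor")
  expect_equal(qa1, dplyr::arrange(qa2, gene_id))
  # ties broken lexicographically: g01, g02 land in Q1
  expect_equal(as.character(qa1$quartile[qa1$gene_id %in% c("g01", "g02")]),
               c("Q1", "Q1"))
})

test_that("methylation meta-profile separates planted quartile structure", {
  co <- simulate_cohort(cohort_config(n_genes = 120, n_tumor = 20,
                                      n_normal = 20,
                                      frac_coupled_genes = 0.5, seed = 3))
  qa <- assign_quartiles(co$expr, co$samples, "tumor")
  mp <- methylation_meta_profile(co$segments, co$samples, co$genes, qa,
                                 group = "tumor")
  at_tss <- mp[mp$position == 0L, ]
  q1 <- at_tss$mean_signal[at_tss$quartile == "Q1"]
  q4 <- at_tss$mean_signal[at_tss$quartile == "Q4"]
  expect_gt(q1, q4)
  # far from the TSS the quartiles are indistinguishable baseline
  far <- mp[mp$position == -4800L, ]
  expect_lt(abs(diff(range(far$mean_signal))), 0.15)
})

test_that("meta-profile handles degenerate inputs exactly", {
  fx <- quartile_fixture(4, 6, seed = 9)
  genes <- purrr::map(1:4, function(i) {
    fixture_gene(sprintf("g%02d", i), 20000L + 12000L * (i - 1L), "+")
  }) |> purrr::list_rbind()
  grid <- segment_grid(genes)
  seg <- grid
  for (s in fx$samples$sample_id) seg[[s]] <- 0L
  qa <- assign_quartiles(fx$expr, fx$samples, "tumor")
  mp <- methylation_meta_profile(seg, fx$samples, genes, qa, group = "tumor")
  expect_true(all(mp$mean_signal == 0))
  # single gene per quartile: profile equals that gene's own ratios
  seg2 <- seg
  seg2[[fx$samples$sample_id[1]]] <- rbinom(nrow(seg2), 1, 0.5)
  mp2 <- methylation_meta_profile(seg2, fx$samples, genes, qa,
                                  group = "tumor")
  expect_true(all(mp2$n_genes == 1))
  r <- methylation_ratio(seg2, fx$samples, "tumor")
  one_gene <- qa$gene_id[qa$quartile == "Q1"]
  bins <- tssmeth:::gene_segment_bins(genes[genes$gene_id == one_gene, ])
  want <- r$ratio[match(bins$seg_start, r$start)]
  got <- mp2$mean_signal[mp2$quartile == "Q1"][order(mp2$position[mp2$quartile == "Q1"])]
  expect_equal(got, want[order(bins$position)])
})

test_that("union of quartile profiles equals the gene-weighted mean", {
  co <- simulate_cohort(cohort_config(n_genes = 60, n_tumor = 10,
                                      n_normal = 10, seed = 12))
  qa <- assign_quartiles(co$expr, co$samples, "tumor")
  mp <- methylation_meta_profile(co$segments, co$samples, co$genes, qa,
                                 group = "tumor")
  pooled <- qa
  pooled$quartile <- factor("Q1", levels = paste0("Q", 1:4))
  mp_all <- methylation_meta_profile(co$segments, co$samples, co$genes,
                                     pooled, group = "tumor")
  by_pos <- mp |>
    dplyr::group_by(position) |>
    dplyr::summarise(m = sum(mean_signal * n_genes) / sum(n_genes))
  expect_equal(by_pos$m,
               mp_all$mean_signal[match(by_pos$position, mp_all$position)],
               tolerance = 1e-12)
})

test_that("ChIP meta-profiles are flat for constant coverage", {
  genes <- purrr::map(1:8, function(i) {
    fixture_gene(sprintf("g%02d", i), 20000L + 12000L * (i - 1L),
                 c("+", "-")[1 + i %% 2])
  }) |> purrr::list_rbind()
  fx <- quartile_fixture(8, 6, seed = 2)
  qa <- assign_quartiles(fx$expr, fx$samples, "tumor")
  cov <- tibble::tibble(chrom = "chr1", start = 0L, end = 200000L, value = 3)
  mp <- chip_meta_profile(cov, genes, qa)
  expect_true(all(abs(mp$mean_signal - 3) < 1e-9))
  expect_equal(sort(unique(mp$position)), seq(-5000L, 4990L, by = 10L))
})

test_that("triangular TSS peaks produce a meta-profile peak at bin 0", {
  genes <- purrr::map(1:4, function(i) {
    fixture_gene(sprintf("g%02d", i), 20000L + 12000L * (i - 1L), "+")
  }) |> purrr::list_rbind()
  fx <- quartile_fixture(4, 4, seed = 5)
  qa <- assign_quartiles(fx$expr, fx$samples, "tumor")
  cov <- purrr::map(genes$tss, function(t) {
    pos <- seq(t - 1000L, t + 990L, by = 10L)
    tibble::tibble(chrom = "chr1", start = pos, end = pos + 10L,
                   value = pmax(0, 100 - abs(pos + 5 - t) / 10))
  }) |> purrr::list_rbind()
  mp <- chip_meta_profile(cov, genes, qa)
  peak_pos <- mp$position[which.max(mp$mean_signal)]
  expect_lte(abs(peak_pos), 10)
})

test_that("ChIP profiles mirror exactly for minus-strand twins", {
  gp <- fixture_gene("plus", 20000L, "+", chrom = "chrP")
  gm <- fixture_gene("minus", 20000L, "-", chrom = "chrM")
  pos <- seq(12000L, 27990L, by = 10L)
  shape <- 5 + 40 * exp(-(pos + 5 - 21000)^2 / (2 * 300^2))  # bump +1 kb on plus
  cov <- dplyr::bind_rows(
    tibble::tibble(chrom = "chrP", start = pos, end = pos + 10L, value = shape),
    # mirrored bump: at 19000 on the minus chromosome (i.e. +1 kb downstream)
    tibble::tibble(chrom = "chrM", start = pos, end = pos + 10L,
                   value = 5 + 40 * exp(-(pos + 5 - 19000)^2 / (2 * 300^2)))
  )
  qa <- tibble::tibble(gene_id = c("plus", "minus"),
                       summary_expr = c(1, 1),
                       quartile = factor(c("Q1", "Q1"),
                                         levels = paste0("Q", 1:4)))
  genes <- dplyr::bind_rows(gp, gm)
  M <- tssmeth:::gene_coverage_matrix(cov, genes)
  expect_equal(M["plus", ], M["minus", ], tolerance = 1e-9)
})

test_that("ChIP profiles are linear under coverage rescaling", {
  genes <- purrr::map(1:4, function(i) {
    fixture_gene(sprintf("g%02d", i), 20000L + 12000L * (i - 1L), "+")
  }) |> purrr::list_rbind()
  fx <- quartile_fixture(4, 4, seed = 6)
  qa <- assign_quartiles(fx$expr, fx$samples, "tumor")
  set.seed(31)
  pos <- seq(10000L, 70000L, by = 10L)
  cov <- tibble::tibble(chrom = "chr1", start = pos, end = pos + 10L,
                        value = runif(length(pos), 0, 10))
  cov2 <- dplyr::mutate(cov, value = value * 7)
  mp1 <- chip_meta_profile(cov, genes, qa)
  mp2 <- chip_meta_profile(cov2, genes, qa)
  expect_equal(mp2$mean_signal, mp1$mean_signal * 7, tolerance = 1e-9)
})

test_that("randomized background bands behave and are reproducible", {
  co <- simulate_cohort(cohort_config(n_genes = 60, n_tumor = 8,
                                      n_normal = 8, seed = 13))
  qa <- assign_quartiles(co$expr, co$samples, "tumor")
  cov <- simulate_chip_coverage(co$genes, qa, mark = "active", seed = 2)
  b1 <- randomized_background(cov, co$genes, co$genes$gene_id,
                              list_size = 20, n_lists = 15, seed = 8)
  b2 <- randomized_background(cov, co$genes, co$genes$gene_id,
                              list_size = 20, n_lists = 15, seed = 8)
  expect_identical(b1, b2)
  expect_true(all(b1$lower <= b1$upper))
  # single list: band collapses onto that list's profile
  b3 <- randomized_background(cov, co$genes, co$genes$gene_id,
                              list_size = 20, n_lists = 1, seed = 8)
  expect_equal(b3$lower, b3$upper)
  expect_error(randomized_background(cov, co$genes, co$genes$gene_id[1:5],
                                     list_size = 20, n_lists = 2, seed = 1),
               "smaller than list_size")
})

test_that("central-95% band covers fresh random lists at most bins", {
  co <- simulate_cohort(cohort_config(n_genes = 80, n_tumor = 8,
                                      n_normal = 8, seed = 23))
  qa <- assign_quartiles(co$expr, co$samples, "tumor")
  cov <- simulate_chip_coverage(co$genes, qa, mark = "repressive", seed = 3)
  band <- randomized_background(cov, co$genes, co$genes$gene_id,
                                list_size = 25, n_lists = 120, seed = 10,
                                band = "central95", bin = 50L)
  M <- tssmeth:::gene_coverage_matrix(cov, co$genes, bin = 50L)
  set.seed(99)
  frac_inside <- replicate(25, {
    rows <- sample.int(nrow(M), 25)
    prof <- colMeans(M[rows, , drop = FALSE])
    mean(prof >= band$lower & prof <= band$upper)
  })
  expect_gte(mean(frac_inside), 0.90)
})
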