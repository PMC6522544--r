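test_that("select_genes picks the minimum-q window with stable ties", {
  cm <- tibble::tibble(
    gene_id = c("a", "a", "b", "c"),
    window_start = c(-500L, 0L, 500L, -1000L),
    rho = c(-0.7, -0.5, 0.6, -0.8),
    p = c(1e-5, 1e-3, 1e-6, 1e-6),
    q = c(5e-4, 1e-2, 1e-5, 2e-3), n = 30L
  )
  sel <- select_genes(cm, q_max = 0.001)
  # a passes at its best window; b fails the sign filter; c fails q_max
  expect_equal(sel$gene_id, "a")
  expect_equal(sel$best_window_start, -500L)
  # tie on q: smaller |window start| wins, then the upstream one
  cm_tie <- tibble::tibble(gene_id = "t", window_start = c(-500L, 0L, 500L),
                           rho = -0.5, p = 1e-4, q = 1e-4, n = 30L)
  expect_equal(select_genes(cm_tie)$best_window_start, 0L)
  cm_tie2 <- tibble::tibble(gene_id = "t", window_start = c(-500L, 500L),
                            rho = -0.5, p = 1e-4, q = 1e-4, n = 30L)
  expect_equal(select_genes(cm_tie2)$best_window_start, -500L)
  expect_equal(nrow(select_genes(cm[0, ])), 0L)
})

test_that("select_genes is stable under row permutation", {
  set.seed(41)
  cm <- tibble::tibble(
    gene_id = rep(sprintf("g%02d", 1:20), each = 20),
    window_start = rep(seq(-5000L, 4500L, by = 500L), 20),
    rho = runif(400, -1, 0), p = runif(400) / 50, n = 30L
  )
  cm$q <- bh_fdr(cm$p)
  s1 <- select_genes(cm, q_max = 0.2)
  s2 <- select_genes(cm[sample(400), ], q_max = 0.2)
  expect_equal(s1, s2)
  expect_equal(s1, select_genes(cm, q_max = 0.2))  # idempotent
})

test_that("methylation change direction recovers planted hyper/hypo mix", {
  co <- simulate_cohort(cohort_config(n_genes = 200, frac_coupled_genes = 0.5,
                                      frac_hyper = 0.9, seed = 29))
  w <- window_scores(co$segments, co$genes, co$chrom_sizes)
  coupled <- co$truth[co$truth$coupled, ]
  sel <- tibble::tibble(gene_id = coupled$gene_id,
                        best_window_start = 0L,
                        rho = -0.5, q = 1e-4)
  mc <- methylation_change(sel, w, co$samples)
  got_hyper <- mean(mc$direction == "increased")
  expect_lt(abs(got_hyper - 0.9), 0.05)
  agree <- mean((mc$direction == "increased") == (coupled$direction == "hyper"))
  expect_gt(agree, 0.9)
})

test_that("exact mean ties classify as decreased with a warning", {
  w <- tibble::tibble(gene_id = "g", window_start = 0L,
                      t1 = 2L, t2 = 2L, n1 = 2L, n2 = 2L)
  samples <- tibble::tibble(sample_id = c("t1", "t2", "n1", "n2"),
                            group = c("tumor", "tumor", "normal", "normal"))
  sel <- tibble::tibble(gene_id = "g", best_window_start = 0L,
                        rho = -0.5, q = 1e-4)
  expect_warning(mc <- methylation_change(sel, w, samples), "decreased")
  expect_equal(mc$direction, "decreased")
})

test_that("ward clustering recovers well-separated planted subtypes", {
  co <- simulate_subtype_cohort(cohort_config(n_genes = 120, n_tumor = 30,
                                              n_normal = 10,
                                              frac_coupled_genes = 0.5,
                                              n_subtypes = 3,
                                              subtype_effect = 4, seed = 5))
  w <- window_scores(co$segments, co$genes, co$chrom_sizes)
  coupled <- co$truth$gene_id[co$truth$coupled]
  sel <- tibble::tibble(gene_id = coupled, best_window_start = 0L,
                        rho = -0.5, q = 1e-4)
  sub <- ward_cluster(sel, w, co$samples, k = 3)
  truth <- co$subtype_truth$subtype[match(sub$assignment$sample_id,
                                          co$subtype_truth$sample_id)]
  ari <- mclust::adjustedRandIndex(sub$assignment$cluster, truth)
  expect_gte(ari, 0.9)
  # cluster 1 is the highest-methylation subtype
  X <- sub$matrix
  mean_by_cluster <- tapply(rowMeans(X), sub$assignment$cluster, mean)
  expect_equal(which.max(mean_by_cluster), c("1" = 1L))
})

test_that("ward clustering degenerate cases behave", {
  co <- small_cohort(seed = 9)
  w <- window_scores(co$segments, co$genes, co$chrom_sizes)
  sel <- tibble::tibble(gene_id = co$genes$gene_id[1:5],
                        best_window_start = 0L, rho = -0.5, q = 1e-4)
  one <- ward_cluster(sel, w, co$samples, k = 1)
  expect_true(all(one$assignment$cluster == 1L))
  expect_error(ward_cluster(sel, w, co$samples, k = 100), "exceeds")
  # duplicated sample rows always co-cluster
  w2 <- w
  w2$dup_a <- w$tumor_01
  w2$dup_b <- w$tumor_01
  samples2 <- dplyr::bind_rows(
    co$samples,
    tibble::tibble(sample_id = c("dup_a", "dup_b"), group = "tumor")
  )
  sub2 <- ward_cluster(sel, w2, samples2, k = 3)
  labs <- sub2$assignment$cluster[sub2$assignment$sample_id %in%
                                    c("dup_a", "dup_b", "tumor_01")]
  expect_equal(length(unique(labs)), 1L)
})

test_that("protein change notation parses into kinds and positions", {
  pc <- parse_protein_change(c("E1566X", "Q771X", "R1446C", "E1550K",
                               "Q2202_Q2203del", "p.S33fs", "p.M1V"))
  expect_equal(pc$kind, c("nonsense", "nonsense", "missense", "missense",
                          "inframe_del", "frameshift", "missense"))
  expect_equal(pc$position_start, c(1566L, 771L, 1446L, 1550L, 2202L, 33L, 1L))
  expect_equal(pc$position_end[5], 2203L)
  expect_error(parse_protein_change("not-a-change"), "not-a-change")
  expect_error(parse_protein_change("Q2203_Q2202del"), "range")
})

test_that("domain-effect classification matches the worked CREBBP example", {
  hat <- c(1342, 1649)
  changes <- c("E1566X", "Q771X", "R1446C", "E1550K", "Q2202_Q2203del")
  hits <- classify_domain_effect(changes, domain = hat)
  expect_equal(hits, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(sum(hits), 4L)
  # truncation downstream of the domain leaves it intact
  expect_false(classify_domain_effect("Q1700X", domain = hat))
  # in-frame deletion overlapping the domain counts
  expect_true(classify_domain_effect("Q1640_Q1660del", domain = hat))
})

test_that("fisher association matches the enumeration oracle", {
  subtypes <- tibble::tibble(sample_id = sprintf("s%02d", 1:12),
                             cluster = rep(c(1L, 2L), c(5, 7)))
  status <- tibble::tibble(sample_id = sprintf("s%02d", 1:12),
                           status = rep(c("mutant", "wildtype", "mutant",
                                          "wildtype"), c(5, 0, 1, 6)))
  out <- fisher_association(status, subtypes, target_cluster = 1)
  # table [[5,0],[1,6]]
  expect_equal(c(out$target_mutant, out$target_wildtype,
                 out$rest_mutant, out$rest_wildtype), c(5L, 0L, 1L, 6L))
  expect_equal(out$p_value, oracle_fisher_p(5, 0, 1, 6), tolerance = 1e-12)
  # Haldane-corrected odds ratio with a zero cell
  expect_equal(out$odds_ratio, (5.5 * 6.5) / (0.5 * 1.5))
  # balanced table: no association
  subtypes2 <- tibble::tibble(sample_id = sprintf("s%02d", 1:8),
                              cluster = rep(c(1L, 2L), each = 4))
  status2 <- tibble::tibble(sample_id = sprintf("s%02d", 1:8),
                            status = rep(c("mutant", "wildtype"), 4))
  expect_equal(fisher_association(status2, subtypes2, 1)$p_value, 1)
})

test_that("fisher p equals the oracle across random small tables", {
  set.seed(61)
  for (i in 1:300) {
    n <- sample(4:40, 1)
    cl <- sample(1:2, n, replace = TRUE)
    mut <- sample(c("mutant", "wildtype"), n, replace = TRUE)
    if (length(unique(cl)) < 2 || length(unique(mut)) < 2) next
    subtypes <- tibble::tibble(sample_id = sprintf("s%03d", 1:n), cluster = cl)
    status <- tibble::tibble(sample_id = sprintf("s%03d", 1:n), status = mut)
    out <- fisher_association(status, subtypes, 1)
    want <- oracle_fisher_p(out$target_mutant, out$target_wildtype,
                            out$rest_mutant, out$rest_wildtype)
    expect_equal(out$p_value, want, tolerance = 1e-12)
  }
})

test_that("fisher p-values are calibrated under independence", {
  set.seed(71)
  ps <- replicate(400, {
    n <- 30
    cl <- sample(rep(c(1L, 2L), c(10, 20)))
    mut <- sample(rep(c("mutant", "wildtype"), c(12, 18)))
    fisher_association(
      tibble::tibble(sample_id = sprintf("s%02d", 1:n), status = mut),
      tibble::tibble(sample_id = sprintf("s%02d", 1:n), cluster = cl),
      1
    )$p_value
  })
  # discrete p-values are super-uniform: P(p <= a) <= a
  for (a in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / 400))
  }
  expect_gt(mean(ps <= 0.5), 0.2)  # and not wildly conservative
})
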