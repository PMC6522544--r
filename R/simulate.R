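#' Configuration for a synthetic methylation-expression cohort
#'
#' Defaults encode the study conditions emulated throughout the package:
#' coupling between methylation and expression sits 1 kb upstream of the
#' TSS in the normal arm and directly at the TSS in the tumor arm, with a
#' realized window-expression Spearman correlation of about 0.5 at the
#' planted window.
#'
#' @param n_genes Number of genes on the synthetic contig.
#' @param n_tumor,n_normal Samples per arm.
#' @param frac_cgi_genes Fraction of genes given a promoter CpG island.
#' @param coupling_normal_center,coupling_tumor_center TSS-relative center
#'   (bp) of the methylation-expression coupling bump per arm.
#' @param coupling_width Gaussian sd (bp) of the spatial coupling bump.
#' @param coupling_rho Target |Spearman rho| between the planted window's
#'   score and expression.
#' @param frac_coupled_genes Fraction of genes with planted coupling.
#' @param frac_hyper Among coupled genes, fraction hypermethylated in
#'   tumor (the rest are hypomethylated: elevated in normal instead).
#' @param n_subtypes Number of planted tumor methylation subtypes.
#' @param subtype_effect Logit-scale separation between adjacent subtype
#'   means at coupled genes (0 = no subtype structure).
#' @param baseline_meth_prob Marginal segment methylation probability away
#'   from coupling bumps.
#' @param noise_sd SD of log2 expression noise.
#' @param seed Integer seed; every generator output is a pure function of
#'   config + seed.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_genes = 300L, n_tumor = 40L, n_normal = 40L,
                          frac_cgi_genes = 0.66,
                          coupling_normal_center = -1000L,
                          coupling_tumor_center = 0L,
                          coupling_width = 300L, coupling_rho = 0.5,
                          frac_coupled_genes = 0.3, frac_hyper = 0.88,
                          n_subtypes = 1L, subtype_effect = 0,
                          baseline_meth_prob = 0.2, noise_sd = 0.5,
                          seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_tumor = as.integer(n_tumor),
              n_normal = as.integer(n_normal),
              frac_cgi_genes = frac_cgi_genes,
              coupling_normal_center = as.integer(coupling_normal_center),
              coupling_tumor_center = as.integer(coupling_tumor_center),
              coupling_width = as.integer(coupling_width),
              coupling_rho = coupling_rho,
              frac_coupled_genes = frac_coupled_genes,
              frac_hyper = frac_hyper, n_subtypes = as.integer(n_subtypes),
              subtype_effect = subtype_effect,
              baseline_meth_prob = baseline_meth_prob,
              noise_sd = noise_sd, seed = as.integer(seed))
  fr <- c("frac_cgi_genes", "frac_coupled_genes", "frac_hyper",
          "baseline_meth_prob")
  for (f in fr) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(sprintf("%s must be in [0, 1]", f))
  }
  if (abs(cfg$coupling_normal_center) > SPAN ||
      abs(cfg$coupling_tumor_center) > SPAN) {
    abort("coupling centers must lie within +/- 5000 bp")
  }
  if (cfg$coupling_rho <= 0 || cfg$coupling_rho >= 1) {
    abort("coupling_rho must be in (0, 1)")
  }
  if (cfg$n_subtypes < 1) abort("n_subtypes must be >= 1")
  structure(cfg, class = "cohort_config")
}

# Logit slope of the latent propensity on segment methylation needed to
# realize a target window-score/expression Spearman rho (with the
# expression side fixed at one unit of latent signal + noise_sd 0.5).
# Calibration table fitted once by simulation at 40 samples/arm (120
# replicates per point) and frozen; discreteness of the 0-5 window score
# caps the achievable |rho| near 0.79, so targets above that are clamped.
# See the methods vignette.
calib_table <- list(
  slope = c(0.05, 0.10, 0.15, 0.20, 0.30, 0.40, 0.50, 0.60, 0.70, 0.80,
            1.00, 1.30, 1.60, 2.00, 2.50, 3.00, 4.00),
  rho = c(0.1284, 0.1336, 0.1580, 0.1861, 0.2434, 0.3034, 0.3650, 0.4151,
          0.4583, 0.5039, 0.5657, 0.6446, 0.6867, 0.7318, 0.7602, 0.7744,
          0.7873)
)

calib_slope <- function(rho) {
  tab <- calib_table
  if (rho <= tab$rho[1]) return(tab$slope[1])
  if (rho >= max(tab$rho)) return(max(tab$slope))
  stats::splinefun(tab$rho, tab$slope, method = "hyman")(rho)
}

slot_bp <- 12000L

#' Generate a synthetic cohort (annotation, methylation, expression)
#'
#' Genes are laid out on one synthetic contig with disjoint TSS +/- 5 kb
#' territories. For coupled genes, a per-sample latent propensity drives
#' both segment methylation (through a thresholded Bernoulli under a
#' spatial Gaussian bump centered at the arm's coupling location) and
#' log-scale expression, producing a negative methylation-expression
#' correlation of the configured strength at the planted window.
#' Hypermethylated coupled genes additionally carry an elevated bump and
#' reduced mean expression in tumor (hypomethylated ones in normal), so
#' expression quartiles also separate methylation at the TSS. Uncoupled
#' genes are independent Bernoulli segments with log-normal expression.
#'
#' @param cfg A [cohort_config()].
#' @return List with `genes`, `cgi`, `chrom_sizes`, `segments` (binary
#'   calls), `expr`, `samples`, `truth` (per-gene ground truth), and
#'   `subtype_truth` (per-tumor-sample planted subtype).
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  chrom <- "chrS1"
  chrom_sizes <- setNames(n * slot_bp, chrom)

  tss <- 5500L + slot_bp * (seq_len(n) - 1L)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_id <- sprintf("g%04d", seq_len(n))
  start <- ifelse(strand == "+", tss, tss - 1999L)
  end <- ifelse(strand == "+", tss + 2000L, tss + 1L)
  genes <- tibble(gene_id = gene_id, chrom = chrom,
                  start = as.integer(start), end = as.integer(end),
                  strand = strand, tss = tss)
  prom <- make_promoter(genes$tss, genes$strand)
  genes$promoter_start <- prom$start
  genes$promoter_end <- prom$end

  is_cgi <- seq_len(n) %in% sample.int(n, round(cfg$frac_cgi_genes * n))
  cgi <- tibble(chrom = chrom, start = tss[is_cgi] - 300L,
                end = tss[is_cgi] + 300L)
  genes$is_cgi_gene <- classify_cgi_genes(genes, cgi)

  n_coupled <- round(cfg$frac_coupled_genes * n)
  coupled <- seq_len(n) %in% sample.int(n, n_coupled)
  hyper <- logical(n)
  hyper[coupled] <- seq_len(n_coupled) %in%
    sample.int(n_coupled, round(cfg$frac_hyper * n_coupled))

  samples <- tibble(
    sample_id = c(sprintf("tumor_%02d", seq_len(cfg$n_tumor)),
                  sprintf("normal_%02d", seq_len(cfg$n_normal))),
    group = rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal))
  )
  n_s <- nrow(samples)
  is_tumor <- samples$group == "tumor"

  subtype <- rep(1L, cfg$n_tumor)
  if (cfg$n_subtypes > 1) {
    subtype <- sample(rep_len(seq_len(cfg$n_subtypes), cfg$n_tumor))
  }
  # centered logit offset per tumor sample at coupled genes
  sub_off <- numeric(n_s)
  sub_off[is_tumor] <- cfg$subtype_effect *
    (subtype - (cfg$n_subtypes + 1) / 2)

  a <- calib_slope(cfg$coupling_rho)
  delta_bump <- 1.5   # arm-specific bump elevation for hyper/hypo genes
  expr_shift <- 1.5   # matching log2 expression drop in the elevated arm
  q0 <- stats::qlogis(cfg$baseline_meth_prob)
  center <- ifelse(is_tumor, cfg$coupling_tumor_center,
                   cfg$coupling_normal_center)

  mu <- rnorm(n, mean = 5, sd = 1.5)
  smap <- gene_segment_bins(genes)  # rel position of each segment (100-bp bin start)

  M <- matrix(0L, nrow = n * 100L, ncol = n_s)
  logE <- matrix(0, nrow = n, ncol = n_s)
  for (g in seq_len(n)) {
    rows <- ((g - 1L) * 100L + 1L):(g * 100L)
    if (!coupled[g]) {
      M[rows, ] <- rbinom(100L * n_s, 1L, cfg$baseline_meth_prob)
      logE[g, ] <- mu[g] + rnorm(n_s, sd = cfg$noise_sd)
      next
    }
    r_mid <- smap$position[rows] + 50L  # strand-aware segment midpoint
    z <- rnorm(n_s)
    elevated_arm <- if (hyper[g]) is_tumor else !is_tumor
    bump_amp <- delta_bump * elevated_arm + sub_off + a * z
    G <- exp(-outer(r_mid, center, "-")^2 / (2 * cfg$coupling_width^2))
    p <- stats::plogis(q0 + G * matrix(bump_amp, nrow = 100L, ncol = n_s,
                                       byrow = TRUE))
    M[rows, ] <- rbinom(length(p), 1L, p)
    logE[g, ] <- mu[g] - expr_shift * elevated_arm - z +
      rnorm(n_s, sd = cfg$noise_sd)
  }

  segments <- tibble(chrom = smap$chrom, start = smap$seg_start)
  ord <- order(segments$start)
  segments <- segments[ord, ]
  for (j in seq_len(n_s)) segments[[samples$sample_id[j]]] <- M[ord, j]

  expr <- tibble(gene_id = gene_id)
  for (j in seq_len(n_s)) expr[[samples$sample_id[j]]] <- 2^logE[, j]

  truth <- tibble(
    gene_id = gene_id, coupled = coupled,
    direction = ifelse(!coupled, NA_character_,
                       ifelse(hyper, "hyper", "hypo")),
    tumor_center = ifelse(coupled, cfg$coupling_tumor_center, NA_integer_),
    normal_center = ifelse(coupled, cfg$coupling_normal_center, NA_integer_),
    is_cgi_gene = genes$is_cgi_gene
  )

  list(genes = genes, cgi = cgi, chrom_sizes = chrom_sizes,
       segments = segments, expr = expr, samples = samples, truth = truth,
       subtype_truth = tibble(
         sample_id = samples$sample_id[is_tumor], subtype = subtype),
       config = cfg)
}

#' Generate a cohort with planted tumor methylation subtypes
#'
#' Convenience wrapper around [simulate_cohort()] with subtype structure
#' switched on: tumor samples are partitioned into `n_subtypes` groups
#' whose mean methylation at coupled genes is shifted by multiples of
#' `subtype_effect`.
#'
#' @param cfg A [cohort_config()]; `n_subtypes` defaults to 3 and
#'   `subtype_effect` to 2 if left at the no-structure defaults.
#' @return As [simulate_cohort()]; `subtype_truth` carries the planted
#'   labels.
#' @export
simulate_subtype_cohort <- function(cfg = cohort_config(n_subtypes = 3L,
                                                        subtype_effect = 2)) {
  if (cfg$n_subtypes > 1 && cfg$subtype_effect == 0) {
    abort("subtype_effect must be > 0 when planting subtypes")
  }
  simulate_cohort(cfg)
}

#' Simulate a ChIP coverage track around every TSS
#'
#' Active-mark coverage is biphasic: bumps flank a nucleosome-depleted
#' TSS, the stronger one about 1 kb downstream, scaled up with expression
#' quartile. Repressive-mark coverage is a broad plateau scaled down with
#' expression, depleted at the TSS in `mode = "normal"` but not in
#' `mode = "tumor"`. Optional Poisson count noise.
#'
#' @param genes Gene tibble.
#' @param quartiles Quartile assignment from [assign_quartiles()].
#' @param mark `"active"` or `"repressive"`.
#' @param mode `"normal"` or `"tumor"` (repressive mark only: tumor mode
#'   removes the TSS depletion).
#' @param noise `"poisson"` or `"none"` (exact analytic profile).
#' @param seed Integer seed.
#' @param bin Bin width in bp (default 10).
#' @return bedGraph-style tibble `chrom`, `start`, `end`, `value` covering
#'   each gene's TSS +/- 5 kb in `bin`-bp steps.
#' @export
simulate_chip_coverage <- function(genes, quartiles,
                                   mark = c("active", "repressive"),
                                   mode = c("normal", "tumor"),
                                   noise = c("poisson", "none"),
                                   seed = 1, bin = 10L) {
  mark <- match.arg(mark)
  mode <- match.arg(mode)
  noise <- match.arg(noise)
  set.seed(as.integer(seed))
  qnum <- as.integer(quartiles$quartile[match(genes$gene_id,
                                              quartiles$gene_id)])
  if (anyNA(qnum)) abort("every gene needs a quartile assignment")
  rel <- seq(-SPAN, SPAN - bin, by = bin) + bin / 2
  out <- purrr::pmap(
    list(genes$chrom, genes$tss, genes$strand, qnum),
    function(ch, t, st, q) {
      lam <- if (mark == "active") {
        amp <- 0.5 + 1.5 * (q - 1)
        dip <- 1 - 0.8 * exp(-rel^2 / (2 * 150^2))
        0.2 + amp * dip * (0.35 * exp(-(rel + 500)^2 / (2 * 300^2)) +
                             exp(-(rel - 1000)^2 / (2 * 400^2)))
      } else {
        level <- 2 * (1 + 0.8 * (4 - q) / 3)
        plateau <- exp(-rel^2 / (2 * 6000^2))
        dip <- if (mode == "normal") {
          1 - 0.6 * exp(-rel^2 / (2 * 400^2))
        } else {
          1
        }
        0.2 + level * plateau * dip
      }
      value <- if (noise == "poisson") rpois(length(lam), lam * bin) / bin else lam
      gstart <- if (st == "+") t + rel - bin / 2 else t - rel - bin / 2
      tibble(chrom = ch, start = as.integer(gstart),
             end = as.integer(gstart + bin), value = value)
    }
  ) |>
    purrr::list_rbind() |>
    arrange(.data$chrom, .data$start)
  out
}

#' Write a synthetic cohort to disk in standard formats
#'
#' Writes the exact formats the readers consume: BED6 genes, BED3 CpG
#' islands, a chrom.sizes TSV, a per-sample peak BED (runs of methylated
#' segments merged into intervals) plus a sample manifest, the expression
#' TSV, ground-truth sidecar TSVs, and the config as YAML.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- cohort$genes
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", g$chrom, g$start, g$end,
                     g$gene_id, g$strand),
             file.path(dir, "genes.bed"))
  writeLines(sprintf("%s\t%d\t%d", cohort$cgi$chrom, cohort$cgi$start,
                     cohort$cgi$end),
             file.path(dir, "cgi.bed"))
  writeLines(sprintf("%s\t%d", names(cohort$chrom_sizes),
                     cohort$chrom_sizes),
             file.path(dir, "chrom.sizes"))
  peaks_dir <- file.path(dir, "peaks")
  dir.create(peaks_dir, showWarnings = FALSE)
  segs <- cohort$segments
  manifest <- cohort$samples
  manifest$path <- file.path("peaks", paste0(manifest$sample_id, ".bed"))
  for (s in manifest$sample_id) {
    on <- which(segs[[s]] == 1L)
    lines <- character(0)
    if (length(on)) {
      # merge consecutive methylated segments into peak intervals
      runs <- split(on, cumsum(c(1, diff(segs$start[on]) != 100L |
                                   diff(on) != 1L)))
      lines <- vapply(runs, function(ix) {
        sprintf("%s\t%d\t%d", segs$chrom[ix[1]], segs$start[ix[1]],
                segs$start[ix[length(ix)]] + 100L)
      }, "")
    }
    writeLines(lines, file.path(dir, "peaks", paste0(s, ".bed")))
  }
  readr::write_tsv(manifest, file.path(dir, "samples.tsv"))
  readr::write_tsv(cohort$expr, file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth_genes.tsv"))
  readr::write_tsv(cohort$subtype_truth, file.path(dir, "truth_subtypes.tsv"))
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(unclass(cohort$config), file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
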