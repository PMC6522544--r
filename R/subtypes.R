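#' Select genes with strongly significant methylation-expression coupling
#'
#' Picks, per gene, the window with the smallest q-value (ties broken by
#' smaller absolute TSS-relative start, then upstream) and keeps genes
#' whose best window passes the significance and sign filters — the gene
#' set used for methylation subtype clustering.
#'
#' @param cm Correlation map built on the tumor arm.
#' @param q_max Significance threshold (default 0.001).
#' @param sign `"negative"` (default), `"positive"`, or `"any"`.
#' @return Tibble `gene_id`, `best_window_start`, `rho`, `q`, one row per
#'   selected gene.
#' @export
select_genes <- function(cm, q_max = 0.001,
                         sign = c("negative", "positive", "any")) {
  sign <- match.arg(sign)
  if (nrow(cm) == 0) {
    return(tibble(gene_id = character(), best_window_start = integer(),
                  rho = numeric(), q = numeric()))
  }
  best <- cm |>
    group_by(.data$gene_id) |>
    arrange(.data$q, abs(.data$window_start), .data$window_start,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  keep <- best$q < q_max
  if (sign == "negative") keep <- keep & best$rho < 0
  if (sign == "positive") keep <- keep & best$rho > 0
  best[keep, ] |>
    transmute(gene_id = .data$gene_id,
              best_window_start = .data$window_start,
              rho = .data$rho, q = .data$q) |>
    arrange(.data$gene_id)
}

#' Direction of tumor methylation change at selected genes
#'
#' Compares tumor and normal mean window scores at each selected gene's
#' best window: `increased` when the tumor mean exceeds the normal mean,
#' otherwise `decreased` (exact ties count as decreased, with a warning).
#'
#' @param selection Gene selection from [select_genes()].
#' @param wsm Window-score tibble.
#' @param samples Sample manifest.
#' @return The selection with `tumor_mean`, `normal_mean`, `direction`
#'   columns appended.
#' @export
methylation_change <- function(selection, wsm, samples) {
  t_ids <- samples$sample_id[samples$group == "tumor"]
  n_ids <- samples$sample_id[samples$group == "normal"]
  if (length(t_ids) == 0 || length(n_ids) == 0) {
    abort("both tumor and normal samples are required")
  }
  idx <- match(paste(selection$gene_id, selection$best_window_start),
               paste(wsm$gene_id, wsm$window_start))
  if (anyNA(idx)) abort("selection refers to windows absent from the score matrix")
  tm <- rowMeans(sample_cols(wsm, t_ids)[idx, , drop = FALSE])
  nm <- rowMeans(sample_cols(wsm, n_ids)[idx, , drop = FALSE])
  if (any(tm == nm)) {
    warn(sprintf("%d gene(s) with exactly equal tumor and normal means classified as 'decreased'",
                 sum(tm == nm)))
  }
  selection |>
    mutate(tumor_mean = tm, normal_mean = nm,
           direction = ifelse(tm > nm, "increased", "decreased"))
}

#' Ward-linkage methylation subtype clustering
#'
#' Clusters tumor samples on the window scores of the selected genes'
#' best windows using Euclidean distance and Ward's linkage, cutting the
#' tree at `k` clusters. Cluster labels are reordered by descending mean
#' methylation so cluster 1 is always the "high" methylation subtype.
#'
#' @param selection Gene selection from [select_genes()].
#' @param wsm Window-score tibble.
#' @param samples Sample manifest; clustering is over the tumor arm.
#' @param k Number of clusters (default 3).
#' @param scale_genes Z-score each gene's scores before clustering
#'   (default FALSE: raw 0-5 scores).
#' @return A `tss_subtypes` object: list with `assignment` (tibble
#'   `sample_id`, `cluster`), `k`, `hclust`, `cut_height`, `matrix`.
#' @export
ward_cluster <- function(selection, wsm, samples, k = 3,
                         scale_genes = FALSE) {
  ids <- samples$sample_id[samples$group == "tumor"]
  if (length(ids) < k) abort(sprintf("k = %d exceeds the %d tumor samples", k, length(ids)))
  if (nrow(selection) == 0) abort("empty gene selection")
  idx <- match(paste(selection$gene_id, selection$best_window_start),
               paste(wsm$gene_id, wsm$window_start))
  X <- t(sample_cols(wsm, ids)[idx, , drop = FALSE])  # samples x genes
  colnames(X) <- selection$gene_id
  rownames(X) <- ids
  if (scale_genes) {
    keep <- apply(X, 2, sd) > 0
    X <- scale(X[, keep, drop = FALSE])
  }
  hc <- hclust(dist(X), method = "ward.D2")
  raw <- if (k == 1) setNames(rep(1L, length(ids)), ids) else cutree(hc, k = k)
  # relabel: cluster 1 = highest mean methylation
  means <- vapply(seq_len(k), function(j) mean(X[raw == j, , drop = FALSE]),
                  numeric(1))
  relabel <- match(seq_len(k), order(means, decreasing = TRUE))
  cluster <- as.integer(relabel[raw])
  cut_height <- if (k == 1 || k >= length(ids)) NA_real_ else {
    h <- sort(hc$height, decreasing = TRUE)
    mean(h[c(k - 1, k)])
  }
  structure(
    list(assignment = tibble(sample_id = ids, cluster = cluster),
         k = as.integer(k), hclust = hc, cut_height = cut_height,
         matrix = X),
    class = "tss_subtypes"
  )
}

#' @export
print.tss_subtypes <- function(x, ...) {
  cat(sprintf("Methylation subtypes: %d clusters over %d tumor samples (Ward/Euclidean)\n",
              x$k, nrow(x$assignment)))
  print(table(cluster = x$assignment$cluster))
  invisible(x)
}

#' @describeIn ward_cluster Per-sample cluster assignment as a tibble.
#' @param x A `tss_subtypes` object.
#' @param ... Unused.
#' @export
tidy.tss_subtypes <- function(x, ...) x$assignment

#' @describeIn ward_cluster One-row summary (k, n, cut height, cluster
#'   sizes).
#' @export
glance.tss_subtypes <- function(x, ...) {
  sizes <- table(x$assignment$cluster)
  tibble(k = x$k, n_samples = nrow(x$assignment),
         cut_height = x$cut_height,
         size_high = as.integer(sizes[1]),
         size_smallest = as.integer(min(sizes)))
}

#' Parse a compact protein-change string
#'
#' Accepts the compact notation used in mutation tables (`R1446C`,
#' `Q771X`, `Q2202_Q2203del`, `S33fs`) and the same forms with an `p.`
#' prefix. Substitutions to `X`/`*` are nonsense; `fs` suffixes are
#' frameshifts; `_..del` ranges are in-frame deletions.
#'
#' @param raw Character vector of protein-change strings.
#' @return Tibble `raw`, `kind` (missense/nonsense/frameshift/
#'   inframe_del), `position_start`, `position_end`.
#' @export
parse_protein_change <- function(raw) {
  parse_one <- function(s) {
    s0 <- s
    s <- sub("^p\\.", "", s)
    m <- regmatches(s, regexec("^[A-Z](\\d+)_[A-Z](\\d+)del$", s))[[1]]
    if (length(m)) {
      a <- as.integer(m[2]); b <- as.integer(m[3])
      if (a > b) abort(sprintf("invalid residue range in '%s'", s0))
      return(tibble(raw = s0, kind = "inframe_del",
                    position_start = a, position_end = b))
    }
    m <- regmatches(s, regexec("^[A-Z](\\d+)del$", s))[[1]]
    if (length(m)) {
      a <- as.integer(m[2])
      return(tibble(raw = s0, kind = "inframe_del",
                    position_start = a, position_end = a))
    }
    m <- regmatches(s, regexec("^[A-Z](\\d+)(fs.*)$", s))[[1]]
    if (length(m)) {
      a <- as.integer(m[2])
      return(tibble(raw = s0, kind = "frameshift",
                    position_start = a, position_end = a))
    }
    m <- regmatches(s, regexec("^[A-Z](\\d+)([A-Z*])$", s))[[1]]
    if (length(m)) {
      a <- as.integer(m[2])
      kind <- if (m[3] %in% c("X", "*")) "nonsense" else "missense"
      return(tibble(raw = s0, kind = kind,
                    position_start = a, position_end = a))
    }
    abort(sprintf("cannot parse protein change '%s'", s0))
  }
  purrr::map(raw, parse_one) |> purrr::list_rbind()
}

#' Does a protein change affect a domain?
#'
#' TRUE when any altered residue lies within the domain, or when the
#' change truncates the protein (nonsense or frameshift) at or upstream of
#' the domain end — a truncation before the domain's last residue removes
#' or disrupts it.
#'
#' @param changes Parsed changes from [parse_protein_change()] (or a
#'   character vector, parsed on the fly).
#' @param domain Integer length-2 residue interval, e.g. `c(1342, 1649)`.
#' @return Logical vector, one element per change.
#' @export
#' @examples
#' classify_domain_effect(c("R1446C", "Q771X", "Q2202_Q2203del"),
#'                        domain = c(1342, 1649))
classify_domain_effect <- function(changes, domain) {
  stopifnot(length(domain) == 2, domain[1] <= domain[2], domain[1] >= 1)
  if (is.character(changes)) changes <- parse_protein_change(changes)
  overlap <- changes$position_start <= domain[2] &
    changes$position_end >= domain[1]
  truncates <- changes$kind %in% c("nonsense", "frameshift") &
    changes$position_start <= domain[2]
  overlap | truncates
}

#' Mutation-subtype association by Fisher's exact test
#'
#' Tests the 2x2 table (target cluster vs rest) x (mutant vs wildtype)
#' with the two-sided Fisher exact test. The odds ratio is the sample
#' cross-product ratio with Haldane's 0.5 correction applied when any
#' cell is zero.
#'
#' @param mutation_status Tibble `sample_id`, `status` with values
#'   `mutant`/`wildtype`.
#' @param subtypes A `tss_subtypes` object (or its `tidy()` tibble).
#' @param target_cluster Cluster label defining the phenotype of interest
#'   (e.g. 1 for the hypermethylation subtype).
#' @return Tibble with `odds_ratio`, `p_value`, and the four table cells.
#' @export
fisher_association <- function(mutation_status, subtypes, target_cluster) {
  assignment <- if (inherits(subtypes, "tss_subtypes")) {
    subtypes$assignment
  } else {
    subtypes
  }
  df <- inner_join(assignment, mutation_status, by = "sample_id")
  if (nrow(df) == 0) abort("no overlapping samples")
  if (!all(df$status %in% c("mutant", "wildtype"))) {
    abort("status must be 'mutant' or 'wildtype'")
  }
  in_target <- df$cluster == target_cluster
  mutant <- df$status == "mutant"
  a <- sum(in_target & mutant)
  b <- sum(in_target & !mutant)
  c <- sum(!in_target & mutant)
  d <- sum(!in_target & !mutant)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    abort("degenerate margin in the 2x2 table")
  }
  p <- fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
  hal <- if (any(c(a, b, c, d) == 0)) 0.5 else 0
  or <- ((a + hal) * (d + hal)) / ((b + hal) * (c + hal))
  tibble(odds_ratio = or, p_value = p,
         target_mutant = a, target_wildtype = b,
         rest_mutant = c, rest_wildtype = d)
}
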