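#' Read a BED6 gene annotation
#'
#' Parses a BED6 file (chrom, start, end, name, score, strand; 0-based
#' half-open coordinates) into a gene table with one canonical TSS per gene.
#' The TSS is `start` for `+` genes and `end - 1` for `-` genes. Promoters
#' (-1500/+500 bp around the TSS, strand-aware) and CpG-island gene status
#' are added when `cgi` is supplied.
#'
#' @param path Path to a BED6 file. Comment (`#`) and `track` lines are
#'   ignored.
#' @param cgi Optional CpG-island interval tibble (`chrom`, `start`, `end`),
#'   e.g. from [read_cgi_bed()]; used to classify CGI vs noCGI genes.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `promoter_start`, `promoter_end` and, when `cgi` is
#'   given, `is_cgi_gene`.
#' @export
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t1000\t5000\tgeneA\t0\t+",
#'              "chr1\t9000\t12000\tgeneB\t0\t-"), bed)
#' read_gene_bed(bed)
read_gene_bed <- function(path, cgi = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 6)) {
    i <- which(n_fields < 6)[1]
    abort(sprintf("line %d: expected >= 6 BED fields, got %d (strand required)",
                  line_no[i], n_fields[i]))
  }
  genes <- tibble(
    chrom   = vapply(fields, `[[`, "", 1),
    start   = suppressWarnings(as.integer(vapply(fields, `[[`, "", 2))),
    end     = suppressWarnings(as.integer(vapply(fields, `[[`, "", 3))),
    gene_id = vapply(fields, `[[`, "", 4),
    strand  = vapply(fields, `[[`, "", 6)
  )
  bad <- which(is.na(genes$start) | is.na(genes$end))
  if (length(bad)) {
    abort(sprintf("line %d: non-integer start/end", line_no[bad[1]]))
  }
  bad <- which(genes$start >= genes$end | genes$start < 0)
  if (length(bad)) {
    abort(sprintf("line %d: requires 0 <= start < end, got [%d, %d)",
                  line_no[bad[1]], genes$start[bad[1]], genes$end[bad[1]]))
  }
  bad <- which(!genes$strand %in% c("+", "-"))
  if (length(bad)) {
    abort(sprintf("line %d: strand must be '+' or '-', got '%s'",
                  line_no[bad[1]], genes$strand[bad[1]]))
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup)) {
    abort(sprintf("duplicate gene id(s): %s",
                  paste(unique(dup), collapse = ", ")))
  }
  genes <- genes |>
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L)) |>
    select("gene_id", "chrom", "start", "end", "strand", "tss")
  prom <- make_promoter(genes$tss, genes$strand)
  genes$promoter_start <- prom$start
  genes$promoter_end <- prom$end
  if (!is.null(cgi)) {
    genes$is_cgi_gene <- classify_cgi_genes(genes, cgi)
  }
  genes
}

#' Read CpG island intervals (BED3+)
#'
#' Accepts plain BED3/BED4 or UCSC `cpgIslandExt`-style tables; columns past
#' the third are ignored.
#'
#' @param path Path to a BED-like file.
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
read_cgi_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) abort("CGI BED requires >= 3 columns")
  out <- tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = as.integer(vapply(fields, `[[`, "", 2)),
    end   = as.integer(vapply(fields, `[[`, "", 3))
  )
  if (any(is.na(out$start) | is.na(out$end) | out$start >= out$end)) {
    abort("malformed CGI interval (start must be < end)")
  }
  out
}

#' Read a two-column chromosome sizes table
#'
#' @param path Path to a TSV with columns chrom, length.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "size"),
                       col_types = "ci", progress = FALSE)
  setNames(x$size, x$chrom)
}

#' Promoter interval around a TSS
#'
#' The promoter is the region 1500 bp upstream through 500 bp downstream of
#' the TSS, strand-aware, as a 0-based half-open interval clipped at
#' position 0. Unclipped promoters are exactly 2000 bp.
#'
#' @param tss Integer vector of TSS positions (0-based).
#' @param strand Character vector, `"+"` or `"-"`, recycled with `tss`.
#' @return A tibble with columns `start`, `end`, `clipped`.
#' @export
#' @examples
#' make_promoter(10000, "+") # [8500, 10500)
#' make_promoter(10000, "-") # [9501, 11501)
make_promoter <- function(tss, strand) {
  stopifnot(all(tss >= 0), all(strand %in% c("+", "-")))
  n <- max(length(tss), length(strand))
  tss <- as.integer(rep_len(tss, n))
  strand <- rep_len(strand, n)
  start <- ifelse(strand == "+", tss - 1500L, tss - 499L)
  end <- ifelse(strand == "+", tss + 500L, tss + 1501L)
  clipped <- start < 0L
  tibble(start = pmax(start, 0L), end = as.integer(end), clipped = clipped)
}

#' Classify genes as CGI or noCGI
#'
#' A gene is a CGI gene iff any CpG island overlaps its promoter by at
#' least 1 bp.
#'
#' @param genes Gene tibble with `chrom`, `promoter_start`, `promoter_end`.
#' @param cgi CpG island tibble (`chrom`, `start`, `end`).
#' @return Logical vector, one element per gene.
#' @export
classify_cgi_genes <- function(genes, cgi) {
  out <- logical(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    ci <- cgi[cgi$chrom == ch, ]
    if (nrow(ci) == 0) next
    prom <- IRanges::IRanges(start = genes$promoter_start[gi] + 1L,
                             end = genes$promoter_end[gi])
    isl <- IRanges::IRanges(start = ci$start + 1L, end = ci$end)
    out[gi] <- IRanges::overlapsAny(prom, isl)
  }
  out
}

#' Strand-aware TSS-relative position
#'
#' Signed distance of genomic positions from a TSS: negative values are
#' upstream of the TSS on the gene's strand.
#'
#' @param pos Integer vector of genomic positions.
#' @param tss TSS position(s).
#' @param strand `"+"` or `"-"`.
#' @return Integer vector of signed TSS-relative offsets.
#' @export
#' @examples
#' tss_relative(1100, 1000, "+") # +100 (downstream)
#' tss_relative(1100, 1000, "-") # -100 (upstream)
tss_relative <- function(pos, tss, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  n <- max(length(pos), length(tss), length(strand))
  pos <- rep_len(pos, n)
  tss <- rep_len(tss, n)
  strand <- rep_len(strand, n)
  as.integer(ifelse(strand == "+", pos - tss, tss - pos))
}
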