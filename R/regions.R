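#' Construct a region table
#'
#' All genomic intervals in rddm — tiles, windows, DMRs, siRNA clusters,
#' annotation features — are plain tibbles with 0-based, half-open
#' coordinates: `chrom`, `start` (0-based, inclusive), `end` (0-based,
#' exclusive) and `strand` (`"+"`, `"-"` or `"."`). One-based coordinates
#' appear only at file boundaries (GFF3, methratio TSV).
#'
#' @param chrom Chromosome names (character).
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions (`end > start`).
#' @param strand Strand, one of `"+"`, `"-"`, `"."` (recycled).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' region_tbl("chr1", 0, 500)
#' @export
region_tbl <- function(chrom, start, end, strand = ".") {
  x <- tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = as.character(strand)
  )
  validate_regions(x)
  x
}

validate_regions <- function(x, what = "regions") {
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s must have columns %s (missing: %s)",
                  what, paste(need, collapse = ", "),
                  paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    abort(sprintf("%s: chrom must be non-empty", what))
  }
  if (any(x$start < 0)) abort(sprintf("%s: start must be >= 0", what))
  bad <- which(x$end <= x$start)
  if (length(bad) > 0) {
    abort(sprintf("%s: end must be > start (first bad row: %d, [%s, %s))",
                  what, bad[1], x$start[bad[1]], x$end[bad[1]]))
  }
  invisible(x)
}

# 0-based half-open tibble -> GRanges (1-based closed). Strand "." -> "*".
as_granges <- function(x) {
  if (nrow(x) == 0) return(GenomicRanges::GRanges())
  strand <- if ("strand" %in% names(x)) x$strand else "."
  strand <- ifelse(strand %in% c("+", "-"), strand, "*")
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = strand
  )
}

# For each row of `a`, does it overlap (>= 1 bp, strand-blind) any row of `b`?
overlaps_any <- function(a, b) {
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  GenomicRanges::countOverlaps(as_granges(a), as_granges(b),
                               ignore.strand = TRUE) > 0
}

# Index (into b) of some overlapping row of b per row of a, NA if none.
overlap_index <- function(a, b) {
  out <- rep(NA_integer_, nrow(a))
  if (nrow(b) == 0) return(out)
  hits <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b),
                                      ignore.strand = TRUE)
  first_hit <- !duplicated(S4Vectors::queryHits(hits))
  out[S4Vectors::queryHits(hits)[first_hit]] <- S4Vectors::subjectHits(hits)[first_hit]
  out
}

#' Read per-cytosine methylation calls (methratio-shaped TSV)
#'
#' Reads a tab-separated table with columns `chrom`, `pos` (1-based cytosine
#' position), `strand`, `context` (CG/CHG/CHH), `n_meth`, `n_total` — the
#' canonical 6-column subset of BSMAP methratio output. Positions are
#' converted to 0-based half-open single-base regions.
#'
#' @param path Path to the TSV file (a header line is expected).
#' @param sample Optional sample name stored in a `sample` column.
#' @return A tibble with columns `sample` (if given), `chrom`, `start`,
#'   `end`, `strand`, `context`, `n_meth`, `n_total`.
#' @export
read_methylation_calls <- function(path, sample = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           pos = readr::col_double(),
                           strand = readr::col_character(),
                           context = readr::col_character(),
                           n_meth = readr::col_double(),
                           n_total = readr::col_double()
                         ))
  check_calls(raw, path)
  out <- tibble(
    chrom = raw$chrom,
    start = raw$pos - 1,
    end = raw$pos,
    strand = raw$strand,
    context = raw$context,
    n_meth = raw$n_meth,
    n_total = raw$n_total
  )
  if (!is.null(sample)) out <- mutate(out, sample = sample, .before = 1)
  out
}

check_calls <- function(raw, path) {
  line_of <- function(i) i + 1L  # header occupies line 1
  bad <- which(!raw$context %in% c("CG", "CHG", "CHH"))
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: unknown context '%s'",
                  path, line_of(bad[1]), raw$context[bad[1]]))
  }
  bad <- which(raw$n_meth > raw$n_total)
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: n_meth (%s) exceeds n_total (%s)",
                  path, line_of(bad[1]), raw$n_meth[bad[1]], raw$n_total[bad[1]]))
  }
  bad <- which(raw$n_total <= 0 | raw$n_meth < 0)
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: counts must satisfy 0 <= n_meth <= n_total, n_total > 0",
                  path, line_of(bad[1])))
  }
  bad <- which(raw$pos < 1)
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: pos is 1-based and must be >= 1", path, line_of(bad[1])))
  }
  invisible(raw)
}

#' Read a BED file into a region table
#'
#' BED3 or BED6; BED is already 0-based half-open so coordinates pass
#' through unchanged. Extra columns beyond the first six are ignored.
#'
#' @param path Path to a BED file.
#' @return A region tibble (`chrom`, `start`, `end`, `strand`, and `name`,
#'   `score` when BED6).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  out$strand[out$strand == "*"] <- "."
  md <- as.data.frame(S4Vectors::mcols(gr))
  if ("name" %in% names(md)) out$name <- ifelse(is.na(md$name), ".", md$name)
  if ("score" %in% names(md)) out$score <- md$score
  validate_regions(out, what = path)
  out
}

#' Write a region table as BED
#'
#' Writes BED3 when no `name`/`score`/`strand` information is present,
#' BED6 otherwise; extra numeric columns passed in `extra_cols` are
#' appended after the sixth field (BED6+).
#'
#' @param regions A region tibble.
#' @param path Output path.
#' @param extra_cols Character vector of additional columns to append.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path, extra_cols = NULL) {
  validate_regions(regions)
  has6 <- any(c("name", "score") %in% names(regions)) ||
    ("strand" %in% names(regions) && any(regions$strand %in% c("+", "-"))) ||
    length(extra_cols) > 0
  out <- tibble(
    chrom = regions$chrom,
    start = format(regions$start, scientific = FALSE, trim = TRUE),
    end = format(regions$end, scientific = FALSE, trim = TRUE)
  )
  if (has6) {
    out$name <- if ("name" %in% names(regions)) regions$name else "."
    out$score <- if ("score" %in% names(regions)) regions$score else 0
    out$strand <- if ("strand" %in% names(regions)) regions$strand else "."
  }
  for (col in extra_cols) out[[col]] <- regions[[col]]
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Genome annotation container
#'
#' Bundles chromosome sizes with the three feature tracks the pipeline
#' needs: genes, transposable elements (TEs), and structural RNAs
#' (tRNA/rRNA/snRNA/snoRNA, used to exclude degradation products from
#' small-RNA libraries).
#'
#' @param chrom_sizes Tibble with columns `chrom`, `length`.
#' @param genes,tes,structural_rna Region tibbles (may be empty).
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(chrom_sizes,
                              genes = region_tbl(character(), numeric(), numeric())[0, ],
                              tes = genes[0, ],
                              structural_rna = genes[0, ]) {
  chrom_sizes <- as_tibble(chrom_sizes)
  if (!all(c("chrom", "length") %in% names(chrom_sizes))) {
    abort("chrom_sizes must have columns chrom, length")
  }
  ann <- structure(
    list(chrom_sizes = chrom_sizes,
         genes = as_tibble(genes),
         tes = as_tibble(tes),
         structural_rna = as_tibble(structural_rna)),
    class = "genome_annotation"
  )
  sizes <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  for (track in c("genes", "tes", "structural_rna")) {
    x <- ann[[track]]
    if (nrow(x) == 0) next
    validate_regions(x, what = track)
    unknown <- setdiff(unique(x$chrom), names(sizes))
    if (length(unknown) > 0) {
      abort(sprintf("%s: chromosome '%s' not in chrom_sizes", track, unknown[1]))
    }
    if (any(x$end > sizes[x$chrom])) {
      abort(sprintf("%s: a feature extends beyond its chromosome", track))
    }
  }
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation>\n")
  cat(sprintf("  %d chromosome(s), %s bp total\n",
              nrow(x$chrom_sizes),
              format(sum(x$chrom_sizes$length), big.mark = ",")))
  cat(sprintf("  genes: %d  TEs: %d  structural RNAs: %d\n",
              nrow(x$genes), nrow(x$tes), nrow(x$structural_rna)))
  invisible(x)
}

#' Read genome annotation from GFF3
#'
#' GFF3 coordinates (1-based, closed) are converted to the package's
#' 0-based half-open convention. Feature types are routed to the three
#' annotation tracks via `feature_types`.
#'
#' @param path Path to a GFF3 file.
#' @param chrom_sizes Optional tibble (`chrom`, `length`); when `NULL`,
#'   sizes are taken from `##sequence-region` pragmas, falling back to the
#'   maximum feature end per chromosome.
#' @param feature_types Named list mapping track names (`genes`, `tes`,
#'   `structural_rna`) to GFF3 `type` values.
#' @return A [genome_annotation()] object.
#' @export
read_gff3_features <- function(path, chrom_sizes = NULL,
                               feature_types = list(
                                 genes = "gene",
                                 tes = c("transposable_element",
                                         "transposable_element_gene",
                                         "transposon_fragment"),
                                 structural_rna = c("tRNA", "rRNA", "snRNA", "snoRNA")
                               )) {
  gr <- rtracklayer::import(path, format = "gff3")
  feats <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type)
  )
  feats$strand[feats$strand == "*"] <- "."
  if (is.null(chrom_sizes)) {
    # ##sequence-region pragmas carry the chromosome bounds
    header <- grep("^##sequence-region", readLines(path, n = 1000), value = TRUE)
    if (length(header) > 0) {
      parts <- strsplit(trimws(header), "\\s+")
      chrom_sizes <- tibble(
        chrom = vapply(parts, `[`, character(1), 2),
        length = as.numeric(vapply(parts, `[`, character(1), 4))
      )
    }
    if (is.null(chrom_sizes) || nrow(chrom_sizes) == 0) {
      chrom_sizes <- feats |>
        group_by(chrom = .data$chrom) |>
        summarise(length = max(.data$end), .groups = "drop")
    }
  }
  pick <- function(types) {
    select(filter(feats, .data$type %in% types), -"type") |>
      arrange(.data$chrom, .data$start)
  }
  genome_annotation(
    chrom_sizes = arrange(as_tibble(chrom_sizes), .data$chrom),
    genes = pick(feature_types$genes),
    tes = pick(feature_types$tes),
    structural_rna = pick(feature_types$structural_rna)
  )
}
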