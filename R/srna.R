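#' Read small-RNA alignments from a tabular file
#'
#' The expected shape is one row per (library, sequence, locus):
#' `library`, `sequence`, `read_count`, `chrom`, `start` (0-based), `end`,
#' `strand`, optionally `genotype`. A distinct sequence that matches the
#' genome at h loci appears h times per library with the same `read_count`.
#'
#' @param path Path to the TSV file.
#' @return A small-RNA alignment tibble with a `length` column added.
#' @export
read_srna_tab <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("library", "sequence", "read_count", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing column(s) %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  mutate(x, length = nchar(.data$sequence))
}

#' Read small-RNA alignments from a SAM/BAM file
#'
#' Multimapping sequences must be reported as one record per locus (the
#' aligner's `-k` style output). Read counts are taken as the number of
#' identical sequences observed (collapsed libraries can encode the count
#' in the read name as `name_xCOUNT`; otherwise each distinct sequence
#' counts its records at one locus).
#'
#' @param path Path to a SAM or BAM file.
#' @param library Library name to assign.
#' @return A small-RNA alignment tibble (see [read_srna_tab()]).
#' @export
read_srna_sam <- function(path, library = basename(path)) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  aln <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  ))[[1]]
  seqs <- as.character(aln$seq)
  counts <- ifelse(grepl("_x([0-9]+)$", aln$qname),
                   as.numeric(sub(".*_x([0-9]+)$", "\\1", aln$qname)), NA)
  tibble(
    library = library,
    sequence = seqs,
    qname = aln$qname,
    read_count = counts,
    chrom = as.character(aln$rname),
    start = aln$pos - 1,
    end = aln$pos - 1 + nchar(seqs),
    strand = as.character(aln$strand),
    length = nchar(seqs)
  ) |>
    group_by(.data$sequence) |>
    mutate(read_count = if_else(is.na(.data$read_count),
                                as.numeric(length(unique(.data$qname))),
                                .data$read_count)) |>
    ungroup() |>
    select(-"qname")
}

#' Per-library totals of genome-matched small-RNA reads
#'
#' Sums `read_count` over the distinct sequences of each library. This is
#' the RPTM denominator and must be computed on the genome-matched set
#' *before* length filtering and structural-RNA exclusion.
#'
#' @param alignments Small-RNA alignment tibble.
#' @return Tibble `library`, `total_reads`.
#' @export
srna_totals <- function(alignments) {
  alignments |>
    distinct(.data$library, .data$sequence, .data$read_count) |>
    group_by(.data$library) |>
    summarise(total_reads = sum(.data$read_count), .groups = "drop")
}

#' Filter small-RNA sequences by length and structural-RNA overlap
#'
#' Drops sequences whose length is outside `[min_len, max_len]` and drops a
#' sequence entirely (all loci, all libraries) if *any* of its genomic loci
#' overlaps an annotated tRNA/rRNA/snRNA/snoRNA by at least 1 bp. The
#' operation is idempotent. The number of distinct sequences removed is
#' recorded in attributes `n_dropped_length` and `n_dropped_structural`.
#'
#' @param alignments Small-RNA alignment tibble.
#' @param annotation A [genome_annotation()] (its `structural_rna` track is
#'   used); `NULL` skips the structural filter.
#' @param min_len,max_len Retained length range in nt (defaults 18 and 31).
#' @return The filtered alignment tibble.
#' @export
filter_srna <- function(alignments, annotation = NULL, min_len = 18, max_len = 31) {
  if (!"length" %in% names(alignments)) {
    alignments <- mutate(alignments, length = nchar(.data$sequence))
  }
  keep_len <- alignments$length >= min_len & alignments$length <= max_len
  n_len <- length(setdiff(unique(alignments$sequence[!keep_len]),
                          unique(alignments$sequence[keep_len])))
  out <- alignments[keep_len, , drop = FALSE]
  n_struct <- 0L
  if (!is.null(annotation) && nrow(annotation$structural_rna) > 0 && nrow(out) > 0) {
    hit <- overlaps_any(out, annotation$structural_rna)
    bad_seqs <- unique(out$sequence[hit])
    n_struct <- length(bad_seqs)
    out <- filter(out, !.data$sequence %in% bad_seqs)
  }
  attr(out, "n_dropped_length") <- n_len
  attr(out, "n_dropped_structural") <- n_struct
  out
}

#' Reads-per-ten-million normalization
#'
#' Adds an `rptm` column: `read_count / total_reads * scale` per library,
#' where `total_reads` defaults to the totals of the *input* table. When
#' the pipeline excludes structural RNAs first, pass the totals computed on
#' the unfiltered genome-matched set via `totals` (see [srna_totals()]).
#'
#' @param alignments Small-RNA alignment tibble.
#' @param totals Optional tibble `library`, `total_reads`.
#' @param scale Normalization constant (default 1e7, i.e. RPTM).
#' @return `alignments` with an `rptm` column.
#' @export
compute_rptm <- function(alignments, totals = NULL, scale = 1e7) {
  if (is.null(totals)) totals <- srna_totals(alignments)
  if (any(totals$total_reads <= 0)) {
    abort("library with zero genome-matched reads: RPTM undefined")
  }
  alignments |>
    left_join(totals, by = "library") |>
    mutate(rptm = .data$read_count / .data$total_reads * scale) |>
    select(-"total_reads")
}

#' Distribute RPTM over genomic hits
#'
#' A sequence's "hits" are the genomic loci at which it perfectly matches
#' the genome, capped at `max_hits` (the aligner reports at most that
#' many). Each retained locus receives `rptm / hits`; loci beyond the cap
#' (in chromosome/position order) are dropped from assignment, mirroring
#' aligner behaviour. Use `max_hits = Inf` for exact conservation of RPTM.
#'
#' @param alignments Alignment tibble with an `rptm` column.
#' @param max_hits Cap on loci per sequence (default 10).
#' @return The tibble with columns `hits` and `hna` (per-locus HNA
#'   contribution) added, capped loci removed.
#' @export
compute_hna <- function(alignments, max_hits = 10) {
  loci <- alignments |>
    distinct(.data$sequence, .data$chrom, .data$start, .data$end) |>
    arrange(.data$sequence, .data$chrom, .data$start, .data$end) |>
    group_by(.data$sequence) |>
    mutate(locus_rank = row_number(), n_loci = n()) |>
    ungroup() |>
    mutate(hits = pmin(.data$n_loci, max_hits)) |>
    filter(.data$locus_rank <= max_hits) |>
    select(-"locus_rank", -"n_loci")
  alignments |>
    inner_join(loci, by = c("sequence", "chrom", "start", "end")) |>
    mutate(hna = .data$rptm / .data$hits)
}

#' Sum HNA contributions over non-overlapping genomic windows
#'
#' Assigns each locus to the fixed `window`-bp grid window containing its
#' 5' start coordinate (left end on `+`/`.`, right end minus one on `-`)
#' and sums HNA per library. Windows carry both the all-sizes HNA (`hna`)
#' and the 24-nt-only HNA (`hna24`). Windows with no assigned locus are
#' omitted (their HNA is 0).
#'
#' @param alignments Output of [compute_hna()].
#' @param chrom_sizes Tibble `chrom`, `length`.
#' @param window Window size in bp (default 200).
#' @return Tibble `library` (and `genotype` if present), `chrom`, `start`,
#'   `end`, `hna`, `hna24`.
#' @export
window_hna <- function(alignments, chrom_sizes, window = 200) {
  sizes <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  keys <- intersect(c("library", "genotype"), names(alignments))
  alignments |>
    mutate(pos5 = if_else(.data$strand == "-", .data$end - 1, .data$start),
           wstart = floor(.data$pos5 / window) * window) |>
    group_by(across(all_of(c(keys, "chrom", "wstart")))) |>
    summarise(hna24 = sum(.data$hna[.data$length == 24]),
              hna = sum(.data$hna),
              .groups = "drop") |>
    mutate(start = .data$wstart,
           end = pmin(.data$wstart + window, sizes[.data$chrom])) |>
    select(all_of(keys), "chrom", "start", "end", "hna", "hna24") |>
    arrange(across(all_of(c(keys, "chrom", "start"))))
}

#' Average window HNA over replicate libraries per genotype
#'
#' Windows absent from a library have HNA 0 and enter the mean as such.
#'
#' @param windows Output of [window_hna()] with a `genotype` column.
#' @param n_reps Optional tibble `genotype`, `n_reps`; by default the
#'   number of distinct libraries per genotype in `windows`.
#' @return Tibble `genotype`, `chrom`, `start`, `end`, `hna`, `hna24`.
#' @export
genotype_hna <- function(windows, n_reps = NULL) {
  if (!"genotype" %in% names(windows)) {
    abort("windows must carry a genotype column")
  }
  if (is.null(n_reps)) {
    n_reps <- windows |>
      distinct(.data$genotype, .data$library) |>
      count(.data$genotype, name = "n_reps")
  }
  windows |>
    group_by(.data$genotype, .data$chrom, .data$start, .data$end) |>
    summarise(hna = sum(.data$hna), hna24 = sum(.data$hna24),
              .groups = "drop") |>
    left_join(n_reps, by = "genotype") |>
    mutate(hna = .data$hna / .data$n_reps,
           hna24 = .data$hna24 / .data$n_reps) |>
    select(-"n_reps")
}

#' Call siRNA-depleted regions from genotype-mean window HNA
#'
#' A 200-bp window is depleted when the summed WT + mutant all-sizes HNA
#' reaches `hna_sum_cutoff` (ensuring adequate accumulation in WT) *and*
#' the mutant shows at least a `depletion_fold`-fold HNA reduction
#' (`mut_hna <= wt_hna / depletion_fold`). Windows missing from one
#' genotype count as HNA 0 there; `fold_reduction` is `Inf` when the
#' mutant HNA is 0.
#'
#' @param wt,mut Genotype-mean window tibbles ([genotype_hna()] rows for
#'   one genotype each, or any tibble with `chrom`, `start`, `end`, `hna`).
#' @param hna_sum_cutoff Minimum WT + mutant HNA (default 25).
#' @param depletion_fold Minimum fold reduction (default 2).
#' @param merge_adjacent Merge book-ended depleted windows into one region
#'   (default `FALSE`: a cluster is one window).
#' @return Tibble `chrom`, `start`, `end`, `wt_hna`, `mut_hna`,
#'   `fold_reduction`.
#' @export
call_depleted_regions <- function(wt, mut, hna_sum_cutoff = 25,
                                  depletion_fold = 2,
                                  merge_adjacent = FALSE) {
  joined <- full_join(
    select(wt, "chrom", "start", "end", wt_hna = "hna"),
    select(mut, "chrom", "start", "end", mut_hna = "hna"),
    by = c("chrom", "start", "end")
  ) |>
    mutate(wt_hna = replace_na(.data$wt_hna, 0),
           mut_hna = replace_na(.data$mut_hna, 0))
  out <- joined |>
    filter(.data$wt_hna + .data$mut_hna >= hna_sum_cutoff,
           .data$mut_hna * depletion_fold <= .data$wt_hna,
           .data$wt_hna > 0) |>
    mutate(fold_reduction = if_else(.data$mut_hna > 0,
                                    .data$wt_hna / .data$mut_hna, Inf)) |>
    arrange(.data$chrom, .data$start)
  if (merge_adjacent && nrow(out) > 0) {
    out <- out |>
      group_by(.data$chrom) |>
      mutate(run = cumsum(.data$start > lag(.data$end, default = -1))) |>
      group_by(.data$chrom, .data$run) |>
      summarise(start = min(.data$start), end = max(.data$end),
                wt_hna = sum(.data$wt_hna), mut_hna = sum(.data$mut_hna),
                .groups = "drop") |>
      mutate(fold_reduction = if_else(.data$mut_hna > 0,
                                      .data$wt_hna / .data$mut_hna, Inf)) |>
      select(-"run") |>
      arrange(.data$chrom, .data$start)
  }
  out
}

#' Summed window HNA over arbitrary regions
#'
#' A window contributes to a region when the window midpoint lies inside
#' it. Returns one row per region per grouping (library or genotype)
#' present in `windows`; regions without any window get 0.
#'
#' @param windows [window_hna()] or [genotype_hna()] output.
#' @param regions Region tibble.
#' @param size_filter `"all"` (sum `hna`) or `"24nt"` (sum `hna24`).
#' @return Tibble of regions with grouping columns and an `abundance`
#'   column.
#' @export
region_abundance <- function(windows, regions, size_filter = c("24nt", "all")) {
  size_filter <- match.arg(size_filter)
  value_col <- if (size_filter == "24nt") "hna24" else "hna"
  validate_regions(regions, "regions")
  keys <- intersect(c("library", "genotype"), names(windows))
  regions <- mutate(as_tibble(regions), .region_id = row_number())
  mids <- windows |>
    mutate(mid = floor((.data$start + .data$end) / 2)) |>
    mutate(mstart = .data$mid, mend = .data$mid + 1) |>
    select(all_of(keys), "chrom", start = "mstart", end = "mend",
           value = all_of(value_col))
  hits <- GenomicRanges::findOverlaps(as_granges(mids), as_granges(regions),
                                      ignore.strand = TRUE)
  contrib <- mids[S4Vectors::queryHits(hits), , drop = FALSE] |>
    mutate(.region_id = S4Vectors::subjectHits(hits)) |>
    group_by(across(all_of(c(keys, ".region_id")))) |>
    summarise(abundance = sum(.data$value), .groups = "drop")
  if (length(keys) == 0) {
    scaffold <- regions
  } else {
    scaffold <- tidyr::crossing(distinct(windows[, keys, drop = FALSE]), regions)
  }
  scaffold |>
    left_join(contrib, by = c(keys, ".region_id")) |>
    mutate(abundance = replace_na(.data$abundance, 0)) |>
    arrange(across(all_of(c(keys, ".region_id")))) |>
    select(-".region_id")
}
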