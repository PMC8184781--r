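# Shared fixture builders. Everything is generated in code at test time;
# files are written to tempdir().

write_methratio <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path)
  path
}

# a tiny deterministic annotation: one 1e4-bp chromosome with one gene,
# one TE (overlapping nothing) and one rRNA locus
tiny_annotation <- function() {
  genome_annotation(
    chrom_sizes = tibble::tibble(chrom = "chr1", length = 10000),
    genes = region_tbl("chr1", 1000, 3000, "+"),
    tes = region_tbl("chr1", 5000, 7000, "-"),
    structural_rna = region_tbl("chr1", 8000, 8120, "+")
  )
}

# alignment-record tibble builder: one row per locus
srna_records <- function(sequence, library, read_count, chrom, start,
                         strand = "+", genotype = NULL) {
  out <- tibble::tibble(
    library = library, sequence = sequence,
    read_count = read_count, chrom = chrom, start = start,
    end = start + nchar(sequence), strand = strand,
    length = nchar(sequence)
  )
  if (!is.null(genotype)) out$genotype <- genotype
  out
}

# independent one-site isotherm oracle: same displacement-dilution
# bookkeeping, but the equilibrium is solved by brute-force root finding
# instead of the closed-form quadratic
oracle_heats <- function(n, ka, dh, v0, m0, x_syr, vols) {
  m <- m0; x <- 0; pl_prev <- 0
  out <- numeric(length(vols))
  for (i in seq_along(vols)) {
    f <- vols[i] / v0
    m <- m * (1 - f)
    x <- x * (1 - f) + x_syr * f
    s <- n * m
    pl <- stats::uniroot(
      function(pl) ka * (s - pl) * (x - pl) - pl,
      lower = 0, upper = min(s, x) * (1 - 1e-12), tol = 1e-15
    )$root
    out[i] <- dh * v0 * (pl - pl_prev * (1 - f)) / (x_syr * vols[i])
    pl_prev <- pl
  }
  out
}
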