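#' Simulate a genome annotation
#'
#' Lays out non-overlapping genes, transposable elements, and short
#' structural-RNA loci (tRNA/rRNA-like) along each chromosome. Feature
#' lengths are gamma-distributed around typical plant sizes; features are
#' shuffled and separated by random gaps so that the realized TE and gene
#' base-pair fractions match the requested fractions up to placement
#' noise. Deterministic for a fixed seed.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bp (recycled).
#' @param te_fraction,gene_fraction Target fractions of bp covered
#'   (sum must be <= 0.95 to leave room for gaps).
#' @param n_structural Structural-RNA loci per chromosome.
#' @param te_len_mean,gene_len_mean Mean feature lengths in bp.
#' @param seed Integer seed.
#' @return A [genome_annotation()].
#' @export
simulate_genome <- function(n_chrom = 2, chrom_len = 3e5,
                            te_fraction = 0.3, gene_fraction = 0.3,
                            n_structural = 8,
                            te_len_mean = 3000, gene_len_mean = 2000,
                            seed = 1L) {
  if (te_fraction < 0 || gene_fraction < 0 ||
      te_fraction > 1 || gene_fraction > 1) {
    abort("fractions must lie in [0, 1]")
  }
  if (te_fraction + gene_fraction > 0.95) {
    abort("te_fraction + gene_fraction must be <= 0.95")
  }
  set.seed(seed)
  chrom_len <- rep_len(chrom_len, n_chrom)
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  feats <- map_dfr(seq_len(n_chrom), function(ci) {
    len <- chrom_len[ci]
    draw_lens <- function(target_bp, mean_len) {
      n <- round(target_bp / mean_len)
      if (n == 0) return(numeric(0))
      pmax(50, round(rgamma(n, shape = 4, scale = mean_len / 4)))
    }
    pool <- tibble(
      type = c(rep("te", length(tl <- draw_lens(te_fraction * len, te_len_mean))),
               rep("gene", length(gl <- draw_lens(gene_fraction * len, gene_len_mean))),
               rep("structural_rna", n_structural)),
      len = c(tl, gl, round(runif(n_structural, 80, 160)))
    )
    pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
    total_feat <- sum(pool$len)
    if (total_feat >= len) abort("features exceed chromosome length; lower fractions")
    gap_total <- len - total_feat
    w <- stats::rexp(nrow(pool) + 1)
    gaps <- floor(gap_total * w / sum(w))
    starts <- cumsum(gaps[-length(gaps)] + c(0, pool$len[-nrow(pool)]))
    tibble(
      chrom = chroms[ci],
      start = starts,
      end = starts + pool$len,
      strand = sample(c("+", "-"), nrow(pool), replace = TRUE),
      type = pool$type
    )
  })
  genome_annotation(
    chrom_sizes = tibble(chrom = chroms, length = chrom_len),
    genes = select(filter(feats, .data$type == "gene"), -"type"),
    tes = select(filter(feats, .data$type == "te"), -"type"),
    structural_rna = select(filter(feats, .data$type == "structural_rna"), -"type")
  )
}

#' Simulate per-genotype methylomes with planted hypomethylated regions
#'
#' Cytosines sit on a regular grid with random contexts; baseline
#' methylation probabilities are context-specific and elevated inside TEs
#' (defaults CG 0.8, CHG 0.4, CHH 0.15 in TEs; near zero elsewhere),
#' mimicking the TE-concentrated methylation of a plant genome. Coverage
#' per cytosine is Poisson; methylated counts are binomial. Inside a
#' planted DMR, every non-reference genotype's per-context probability is
#' shifted by the planted delta (percentage points; negative = hypo),
#' clipped to [0, 1] with a warning when clipping occurs.
#'
#' @param annotation A [genome_annotation()].
#' @param planted_dmrs Tibble `chrom`, `start`, `end`, `d_cg`, `d_chg`,
#'   `d_chh` (pp), or `NULL` for a null methylome.
#' @param genotypes Genotype names; the first is the reference (WT).
#' @param n_reps Replicates per genotype.
#' @param coverage_mean Mean read coverage per cytosine.
#' @param cytosine_spacing Distance between simulated cytosines (bp).
#' @param baseline Named list `te`, `bg` of per-context probabilities.
#' @param context_probs Sampling probabilities of CG/CHG/CHH contexts.
#' @param seed Integer seed.
#' @return List: `calls` (tibble with `sample`, `genotype`, coordinates,
#'   `context`, `n_meth`, `n_total`) and `truth` (list with the planted
#'   DMR table and the generating baselines).
#' @export
simulate_methylome <- function(annotation, planted_dmrs = NULL,
                               genotypes = c("WT", "mut"), n_reps = 2,
                               coverage_mean = 20, cytosine_spacing = 8,
                               baseline = list(
                                 te = c(CG = 0.8, CHG = 0.4, CHH = 0.15),
                                 bg = c(CG = 0.02, CHG = 0.02, CHH = 0.01)
                               ),
                               context_probs = c(CG = 0.2, CHG = 0.2, CHH = 0.6),
                               seed = 1L) {
  set.seed(seed)
  if (coverage_mean < 0) abort("coverage_mean must be >= 0")
  sizes <- annotation$chrom_sizes
  cyt <- map_dfr(seq_len(nrow(sizes)), function(i) {
    pos <- seq(0, sizes$length[i] - 1, by = cytosine_spacing)
    tibble(chrom = sizes$chrom[i], start = pos, end = pos + 1,
           strand = sample(c("+", "-"), length(pos), replace = TRUE),
           context = sample(names(context_probs), length(pos),
                            replace = TRUE, prob = context_probs))
  })
  in_te <- overlaps_any(cyt, annotation$tes)
  p_base <- ifelse(in_te, baseline$te[cyt$context], baseline$bg[cyt$context])
  delta <- rep(0, nrow(cyt))
  if (!is.null(planted_dmrs) && nrow(planted_dmrs) > 0) {
    validate_regions(planted_dmrs, "planted_dmrs")
    idx <- overlap_index(cyt, planted_dmrs)
    inside <- !is.na(idx)
    dcol <- c(CG = "d_cg", CHG = "d_chg", CHH = "d_chh")
    dmat <- as.matrix(planted_dmrs[, dcol, drop = FALSE])
    delta[inside] <- dmat[cbind(idx[inside],
                                match(dcol[cyt$context[inside]], dcol))] / 100
  }
  n_clip <- 0L
  calls <- map_dfr(genotypes, function(g) {
    p <- p_base
    if (g != genotypes[1]) {
      p <- p + delta
      n_clip <<- n_clip + sum(p < 0)
      p <- pmin(pmax(p, 0), 1)
    }
    map_dfr(seq_len(n_reps), function(r) {
      n_total <- rpois(nrow(cyt), coverage_mean)
      keep <- n_total > 0
      tibble(
        sample = sprintf("%s_r%d", g, r),
        genotype = g,
        chrom = cyt$chrom[keep], start = cyt$start[keep],
        end = cyt$end[keep], strand = cyt$strand[keep],
        context = cyt$context[keep],
        n_meth = rbinom(sum(keep), n_total[keep], p[keep]),
        n_total = n_total[keep]
      )
    })
  })
  if (n_clip > 0) {
    warn(sprintf("planted delta pushed %d cytosine probabilities below 0; clipped",
                 n_clip))
  }
  list(
    calls = calls,
    truth = list(planted_dmrs = planted_dmrs, baseline = baseline,
                 genotypes = genotypes, coverage_mean = coverage_mean)
  )
}

#' Simulate small-RNA libraries with planted depleted windows
#'
#' Emits distinct-sequence alignment records (one row per library,
#' sequence and locus) for a WT and a mutant genotype with replicates.
#' Background siRNA families are mostly 24-nt, multimap according to
#' `multimap_profile`, and have identical expected abundance in both
#' genotypes; their loci avoid the planted windows and structural RNAs so
#' the planted ground truth is clean. Each planted 200-bp window receives
#' a single-locus family whose per-library Poisson read counts are scaled
#' so the recomputed window HNA matches `wt_hna`/`mut_hna` in expectation
#' at nominal depth `total_reads`. Decoy families overlapping structural
#' RNAs are included to exercise the exclusion filter.
#'
#' @param annotation A [genome_annotation()].
#' @param planted_windows Tibble `chrom`, `start`, `end`, `wt_hna`,
#'   `mut_hna`; starts must sit on the `window` grid and spans must equal
#'   `window`.
#' @param n_families Number of background families.
#' @param multimap_profile Probabilities of 1, 2, ... loci per background
#'   family.
#' @param total_reads Nominal genome-matched reads per library.
#' @param genotypes Two genotype names, WT first.
#' @param n_reps Replicates per genotype.
#' @param window Grid size in bp (default 200).
#' @param n_decoys Structural-RNA decoy families.
#' @param seed Integer seed.
#' @return List: `alignments` (tibble `library`, `genotype`, `sequence`,
#'   `length`, `read_count`, `chrom`, `start`, `end`, `strand`) and
#'   `truth` (planted window table and nominal depth).
#' @export
simulate_srna_library <- function(annotation, planted_windows = NULL,
                                  n_families = 300,
                                  multimap_profile = c(0.6, 0.2, 0.1, 0.06, 0.04),
                                  total_reads = 2e7,
                                  genotypes = c("WT", "mut"), n_reps = 2,
                                  window = 200, n_decoys = 20, seed = 1L) {
  set.seed(seed)
  sizes <- annotation$chrom_sizes
  if (!is.null(planted_windows) && nrow(planted_windows) > 0) {
    validate_regions(planted_windows, "planted_windows")
    off_grid <- planted_windows$start %% window != 0 |
      planted_windows$end - planted_windows$start != window
    if (any(off_grid)) {
      abort(sprintf("planted window %d is off the %d-bp grid",
                    which(off_grid)[1], window))
    }
  }
  lens <- 18:31
  len_probs <- ifelse(lens == 24, 0.7, 0.3 / (length(lens) - 1))
  random_seqs <- function(n, lengths) {
    vapply(lengths, function(l) {
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
    }, character(1))
  }
  avoid <- bind_rows(
    if (!is.null(planted_windows)) planted_windows[, c("chrom", "start", "end")],
    annotation$structural_rna[, c("chrom", "start", "end")]
  )
  draw_locus <- function(n, seq_len_nt) {
    out <- tibble(chrom = character(0), start = numeric(0), end = numeric(0))
    while (nrow(out) < n) {
      need <- n - nrow(out)
      ci <- sample.int(nrow(sizes), need, replace = TRUE, prob = sizes$length)
      start <- floor(runif(need, 0, sizes$length[ci] - seq_len_nt))
      cand <- tibble(chrom = sizes$chrom[ci], start = start,
                     end = start + seq_len_nt)
      if (!is.null(avoid) && nrow(avoid) > 0) {
        cand <- cand[!overlaps_any(cand, avoid), , drop = FALSE]
      }
      out <- bind_rows(out, cand)
    }
    out[seq_len(n), , drop = FALSE]
  }
  # background families: identical expected abundance in both genotypes
  bg_len <- sample(lens, n_families, replace = TRUE, prob = len_probs)
  bg_hits <- sample(seq_along(multimap_profile), n_families, replace = TRUE,
                    prob = multimap_profile)
  bg_abund <- rlnorm(n_families, meanlog = 0, sdlog = 1.2)
  bg_abund <- bg_abund / sum(bg_abund)
  bg <- tibble(
    family = sprintf("bg%04d", seq_len(n_families)),
    sequence = random_seqs(n_families, bg_len),
    length = bg_len, hits = bg_hits,
    mean_count = bg_abund * total_reads
  )
  bg_loci <- bg |>
    select("family", "sequence", "length", "hits") |>
    (\(d) map_dfr(seq_len(nrow(d)), function(i) {
      loc <- draw_locus(d$hits[i], d$length[i])
      mutate(loc, family = d$family[i], sequence = d$sequence[i],
             length = d$length[i],
             strand = sample(c("+", "-"), d$hits[i], replace = TRUE))
    }))()
  # planted families: one 24-nt single-locus family per window
  pl <- NULL
  pl_loci <- NULL
  if (!is.null(planted_windows) && nrow(planted_windows) > 0) {
    npl <- nrow(planted_windows)
    pl <- tibble(
      family = sprintf("pl%04d", seq_len(npl)),
      sequence = random_seqs(npl, rep(24, npl)),
      length = 24,
      wt_count = planted_windows$wt_hna * total_reads / 1e7,
      mut_count = planted_windows$mut_hna * total_reads / 1e7
    )
    pl_loci <- tibble(
      family = pl$family, sequence = pl$sequence, length = 24,
      chrom = planted_windows$chrom,
      start = planted_windows$start + floor((window - 24) / 2),
      strand = "+"
    ) |>
      mutate(end = .data$start + 24)
  }
  # decoys: 24-nt families sitting inside structural RNAs
  dc_loci <- NULL
  dc <- NULL
  if (n_decoys > 0 && nrow(annotation$structural_rna) > 0) {
    sr <- annotation$structural_rna
    pick <- sample.int(nrow(sr), n_decoys, replace = TRUE)
    dc <- tibble(
      family = sprintf("dc%04d", seq_len(n_decoys)),
      sequence = random_seqs(n_decoys, rep(24, n_decoys)),
      length = 24,
      mean_count = stats::rexp(n_decoys, 1 / (total_reads * 1e-5)) + 1
    )
    dstart <- floor(sr$start[pick] +
                      runif(n_decoys, 0, pmax(1, sr$end[pick] - sr$start[pick] - 24)))
    dc_loci <- tibble(family = dc$family, sequence = dc$sequence, length = 24,
                      chrom = sr$chrom[pick], start = dstart,
                      end = dstart + 24, strand = "+")
  }
  libs <- tidyr::crossing(genotype = genotypes, rep = seq_len(n_reps)) |>
    mutate(library = sprintf("%s_r%d", .data$genotype, .data$rep))
  counts <- map_dfr(seq_len(nrow(libs)), function(i) {
    g <- libs$genotype[i]
    lib <- libs$library[i]
    rows <- list(
      tibble(family = bg$family, mean = bg$mean_count),
      if (!is.null(pl)) tibble(family = pl$family,
                               mean = if (g == genotypes[1]) pl$wt_count else pl$mut_count),
      if (!is.null(dc)) tibble(family = dc$family, mean = dc$mean_count)
    )
    bind_rows(rows) |>
      mutate(library = lib, genotype = g,
             read_count = rpois(n(), .data$mean)) |>
      filter(.data$read_count > 0) |>
      select("library", "genotype", "family", "read_count")
  })
  loci <- bind_rows(bg_loci, pl_loci, dc_loci)
  alignments <- counts |>
    inner_join(loci, by = "family", relationship = "many-to-many") |>
    select("library", "genotype", "sequence", "length", "read_count",
           "chrom", "start", "end", "strand") |>
    arrange(.data$library, .data$sequence, .data$chrom, .data$start)
  list(
    alignments = alignments,
    truth = list(planted_windows = planted_windows, total_reads = total_reads,
                 genotypes = genotypes)
  )
}

#' Simulate ChIP and input fragment tracks with known enrichment
#'
#' Input fragments are uniform over the genome; ChIP fragments are drawn
#' with a per-region rate multiplier `2^enrichment` over the same uniform
#' background, so the realized input-normalized log2 enrichment of each
#' region converges to its planted value as `total_fragments` grows
#' (up to a vanishing genome-composition term when enriched regions are a
#' small genome fraction).
#'
#' @param chrom_sizes Tibble `chrom`, `length`.
#' @param regions Region tibble with an `enrichment` column (planted
#'   log2 enrichment; non-overlapping regions).
#' @param total_fragments Fragments per track.
#' @param frag_len Fragment length in bp.
#' @param seed Integer seed.
#' @return List: `chip` and `input` fragment tibbles and `truth` (the
#'   planted region table).
#' @export
simulate_chip <- function(chrom_sizes, regions, total_fragments = 1e6,
                          frag_len = 200, seed = 1L) {
  if (total_fragments < 0) abort("total_fragments must be >= 0")
  validate_regions(regions, "regions")
  if (!"enrichment" %in% names(regions)) {
    abort("regions must carry an 'enrichment' column of planted log2 values")
  }
  set.seed(seed)
  genome_bp <- sum(chrom_sizes$length)
  region_bp <- regions$end - regions$start
  sample_track <- function(n, weights_regions) {
    w_bg <- genome_bp - sum(region_bp)
    w <- c(weights_regions, w_bg)
    seg <- sample.int(length(w), n, replace = TRUE, prob = w)
    in_region <- seg <= nrow(regions)
    out <- vector("list", 2)
    if (any(in_region)) {
      ri <- seg[in_region]
      pos <- floor(regions$start[ri] +
                     runif(sum(in_region), 0, pmax(1, region_bp[ri] - frag_len)))
      out[[1]] <- tibble(chrom = regions$chrom[ri], start = pmax(0, pos),
                         end = pmax(0, pos) + frag_len)
    }
    n_bg <- sum(!in_region)
    if (n_bg > 0) {
      # background is uniform over the genome *outside* the planted regions
      # (rejection sampling; the regions are a small genome fraction)
      bg <- tibble(chrom = character(0), start = numeric(0), end = numeric(0))
      while (nrow(bg) < n_bg) {
        need <- n_bg - nrow(bg)
        ci <- sample.int(nrow(chrom_sizes), need, replace = TRUE,
                         prob = chrom_sizes$length)
        pos <- floor(runif(need, 0, pmax(1, chrom_sizes$length[ci] - frag_len)))
        cand <- tibble(chrom = chrom_sizes$chrom[ci], start = pos,
                       end = pos + frag_len)
        cand <- cand[!overlaps_any(cand, regions), , drop = FALSE]
        bg <- bind_rows(bg, cand)
      }
      out[[2]] <- bg[seq_len(n_bg), , drop = FALSE]
    }
    bind_rows(out)
  }
  chip <- sample_track(total_fragments, region_bp * 2^regions$enrichment)
  input <- sample_track(total_fragments, region_bp)
  list(chip = chip, input = input, truth = regions)
}
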