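# Synthetic-data generator: emulates every empirical input of the pipeline
# (annotation, accessibility and conservation masks, rate maps, ancestral
# states, multi-population polymorphism) under a known truth model, so the
# whole inference chain can be exercised without downloads and checked for
# parameter recovery.

#' Specification of a synthetic genome
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param gene_density fraction of the genome in functional (genic) intervals.
#' @param gene_length_range bp interval for gene lengths.
#' @param mask_fraction fraction of bases inaccessible (drawn as
#'   geometric-length blocks to mimic real mask clumping).
#' @param conserved_fraction fraction of noncoding bases flagged as conserved
#'   (conservation score > 0); their only role is to be masked out by
#'   curation.
#' @param mu_range,rec_range per-bp per-generation rate intervals for the
#'   piecewise-constant rate maps.
#' @param rate_piece_length length in bp of each constant rate-map piece.
#' @param mask_block_mean mean length (bp) of inaccessible blocks.
#' @param gene_spacing `"random"` scatters genes uniformly (gaps are
#'   exponential-like, as after Poisson placement); `"regular"` spaces them
#'   evenly, which gives near-equal intergenic gaps — convenient when a test
#'   needs many curated regions of comparable length.
#' @param seed integer seed; with the seed fixed, all generated files are
#'   byte-identical across runs.
#' @return A `synth_genome_spec` list.
#' @export
synthetic_genome_spec <- function(n_chromosomes = 1,
                                  chrom_length = 1e6,
                                  gene_density = 0.05,
                                  gene_length_range = c(2000, 10000),
                                  mask_fraction = 0.1,
                                  conserved_fraction = 0.05,
                                  mu_range = c(1e-8, 2e-8),
                                  rec_range = c(1e-8, 2e-8),
                                  rate_piece_length = 50000,
                                  mask_block_mean = 300,
                                  gene_spacing = c("random", "regular"),
                                  seed = 1) {
  gene_spacing <- match.arg(gene_spacing)
  fracs <- c(gene_density, mask_fraction, conserved_fraction)
  assert_that(all(fracs >= 0 & fracs <= 1), "All fractions must lie in [0, 1].")
  assert_that(chrom_length > 0 && n_chromosomes >= 1, "Lengths must be positive.")
  assert_that(gene_length_range[1] > 0 && diff(gene_length_range) >= 0,
              "`gene_length_range` must be a positive interval.")
  assert_that(gene_density < 0.95,
              "Impossible geometry: gene_density leaves no room for intergenic gaps.")
  structure(
    list(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
         gene_density = gene_density, gene_length_range = gene_length_range,
         mask_fraction = mask_fraction, conserved_fraction = conserved_fraction,
         mu_range = mu_range, rec_range = rec_range,
         rate_piece_length = rate_piece_length,
         mask_block_mean = mask_block_mean, gene_spacing = gene_spacing,
         seed = seed),
    class = "synth_genome_spec"
  )
}

# Draw non-overlapping gene intervals totalling ~density*L
draw_genes <- function(L, density, len_range, spacing = "random") {
  target <- density * L
  if (target == 0) return(tibble(start = numeric(0), end = numeric(0)))
  lens <- numeric(0)
  while (sum(lens) < target) {
    lens <- c(lens, runif(1, len_range[1], len_range[2]))
  }
  # drop the last gene if that leaves us closer to the target
  if (length(lens) > 1 &&
      abs(sum(lens) - target) > abs(sum(head(lens, -1)) - target)) {
    lens <- head(lens, -1)
  }
  lens <- round(lens)
  total <- sum(lens)
  assert_that(total <= L, "Impossible geometry: genes exceed chromosome length.")
  n <- length(lens)
  gap_total <- L - total
  if (spacing == "regular") {
    gaps <- rep(round(gap_total / (n + 1)), n)
  } else {
    cuts <- sort(runif(n, 0, gap_total))
    gaps <- diff(c(0, cuts))
  }
  starts <- round(cumsum(gaps) + cumsum(c(0, head(lens, -1))))
  tibble(start = starts, end = starts + lens)
}

# Geometric-length blocks until `target` bp are covered, restricted to
# `within` intervals (or the whole [0, L) when NULL).
draw_blocks <- function(L, target, mean_len, within = NULL) {
  out <- tibble(start = numeric(0), end = numeric(0))
  if (target <= 0) return(out)
  guard <- 0
  while (iv_union_bp(out) < target && guard < 10000) {
    guard <- guard + 1
    s <- floor(runif(1, 0, L))
    len <- rgeom(1, 1 / mean_len) + 1
    block <- tibble(start = s, end = min(L, s + len))
    if (!is.null(within)) block <- iv_intersect(block, within)
    out <- iv_normalize(bind_rows(out, block))
  }
  out
}

piecewise_rates <- function(L, piece_len, range) {
  starts <- seq(0, L - 1, by = piece_len)
  tibble(start = starts, end = pmin(starts + piece_len, L),
         rate = runif(length(starts), range[1], range[2]))
}

#' Generate a synthetic genome
#'
#' Produces annotation (GFF3: one gene with a spanning exon per functional
#' interval), an accessibility mask (BED of accessible intervals), a
#' conserved-element mask (BED), piecewise-constant mutation and recombination
#' rate maps (TSV), an ancestral-state FASTA, and a truth record. Coordinate
#' conventions: GFF3 1-based closed, BED and rate maps 0-based half-open.
#'
#' @param spec a [synthetic_genome_spec()].
#' @param out_dir optional directory; when given, all files are written there
#'   (`genes.gff3`, `accessible.bed`, `conserved.bed`, `mu_map.tsv`,
#'   `rec_map.tsv`, `ancestral.fa`, `truth.json`).
#' @return A `synth_genome` list of tidy tables (`genes`, `accessible`,
#'   `conserved`, `mu_map`, `rec_map`, `ancestral`, `chrom_lengths`, `truth`).
#' @export
generate_genome <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synth_genome_spec"))
  with_seed(spec$seed, {
    chroms <- sprintf("chr%d", seq_len(spec$n_chromosomes))
    L <- spec$chrom_length
    per_chrom <- purrr::map(chroms, function(ch) {
      genes <- draw_genes(L, spec$gene_density, spec$gene_length_range,
                          spec$gene_spacing) |>
        mutate(chrom = ch, .before = 1)
      inaccessible <- draw_blocks(L, spec$mask_fraction * L,
                                  spec$mask_block_mean) |>
        mutate(chrom = ch, .before = 1)
      accessible <- iv_complement(inaccessible[, c("start", "end")], 0, L) |>
        mutate(chrom = ch, .before = 1)
      noncoding <- iv_complement(genes[, c("start", "end")], 0, L)
      conserved <- draw_blocks(L, spec$conserved_fraction * iv_union_bp(noncoding),
                               spec$mask_block_mean, within = noncoding) |>
        mutate(chrom = ch, .before = 1)
      mu_map <- piecewise_rates(L, spec$rate_piece_length, spec$mu_range) |>
        mutate(chrom = ch, .before = 1)
      rec_map <- piecewise_rates(L, spec$rate_piece_length, spec$rec_range) |>
        mutate(chrom = ch, .before = 1)
      anc <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                   collapse = "")
      list(genes = genes, accessible = accessible, conserved = conserved,
           mu_map = mu_map, rec_map = rec_map, ancestral = anc)
    })
    genome <- list(
      genes = purrr::map_dfr(per_chrom, "genes"),
      accessible = purrr::map_dfr(per_chrom, "accessible"),
      conserved = purrr::map_dfr(per_chrom, "conserved"),
      mu_map = purrr::map_dfr(per_chrom, "mu_map"),
      rec_map = purrr::map_dfr(per_chrom, "rec_map"),
      ancestral = setNames(purrr::map_chr(per_chrom, "ancestral"), chroms),
      chrom_lengths = setNames(rep(L, length(chroms)), chroms),
      truth = list(spec = unclass(spec))
    )
    class(genome) <- "synth_genome"
    if (!is.null(out_dir)) write_genome_files(genome, out_dir)
    genome
  })
}

write_genome_files <- function(genome, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sl <- genome$chrom_lengths
  as_gr <- function(tb) {
    if (nrow(tb) == 0) {
      return(GenomicRanges::GRanges(seqlengths = sl))
    }
    GenomicRanges::GRanges(tb$chrom,
                           IRanges::IRanges(tb$start + 1, tb$end),
                           seqlengths = sl)
  }
  genes_gr <- as_gr(genome$genes)
  n <- length(genes_gr)
  gff <- c(rep(genes_gr, 2))
  if (n > 0) {
    gff$type <- rep(c("gene", "exon"), each = n)
    gff$ID <- c(sprintf("gene%04d", seq_len(n)), sprintf("exon%04d", seq_len(n)))
    gff$Parent <- c(rep(NA_character_, n), sprintf("gene%04d", seq_len(n)))
    gff <- sort(gff)
  } else {
    gff$type <- character(0)
  }
  rtracklayer::export(gff, file.path(out_dir, "genes.gff3"), format = "gff3")
  rtracklayer::export(as_gr(genome$accessible),
                      file.path(out_dir, "accessible.bed"), format = "bed")
  rtracklayer::export(as_gr(genome$conserved),
                      file.path(out_dir, "conserved.bed"), format = "bed")
  readr::write_tsv(genome$mu_map[, c("chrom", "start", "end", "rate")],
                   file.path(out_dir, "mu_map.tsv"))
  readr::write_tsv(genome$rec_map[, c("chrom", "start", "end", "rate")],
                   file.path(out_dir, "rec_map.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$ancestral),
                              file.path(out_dir, "ancestral.fa"))
  jsonlite::write_json(genome$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Generate multi-population polymorphism data over a synthetic genome
#'
#' Simulates each chromosome under the given demographic truth model (through
#' the coalescent backend, honouring the genome's piecewise rate maps), drops
#' variants at inaccessible sites, and writes one VCF per chromosome with
#' per-population sample columns, the ancestral allele in `INFO/AA`, a shared
#' sample panel, and a truth record holding the generating model. The truth
#' record is written for test harnesses only and is never consumed by
#' inference code paths.
#'
#' @param model an [ooa_model()]: the truth demography.
#' @param genome a `synth_genome` from [generate_genome()].
#' @param sample_sizes named vector of diploid sample counts
#'   (default `c(AFR = 99, EUR = 502, EAS = 104, SAS = 489)`).
#' @param seed master seed.
#' @param out_dir optional output directory for `chrN.vcf.gz`, the panel and
#'   `polymorphism_truth.json`.
#' @return A list with `samples` (named list of [hap_sample()] per
#'   chromosome, masked to accessible sites) and `truth`.
#' @export
generate_polymorphism <- function(model, genome,
                                  sample_sizes = c(AFR = 99, EUR = 502,
                                                   EAS = 104, SAS = 489),
                                  seed = 1, out_dir = NULL) {
  model <- validate_model(model)
  pops <- compile_demography(model)$populations
  present <- setNames(pops$initial_size, pops$name)
  for (p in names(sample_sizes)) {
    assert_that(sample_sizes[[p]] <= present[[p]],
                sprintf("Sample size for %s exceeds its present population size.", p))
  }
  chroms <- names(genome$chrom_lengths)
  requests <- purrr::map_dfr(chroms, function(ch) {
    mu_tab <- genome$mu_map[genome$mu_map$chrom == ch, ]
    rec_tab <- genome$rec_map[genome$rec_map$chrom == ch, ]
    tibble(id = ch, length = genome$chrom_lengths[[ch]],
           mu = mean(mu_tab$rate), rec = mean(rec_tab$rate), replicates = 1L,
           mu_map = list(list(position = c(mu_tab$start, max(mu_tab$end)),
                              rate = mu_tab$rate)),
           rec_map = list(list(position = c(rec_tab$start, max(rec_tab$end)),
                               rate = rec_tab$rate)))
  })
  sims <- simulate_regions(model, requests, sample_sizes, seed)
  samples <- purrr::imap(sims, function(reps, ch) {
    s <- reps[[1]]
    masked <- iv_complement(
      genome$accessible[genome$accessible$chrom == ch, c("start", "end")],
      0, genome$chrom_lengths[[ch]])
    apply_mask(s, masked)
  })
  truth <- list(model = as.list(model$params),
                generation_time_years = model$generation_time_years,
                founding_epoch_gens = model$founding_epoch_gens,
                sample_sizes = as.list(sample_sizes), seed = seed,
                sweeps = list())
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (ch in chroms) {
      s <- samples[[ch]]
      anc <- strsplit(genome$ancestral[[ch]], "")[[1]]
      ref <- anc[floor(s$positions) + 1]
      alt <- c(A = "G", C = "T", G = "A", T = "C")[ref]
      write_sample_vcf(s, file.path(out_dir, paste0(ch, ".vcf.gz")),
                       chrom = ch, ref = ref, alt = unname(alt))
    }
    jsonlite::write_json(truth, file.path(out_dir, "polymorphism_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(samples = samples, truth = truth)
}
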