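# The synthetic-data generator: geometry, determinism, file round-trips, and
# polymorphism emulation under a known truth model.

test_that("degenerate specs produce empty annotation and full accessibility", {
  spec <- synthetic_genome_spec(chrom_length = 1e5, gene_density = 0,
                                mask_fraction = 0, conserved_fraction = 0,
                                seed = 1)
  g <- generate_genome(spec)
  expect_equal(nrow(g$genes), 0)
  expect_equal(nrow(g$conserved), 0)
  expect_equal(g$accessible$start, 0)
  expect_equal(g$accessible$end, 1e5)
  expect_error(synthetic_genome_spec(gene_density = 0.99), "Impossible geometry")
  expect_error(synthetic_genome_spec(mask_fraction = 1.2), "fractions")
})

test_that("total functional bp lands within one gene length of the target", {
  spec <- synthetic_genome_spec(chrom_length = 1e6, gene_density = 0.05,
                                gene_length_range = c(2000, 10000), seed = 17)
  g <- generate_genome(spec)
  total <- sum(g$genes$end - g$genes$start)   # oracle: direct summation
  expect_lte(abs(total - 50000), 10000)
  # genes never overlap
  expect_true(all(diff(g$genes$start) >= (g$genes$end - g$genes$start)[-nrow(g$genes)]))
})

test_that("generated files are byte-identical across runs with a fixed seed", {
  spec <- synthetic_genome_spec(chrom_length = 2e5, gene_density = 0.05,
                                seed = 5)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  generate_genome(spec, out_dir = d1)
  generate_genome(spec, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("emitted files round-trip through the curation readers", {
  spec <- synthetic_genome_spec(chrom_length = 5e5, gene_density = 0.06,
                                mask_fraction = 0.1, conserved_fraction = 0.1,
                                seed = 7)
  dir <- withr::local_tempdir()
  g <- generate_genome(spec, out_dir = dir)

  ann <- read_gff_annotation(file.path(dir, "genes.gff3"))
  genes_back <- ann[ann$type == "gene", c("chrom", "start", "end")]
  expect_equal(as.data.frame(genes_back), as.data.frame(g$genes),
               ignore_attr = TRUE)

  acc <- read_bed_intervals(file.path(dir, "accessible.bed"))
  expect_equal(acc$start, g$accessible$start)
  expect_equal(acc$end, g$accessible$end)

  mu <- read_rate_map(file.path(dir, "mu_map.tsv"))
  expect_equal(mu$rate, g$mu_map$rate)

  # curation over the round-tripped files matches curation over the tables
  masks_f <- list(accessible = acc,
                  conserved = read_bed_intervals(file.path(dir, "conserved.bed")))
  regs_f <- select_nonfunctional(genes_back, masks_f, mu,
                                 read_rate_map(file.path(dir, "rec_map.tsv")),
                                 g$chrom_lengths)
  regs_t <- select_nonfunctional(g$genes,
                                 list(accessible = g$accessible,
                                      conserved = g$conserved),
                                 g$mu_map, g$rec_map, g$chrom_lengths)
  expect_equal(as.data.frame(regs_f), as.data.frame(regs_t))
})

test_that("polymorphism generation respects sample sizes, masks and ancestry", {
  spec <- synthetic_genome_spec(chrom_length = 1e5, gene_density = 0.02,
                                mask_fraction = 0.2, mu_range = c(5e-8, 1e-7),
                                seed = 9)
  g <- generate_genome(spec)
  m <- toy_model(kappa = 25)
  dir <- withr::local_tempdir()
  pol <- generate_polymorphism(m, g, sample_sizes = c(AFR = 4, EUR = 3),
                               seed = 13, out_dir = dir)
  s <- pol$samples$chr1
  expect_equal(nrow(s$geno), 2 * 7)
  expect_equal(sort(unique(s$pop)), c("AFR", "EUR"))
  # accessible-site filter: no variant inside a masked interval
  masked <- popbaseline:::iv_complement(g$accessible[, c("start", "end")], 0, 1e5)
  expect_false(any(popbaseline:::pos_in_intervals(s$positions, masked)))

  # VCF on disk reads back to the same haplotypes
  back <- read_sample_vcf(file.path(dir, "chr1.vcf.gz"),
                          region_length = 1e5,
                          accessible_bp = s$accessible_bp)
  expect_equal(back$positions, floor(s$positions))
  expect_equal(back$geno, s$geno)

  # truth record stores the generating model, never consumed by inference
  truth <- jsonlite::read_json(file.path(dir, "polymorphism_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$model$N_AFR_anc, m$params[["N_AFR_anc"]])

  # sample size exceeding the present population size errors
  expect_error(generate_polymorphism(m, g, sample_sizes = c(AFR = 1e6),
                                     seed = 1), "exceeds")
})

test_that("zero mutation rate produces a VCF with zero variant records", {
  spec <- synthetic_genome_spec(chrom_length = 5e4, gene_density = 0,
                                mask_fraction = 0, mu_range = c(0, 0), seed = 2)
  g <- generate_genome(spec)
  m <- toy_model(kappa = 25)
  pol <- generate_polymorphism(m, g,
                               sample_sizes = c(AFR = 1, EUR = 1, EAS = 1,
                                                SAS = 1), seed = 3)
  expect_equal(ncol(pol$samples$chr1$geno), 0)
  expect_equal(nrow(pol$samples$chr1$geno), 8)
})
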