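# Region curation against hand interval arithmetic and a brute-force oracle.

empty_masks <- function(chrom = "chr1", L = 1e5) {
  list(accessible = tibble::tibble(chrom = chrom, start = 0, end = L),
       conserved = tibble::tibble(chrom = character(0), start = numeric(0),
                                  end = numeric(0)))
}

uniform_map <- function(rate, chrom = "chr1", L = 1e5) {
  tibble::tibble(chrom = chrom, start = 0, end = L, rate = rate)
}

test_that("nonfunctional selection reproduces hand interval arithmetic", {
  ann <- tibble::tibble(chrom = "chr1", start = 40000, end = 45000)
  out <- select_nonfunctional(ann, empty_masks(), uniform_map(1e-8),
                              uniform_map(1e-8), c(chr1 = 1e5))
  expect_equal(nrow(out), 2)
  expect_equal(out$start, c(0, 55000))
  expect_equal(out$end, c(30000, 100000))
  expect_equal(out$kind, rep("nonfunctional", 2))
  expect_equal(out$mean_mu, rep(1e-8, 2))

  # first region fully inaccessible -> dropped
  masks <- empty_masks()
  masks$accessible <- tibble::tibble(chrom = "chr1", start = 30000, end = 1e5)
  out2 <- select_nonfunctional(ann, masks, uniform_map(1e-8), uniform_map(1e-8),
                               c(chr1 = 1e5))
  expect_equal(nrow(out2), 1)
  expect_equal(out2$start, 55000)

  # no annotation at all -> one region spanning the chromosome
  out3 <- select_nonfunctional(ann[0, ], empty_masks(), uniform_map(1e-8),
                               uniform_map(1e-8), c(chr1 = 1e5))
  expect_equal(nrow(out3), 1)
  expect_equal(c(out3$start, out3$end), c(0, 1e5))

  expect_error(select_nonfunctional(ann, empty_masks(), uniform_map(1e-8)[0, ],
                                    uniform_map(1e-8), c(chr1 = 1e5)),
               "Empty rate map")
})

test_that("masked bases inside retained regions reduce accessible_bp only", {
  ann <- tibble::tibble(chrom = "chr1", start = 40000, end = 45000)
  masks <- empty_masks()
  masks$conserved <- tibble::tibble(chrom = "chr1", start = 1000, end = 3000)
  out <- select_nonfunctional(ann, masks, uniform_map(1e-8), uniform_map(1e-8),
                              c(chr1 = 1e5))
  r1 <- out[out$start == 0, ]
  expect_equal(r1$end - r1$start, 30000)       # span unchanged
  expect_equal(r1$accessible_bp, 28000)        # 2 kb conserved masked out
})

test_that("exonic selection drops clusters without rate coverage and averages rates", {
  ann <- tibble::tibble(chrom = "chr1",
                        start = c(1000, 5000, 9000, 13000, 90000),
                        end = c(2000, 6000, 10000, 14000, 91000),
                        type = "exon")
  # rate maps cover only the first four exons
  mu <- tibble::tibble(chrom = "chr1", start = 0, end = 20000, rate = 2e-8)
  rec <- tibble::tibble(chrom = "chr1", start = 0, end = 20000, rate = 1e-8)
  out <- select_exonic(ann, mu, rec)
  expect_equal(nrow(out), 4)
  expect_true(all(out$kind == "exonic"))

  # exon covered by two equal-length pieces at 1e-8 and 3e-8 -> 2e-8
  exon <- tibble::tibble(chrom = "chr1", start = 0, end = 2000, type = "exon")
  mu2 <- tibble::tibble(chrom = "chr1", start = c(0, 1000), end = c(1000, 2000),
                        rate = c(1e-8, 3e-8))
  out2 <- select_exonic(exon, mu2, tibble::tibble(chrom = "chr1", start = 0,
                                                  end = 2000, rate = 1e-8))
  expect_equal(out2$mean_mu, 2e-8)

  expect_equal(nrow(select_exonic(ann[0, ], mu, rec)), 0)
})

test_that("region mean rates are length-weighted with coverage reporting", {
  region <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  expect_equal(region_mean_rate(region, uniform_map(5e-8))$mean_rate, 5e-8)
  half <- tibble::tibble(chrom = "chr1", start = c(0, 500), end = c(500, 1000),
                         rate = c(1e-8, 2e-8))
  expect_equal(region_mean_rate(region, half)$mean_rate, 1.5e-8)
  off <- tibble::tibble(chrom = "chr1", start = 5000, end = 6000, rate = 1e-8)
  r <- region_mean_rate(region, off)
  expect_true(is.na(r$mean_rate))
  expect_equal(r$covered_fraction, 0)
})

test_that("curation is idempotent and monotone in its thresholds", {
  set.seed(11)
  starts <- sort(sample(seq(0, 9.5e5, by = 1000), 12))
  ann <- tibble::tibble(chrom = "chr1", start = starts, end = starts + 4000)
  masks <- empty_masks(L = 1e6)
  mu <- uniform_map(1e-8, L = 1e6)
  # overlapping genes: expect a single normalization warning per call
  out <- suppressWarnings(select_nonfunctional(ann, masks, mu, mu, c(chr1 = 1e6)))

  # feeding curated regions back as "annotation-free" curation is stable:
  # regions already >= min_length survive a second length/rate filter intact
  again <- out[out$end - out$start >= 15000 & !is.na(out$mean_mu), ]
  expect_equal(again, out)

  for (md in c(5000, 10000, 20000)) {
    for (ml in c(10000, 15000, 30000)) {
      n1 <- nrow(suppressWarnings(select_nonfunctional(
        ann, masks, mu, mu, c(chr1 = 1e6),
        min_distance = md, min_length = ml)))
      n2 <- nrow(suppressWarnings(select_nonfunctional(
        ann, masks, mu, mu, c(chr1 = 1e6),
        min_distance = md + 5000, min_length = ml)))
      n3 <- nrow(suppressWarnings(select_nonfunctional(
        ann, masks, mu, mu, c(chr1 = 1e6),
        min_distance = md, min_length = ml + 5000)))
      expect_lte(n2, n1)
      expect_lte(n3, n1)
    }
  }
})

test_that("region boundaries match a brute-force base-wise oracle", {
  set.seed(21)
  L <- 50000
  starts <- sort(sample(seq(1000, 44000, by = 500), 4))
  ann <- tibble::tibble(chrom = "chr1", start = starts,
                        end = starts + sample(500:2000, 4))
  ann <- popbaseline:::iv_normalize(ann[, c("start", "end")]) |>
    dplyr::mutate(chrom = "chr1", .before = 1)
  md <- 3000; ml <- 2000
  out <- select_nonfunctional(ann, empty_masks(L = L), uniform_map(1e-8, L = L),
                              uniform_map(1e-8, L = L), c(chr1 = L),
                              min_distance = md, min_length = ml)
  # brute force: mark every base within md of a functional base, take runs
  occupied <- logical(L)
  for (i in seq_len(nrow(ann))) {
    lo <- max(0, ann$start[i] - md); hi <- min(L, ann$end[i] + md)
    occupied[(lo + 1):hi] <- TRUE
  }
  r <- rle(!occupied)
  ends <- cumsum(r$lengths)
  starts_r <- ends - r$lengths
  free <- tibble::tibble(start = starts_r[r$values], end = ends[r$values])
  free <- free[free$end - free$start >= ml, ]
  expect_equal(out$start, free$start)
  expect_equal(out$end, free$end)
})

test_that("curated regions round-trip through the TSV writer", {
  ann <- tibble::tibble(chrom = "chr1", start = 40000, end = 45000)
  out <- select_nonfunctional(ann, empty_masks(), uniform_map(1e-8),
                              uniform_map(1e-8), c(chr1 = 1e5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_curated_regions(out, path)
  back <- read_curated_regions(path)
  expect_equal(as.data.frame(back), as.data.frame(out))
})
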