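# Summary statistics against hand-computed oracles and their invariants.

test_that("segregating sites per site counts polymorphic unmasked sites over accessible bp", {
  s <- hap_from_strings(c("00000", "11111", "10101", "01010"),
                        region_length = 10000)
  expect_equal(segregating_sites_per_site(s), 5 / 10000)

  none <- hap_sample(numeric(0), matrix(0L, 4, 0), rep("AFR", 4), 10000)
  expect_equal(segregating_sites_per_site(none), 0)

  # masked site excluded from numerator and denominator: 6 sites on 1000 bp,
  # masking [0, 100) removes the two sites at 10 and 20 and 100 bp of length
  s6 <- hap_from_strings(c("000000", "111111", "101010", "010101"),
                         region_length = 1000,
                         positions = c(10, 20, 300, 400, 500, 600))
  m <- apply_mask(s6, tibble::tibble(start = 0, end = 100))
  expect_equal(ncol(m$geno), 4)
  expect_equal(m$accessible_bp, 900)
  expect_equal(segregating_sites_per_site(m), 4 / 900)

  zero <- hap_sample(numeric(0), matrix(0L, 2, 0), rep("A", 2), 100,
                     accessible_bp = 0)
  expect_error(segregating_sites_per_site(zero), "no accessible")
})

test_that("Tajima's D matches the hand-evaluated n = 4 oracle and window rules", {
  # n = 4, S = 3, pi = 5/3: D = (5/3 - 18/11) / sqrt(e1*3 + e2*6) ~ +0.168
  s <- hap_from_strings(c("000", "100", "110", "111"), region_length = 500)
  expect_equal(tajimas_d(s)$D, 0.16766, tolerance = 1e-3)

  # windows with S = 0 are undefined, not zero
  empty <- hap_sample(numeric(0), matrix(0L, 4, 0), rep("AFR", 4), 5000)
  expect_true(all(is.na(tajimas_d(empty)$D)))

  # n = 2: numerator is identically zero (pi = S, a1 = 1); the variance is
  # degenerate too, so D is never defined
  s2 <- hap_from_strings(c("00", "11"), region_length = 100)
  d2 <- tajimas_d(s2)$D
  expect_true(all(is.na(d2) | abs(d2) < 1e-12))

  expect_error(tajimas_d(hap_sample(1, matrix(1L, 1, 1), "A", 10)),
               "at least 2")
})

test_that("mean r-squared matches the coupling oracles", {
  # perfectly coupled pair
  s1 <- hap_from_strings(c("00", "00", "11", "11"), region_length = 100)
  expect_equal(mean_r2(s1)$r2, 1)
  # independent pair, all four gametes equally frequent
  s0 <- hap_from_strings(c("00", "01", "10", "11"), region_length = 100)
  expect_equal(mean_r2(s0)$r2, 0)
  # D = 0.125 over denominators 0.25 * 0.1875 -> 1/3
  s3 <- hap_from_strings(c("00", "01", "11", "11"), region_length = 100)
  expect_equal(mean_r2(s3)$r2, 1 / 3)
  # fewer than two polymorphic sites -> undefined
  s_one <- hap_from_strings(c("0", "1", "1", "0"), region_length = 100)
  expect_true(is.na(mean_r2(s_one)$r2))
})

test_that("Hudson F_ST matches the two-population oracles", {
  # identical allele counts in both populations: the (p1-p2)^2 term vanishes
  # and the small-sample corrections leave exactly -1/(n-1), which tends to 0
  # (the estimator is unbiased around 0 under no differentiation)
  half <- matrix(rep(c(1L, 0L), 10), 10, 2)
  s <- hap_sample(c(10, 20), rbind(half, half), rep(c("A", "B"), each = 10), 1000)
  expect_equal(fst(s, c("A", "B")), -1 / 9)
  big <- matrix(rep(c(1L, 0L), 100), 100, 2)
  s_big <- hap_sample(c(10, 20), rbind(big, big),
                      rep(c("A", "B"), each = 100), 1000)
  expect_lt(abs(fst(s_big, c("A", "B"))), 0.011)

  # fixed difference approaches 1
  g2 <- rbind(matrix(1L, 20, 1), matrix(0L, 20, 1))
  s2 <- hap_sample(5, g2, rep(c("A", "B"), each = 20), 100)
  expect_equal(fst(s2, c("A", "B")), 1, tolerance = 0.06)

  # derived counts 2/10 and 8/10: 0.324444/0.68
  g3 <- rbind(matrix(c(rep(1L, 2), rep(0L, 8))), matrix(c(rep(1L, 8), rep(0L, 2))))
  s3 <- hap_sample(5, g3, rep(c("A", "B"), each = 10), 100)
  expect_equal(fst(s3, c("A", "B")), 0.324444444 / 0.68, tolerance = 1e-6)

  # Weir-Cockerham route stays in a sane range on the same data
  expect_gt(fst(s3, c("A", "B"), method = "wc"), 0.2)
  expect_error(fst(s3, c("A", "B", "C")), "exactly two")
})

test_that("divergence counting follows the masked fixed-difference convention", {
  expect_equal(divergence_from_sequences("ACGT", "ACGT"), 0)
  # 9 mismatches, 2 of them at polymorphic (masked) sites, 10 kb region
  set.seed(5)
  ref <- rep("A", 10000)
  anc <- ref
  diff_sites <- c(3, 100, 2000, 3000, 4000, 5000, 6000, 7000, 9000)
  anc[diff_sites + 1] <- "G"
  expect_equal(
    divergence_from_sequences(ref, anc, polymorphic_pos = c(3, 100)),
    7 / 10000)
  expect_equal(divergence_rate(12, 24000), 5e-4)
})

test_that("H12 matches direct evaluation of the pooled-homozygosity formula", {
  all_same <- hap_from_strings(rep("01", 8), region_length = 100)
  expect_equal(h12(all_same, 15, 100), 1)

  # class frequencies 0.4 / 0.3 / 0.2 / 0.1 -> 0.7^2 + 0.04 + 0.01 = 0.54
  strs <- c(rep("000", 4), rep("100", 3), rep("010", 2), rep("001", 1))
  s <- hap_from_strings(strs, region_length = 1000)
  expect_equal(h12(s, 20, 1000), 0.54)

  # n all-distinct haplotypes: (2/n)^2 + (n-2)/n^2
  n <- 6
  distinct <- diag(1L, n)
  sd6 <- hap_sample(seq_len(n) * 10, distinct, rep("X", n), 1000)
  expect_equal(h12(sd6, 30, 1000), (2 / n)^2 + (n - 2) / n^2)

  # empty window undefined
  expect_true(is.na(h12(s, 900, 10)))
})

test_that("replicate aggregation uses mean of means and mean of SDs", {
  stats <- tibble::tibble(
    region = rep(c("r1", "r2"), each = 4),
    replicate = rep(1:4, 2),
    statistic = "S_per_site", population = "AFR",
    value = c(c(1, 1, 1, 1) + c(-0.1, 0.1, -0.1, 0.1),
              c(2, 2, 2, 2) + c(-0.3, 0.3, -0.3, 0.3)))
  agg <- aggregate_replicates(stats)
  expect_equal(agg$display$value, 1.5)
  expect_equal(agg$display$bar,
               mean(c(sd(c(0.9, 1.1, 0.9, 1.1)), sd(c(1.7, 2.3, 1.7, 2.3)))))

  # identical replicates -> zero SD
  same <- dplyr::mutate(stats, value = 2)
  expect_equal(aggregate_replicates(same)$display$bar, 0)

  # 100 standard-normal draws per region: region SDs concentrate near 1
  set.seed(42)
  norm <- tibble::tibble(
    region = rep(sprintf("r%d", 1:20), each = 100),
    replicate = rep(1:100, 20),
    statistic = "x", population = "AFR",
    value = rnorm(2000))
  per <- aggregate_replicates(norm)$per_region
  expect_true(all(per$sd > 0.8 & per$sd < 1.2))
})

test_that("window specs validate and tile regions sensibly", {
  expect_error(window_spec(step = 0), "step")
  expect_error(window_spec(width = 1000, step = 2000), "step")
  w <- window_spec(10000, 5000)
  expect_equal(nrow(popbaseline:::region_windows(30000, w)), 5)
  expect_equal(nrow(popbaseline:::region_windows(8000, w)), 1)
})

test_that("the fitting vector has exactly 18 entries for four populations", {
  set.seed(9)
  n_per <- 6
  pops <- rep(c("AFR", "EUR", "EAS", "SAS"), each = n_per)
  geno <- matrix(rbinom(24 * 40, 1, 0.3), nrow = 24)
  s <- hap_sample(sort(sample(1:20000, 40)), geno, pops, 20000)
  sv <- stat_vector(s)
  expect_equal(nrow(sv), 18)
  expect_equal(sum(sv$statistic == "fst"), 6)
  expect_true(all(table(sv$statistic[sv$statistic != "fst"]) == 4))
})
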