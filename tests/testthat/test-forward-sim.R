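# The forward Wright-Fisher engine: DFE draws, layouts, neutral calibration,
# fixation probabilities, scaling, and sweep conditioning semantics.

test_that("DFE draws follow class frequencies and scale conversions", {
  dfe <- dfe_model(f = c(0.4, 0.3, 0.2, 0.1), n_ref = 5000)
  set.seed(61)
  d <- draw_fitness_effect(dfe, 1e5)
  counts <- table(factor(d$class, levels = c("f0", "f1", "f2", "f3")))
  p <- suppressWarnings(chisq.test(counts, p = c(0.4, 0.3, 0.2, 0.1))$p.value)
  expect_gt(p, 0.01)
  # all deleterious draws are negative; class ranges respected
  expect_true(all(d$s <= 0))
  expect_true(all(d$scaled_s[d$class == "f1"] >= 1 &
                    d$scaled_s[d$class == "f1"] < 10))

  # f0 = 1: every draw effectively neutral (2 N s < 1)
  d0 <- draw_fitness_effect(dfe_model(f = c(1, 0, 0, 0), n_ref = 5000), 1000)
  expect_true(all(abs(d0$s) < 1 / (2 * 5000)))

  # beneficial class 100 <= 2 N s < 1000 at N_ref = 5000 -> s in [0.01, 0.1)
  dfe_b <- dfe_model(f = c(0.399, 0.3, 0.2, 0.1), n_ref = 5000,
                     beneficial = list(f = 0.001, lo = 100, hi = 1000))
  db <- draw_fitness_effect(dfe_b, 5e4)
  ben <- db[db$class == "fb", ]
  expect_true(all(ben$s >= 0.01 & ben$s < 0.1))
})

test_that("beneficial rebalancing preserves total frequency and guards f0", {
  dfe <- dfe_model(f = c(0.25, 0.5, 0.15, 0.1), n_ref = 1000)
  reb <- add_beneficial_class(dfe, 0.01, c(100, 1000))
  expect_equal(sum(reb$f), 1)
  expect_equal(reb$f[1], 0.24)
  expect_error(add_beneficial_class(dfe, 0.3, c(1, 10)), "f0 is smaller")
})

test_that("the default sweep chromosome has the expected default geometry", {
  lay <- assemble_sweep_chromosome()
  expect_equal(attr(lay, "total_length"), 198345)
  expect_equal(sum(lay$type == "exon"), 63)       # 7 regions x 9 exons
  expect_equal(sum(lay$type == "intron"), 56)     # 7 regions x 8 introns
  expect_equal(exonic_bp(lay), 7 * 9 * 1317)
  # contiguous, non-overlapping, lengths sum to the total
  expect_equal(lay$start[-1], lay$end[-nrow(lay)])
  expect_equal(sum(lay$end - lay$start), attr(lay, "total_length"))

  one <- chromosome_layout(n_regions = 1, n_exons = 1, n_introns = 0,
                           intergenic_bp = 0)
  expect_equal(attr(one, "total_length"), 1317)
})

test_that("rate maps drawn per replicate hit the requested mean exactly", {
  set.seed(71)
  rm <- draw_rate_map(1e-8, 198345, n_pieces = 25)
  w <- rm$end - rm$start
  expect_equal(sum(rm$rate * w) / sum(w), 1e-8)
  expect_gt(max(rm$rate) / min(rm$rate), 1.2)
})

test_that("zero mutation rate yields zero polymorphism and zero fixations", {
  r <- run_forward(N = 50, L = 1e4, mu = 0, rec = 1e-8, sample_sizes = 10,
                   divergence_generations = 50, seed = 1)
  expect_equal(ncol(r$sample$geno), 0)
  expect_equal(nrow(r$fixations), 0)
})

test_that("the engine is deterministic under a fixed seed", {
  args <- list(N = 50, L = 5e4, mu = 1e-6, rec = 1e-7, sample_sizes = 10,
               divergence_generations = 100)
  a <- do.call(run_forward, c(args, seed = 9))
  b <- do.call(run_forward, c(args, seed = 9))
  expect_identical(a$sample, b$sample)
  expect_identical(a$fixations, b$fixations)
  c2 <- do.call(run_forward, c(args, seed = 10))
  expect_false(identical(a$sample$positions, c2$sample$positions))
})

test_that("neutral fixation probability of a new allele is ~ 1/(2N)", {
  N <- 25
  fixed <- vapply(1:1500, function(i) {
    r <- run_introduction(N = N, L = 1000, mu = 0, rec = 0, sample_sizes = 2,
                          divergence_generations = 160, seed = 20000 + i,
                          s = 0, gen = 0, pos = 500, burn_in_multiplier = 0.2)
    r$sweep_fixed_globally
  }, logical(1))
  ci <- stats::binom.test(sum(fixed), length(fixed),
                          p = 1 / (2 * N))$conf.int
  expect_true(ci[1] <= 1 / (2 * N) && 1 / (2 * N) <= ci[2])
})

test_that("rescaled runs reproduce diversity within sampling error", {
  base <- list(N = 200, mu = 5e-7, rec = 5e-7, span = 200)
  pis <- vapply(c(1, 2, 5), function(kap) {
    mean(vapply(1:20, function(i) {
      r <- run_forward(N = base$N / kap, L = 2e4, mu = base$mu * kap,
                       rec = base$rec * kap, sample_sizes = 10,
                       divergence_generations = round(base$span / kap),
                       seed = 300 * kap + i)
      sample_pi(r$sample)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(abs(pis / pis[1] - 1) < 0.35))
})

test_that("conditioned sweeps respect their conditioning sets and restart caps", {
  m <- toy_model(kappa = 25)
  lay <- chromosome_layout(n_regions = 1)
  dfe <- dfe_model(n_ref = m$params[["N_AFR_anc"]])
  # strong selection: conditioning succeeds with few restarts
  cfg <- sweep_config(3, two_ns = 1000, max_restarts = 20000)
  r <- run_conditioned_sweep(cfg, m, lay, dfe, mu = 2.5e-7, rec = 2.5e-7,
                             sample_sizes = c(AFR = 8, EUR = 8),
                             divergence_generations = 160, seed = 81,
                             fix_interval = 10)
  expect_lt(r$restarts, 2000)
  # fixed in EUR: every sampled EUR haplotype carries it at the sweep site
  eur <- subset_pops(r$sample, "EUR", drop_monomorphic = FALSE)
  sweep_col <- which(r$sites$element == "exon" &
                       abs(r$sites$sel - 1000 / (2 * m$params[["N_AFR_anc"]])) < 1e-12)
  if (length(sweep_col) == 1) { # absent when it fixed globally and was logged
    expect_true(all(eur$geno[, sweep_col] == 1))
  } else {
    expect_true(r$sweep_fixed_globally)
  }
  # model 3 does not condition on AFR carrying the allele
  expect_true(r$sweep_in_sample)

  # restart cap errors out with the attempt count
  cfg2 <- sweep_config(1, two_ns = 0.01, max_restarts = 1)
  expect_error(
    run_conditioned_sweep(cfg2, m, lay, dfe, mu = 0, rec = 2.5e-7,
                          sample_sizes = c(AFR = 4),
                          divergence_generations = 160, seed = 82,
                          fix_interval = 10),
    "restart attempts")
})

test_that("neutral conditioning needs on the order of 2N attempts", {
  m <- toy_model(kappa = 625)  # tiny sizes: N_AFR ~ 20
  lay <- chromosome_layout(n_regions = 1, n_exons = 1, n_introns = 0,
                           intergenic_bp = 100)
  N <- m$params[["N_AFR_anc"]]
  cfg <- sweep_config(1, two_ns = 1e-6, max_restarts = 1e6)
  restarts <- vapply(1:25, function(i) {
    r <- run_conditioned_sweep(cfg, m, lay, dfe = NULL, mu = 0, rec = 0,
                               sample_sizes = c(AFR = 2),
                               divergence_generations = 300, seed = 900 + i,
                               fix_interval = 5)
    r$restarts
  }, numeric(1))
  # geometric with success probability ~ 1/(2N): mean within 3x of 2N
  expect_gt(mean(restarts), 2 * N / 3)
  expect_lt(mean(restarts), 3 * 2 * N)
})

test_that("beneficial fixations land only in exonic elements", {
  lay <- chromosome_layout(n_regions = 1)
  dfe <- dfe_model(f = c(0.889, 0, 0.1, 0.01), n_ref = 100,
                   beneficial = list(f = 0.001, lo = 100, hi = 1000))
  fx <- dplyr::bind_rows(lapply(1:10, function(i) {
    run_forward(N = 100, layout = lay, dfe = dfe, mu = 5e-6, rec = 5e-7,
                sample_sizes = 10, divergence_generations = 200,
                seed = 400 + i)$fixations
  }))
  expect_true(all(fx$element[fx$sel > 0] == "exon"))
  expect_true(all(fx$element[fx$sel < 0] == "exon"))
})
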