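# Sweep scans: background SFS, CLR model, H12 windows, ROC machinery.

test_that("background SFS normalizes polymorphic and substitution classes", {
  # counts {1:3, 2:1} plus one substitution in n = 4 -> (0.6, 0.2, 0, 0.2)
  geno <- cbind(c(1L, 0L, 0L, 0L), c(1L, 0L, 0L, 0L),
                c(1L, 0L, 0L, 0L), c(1L, 1L, 0L, 0L))
  s <- hap_sample(c(10, 20, 30, 40), geno, rep("A", 4), 1000)
  bg <- build_background_sfs(s, n_substitutions = 1)
  expect_equal(as.numeric(bg), c(0.6, 0.2, 0, 0.2))
  expect_equal(attr(bg, "n"), 4L)

  expect_error(build_background_sfs(list()), "at least one")
  s2 <- hap_sample(5, matrix(c(1L, 0L), 2, 1), rep("A", 2), 100)
  expect_error(build_background_sfs(list(s, s2)), "same haplotype count")
})

test_that("neutral simulations reproduce the 1/i frequency law", {
  m <- toy_model(kappa = 25)
  req <- region_sim_request("r", 5e4, 4e-7, 2e-7, replicates = 40)
  sims <- simulate_region(m, req, c(AFR = 6), seed = 19)
  bg <- build_background_sfs(sims)
  n <- attr(bg, "n")
  expected <- (1 / seq_len(n - 1)) / sum(1 / seq_len(n - 1))
  observed <- as.numeric(bg)[seq_len(n - 1)] / sum(as.numeric(bg)[seq_len(n - 1)])
  expect_lt(max(abs(observed - expected)), 0.05)
})

# Independent CLR oracle: direct evaluation of the escape-probability sweep
# spectrum and the composite likelihood over a dense alpha grid.
oracle_lambda <- function(sample, bg, x, subs, rec_rate, alphas) {
  n <- attr(bg, "n")
  p <- as.numeric(bg)
  cs <- colSums(sample$geno)
  keep <- cs >= 1 & cs < n
  b <- c(cs[keep], rep(n, length(subs)))
  d <- abs(c(sample$positions[keep], subs) - x) * rec_rate
  ll0 <- sum(log(p[b]))
  spec_at <- function(pe) {
    out <- numeric(n)
    for (k in 0:n) {
      w_k <- dbinom(k, n, pe)
      if (w_k < 1e-14) next
      if (k == n) { out <- out + w_k * p; next }
      m <- k + 1
      pm <- sapply(0:m, function(j) sum(p * dhyper(j, 1:n, n - (1:n), m)))
      for (j in 0:m) {
        if (j > 0) {
          bb <- j - 1 + (n - k)
          out[bb] <- out[bb] + w_k * pm[j + 1] * j / m
        }
        if (j < m && j >= 1) out[j] <- out[j] + w_k * pm[j + 1] * (m - j) / m
      }
    }
    out / sum(out)
  }
  lls <- sapply(alphas, function(a) {
    pe <- 1 - exp(-a * d)
    sum(sapply(seq_along(b), function(i) log(max(spec_at(pe[i])[b[i]], 1e-300))))
  })
  max(0, 2 * (max(lls) - ll0))
}

test_that("the CLR scan agrees with a brute-force alpha-grid oracle", {
  set.seed(23)
  n <- 8
  p_bg <- (1 / 1:n); p_bg <- p_bg / sum(p_bg)
  bg <- structure(p_bg, n = as.integer(n), class = "pb_sfs")
  # data drawn from the background itself (no sweep)
  S <- 40
  pos <- sort(runif(S, 0, 5e4))
  counts <- sample(1:n, S, replace = TRUE, prob = p_bg)
  geno <- matrix(0L, n, S)
  for (j in seq_len(S)) geno[seq_len(counts[j]), j] <- 1L
  poly <- counts < n
  s <- hap_sample(pos[poly], geno[, poly, drop = FALSE], rep("X", n), 5e4)
  subs <- pos[!poly]
  grid <- c(10000, 25000, 40000)
  track <- clr_scan(s, bg, grid_positions = grid, substitution_pos = subs,
                    rec_rate = 1e-8)
  expect_true(all(track$score >= 0))
  alphas <- 10^seq(1, 6, length.out = 60)
  for (i in seq_along(grid)) {
    lam <- oracle_lambda(s, bg, grid[i], subs, 1e-8, alphas)
    expect_lt(abs(track$score[i] - lam), 0.2 + 0.05 * lam)
  }
})

test_that("a hard sweep lifts both CLR and H12 at the swept site", {
  m <- toy_model(kappa = 25)
  lay <- chromosome_layout(n_regions = 2)
  dfe <- dfe_model(n_ref = m$params[["N_AFR_anc"]])
  L <- attr(lay, "total_length")
  args <- list(model = m, layout = lay, dfe = dfe, mu = 3.1e-7, rec = 3.1e-7,
               sample_sizes = c(EUR = 15), divergence_generations = 160,
               fix_interval = 10)
  swept <- do.call(run_conditioned_sweep,
                   c(list(cfg = sweep_config(3, 1000, 20000)), args, seed = 29))
  null <- do.call(run_forward, c(args, seed = 31))
  eur_s <- subset_pops(swept$sample, "EUR")
  eur_n <- subset_pops(null$sample, "EUR")
  sweep_pos <- L / 2

  # H12 near 1 immediately after fixation, above the neutral value
  h_s <- h12(eur_s, sweep_pos, 10000)
  h_n <- h12(eur_n, sweep_pos, 10000)
  expect_gt(h_s, 0.5)
  expect_gt(h_s, h_n)

  bg <- build_background_sfs(
    eur_n, n_substitutions = sum(null$fixations$post_burnin))
  grid <- seq(0, L, length.out = 11)
  tr_s <- clr_scan(eur_s, bg, grid,
                   substitution_pos =
                     swept$fixations$position[swept$fixations$post_burnin],
                   rec_rate = 3.1e-7)
  expect_true(all(is.finite(tr_s$score)))
  near <- which.min(abs(tr_s$position - sweep_pos))
  expect_gt(tr_s$score[near], 0)
})

test_that("H12 scans decrease with window width on neutral data", {
  m <- toy_model(kappa = 25)
  req <- region_sim_request("r", 4e4, 4e-7, 4e-7, replicates = 15)
  sims <- simulate_region(m, req, c(AFR = 10), seed = 37)
  means <- sapply(c(1000, 5000, 20000, 40000), function(wd) {
    mean(sapply(sims, function(s) {
      tr <- h12_scan(s, widths = wd)
      mean(tr$score, na.rm = TRUE)
    }))
  })
  expect_true(all(diff(means) < 0))
  expect_true(all(means < 1 & means > 0))
})

test_that("ROC curves match hand enumeration and the Mann-Whitney identity", {
  mk_track <- function(scores, positions = seq_along(scores) * 100) {
    tibble::tibble(position = positions, score = scores, method = "clr")
  }
  # identical score distributions -> diagonal, AUC 1/2
  same <- lapply(1:10, function(i) mk_track(rep(i, 5)))
  r0 <- roc(same, same, truth = 300)
  expect_equal(attr(r0, "auc"), 0.5, tolerance = 1e-9)

  # perfectly separated -> AUC 1
  hi <- lapply(1:10, function(i) mk_track(rep(10 + i, 5)))
  lo <- lapply(1:10, function(i) mk_track(rep(i / 100, 5)))
  expect_equal(auc(roc(hi, lo, truth = 300)), 1)

  # 20 + 20 replicates with hand-assigned scores: brute-force enumeration
  set.seed(41)
  sweep_scores <- rnorm(20, 1)
  null_scores <- rnorm(20, 0)
  sw <- lapply(sweep_scores, function(x) mk_track(x, positions = 300))
  nl <- lapply(null_scores, function(x) mk_track(x, positions = 300))
  r <- roc(sw, nl, truth = 300, tp_radius = 50)
  for (t in c(-1, 0, 0.5, 1, 2)) {
    expect_equal(r$tpr[which.min(abs(r$threshold - t))[1]],
                 mean(sweep_scores > r$threshold[which.min(abs(r$threshold - t))[1]]))
  }
  # trapezoid AUC equals the Mann-Whitney U statistic on replicate maxima
  u <- mean(outer(sweep_scores, null_scores, ">")) # no ties a.s.
  expect_equal(auc(r), u, tolerance = 1e-9)

  # monotone staircase from (0,0) to (1,1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(tail(r$fpr, 1), tail(r$tpr, 1)), c(1, 1))

  expect_error(roc(sw, nl, truth = numeric(0)), "truth")
})

test_that("SweepFinder-style input files are written in the expected shape", {
  s <- hap_from_strings(c("10", "11", "01", "00"), region_length = 1000,
                        positions = c(100, 600))
  base <- file.path(withr::local_tempdir(), "sf")
  write_sweepfinder_input(s, base, substitution_pos = 800)
  freq <- readr::read_tsv(paste0(base, ".freq"), show_col_types = FALSE)
  expect_equal(names(freq), c("position", "x", "n", "folded"))
  expect_equal(freq$x[freq$position == 800], 4)
  expect_equal(nrow(readr::read_tsv(paste0(base, ".grid"),
                                    show_col_types = FALSE)), 21)
})
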