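# Sweep detection: a composite-likelihood-ratio scan against a genome-wide
# background SFS (SweepFinder-style), windowed H12 at each SNP, and ROC-based
# power evaluation.

the_clr_cache <- new.env(parent = emptyenv())

#' Background site frequency spectrum
#'
#' Unfolded derived-allele-frequency class probabilities for sample size `n`,
#' built from sweep-free simulations, including the fixed-derived
#' (substitution) class `n`; only polymorphic and substitution data enter.
#'
#' @param samples list of [hap_sample()]s with a common haplotype count (or a
#'   single sample).
#' @param n_substitutions total count of substitutions (fixed derived sites)
#'   to add to class `n`, e.g. post-burn-in fixations from the generating
#'   simulations; sites fixed within the sample matrices are also counted.
#' @return A `pb_sfs`: probability vector over derived counts `1..n` with
#'   attribute `n`.
#' @export
build_background_sfs <- function(samples, n_substitutions = 0) {
  if (inherits(samples, "hap_sample")) samples <- list(samples)
  assert_that(length(samples) >= 1, "Need at least one sample.")
  n <- unique(vapply(samples, function(s) nrow(s$geno), numeric(1)))
  assert_that(length(n) == 1, "All samples must have the same haplotype count.")
  counts <- numeric(n)
  for (s in samples) {
    cs <- colSums(s$geno)
    tab <- tabulate(cs[cs >= 1], nbins = n)
    counts <- counts + tab
  }
  counts[n] <- counts[n] + n_substitutions
  assert_that(sum(counts) > 0, "No polymorphic or substitution data supplied.")
  structure(counts / sum(counts), n = as.integer(n), class = "pb_sfs")
}

# Hypergeometric downsampling of a background SFS p (over 1..n) to sample
# size m: returns matrix Q[m+1, n] with Q[j+1, b] = P(j of m derived | b of n).
downsample_matrix <- function(n, m) {
  b <- matrix(0, nrow = m + 1, ncol = n)
  for (bb in seq_len(n)) {
    j <- 0:m
    b[, bb] <- stats::dhyper(j, bb, n - bb, m)
  }
  b
}

# Sweep-distorted spectrum: with per-lineage escape probability pe, k of n
# lineages escape; the n-k hitchhikers coalesce into one lineage, so the
# effective sample is k escapees + 1 representative drawn from the background
# spectrum at size k+1; the representative's allele is copied to the n-k
# hitchhikers. Renormalized over observable classes 1..n.
sweep_spectrum <- function(p_bg, pe, ds_list) {
  n <- length(p_bg)
  out <- numeric(n)
  kprob <- stats::dbinom(0:n, n, pe)
  for (k in 0:n) {
    if (kprob[k + 1] < 1e-12) next
    if (k == n) {
      out <- out + kprob[k + 1] * p_bg
      next
    }
    m <- k + 1
    # pm[j+1] = P(j derived among the m effective lineages)
    pm <- as.numeric(ds_list[[m]] %*% p_bg)
    contrib <- numeric(n + 1) # index i holds derived count i - 1
    for (j in 0:m) {
      if (pm[j + 1] == 0) next
      # representative carries derived with prob j/m
      if (j > 0) {
        b_hit <- (j - 1) + (n - k) # j-1 escapees derived + n-k copies
        contrib[b_hit + 1] <- contrib[b_hit + 1] + pm[j + 1] * j / m
      }
      if (j < m && j >= 1) {
        # representative ancestral: only the j derived escapees remain
        contrib[j + 1] <- contrib[j + 1] + pm[j + 1] * (m - j) / m
      }
    }
    out <- out + kprob[k + 1] * contrib[2:(n + 1)]
  }
  s <- sum(out)
  if (s <= 0) return(p_bg)
  out / s
}

#' Composite likelihood ratio sweep scan
#'
#' At each grid position, the composite likelihood of the observed derived
#' allele counts (polymorphic sites plus substitutions) under a sweep model
#' centered there — lineages escape the sweep with probability
#' `1 - exp(-alpha * d)`, `d` the recombination distance from the rate map —
#' is maximized over the sweep intensity `alpha >= 0` and compared to the
#' background spectrum: `Lambda = 2 (ln CL_sweep - ln CL_background)`. As
#' `alpha` grows the sweep model recovers the background, so `Lambda >= 0` by
#' construction.
#'
#' @param sample a [hap_sample()].
#' @param background a `pb_sfs` with matching `n`.
#' @param grid_positions positions to test; default 21 evenly spaced points.
#' @param substitution_pos positions of fixed derived sites (substitutions),
#'   e.g. from the fixation log.
#' @param rec_rate scalar recombination rate or piecewise map used for
#'   per-site recombination distances.
#' @param alpha_grid log-spaced candidate intensities (refined by
#'   golden-section around the best).
#' @param x_bins resolution of the cache of sweep spectra over the scaled
#'   distance `x = alpha * d` (log-spaced; `pe = 1 - exp(-x)`).
#' @return A `pb_scan` tibble: `position`, `score`, `alpha`, method tag
#'   `"clr"`.
#' @export
clr_scan <- function(sample, background, grid_positions = NULL,
                     substitution_pos = numeric(0), rec_rate = 1e-8,
                     alpha_grid = 10^seq(1, 6, length.out = 26),
                     x_bins = 400) {
  n <- attr(background, "n")
  assert_that(n == nrow(sample$geno),
              "Background SFS sample size does not match the sample.")
  cs <- colSums(sample$geno)
  keep <- cs >= 1 # sites fixed within the sample are substitution data
  b_obs <- c(cs[keep], rep(n, length(substitution_pos)))
  pos_obs <- c(sample$positions[keep], substitution_pos)
  assert_that(length(b_obs) > 0,
              "No polymorphic or substitution sites: scan undefined.")
  if (is.null(grid_positions)) {
    grid_positions <- seq(0, sample$region_length, length.out = 21)
  }
  # recombination distance of each site from an arbitrary origin
  rmap <- rate_map_matrix(rec_rate, sample$region_length)
  cumr <- c(0, cumsum(rmap[, 3] * (rmap[, 2] - rmap[, 1])))
  rec_coord <- function(x) {
    i <- findInterval(x, rmap[, 1], rightmost.closed = TRUE)
    i <- pmax(1, pmin(i, nrow(rmap)))
    cumr[i] + (x - rmap[i, 1]) * rmap[i, 3]
  }
  d_obs <- rec_coord(pos_obs)
  d_grid <- rec_coord(grid_positions)

  p_bg <- as.numeric(background)
  log_bg <- log(pmax(p_bg, 1e-300))
  ll_bg <- sum(log_bg[b_obs])

  # sweep spectra cached over the scaled distance x = alpha * d on a log grid
  # (pe = 1 - exp(-x)); log spacing keeps resolution near pe = 0 where the
  # likelihood is most sensitive. The cache depends only on the background,
  # so it is memoised across calls (scans over many replicates share it).
  log_x <- seq(log(1e-8), log(1e4), length.out = x_bins)
  x_grid <- c(0, exp(log_x), Inf)
  memo_key <- paste0(n, ";", x_bins, ";",
                     paste(signif(p_bg, 12), collapse = ","))
  spec_cache <- the_clr_cache[[memo_key]]
  if (is.null(spec_cache)) {
    ds_list <- lapply(1:n, function(m) downsample_matrix(n, m))
    spec_cache <- lapply(x_grid, function(x) {
      log(pmax(sweep_spectrum(p_bg, 1 - exp(-x), ds_list), 1e-300))
    })
    the_clr_cache[[memo_key]] <- spec_cache
  }
  step_lx <- log_x[2] - log_x[1]
  ll_sweep <- function(alpha, d) {
    x <- alpha * d
    bin <- ifelse(x <= x_grid[2], 1L,
                  ifelse(x >= 1e4, length(x_grid),
                         2L + as.integer(round((log(x) - log_x[1]) / step_lx))))
    bin <- pmin(length(x_grid), pmax(1L, bin))
    vapply(seq_along(d), function(i) spec_cache[[bin[i]]][b_obs[i]], numeric(1)) |>
      sum()
  }
  score <- numeric(length(grid_positions))
  alpha_hat <- numeric(length(grid_positions))
  for (gi in seq_along(grid_positions)) {
    d <- abs(d_obs - d_grid[gi])
    lls <- vapply(alpha_grid, ll_sweep, numeric(1), d = d)
    best <- which.max(lls)
    # golden-section refinement on log10(alpha) around the best grid value
    lo <- log10(alpha_grid[max(1, best - 1)])
    hi <- log10(alpha_grid[min(length(alpha_grid), best + 1)])
    opt <- stats::optimize(function(la) ll_sweep(10^la, d),
                           c(lo, hi), maximum = TRUE, tol = 0.01)
    ll_best <- max(opt$objective, lls[best])
    score[gi] <- max(0, 2 * (ll_best - ll_bg))
    alpha_hat[gi] <- 10^opt$maximum
  }
  structure(tibble(position = grid_positions, score = score, alpha = alpha_hat,
                   method = "clr"),
            class = c("pb_scan", "tbl_df", "tbl", "data.frame"))
}

#' Windowed H12 scan
#'
#' [h12()] evaluated at each SNP with the SNP at the center of the window,
#' for each requested width (conventionally 1, 2, 5, 10, 20 and 40 kb).
#'
#' @param sample a [hap_sample()].
#' @param widths window widths in bp.
#' @return A `pb_scan` tibble: `position`, `score`, `width`, method `"h12"`.
#' @export
h12_scan <- function(sample, widths = c(1, 2, 5, 10, 20, 40) * 1000) {
  assert_that(ncol(sample$geno) >= 1, "Sample has no SNPs.")
  out <- purrr::map_dfr(widths, function(w) {
    tibble(position = sample$positions,
           score = vapply(sample$positions, function(x) h12(sample, x, w),
                          numeric(1)),
           width = w, method = "h12")
  })
  structure(out, class = c("pb_scan", "tbl_df", "tbl", "data.frame"))
}

#' @export
autoplot.pb_scan <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$position, .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "position (bp)", y = unique(object$method)) +
    ggplot2::theme_minimal()
  if ("width" %in% names(object) && length(unique(object$width)) > 1) {
    p <- p + ggplot2::facet_wrap(~width)
  }
  p
}

#' ROC curve for sweep detection power
#'
#' Replicate-level power: each sweep replicate is summarised by its maximum
#' score within `tp_radius` of the true sweep position, each null replicate
#' by its genome-wide maximum; thresholds are swept over the pooled scores.
#' TPR is the fraction of sweep replicates whose summary exceeds the
#' threshold, FPR the corresponding fraction of null replicates. Site-level
#' bookkeeping (every evaluated site scored against the threshold) is
#' available with `level = "site"`.
#'
#' @param sweep_tracks list of `pb_scan` tibbles from sweep replicates.
#' @param null_tracks list of `pb_scan` tibbles from sweep-free replicates.
#' @param truth true sweep position(s): a single value or one per sweep
#'   replicate.
#' @param tp_radius bp radius around the true position within which a signal
#'   counts as a true positive (default 1 kb).
#' @param level `"replicate"` (default) or `"site"`.
#' @return A `pb_roc` tibble (`threshold`, `fpr`, `tpr`) with attribute
#'   `auc` (trapezoid rule).
#' @export
roc <- function(sweep_tracks, null_tracks, truth, tp_radius = 1000,
                level = c("replicate", "site")) {
  level <- match.arg(level)
  assert_that(length(sweep_tracks) >= 1 && length(null_tracks) >= 1,
              "Need at least one track in each set.")
  assert_that(length(truth) >= 1 && !anyNA(truth), "Empty sweep truth.")
  truth <- rep_len(truth, length(sweep_tracks))
  safe_max <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0) -Inf else max(x)
  }
  if (level == "replicate") {
    sweep_scores <- purrr::map2_dbl(sweep_tracks, truth, function(tr, tp) {
      safe_max(tr$score[abs(tr$position - tp) <= tp_radius])
    })
    null_scores <- purrr::map_dbl(null_tracks, function(tr) safe_max(tr$score))
  } else {
    sweep_scores <- unlist(purrr::map2(sweep_tracks, truth, function(tr, tp) {
      tr$score[abs(tr$position - tp) <= tp_radius]
    }))
    null_scores <- unlist(purrr::map(null_tracks, "score"))
  }
  thresholds <- sort(unique(c(-Inf, sweep_scores, null_scores, Inf)),
                     decreasing = TRUE)
  tpr <- vapply(thresholds, function(t) mean(sweep_scores > t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(null_scores > t), numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(tibble(threshold = thresholds, fpr = fpr, tpr = tpr),
            auc = auc, sweep_scores = sweep_scores, null_scores = null_scores,
            class = c("pb_roc", "tbl_df", "tbl", "data.frame"))
}

#' Area under a ROC curve
#' @param x a `pb_roc`.
#' @return The trapezoid-rule AUC.
#' @export
auc <- function(x) attr(x, "auc")

#' @export
autoplot.pb_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' @export
glance.pb_roc <- function(x, ...) {
  tibble(auc = attr(x, "auc"),
         n_sweep = length(attr(x, "sweep_scores")),
         n_null = length(attr(x, "null_scores")))
}

#' Write SweepFinder-style allele frequency and grid files
#'
#' Interoperability exports mirroring the conventional formats: the frequency
#' file has columns `position`, `x` (derived count), `n` (sample size),
#' `folded` (0); the grid file is one test position per line.
#'
#' @param sample a [hap_sample()].
#' @param path base path; writes `<path>.freq` and `<path>.grid`.
#' @param substitution_pos substitution positions to append with `x = n`.
#' @param grid_positions test positions (default 21 evenly spaced).
#' @return Invisibly, the two paths.
#' @export
write_sweepfinder_input <- function(sample, path, substitution_pos = numeric(0),
                                    grid_positions = NULL) {
  n <- nrow(sample$geno)
  cs <- colSums(sample$geno)
  keep <- cs >= 1
  freq <- tibble(position = c(sample$positions[keep], substitution_pos),
                 x = c(cs[keep], rep(n, length(substitution_pos))),
                 n = n, folded = 0L) |> arrange(.data$position)
  readr::write_tsv(freq, paste0(path, ".freq"))
  if (is.null(grid_positions)) {
    grid_positions <- seq(0, sample$region_length, length.out = 21)
  }
  readr::write_tsv(tibble(position = grid_positions), paste0(path, ".grid"))
  invisible(c(freq = paste0(path, ".freq"), grid = paste0(path, ".grid")))
}
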