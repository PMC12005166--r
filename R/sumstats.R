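#' Sliding-window specification
#'
#' @param width window width in bp (default 10 kb).
#' @param step step between window starts in bp (default 5 kb).
#' @return A `window_spec` list.
#' @export
window_spec <- function(width = 10000, step = 5000) {
  assert_that(is_scalar_number(width) && width > 0, "`width` must be positive.")
  assert_that(is_scalar_number(step) && step > 0 && step <= width,
              "`step` must satisfy 0 < step <= width.")
  structure(list(width = width, step = step), class = "window_spec")
}

# Window start/end table for a region; a region shorter than one window gets a
# single window covering it.
region_windows <- function(region_length, windows) {
  if (region_length <= windows$width) {
    return(tibble(start = 0, end = region_length))
  }
  starts <- seq(0, region_length - windows$width, by = windows$step)
  tibble(start = starts, end = starts + windows$width)
}

#' Segregating sites per accessible site
#'
#' Counts sites polymorphic within the sample and divides by the accessible
#' length (masked bases are excluded from both numerator and denominator by
#' [apply_mask()]).
#'
#' @param sample a [hap_sample()].
#' @return A single rate (per bp).
#' @export
segregating_sites_per_site <- function(sample) {
  assert_that(sample$accessible_bp > 0,
              "Undefined: sample has no accessible bases.")
  cs <- colSums(sample$geno)
  n <- nrow(sample$geno)
  sum(cs > 0 & cs < n) / sample$accessible_bp
}

# Tajima's D constants for sample size n (Tajima 1989).
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

tajima_d_value <- function(geno) {
  n <- nrow(geno)
  cs <- colSums(geno)
  poly <- cs > 0 & cs < n
  S <- sum(poly)
  if (S == 0) return(NA_real_)
  p <- cs[poly] / n
  # mean pairwise differences (unbiased per-site heterozygosity summed)
  pi <- sum(2 * p * (1 - p)) * n / (n - 1)
  k <- tajima_constants(n)
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)
  (pi - S / k$a1) / denom
}

#' Tajima's D in sliding windows
#'
#' Tajima (1989) D computed per window; windows without segregating sites are
#' undefined (`NA`) and are skipped by downstream means rather than
#' zero-filled.
#'
#' @param sample a [hap_sample()] with at least 2 haplotypes.
#' @param windows a [window_spec()].
#' @return A tibble with `start`, `end`, `n_sites`, `D`.
#' @export
tajimas_d <- function(sample, windows = window_spec()) {
  assert_that(nrow(sample$geno) >= 2, "Tajima's D needs at least 2 haplotypes.")
  w <- region_windows(sample$region_length, windows)
  w$D <- NA_real_
  w$n_sites <- 0L
  for (i in seq_len(nrow(w))) {
    in_w <- sample$positions >= w$start[i] & sample$positions < w$end[i]
    w$n_sites[i] <- sum(in_w)
    if (w$n_sites[i] > 0) {
      w$D[i] <- tajima_d_value(sample$geno[, in_w, drop = FALSE])
    }
  }
  w[, c("start", "end", "n_sites", "D")]
}

mean_r2_value <- function(geno) {
  n <- nrow(geno)
  cs <- colSums(geno)
  poly <- cs > 0 & cs < n
  if (sum(poly) < 2) return(NA_real_)
  g <- geno[, poly, drop = FALSE]
  # Pearson correlation of derived-allele indicators equals D/sqrt(p(1-p)q(1-q))
  r <- suppressWarnings(cor(g))
  mean(r[upper.tri(r)]^2)
}

#' Mean r-squared in sliding windows
#'
#' Mean over all pairs of polymorphic sites in the window of the squared
#' correlation of derived-allele indicators. Windows with fewer than two
#' polymorphic sites are undefined (`NA`). No frequency cutoff is applied.
#'
#' @inheritParams tajimas_d
#' @return A tibble with `start`, `end`, `n_sites`, `r2`.
#' @export
mean_r2 <- function(sample, windows = window_spec()) {
  w <- region_windows(sample$region_length, windows)
  w$r2 <- NA_real_
  w$n_sites <- 0L
  for (i in seq_len(nrow(w))) {
    in_w <- sample$positions >= w$start[i] & sample$positions < w$end[i]
    w$n_sites[i] <- sum(in_w)
    if (w$n_sites[i] >= 2) {
      w$r2[i] <- mean_r2_value(sample$geno[, in_w, drop = FALSE])
    }
  }
  w[, c("start", "end", "n_sites", "r2")]
}

#' F_ST between two populations
#'
#' Hudson's estimator per variant, combined across variants as a ratio of sums
#' (Bhatia-style), which is robust to unequal sample sizes. A Weir-Cockerham
#' estimator on haploid allele counts is available behind `method = "wc"`.
#' Sites monomorphic across both populations contribute nothing.
#'
#' @param sample a [hap_sample()] containing both populations.
#' @param pops length-2 character vector naming the pair; defaults to the two
#'   populations present.
#' @param method `"hudson"` (default) or `"wc"`.
#' @return A single F_ST value (can be slightly negative in finite samples).
#' @export
fst <- function(sample, pops = NULL, method = c("hudson", "wc")) {
  method <- match.arg(method)
  if (is.null(pops)) pops <- unique(sample$pop)
  assert_that(length(pops) == 2, "`pops` must name exactly two populations.")
  i1 <- sample$pop == pops[1]
  i2 <- sample$pop == pops[2]
  n1 <- sum(i1); n2 <- sum(i2)
  assert_that(n1 >= 2 && n2 >= 2, "Each population needs at least 2 haplotypes.")
  if (ncol(sample$geno) == 0) return(NA_real_)
  c1 <- colSums(sample$geno[i1, , drop = FALSE])
  c2 <- colSums(sample$geno[i2, , drop = FALSE])
  p1 <- c1 / n1
  p2 <- c2 / n2
  keep <- (c1 + c2) > 0 & (c1 + c2) < (n1 + n2)
  if (!any(keep)) return(NA_real_)
  p1 <- p1[keep]; p2 <- p2[keep]
  if (method == "hudson") {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    return(sum(num) / sum(den))
  }
  # Weir & Cockerham (1984) on haploid allele counts, ratio of sums
  nbar <- (n1 + n2) / 2
  r <- 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2)
  sum(a) / sum(a + b)
}

#' Divergence from fixed differences
#'
#' Empirical convention: the number of sites where the reference differs from
#' the ancestral state, with polymorphic sites masked from the count, divided
#' by the total region length.
#'
#' @param n_fixed count of fixed differences (already excluding polymorphic
#'   sites).
#' @param region_length total region length in bp (the denominator; masked or
#'   polymorphic bases are not subtracted).
#' @return Substitutions per bp.
#' @export
divergence_rate <- function(n_fixed, region_length) {
  assert_that(is_scalar_number(region_length) && region_length > 0,
              "`region_length` must be positive.")
  n_fixed / region_length
}

#' Divergence between reference and ancestral sequences
#'
#' @param reference,ancestral character vectors of equal length (one base per
#'   position) or single strings.
#' @param polymorphic_pos 0-based positions of polymorphic sites to mask from
#'   the fixed-difference count.
#' @return Substitutions per bp of the full region.
#' @export
divergence_from_sequences <- function(reference, ancestral, polymorphic_pos = numeric(0)) {
  if (length(reference) == 1 && nchar(reference[1]) > 1) {
    reference <- strsplit(reference, "")[[1]]
  }
  if (length(ancestral) == 1 && nchar(ancestral[1]) > 1) {
    ancestral <- strsplit(ancestral, "")[[1]]
  }
  assert_that(length(reference) == length(ancestral),
              "Reference and ancestral sequences must have equal length.")
  diff_pos <- which(reference != ancestral) - 1
  diff_pos <- setdiff(diff_pos, floor(polymorphic_pos))
  divergence_rate(length(diff_pos), length(reference))
}

#' H12 haplotype homozygosity in a window around a focal SNP
#'
#' With haplotype-class frequencies sorted decreasingly p1 >= p2 >= ...,
#' H12 = (p1 + p2)^2 + sum_{i>=3} p_i^2; the two most frequent classes are
#' pooled, which makes the statistic sensitive to both hard and soft sweeps.
#' Haplotype identity is exact match over the unmasked SNPs in the window.
#'
#' @param sample a [hap_sample()].
#' @param focal_pos center of the window (bp).
#' @param width window width in bp.
#' @return H12 in (0, 1], or `NA` if the window holds no SNPs.
#' @export
h12 <- function(sample, focal_pos, width) {
  assert_that(nrow(sample$geno) >= 1, "Need at least one haplotype.")
  in_w <- sample$positions >= focal_pos - width / 2 &
    sample$positions <= focal_pos + width / 2
  if (!any(in_w)) return(NA_real_)
  h12_from_matrix(sample$geno[, in_w, drop = FALSE])
}

h12_from_matrix <- function(geno) {
  keys <- apply(geno, 1, paste, collapse = "")
  p <- sort(as.numeric(table(keys)) / length(keys), decreasing = TRUE)
  if (length(p) == 1) return(1)
  (p[1] + p[2])^2 + sum(p[-(1:2)]^2)
}

#' The 18-statistic fitting vector
#'
#' Computes, for each of the four sampled populations, segregating sites per
#' accessible site, mean Tajima's D and mean r-squared over sliding windows,
#' and for each unordered population pair Hudson F_ST combined across variants:
#' 3 x 4 + 6 = 18 statistics in fitting mode.
#'
#' @param sample a multi-population [hap_sample()].
#' @param windows a [window_spec()] for the windowed statistics.
#' @param pops population order; defaults to `c("AFR","EUR","EAS","SAS")`
#'   intersected with the populations present.
#' @return A tibble with columns `statistic`, `population`, `value`.
#' @export
stat_vector <- function(sample, windows = window_spec(), pops = NULL) {
  v <- stat_vector_values(sample, windows, pops)
  tibble(statistic = attr(v, "statistic"),
         population = attr(v, "population"),
         value = as.numeric(v))
}

# Fast path shared by stat_vector() and the grid-search simulator: returns a
# bare numeric vector with statistic/population labels as attributes.
stat_vector_values <- function(sample, windows = window_spec(), pops = NULL) {
  if (is.null(pops)) {
    pops <- intersect(c("AFR", "EUR", "EAS", "SAS"), unique(sample$pop))
  }
  acc <- sample$accessible_bp
  w <- region_windows(sample$region_length, windows)
  n_pop <- length(pops)
  rows_p <- lapply(pops, function(p) which(sample$pop == p))
  n_p <- lengths(rows_p)
  # per-population derived counts at every site
  cs_p <- lapply(rows_p, function(r) .colSums(sample$geno[r, , drop = FALSE],
                                              length(r), ncol(sample$geno)))
  vals <- matrix(NA_real_, nrow = 3, ncol = n_pop)
  for (k in seq_len(n_pop)) {
    cs <- cs_p[[k]]
    n <- n_p[k]
    poly <- cs > 0L & cs < n
    gp <- sample$geno[rows_p[[k]], poly, drop = FALSE]
    pp <- sample$positions[poly]
    vals[1, k] <- sum(poly) / acc
    dvals <- r2vals <- rep(NA_real_, nrow(w))
    for (i in seq_len(nrow(w))) {
      in_w <- pp >= w$start[i] & pp < w$end[i]
      if (any(in_w)) dvals[i] <- tajima_d_value(gp[, in_w, drop = FALSE])
      if (sum(in_w) >= 2) r2vals[i] <- mean_r2_value(gp[, in_w, drop = FALSE])
    }
    vals[2, k] <- if (all(is.na(dvals))) NA_real_ else mean(dvals, na.rm = TRUE)
    vals[3, k] <- if (all(is.na(r2vals))) NA_real_ else mean(r2vals, na.rm = TRUE)
  }
  pairs <- utils::combn(pops, 2)
  fst_vals <- vapply(seq_len(ncol(pairs)), function(j) {
    i1 <- match(pairs[1, j], pops)
    i2 <- match(pairs[2, j], pops)
    hudson_fst_counts(cs_p[[i1]], n_p[i1], cs_p[[i2]], n_p[i2])
  }, numeric(1))
  structure(c(as.numeric(vals), fst_vals),
            statistic = c(rep(c("S_per_site", "tajimas_D", "mean_r2"), n_pop),
                          rep("fst", ncol(pairs))),
            population = c(rep(pops, each = 3),
                           apply(pairs, 2, paste, collapse = "-")))
}

hudson_fst_counts <- function(c1, n1, c2, n2) {
  keep <- (c1 + c2) > 0 & (c1 + c2) < (n1 + n2)
  if (!any(keep)) return(NA_real_)
  p1 <- c1[keep] / n1
  p2 <- c2[keep] / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

#' Aggregate per-replicate statistics
#'
#' Per-region means and standard deviations across replicates, plus the
#' display-level summary used for fit plots: the mean of region means as the
#' point and the mean of region standard deviations as the error bar.
#'
#' @param stats long tibble with columns `region`, `replicate`, `statistic`,
#'   `population`, `value` (as produced by mapping [stat_vector()] over
#'   replicates).
#' @return A list with `per_region` (region-level mean/sd) and `display`
#'   (mean of means, mean of SDs per statistic/population).
#' @export
aggregate_replicates <- function(stats) {
  needed <- c("region", "replicate", "statistic", "population", "value")
  assert_that(all(needed %in% names(stats)),
              paste("`stats` must have columns", paste(needed, collapse = ", ")))
  per_region <- stats |>
    group_by(.data$region, .data$statistic, .data$population) |>
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = sd(.data$value, na.rm = TRUE),
              n_rep = sum(!is.na(.data$value)), .groups = "drop")
  display <- per_region |>
    group_by(.data$statistic, .data$population) |>
    summarise(value = mean(.data$mean, na.rm = TRUE),
              bar = mean(.data$sd, na.rm = TRUE),
              n_regions = n(), .groups = "drop")
  list(per_region = per_region, display = display)
}

#' Fit-style comparison plot of empirical vs simulated statistics
#'
#' Points are means across regions; error bars are the mean of the per-region
#' standard deviations, one panel per statistic.
#'
#' @param emp,sim `display` tibbles from [aggregate_replicates()] (columns
#'   `statistic`, `population`, `value`, `bar`).
#' @return A ggplot object.
#' @export
plot_stat_fit <- function(emp, sim) {
  d <- bind_rows(mutate(emp, source = "empirical"),
                 mutate(sim, source = "simulated"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$population, y = .data$value,
                                  colour = .data$source)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$value - .data$bar,
                                          ymax = .data$value + .data$bar),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
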