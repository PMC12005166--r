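# R-side surface of the forward Wright-Fisher engine: DFE construction,
# chromosome layouts, demographic trajectory compilation, and the run_*
# entry points.

#' Discrete DFE over population-scaled selection classes
#'
#' Four fixed deleterious classes with boundaries on the `2 * N_ref * s`
#' scale — effectively neutral `[0, 1)`, weakly `[1, 10)`, moderately
#' `[10, 100)` and strongly `[100, 2 * N_ref]` deleterious (the upper bound
#' caps `s` at 1, a lethal) — plus an optional beneficial class. `s` is the
#' fitness change of the mutant homozygote; within each class `2 * N_ref * s`
#' is uniform.
#'
#' @param f frequencies `c(f0, f1, f2, f3)` of the deleterious classes.
#' @param n_ref reference (ancestral African) diploid size used for the
#'   scaling.
#' @param h dominance coefficient (default 0.5, genic selection).
#' @param beneficial optional `list(f = , lo = , hi = )`: frequency and
#'   `2 * N_ref * s_b` range of a beneficial class.
#' @return A `pb_dfe` object.
#' @export
dfe_model <- function(f = c(0.25, 0.50, 0.15, 0.10), n_ref = 5000, h = 0.5,
                      beneficial = NULL) {
  assert_that(length(f) == 4 && all(f >= 0), "Need 4 nonnegative class frequencies.")
  f_b <- if (is.null(beneficial)) 0 else beneficial$f
  assert_that(abs(sum(f) + f_b - 1) < 1e-8,
              "Class frequencies (including any beneficial class) must sum to 1.")
  lo <- c(0, 1, 10, 100)
  hi <- c(1, 10, 100, 2 * n_ref)
  sign <- c(-1, -1, -1, -1)
  labels <- c("f0", "f1", "f2", "f3")
  if (!is.null(beneficial)) {
    assert_that(beneficial$lo < beneficial$hi && beneficial$lo >= 0,
                "Beneficial class boundaries must be increasing and nonnegative.")
    lo <- c(lo, beneficial$lo)
    hi <- c(hi, beneficial$hi)
    sign <- c(sign, 1)
    f <- c(f, f_b)
    labels <- c(labels, "fb")
  }
  assert_that(all(hi > lo), "Class boundaries must be strictly increasing.")
  structure(list(f = f, lo = lo, hi = hi, sign = sign, labels = labels,
                 n_ref = n_ref, h = h),
            class = "pb_dfe")
}

#' Draw fitness effects from a DFE
#'
#' Classes are chosen with their frequencies; `2 * N_ref * s` is uniform
#' within the class and converted to `s` by dividing by `2 * N_ref`.
#' Deleterious classes return negative selection coefficients, beneficial
#' positive.
#'
#' @param dfe a [dfe_model()].
#' @param n number of draws.
#' @return A tibble with `class`, `scaled_s` (`2 N_ref s`, unsigned) and `s`
#'   (signed homozygote fitness effect).
#' @export
draw_fitness_effect <- function(dfe, n = 1) {
  cls <- sample.int(length(dfe$f), n, replace = TRUE, prob = dfe$f)
  u <- runif(n, dfe$lo[cls], dfe$hi[cls])
  s <- pmin(u / (2 * dfe$n_ref), 1)
  tibble(class = dfe$labels[cls], scaled_s = u, s = dfe$sign[cls] * s)
}

#' Rebalance a DFE with a beneficial class
#'
#' The beneficial frequency is taken out of the effectively neutral class
#' `f0`, as in recurrent-sweep modelling.
#'
#' @param dfe a [dfe_model()] without beneficial class.
#' @param rate beneficial fraction of new exonic mutations (e.g. 0.001, 0.01,
#'   0.1).
#' @param range `2 * N_ref * s_b` interval, e.g. `c(1, 10)`, `c(10, 100)`,
#'   `c(100, 1000)`.
#' @return A `pb_dfe` with five classes.
#' @export
add_beneficial_class <- function(dfe, rate, range) {
  assert_that(length(dfe$f) == 4, "`dfe` already has a beneficial class.")
  assert_that(dfe$f[1] >= rate,
              "f0 is smaller than the requested beneficial rate; cannot rebalance.")
  dfe_model(f = c(dfe$f[1] - rate, dfe$f[2:4]), n_ref = dfe$n_ref, h = dfe$h,
            beneficial = list(f = rate, lo = range[1], hi = range[2]))
}

#' Chromosome layout for sweep simulations
#'
#' The default layout mirrors a human-like gene architecture: 7 functional regions, each
#' of 9 exons (1,317 bp) alternating with 8 introns (1,520 bp), each region
#' followed by a 4,322 bp intergenic spacer, for a total of 198,345 bp.
#' Selection applies to exonic bases only.
#'
#' @param n_regions number of functional regions.
#' @param n_exons,exon_bp exons per functional region and exon length.
#' @param n_introns,intron_bp introns per functional region and intron
#'   length.
#' @param intergenic_bp length of the intergenic spacer after each functional
#'   region.
#' @return A `pb_layout`: tibble of contiguous elements (`start`, `end`,
#'   `type` in intergenic/intron/exon) with attribute `total_length`.
#' @export
chromosome_layout <- function(n_regions = 7, n_exons = 9, exon_bp = 1317,
                              n_introns = 8, intron_bp = 1520,
                              intergenic_bp = 4322) {
  assert_that(n_regions >= 1 && n_exons >= 1 && exon_bp > 0 &&
                n_introns >= 0 && intron_bp >= 0 && intergenic_bp >= 0,
              "Element counts/lengths must be positive.")
  assert_that(n_introns == 0 || n_introns == n_exons - 1,
              "Introns must alternate with exons (n_introns = n_exons - 1).")
  one_region <- rep(c("exon", "intron"), length.out = 2 * n_exons - 1)
  types <- rep(c(one_region, "intergenic"), n_regions)
  lens <- rep(c(rep(c(exon_bp, intron_bp), length.out = 2 * n_exons - 1),
                intergenic_bp), n_regions)
  keep <- lens > 0
  types <- types[keep]
  lens <- lens[keep]
  ends <- cumsum(lens)
  out <- tibble(start = c(0, head(ends, -1)), end = ends, type = types)
  structure(out, total_length = sum(lens), class = c("pb_layout", class(out)))
}

#' @rdname chromosome_layout
#' @param ... passed to [chromosome_layout()].
#' @export
assemble_sweep_chromosome <- function(...) chromosome_layout(...)

layout_matrix <- function(layout) {
  type_code <- c(intergenic = 0, intron = 1, exon = 2)
  cbind(layout$start, layout$end, unname(type_code[layout$type]))
}

#' Exonic span of a layout
#' @param layout a `pb_layout`.
#' @return Total exonic bp.
#' @export
exonic_bp <- function(layout) {
  sum(layout$end[layout$type == "exon"] - layout$start[layout$type == "exon"])
}

rate_map_matrix <- function(rate, L) {
  if (is.numeric(rate) && length(rate) == 1) {
    return(cbind(0, L, rate))
  }
  assert_that(all(c("start", "end", "rate") %in% names(rate)),
              "Rate map needs columns start, end, rate.")
  cbind(rate$start, rate$end, rate$rate)
}

#' Piecewise rate map with an exact mean
#'
#' Per-replicate variable rates for sweep-scan simulations: piece rates are
#' drawn uniformly and rescaled so the length-weighted mean across the region
#' equals `mean_rate` exactly.
#'
#' @param mean_rate target mean per-bp rate.
#' @param L region length.
#' @param n_pieces number of constant pieces.
#' @param jitter relative half-width of the uniform draw (0.5 means pieces
#'   start in `[0.5, 1.5] * mean_rate` before rescaling).
#' @return A tibble `start`, `end`, `rate`.
#' @export
draw_rate_map <- function(mean_rate, L, n_pieces = 20, jitter = 0.5) {
  bounds <- round(seq(0, L, length.out = n_pieces + 1))
  w <- diff(bounds)
  r <- runif(n_pieces, 1 - jitter, 1 + jitter)
  r <- r * mean_rate / (sum(r * w) / sum(w))
  tibble(start = bounds[-length(bounds)], end = bounds[-1], rate = r)
}

# Per-generation size trajectories (+ founder events and migration epochs)
# for the forward engine, from the same model semantics the coalescent
# backend uses. Row g of `sizes` is post-burn-in generation g (g = span is
# the present).
forward_trajectory <- function(model, span) {
  p <- as.list(model$params)
  d_bn <- model$founding_epoch_gens
  assert_that(span > p$tau_OOA + 1,
              "Demographic event time exceeds the divergence window (span too short).")
  pops <- c("AFR", "EURASI", "EUR", "EAS", "SAS")
  origin <- c(AFR = Inf, EURASI = p$tau_OOA, EUR = p$tau_EUR,
              EAS = p$tau_EAS, SAS = p$tau_SAS)
  size_at <- function(pop, t) {
    # t = generations before present
    switch(pop,
      AFR = if (t >= p$tau_BANTU) p$N_AFR_anc
            else p$N_AFR_anc * exp(p$r_AFR * (p$tau_BANTU - t)),
      EURASI = if (t > p$tau_OOA) 0
               else if (t > p$tau_OOA - d_bn) p$B_EURASI * p$N_AFR_anc
               else p$N_EURASI,
      EUR = founded_size(t, p$tau_EUR, p$B_EUR, p$N_EUR, p$r_EUR),
      EAS = founded_size(t, p$tau_EAS, p$B_EAS, p$N_EAS, p$r_EAS),
      SAS = founded_size(t, p$tau_SAS, p$B_SAS, p$N_SAS, p$r_SAS))
  }
  founded_size <- function(t, tau, B, N, r) {
    if (t > tau) 0
    else if (t > tau - d_bn) B * p$N_EURASI
    else N * exp(r * (tau - d_bn - t))
  }
  g_seq <- 0:span
  t_seq <- span - g_seq
  sizes <- vapply(pops, function(pp) {
    v <- vapply(t_seq, function(t) size_at(pp, t), numeric(1))
    as.integer(ifelse(v > 0, pmax(2, round(v)), 0))
  }, integer(span + 1))
  founder_src <- c(-1L, 0L, 1L, 1L, 1L)  # AFR root; EURASI<-AFR; rest<-EURASI
  # first post-burn-in generation at which each population has individuals
  founder_gen <- vapply(seq_along(pops), function(j) {
    if (is.infinite(origin[[pops[j]]])) return(-1L)
    as.integer(which(sizes[, j] > 0)[1] - 1L)
  }, integer(1))

  # migration epochs keyed by which populations exist
  pair <- compile_demography(model)$migration
  mat_for <- function(t) {
    m <- matrix(0, 5, 5, dimnames = list(pops, pops))
    for (k in seq_len(nrow(pair))) {
      if (t < pair$active_until[k]) {
        m[pair$pop1[k], pair$pop2[k]] <- pair$rate[k]
        m[pair$pop2[k], pair$pop1[k]] <- pair$rate[k]
      }
    }
    m
  }
  # offspring generation g corresponds to time span - g before present
  t_off <- span - seq_len(span)
  keys <- vapply(t_off, function(t) paste(t < origin, collapse = ""), character(1))
  uk <- unique(keys)
  mig_mats <- lapply(uk, function(k) mat_for(t_off[match(k, keys)]))
  mig_index <- match(keys, uk) - 1L
  list(sizes = unname(sizes), founder_src = founder_src,
       founder_gen = unname(founder_gen), mig_mats = mig_mats,
       mig_index = mig_index, pops = pops)
}

#' Run the forward Wright-Fisher simulator
#'
#' Burn-in of `burn_in_multiplier * N_ref` generations at the ancestral size,
#' followed by `divergence_generations` of evolution during which all
#' demographic events are scheduled at their times before present. Exonic
#' mutations draw fitness effects from the DFE; intronic and intergenic
#' mutations are neutral. Post-burn-in fixations are logged for divergence.
#' Pass a rescaled model (see [scale_model()]) together with rates and
#' selection coefficients multiplied by the same factor.
#'
#' @param model an [ooa_model()] (already rescaled for desk-scale runs), or
#'   `NULL` for a single constant-size population of diploid size `N`.
#' @param layout a [chromosome_layout()], or `NULL` for an all-intergenic
#'   (neutral) region of length `L`.
#' @param dfe a [dfe_model()] or `NULL` for fully neutral simulation.
#' @param mu,rec scalar per-bp rates or piecewise maps (`start`, `end`,
#'   `rate`).
#' @param sample_sizes named diploid sample counts per population (for
#'   `model = NULL`, a single unnamed count).
#' @param divergence_generations span of the post-burn-in window (must
#'   exceed all demographic event times).
#' @param seed integer seed (the engine has its own RNG stream).
#' @param N constant population size when `model = NULL`.
#' @param L region length when `layout = NULL`.
#' @param burn_in_multiplier burn-in length in units of `N_ref` generations.
#' @param fix_interval generations between fixation sweeps.
#' @param sweep internal: sweep introduction descriptor.
#' @return A `pb_forward` list: `sample` (a [hap_sample()], including sites
#'   fixed in the sample), `sites` (per-site selection coefficients and
#'   element types), `fixations` (post-burn-in flagged), `restarts`, and the
#'   run configuration.
#' @export
run_forward <- function(model = NULL, layout = NULL, dfe = NULL, mu, rec,
                        sample_sizes, divergence_generations, seed,
                        N = NULL, L = NULL, burn_in_multiplier = 10,
                        fix_interval = 25, sweep = NULL) {
  if (is.null(layout)) {
    assert_that(!is.null(L), "Give `layout` or `L`.")
    elements <- cbind(0, L, 0)
  } else {
    elements <- layout_matrix(layout)
    L <- attr(layout, "total_length")
  }
  if (is.null(model)) {
    assert_that(!is.null(N), "Give `model` or `N`.")
    span <- as.integer(divergence_generations)
    traj <- list(sizes = matrix(as.integer(N), nrow = span + 1, ncol = 1),
                 founder_src = -1L, founder_gen = -1L,
                 mig_mats = list(), mig_index = rep(-1L, span),
                 pops = "pop1")
    n_ref <- N
  } else {
    model <- validate_model(model)
    span <- as.integer(divergence_generations)
    traj <- forward_trajectory(model, span)
    n_ref <- model$params[["N_AFR_anc"]]
  }
  ss <- integer(length(traj$pops))
  names(ss) <- traj$pops
  if (is.null(names(sample_sizes)) && length(sample_sizes) == 1) {
    ss[1] <- sample_sizes
  } else {
    bad <- setdiff(names(sample_sizes), traj$pops)
    assert_that(length(bad) == 0,
                paste("Unknown population(s):", paste(bad, collapse = ", ")))
    ss[names(sample_sizes)] <- sample_sizes
  }
  dfe_cfg <- if (is.null(dfe)) NULL else {
    list(f = dfe$f, lo = dfe$lo, hi = dfe$hi, sign = dfe$sign,
         n_ref = dfe$n_ref, h = dfe$h)
  }
  cfg <- list(
    seed = as.numeric(seed),
    L = L,
    mu_map = rate_map_matrix(mu, L),
    rec_map = rate_map_matrix(rec, L),
    elements = elements,
    dfe = dfe_cfg,
    sizes = traj$sizes,
    founder_src = as.integer(traj$founder_src),
    founder_gen = as.integer(traj$founder_gen),
    mig_mats = traj$mig_mats,
    mig_index = as.integer(traj$mig_index),
    burn_in = as.integer(round(burn_in_multiplier * n_ref)),
    fix_interval = as.integer(fix_interval),
    sample_sizes = as.integer(ss),
    sweep = sweep
  )
  raw <- .wf_simulate(cfg)
  pop_labels <- traj$pops[raw$hap_pop + 1]
  samp <- hap_sample(raw$positions, raw$geno, pop_labels, L)
  structure(
    list(sample = samp,
         sites = tibble(position = raw$positions, sel = raw$site_sel,
                        element = c("intergenic", "intron", "exon")[raw$site_element + 1]),
         fixations = tibble(gen = raw$fix_gen, position = raw$fix_pos,
                            sel = raw$fix_sel,
                            element = c("intergenic", "intron",
                                        "exon")[raw$fix_element + 1],
                            post_burnin = raw$fix_gen > 0),
         restarts = raw$restarts,
         sweep_fixed_globally = raw$sweep_fixed_globally,
         sweep_in_sample = raw$sweep_in_sample,
         n_ref = n_ref, span = span, L = L, seed = seed),
    class = "pb_forward"
  )
}

#' @export
print.pb_forward <- function(x, ...) {
  cat(sprintf(
    "<pb_forward> %d haplotypes, %d sites, %d post-burn-in fixations, %d restarts\n",
    nrow(x$sample$geno), ncol(x$sample$geno),
    sum(x$fixations$post_burnin), x$restarts))
  invisible(x)
}

#' Simulated divergence from the fixation log
#'
#' Fixations after burn-in within the chosen element class divided by that
#' class's total length.
#'
#' @param result a `pb_forward`.
#' @param layout the layout used for the run (`NULL` = whole region).
#' @param element element class to count (default `"exon"`).
#' @return Substitutions per bp.
#' @export
forward_divergence <- function(result, layout = NULL, element = "exon") {
  fx <- filter(result$fixations, .data$post_burnin)
  if (is.null(layout)) {
    return(divergence_rate(nrow(fx), result$L))
  }
  denom <- sum(layout$end[layout$type == element] -
                 layout$start[layout$type == element])
  divergence_rate(sum(fx$element == element), denom)
}

#' Recurrent selective sweeps
#'
#' Adds a beneficial DFE class at the given rate (rebalancing `f0`) and runs
#' the forward simulator; with `beneficial_rate = 0` the run is identical to
#' [run_forward()] under the same seed.
#'
#' @inheritParams run_forward
#' @param beneficial_rate fraction of new exonic mutations that are
#'   beneficial (0.001, 0.01 and 0.1 are the conventional settings).
#' @param beneficial_range `2 * N_ref * s_b` interval.
#' @return A `pb_forward`.
#' @export
run_recurrent_sweeps <- function(model = NULL, layout, dfe, mu, rec,
                                 sample_sizes, divergence_generations, seed,
                                 beneficial_rate, beneficial_range = c(100, 1000),
                                 ...) {
  dfe_b <- if (beneficial_rate > 0) {
    add_beneficial_class(dfe, beneficial_rate, beneficial_range)
  } else dfe
  run_forward(model = model, layout = layout, dfe = dfe_b, mu = mu, rec = rec,
              sample_sizes = sample_sizes,
              divergence_generations = divergence_generations, seed = seed, ...)
}

#' Conditioned single-sweep configuration
#'
#' The three introduction scenarios: model 1 introduces the beneficial
#' mutation into the ancestral African population immediately after burn-in
#' and requires fixation in all four sampled populations; model 2 introduces
#' it into the Eurasian population immediately after the OOA split and
#' requires fixation in EUR/EAS/SAS; model 3 introduces it into the European
#' population immediately after its split and requires fixation in EUR only.
#'
#' @param model_id 1, 2 or 3.
#' @param two_ns population-scaled selection strength `2 * N_ref * s_b`
#'   (1,000 and 10,000 are the conventional settings).
#' @param max_restarts restart cap for the conditioning loop.
#' @return A `pb_sweep_config`.
#' @export
sweep_config <- function(model_id, two_ns = 1000, max_restarts = 10000) {
  assert_that(model_id %in% 1:3, "`model_id` must be 1, 2 or 3.")
  structure(list(model_id = model_id, two_ns = two_ns,
                 max_restarts = max_restarts),
            class = "pb_sweep_config")
}

#' Run a conditioned single hard sweep
#'
#' Terminates and restarts (from the saved state at the introduction
#' generation, with fresh randomness) until the beneficial mutation is fixed
#' in every conditioning population at the present; the restart count is
#' reported.
#'
#' @param cfg a [sweep_config()].
#' @inheritParams run_forward
#' @param sweep_pos position of the beneficial mutation; defaults to the
#'   center of the exon nearest the region midpoint.
#' @return A `pb_forward` with `restarts` and sweep status fields.
#' @export
run_conditioned_sweep <- function(cfg, model, layout, dfe, mu, rec,
                                  sample_sizes, divergence_generations, seed,
                                  sweep_pos = NULL, ...) {
  model <- validate_model(model)
  span <- as.integer(divergence_generations)
  p <- as.list(model$params)
  traj <- forward_trajectory(model, span)
  sweeps <- list(
    list(pop = 0L, gen = 0L, cond = c(0L, 2L, 3L, 4L)),          # model 1
    list(pop = 1L, gen = traj$founder_gen[2], cond = c(2L, 3L, 4L)), # model 2
    list(pop = 2L, gen = traj$founder_gen[3], cond = 2L)         # model 3
  )
  sw <- sweeps[[cfg$model_id]]
  if (is.null(sweep_pos)) {
    exons <- layout[layout$type == "exon", ]
    mid <- attr(layout, "total_length") / 2
    i <- which.min(abs((exons$start + exons$end) / 2 - mid))
    sweep_pos <- (exons$start[i] + exons$end[i]) / 2
  }
  n_ref <- p$N_AFR_anc
  sweep <- list(gen = sw$gen, pop = sw$pop, pos = sweep_pos,
                s = cfg$two_ns / (2 * n_ref), h = dfe$h %||% 0.5,
                condition_pops = as.integer(sw$cond),
                max_restarts = as.integer(cfg$max_restarts))
  run_forward(model = model, layout = layout, dfe = dfe, mu = mu, rec = rec,
              sample_sizes = sample_sizes,
              divergence_generations = divergence_generations, seed = seed,
              sweep = sweep, ...)
}

#' Introduce a single mutation without conditioning
#'
#' Utility used for fixation-probability calibration: introduces one copy of
#' an allele with selection coefficient `s` at the given generation and lets
#' the run finish regardless of its fate.
#'
#' @inheritParams run_forward
#' @param s selection coefficient of the introduced allele (0 = neutral).
#' @param gen post-burn-in generation of introduction.
#' @param pos position of the introduced allele.
#' @return A `pb_forward`; `sweep_fixed_globally` reports fixation.
#' @export
run_introduction <- function(model = NULL, layout = NULL, dfe = NULL, mu, rec,
                             sample_sizes, divergence_generations, seed,
                             s = 0, gen = 0, pos = NULL, ...) {
  L0 <- if (!is.null(layout)) attr(layout, "total_length") else list(...)$L
  sweep <- list(gen = as.integer(gen), pop = 0L,
                pos = pos %||% (L0 / 2), s = s, h = 0.5,
                condition_pops = integer(0), max_restarts = 0L)
  run_forward(model = model, layout = layout, dfe = dfe, mu = mu, rec = rec,
              sample_sizes = sample_sizes,
              divergence_generations = divergence_generations, seed = seed,
              sweep = sweep, ...)
}
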