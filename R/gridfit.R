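# Grid-search fitting of the demographic model to the 18-statistic vector:
# an initially coarse grid search (iterative coordinate sweeps over the
# per-parameter grids) followed by a finer-scaled search around the best
# coarse point.

#' Scaled distance between simulated and empirical statistic vectors
#'
#' Sum over the 18 fitting statistics of `((sim - emp) / scale)^2`, where the
#' scale of each statistic is its empirical across-region standard deviation
#' (floored at a small epsilon). Zero iff the vectors are equal, symmetric,
#' and monotone in each absolute residual.
#'
#' @param sim,emp tibbles with columns `statistic`, `population`, `value`
#'   (aggregated over regions/replicates, e.g. the `display` table of
#'   [aggregate_replicates()] renamed to `value`).
#' @param scales tibble with `statistic`, `population`, `scale`.
#' @param eps floor applied to scales.
#' @return Nonnegative scalar distance (attribute `"residuals"` holds the
#'   per-statistic scaled residual table).
#' @export
stat_distance <- function(sim, emp, scales, eps = 1e-12) {
  key <- c("statistic", "population")
  j <- inner_join(rename(sim[, c(key, "value")], sim = "value"),
                  rename(emp[, c(key, "value")], emp = "value"), by = key)
  missing_sim <- anti_join(emp[, key], sim[, key], by = key)
  missing_emp <- anti_join(sim[, key], emp[, key], by = key)
  if (nrow(missing_sim) || nrow(missing_emp)) {
    miss <- bind_rows(missing_sim, missing_emp)
    abort(c("Statistic vectors are incomplete; missing entries:",
            stats::setNames(paste(miss$statistic, miss$population), NULL)))
  }
  j <- left_join(j, scales[, c(key, "scale")], by = key)
  assert_that(!anyNA(j$scale), "`scales` must cover every statistic.")
  j <- mutate(j, residual = (.data$sim - .data$emp) / pmax(.data$scale, eps))
  structure(sum(j$residual^2), residuals = j)
}

#' Empirical scales for the fit distance
#'
#' Across-region standard deviation of each statistic's region mean (the
#' between-region spread of the empirical data); falls back to simulated
#' spreads when empirical per-region tables are unavailable.
#'
#' @param per_region `per_region` table from [aggregate_replicates()].
#' @return A tibble `statistic`, `population`, `scale`.
#' @export
empirical_scales <- function(per_region) {
  per_region |>
    group_by(.data$statistic, .data$population) |>
    summarise(scale = sd(.data$mean, na.rm = TRUE), .groups = "drop")
}

#' Parameter grid
#'
#' @param ranges tibble with `parameter`, `low`, `high` (see
#'   [ooa_parameter_ranges()]); zero-width ranges give single-point grids.
#' @param n_points grid points per parameter (odd values contain the
#'   midpoint, the documented starting parameterization).
#' @return A named list of grid-value vectors.
#' @export
parameter_grid <- function(ranges, n_points = 3) {
  assert_that(n_points >= 1, "`n_points` must be >= 1.")
  g <- purrr::pmap(ranges, function(parameter, low, high, ...) {
    if (low == high) low else seq(low, high, length.out = n_points)
  })
  setNames(g, ranges$parameter)
}

grid_midpoint <- function(grid) {
  purrr::map_dbl(grid, function(v) v[ceiling(length(v) / 2)])
}

point_key <- function(point) {
  paste(sprintf("%s=%.10g", names(point), point), collapse = ";")
}

# Iterative coordinate sweeps over `grid` starting at `start`: cycle over
# parameters, evaluate each parameter's grid holding others at the current
# best, accept improvements, stop when a full cycle yields none or the
# evaluation budget is exhausted.
coordinate_sweep <- function(grid, start, objective, budget, trace_stage) {
  cache <- new.env(parent = emptyenv())
  trace <- list()
  n_eval <- 0
  evaluate <- function(point) {
    key <- point_key(point)
    if (!is.null(cache[[key]])) return(cache[[key]])
    if (n_eval >= budget) return(NULL)
    n_eval <<- n_eval + 1
    d <- objective(point)
    cache[[key]] <- d
    trace[[length(trace) + 1]] <<- c(as.list(point),
                                     list(distance = d, stage = trace_stage))
    d
  }
  min_cycle <- sum(lengths(grid))
  assert_that(budget >= min_cycle,
              sprintf("Budget (%d) is below one full sweep cycle (%d evaluations).",
                      budget, min_cycle))
  best <- start
  best_d <- evaluate(best)
  repeat {
    improved <- FALSE
    for (p in names(grid)) {
      for (v in grid[[p]]) {
        cand <- best
        cand[p] <- v
        d <- evaluate(cand)
        if (is.null(d)) break
        if (d < best_d - 1e-15) {
          best <- cand
          best_d <- d
          improved <- TRUE
        }
      }
    }
    if (!improved || n_eval >= budget) break
  }
  list(best = best, distance = best_d,
       trace = bind_rows(lapply(trace, as_tibble)), n_eval = n_eval)
}

#' Coarse grid search
#'
#' @param grid named list of per-parameter grid values ([parameter_grid()]).
#' @param emp_stats empirical statistic vector (`statistic`, `population`,
#'   `value`).
#' @param simulate_stats function `(params, seed) -> statistic vector tibble`
#'   producing aggregated simulated statistics at a parameter point.
#' @param scales distance scales ([empirical_scales()]).
#' @param seed master seed; each evaluated point derives its own simulation
#'   seed from its coordinates, so re-runs give identical traces and repeated
#'   visits to a point reuse the cached value.
#' @param budget maximum number of point evaluations.
#' @param start optional named start point; defaults to the grid midpoint.
#' @return A `pb_search` list: `best`, `distance`, `trace`, `n_eval`, `grid`.
#' @export
coarse_search <- function(grid, emp_stats, simulate_stats, scales, seed,
                          budget = 200, start = NULL) {
  start <- start %||% grid_midpoint(grid)
  objective <- function(point) {
    sim <- simulate_stats(point, key_seed(point_key(point), seed))
    as.numeric(stat_distance(sim, emp_stats, scales))
  }
  res <- coordinate_sweep(grid, start, objective, budget, "coarse")
  structure(c(res, list(grid = grid, seed = seed)), class = "pb_search")
}

#' Fine grid search around a coarse optimum
#'
#' Builds, for each parameter, a new grid spanning +/- one coarse grid step
#' around the coarse best point at `refinement_factor` times the coarse
#' resolution (clipped to the declared ranges), then runs the same coordinate
#' sweeps. The final distance can never exceed the coarse best because the
#' sweep starts there.
#'
#' @param coarse a `pb_search` from [coarse_search()].
#' @param refinement_factor grid refinement (must be >= 2).
#' @inheritParams coarse_search
#' @return A `pb_fit` object: best point, distance, 18 residuals, full search
#'   trace (coarse + fine).
#' @export
fine_search <- function(coarse, emp_stats, simulate_stats, scales,
                        refinement_factor = 4, budget = 200) {
  assert_that(refinement_factor >= 2, "`refinement_factor` must be >= 2.")
  grid <- coarse$grid
  best <- coarse$best
  fine_grid <- purrr::imap(grid, function(v, p) {
    if (length(v) == 1) return(v)
    step <- v[2] - v[1]
    lo <- max(min(v), best[[p]] - step)
    hi <- min(max(v), best[[p]] + step)
    vals <- seq(lo, hi, by = step / refinement_factor)
    sort(unique(c(vals, best[[p]])))
  })
  objective <- function(point) {
    sim <- simulate_stats(point, key_seed(point_key(point), coarse$seed))
    as.numeric(stat_distance(sim, emp_stats, scales))
  }
  res <- coordinate_sweep(fine_grid, best, objective, budget, "fine")
  if (res$distance > coarse$distance) {
    # the sweep starts at the coarse best, so this cannot happen unless the
    # objective is non-deterministic; guard anyway
    res$best <- coarse$best
    res$distance <- coarse$distance
  }
  sim_best <- simulate_stats(res$best, key_seed(point_key(res$best), coarse$seed))
  d <- stat_distance(sim_best, emp_stats, scales)
  structure(
    list(best = res$best, distance = res$distance,
         residuals = attr(d, "residuals"),
         trace = bind_rows(coarse$trace, res$trace),
         n_eval = coarse$n_eval + res$n_eval,
         grid = grid, fine_grid = fine_grid),
    class = "pb_fit"
  )
}

#' Fit the demographic model by coarse-then-fine grid search
#'
#' Convenience wrapper: builds the per-point simulator over a set of curated
#' regions, derives scales from the empirical per-region spread, and runs
#' [coarse_search()] then [fine_search()].
#'
#' @param emp empirical statistics: a list as returned by
#'   [aggregate_replicates()] applied to the empirical per-region tables.
#' @param ranges parameter ranges tibble (`parameter`, `low`, `high`); clamp
#'   a parameter by setting `low == high`.
#' @param requests region request table ([region_requests()]).
#' @param sample_sizes diploid sample sizes per population.
#' @param base_model template [ooa_model()] supplying constants.
#' @param seed master seed.
#' @param coarse_points,refinement_factor grid resolutions.
#' @param budget evaluation budget per stage.
#' @param windows [window_spec()] used for the windowed statistics.
#' @return A `pb_fit`.
#' @export
fit_demography <- function(emp, ranges, requests, sample_sizes, base_model,
                           seed, coarse_points = 3, refinement_factor = 4,
                           budget = 200, windows = window_spec()) {
  grid <- parameter_grid(ranges, coarse_points)
  scales <- empirical_scales(emp$per_region)
  emp_vec <- emp$display[, c("statistic", "population", "value")]
  simulate_stats <- function(params, point_seed) {
    m <- set_params(base_model, params)
    sims <- simulate_regions(m, requests, sample_sizes, point_seed)
    aggregate_replicates(sim_stats(sims, windows))$display[,
      c("statistic", "population", "value")]
  }
  co <- coarse_search(grid, emp_vec, simulate_stats, scales, seed, budget)
  fine_search(co, emp_vec, simulate_stats, scales, refinement_factor, budget)
}

#' @export
print.pb_fit <- function(x, ...) {
  cat(sprintf("<pb_fit> distance %.4g after %d evaluations\n",
              x$distance, x$n_eval))
  print(tibble(parameter = names(x$best), value = unname(unlist(x$best))),
        n = length(x$best))
  invisible(x)
}

#' @export
tidy.pb_fit <- function(x, ...) {
  tibble(parameter = names(x$best), estimate = unname(unlist(x$best)))
}

#' @export
glance.pb_fit <- function(x, ...) {
  tibble(distance = x$distance, n_eval = x$n_eval,
         n_statistics = nrow(x$residuals))
}

#' @export
autoplot.pb_fit <- function(object, ...) {
  tr <- mutate(object$trace, eval = row_number(),
               best_so_far = cummin(.data$distance))
  p1 <- ggplot2::ggplot(tr, ggplot2::aes(.data$eval, .data$distance)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$stage), alpha = 0.6) +
    ggplot2::geom_step(ggplot2::aes(y = .data$best_so_far)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "evaluation", y = "distance", colour = NULL) +
    ggplot2::theme_minimal()
  p1
}

#' Write a fit report
#'
#' JSON report (best point, distance, residuals) plus a TSV search trace.
#'
#' @param fit a `pb_fit`.
#' @param path base path; writes `<path>.json` and `<path>_trace.tsv`.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  jsonlite::write_json(
    list(best = as.list(fit$best), distance = fit$distance,
         residuals = fit$residuals, n_eval = fit$n_eval),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(fit$trace, paste0(path, "_trace.tsv"))
  invisible(path)
}
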