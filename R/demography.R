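# The five-population Out-of-Africa demographic model.
#
# Populations: AFR (ancestral African lineage, sampled), EURASI (unsampled
# ancestral Eurasian population), EUR, EAS, SAS (sampled). Free parameters
# (25): the ancestral African size, the Bantu-expansion time and growth rate,
# the OOA split time, founding bottleneck severities and post-founding sizes
# for EURASI/EUR/EAS/SAS, dispersal times and growth rates for EUR/EAS/SAS,
# and seven symmetric pairwise migration rates. Times are in generations
# before present; sizes are diploid; migration rates are per generation.

ooa_param_names <- function() {
  c("N_AFR_anc", "tau_BANTU", "r_AFR", "tau_OOA",
    "B_EURASI", "N_EURASI",
    "tau_EUR", "B_EUR", "N_EUR", "r_EUR",
    "tau_EAS", "B_EAS", "N_EAS", "r_EAS",
    "tau_SAS", "B_SAS", "N_SAS", "r_SAS",
    "m_AFR_EURASI", "m_AFR_EUR", "m_AFR_EAS", "m_AFR_SAS",
    "m_EUR_EAS", "m_EUR_SAS", "m_EAS_SAS")
}

#' Default parameter ranges for the OOA model
#'
#' Literature-informed (Gutenkunst/Gravel-era) ranges for the 25 free
#' parameters, shipped as a YAML registry so alternative enumerations can be
#' swapped in. Midpoints of these ranges are the documented starting point of
#' the grid search.
#'
#' @param path optional path to a YAML registry; defaults to the one installed
#'   with the package.
#' @return A tibble with columns `parameter`, `low`, `high`, `mid`.
#' @export
ooa_parameter_ranges <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ooa_parameter_ranges.yaml",
                        package = "popbaseline")
  }
  reg <- yaml::read_yaml(path)
  out <- purrr::map_dfr(names(reg), function(p) {
    tibble(parameter = p, low = reg[[p]][[1]], high = reg[[p]][[2]])
  })
  out$mid <- (out$low + out$high) / 2
  out
}

#' Construct the 25-parameter OOA demographic model
#'
#' @param ... named parameter overrides (see [ooa_parameter_ranges()] for the
#'   names); unspecified parameters default to the midpoints of the shipped
#'   ranges.
#' @param generation_time_years generation time used to convert years to
#'   generations (fixed constant, not a free parameter).
#' @param founding_epoch_gens duration, in generations, of the founding
#'   bottleneck epoch during which a newly founded population has size
#'   `B * N_source` before recovering to its own size parameter.
#' @return An object of class `ooa_model` (a named list of parameters plus
#'   constants).
#' @export
ooa_model <- function(..., generation_time_years = 26.9,
                      founding_epoch_gens = 100) {
  ranges <- ooa_parameter_ranges()
  pars <- setNames(ranges$mid, ranges$parameter)
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) &&
      (is.list(over[[1]]) || !is.null(names(over[[1]])))) {
    over <- as.list(over[[1]])
  }
  if (length(over)) {
    bad <- setdiff(names(over), names(pars))
    assert_that(length(bad) == 0,
                paste("Unknown parameter(s):", paste(bad, collapse = ", ")))
    pars[names(over)] <- as.numeric(unlist(over))
  }
  m <- structure(
    list(params = pars,
         generation_time_years = generation_time_years,
         founding_epoch_gens = founding_epoch_gens),
    class = "ooa_model"
  )
  validate_model(m)
}

#' @export
print.ooa_model <- function(x, ...) {
  cat("<ooa_model> 5 populations (AFR, EURASI, EUR, EAS, SAS),",
      length(x$params), "free parameters\n")
  print(tibble(parameter = names(x$params), value = unname(x$params)), n = 25)
  invisible(x)
}

#' Validate an OOA model
#'
#' Checks the free-parameter count, positivity of sizes and times, bottleneck
#' severities in (0, 1], nonnegative migration and growth, and the event
#' ordering (the OOA split must predate every dispersal from EURASI, with room
#' for the founding epochs).
#'
#' @param model an `ooa_model`.
#' @return The model, invisibly normalized (parameters in canonical order).
#' @export
validate_model <- function(model) {
  p <- model$params
  assert_that(setequal(names(p), ooa_param_names()) &&
                length(p) == 25,
              "Model must have exactly the 25 canonical free parameters.")
  p <- p[ooa_param_names()]
  sizes <- p[c("N_AFR_anc", "N_EURASI", "N_EUR", "N_EAS", "N_SAS")]
  assert_that(all(sizes > 0), "Population sizes must be positive.")
  taus <- p[c("tau_BANTU", "tau_OOA", "tau_EUR", "tau_EAS", "tau_SAS")]
  assert_that(all(taus > 0), "All event times must be positive (generations ago).")
  B <- p[c("B_EURASI", "B_EUR", "B_EAS", "B_SAS")]
  assert_that(all(B > 0 & B <= 1), "Bottleneck severities must lie in (0, 1].")
  m <- p[grep("^m_", names(p))]
  assert_that(all(m >= 0), "Migration rates must be nonnegative.")
  r <- p[c("r_AFR", "r_EUR", "r_EAS", "r_SAS")]
  assert_that(all(r >= 0), "Growth rates must be nonnegative.")
  disp <- max(p[c("tau_EUR", "tau_EAS", "tau_SAS")])
  assert_that(p[["tau_OOA"]] > disp + model$founding_epoch_gens,
              paste("Time ordering violated: tau_OOA must exceed every dispersal",
                    "time from EURASI by at least the founding epoch."))
  model$params <- p
  invisible(model)
}

#' Update model parameters
#'
#' @param model an `ooa_model`.
#' @param ... named parameter values to set.
#' @return A validated `ooa_model`.
#' @export
set_params <- function(model, ...) {
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) &&
      (is.list(over[[1]]) || !is.null(names(over[[1]])))) {
    over <- as.list(over[[1]])
  }
  model$params[names(over)] <- as.numeric(unlist(over))
  validate_model(model)
}

#' Convert years to generations
#'
#' @param years time in years.
#' @param generation_time_years generation time (default 26.9 years).
#' @param round_to optional rounding unit in generations (e.g. `100`).
#' @return Time in generations.
#' @export
years_to_generations <- function(years, generation_time_years = 26.9,
                                 round_to = NULL) {
  assert_that(all(years >= 0), "`years` must be nonnegative.")
  g <- years / generation_time_years
  if (!is.null(round_to)) g <- round(g / round_to) * round_to
  g
}

#' Compile an OOA model to a time-ordered demographic event list
#'
#' Produces the present-day population table and the backwards-in-time event
#' list (size/growth changes, founding bottleneck epochs, splits, migration
#' deactivations) consumed by both the coalescent backend and the forward
#' simulator. Bottleneck semantics: a population founded at time `tau` has
#' size `B * N_source` during the founding epoch
#' `[tau - founding_epoch_gens, tau]`, then recovers to its size parameter `N`
#' and grows exponentially at rate `r` to the present.
#'
#' @param model a validated `ooa_model`.
#' @return A list with `populations` (tibble: name, initial_size at present,
#'   growth_rate), `events` (tibble sorted by time), and `migration` (tibble of
#'   symmetric pair rates active from the later founding time to the present).
#' @export
compile_demography <- function(model) {
  model <- validate_model(model)
  p <- as.list(model$params)
  d_bn <- model$founding_epoch_gens

  founded <- function(name, tau, B, N, r, source_size) {
    recov <- tau - d_bn
    list(
      pop = tibble(name = name,
                   initial_size = N * exp(r * recov),
                   growth_rate = r),
      events = tibble(
        time = c(recov, tau),
        type = c("size", "split"),
        pop = name,
        size = c(B * source_size, NA),
        growth_rate = c(0, NA),
        ancestral = c(NA, if (name == "EURASI") "AFR" else "EURASI")
      )
    )
  }

  afr <- list(
    pop = tibble(name = "AFR",
                 initial_size = p$N_AFR_anc * exp(p$r_AFR * p$tau_BANTU),
                 growth_rate = p$r_AFR),
    events = tibble(time = p$tau_BANTU, type = "size", pop = "AFR",
                    size = p$N_AFR_anc, growth_rate = 0, ancestral = NA)
  )
  eurasi <- founded("EURASI", p$tau_OOA, p$B_EURASI, p$N_EURASI, 0, p$N_AFR_anc)
  eur <- founded("EUR", p$tau_EUR, p$B_EUR, p$N_EUR, p$r_EUR, p$N_EURASI)
  eas <- founded("EAS", p$tau_EAS, p$B_EAS, p$N_EAS, p$r_EAS, p$N_EURASI)
  sas <- founded("SAS", p$tau_SAS, p$B_SAS, p$N_SAS, p$r_SAS, p$N_EURASI)

  parts <- list(afr, eurasi, eur, eas, sas)
  populations <- purrr::map_dfr(parts, "pop")
  events <- arrange(purrr::map_dfr(parts, "events"), .data$time)

  pair_tbl <- tibble(
    pop1 = c("AFR", "AFR", "AFR", "AFR", "EUR", "EUR", "EAS"),
    pop2 = c("EURASI", "EUR", "EAS", "SAS", "EAS", "SAS", "SAS"),
    rate = unlist(p[c("m_AFR_EURASI", "m_AFR_EUR", "m_AFR_EAS", "m_AFR_SAS",
                      "m_EUR_EAS", "m_EUR_SAS", "m_EAS_SAS")])
  )
  origin <- c(AFR = Inf, EURASI = p$tau_OOA, EUR = p$tau_EUR,
              EAS = p$tau_EAS, SAS = p$tau_SAS)
  pair_tbl$active_until <- pmin(origin[pair_tbl$pop1], origin[pair_tbl$pop2])

  list(populations = populations, events = events, migration = pair_tbl)
}

#' Rescale a model for desk-scale simulation
#'
#' Standard forward-simulation rescaling by a factor `kappa`: sizes and times
#' are divided by `kappa`; growth and migration rates are multiplied by it.
#' Mutation/recombination rates and selection coefficients must be multiplied
#' by `kappa` by the caller, so population-scaled quantities (theta, rho, 2Ns)
#' are preserved.
#'
#' @param model an `ooa_model`.
#' @param kappa scaling factor >= 1.
#' @return A rescaled, validated `ooa_model`.
#' @export
scale_model <- function(model, kappa) {
  assert_that(is_scalar_number(kappa) && kappa >= 1, "`kappa` must be >= 1.")
  p <- model$params
  size_par <- c("N_AFR_anc", "N_EURASI", "N_EUR", "N_EAS", "N_SAS")
  time_par <- c("tau_BANTU", "tau_OOA", "tau_EUR", "tau_EAS", "tau_SAS")
  rate_par <- c("r_AFR", "r_EUR", "r_EAS", "r_SAS",
                grep("^m_", names(p), value = TRUE))
  p[size_par] <- p[size_par] / kappa
  p[time_par] <- p[time_par] / kappa
  p[rate_par] <- p[rate_par] * kappa
  model$params <- p
  model$founding_epoch_gens <- max(1, round(model$founding_epoch_gens / kappa))
  validate_model(model)
}

#' Serialize a model to Demes-style YAML or native JSON
#'
#' @param model an `ooa_model`.
#' @param path output file; format chosen by extension (`.yaml` writes a
#'   Demes-compatible description, `.json` the native parameter list).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  model <- validate_model(model)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(params = as.list(model$params),
           generation_time_years = model$generation_time_years,
           founding_epoch_gens = model$founding_epoch_gens),
      path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  cd <- compile_demography(model)
  p <- as.list(model$params)
  d_bn <- model$founding_epoch_gens
  deme <- function(name, ancestors, start_time, epochs) {
    out <- list(name = name, epochs = epochs)
    if (!is.null(ancestors)) {
      out$ancestors <- list(ancestors)
      out$start_time <- start_time
    }
    out
  }
  founded_epochs <- function(tau, B, N, r, src) list(
    list(end_time = tau - d_bn, start_size = B * src, end_size = B * src),
    list(end_time = 0, start_size = N, end_size = N * exp(r * (tau - d_bn)))
  )
  demes <- list(
    deme("AFR", NULL, NULL, list(
      list(end_time = p$tau_BANTU, start_size = p$N_AFR_anc, end_size = p$N_AFR_anc),
      list(end_time = 0, start_size = p$N_AFR_anc,
           end_size = p$N_AFR_anc * exp(p$r_AFR * p$tau_BANTU))
    )),
    deme("EURASI", "AFR", p$tau_OOA,
         founded_epochs(p$tau_OOA, p$B_EURASI, p$N_EURASI, 0, p$N_AFR_anc)),
    deme("EUR", "EURASI", p$tau_EUR,
         founded_epochs(p$tau_EUR, p$B_EUR, p$N_EUR, p$r_EUR, p$N_EURASI)),
    deme("EAS", "EURASI", p$tau_EAS,
         founded_epochs(p$tau_EAS, p$B_EAS, p$N_EAS, p$r_EAS, p$N_EURASI)),
    deme("SAS", "EURASI", p$tau_SAS,
         founded_epochs(p$tau_SAS, p$B_SAS, p$N_SAS, p$r_SAS, p$N_EURASI))
  )
  migrations <- purrr::pmap(cd$migration, function(pop1, pop2, rate, active_until) {
    list(demes = list(pop1, pop2), rate = rate)
  })
  yaml::write_yaml(list(description = "popbaseline OOA model",
                        time_units = "generations",
                        demes = demes, migrations = migrations), path)
  invisible(path)
}

#' Read a model written by [write_model()] (JSON form)
#'
#' @param path path to a native JSON model file.
#' @return An `ooa_model`.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ooa_model(x$params,
            generation_time_years = x$generation_time_years,
            founding_epoch_gens = x$founding_epoch_gens)
}
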