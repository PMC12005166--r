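#' Region simulation request
#'
#' One row per curated region to simulate under a demographic model, with a
#' single (region-mean) mutation and recombination rate per region.
#'
#' @param id region identifier.
#' @param length region length in bp.
#' @param mean_mu,mean_rec per-bp per-generation rates.
#' @param replicates number of replicates (default 100).
#' @return A one-row tibble; rows can be bound into a request table.
#' @export
region_sim_request <- function(id, length, mean_mu, mean_rec, replicates = 100) {
  assert_that(length > 0 && mean_mu >= 0 && mean_rec >= 0,
              "Region length must be positive and rates nonnegative.")
  tibble(id = as.character(id), length = length, mu = mean_mu,
         rec = mean_rec, replicates = as.integer(replicates))
}

#' Requests from a curated-regions table
#'
#' @param regions tibble from [select_nonfunctional()] / [select_exonic()]
#'   (columns `region`, `start`, `end`, `mean_mu`, `mean_rec`).
#' @param replicates replicates per region.
#' @return A request tibble for [simulate_regions()].
#' @export
region_requests <- function(regions, replicates = 100) {
  purrr::pmap_dfr(regions, function(region, start, end, mean_mu, mean_rec, ...) {
    region_sim_request(region, end - start, mean_mu, mean_rec, replicates)
  })
}

# Build the JSON request consumed by inst/python/coalescent_backend.py.
build_backend_request <- function(model, requests, sample_sizes, seed) {
  cd <- compile_demography(model)
  events <- purrr::pmap(cd$events, function(time, type, pop, size, growth_rate,
                                            ancestral) {
    if (type == "size") {
      list(time = time, type = "size", pop = pop, size = size,
           growth_rate = growth_rate)
    } else {
      list(time = time, type = "split", pop = pop, ancestral = ancestral)
    }
  })
  # deactivate a pair's migration earlier than the younger population's origin
  mig_off <- purrr::pmap(cd$migration, function(pop1, pop2, rate, active_until) {
    if (rate > 0 && is.finite(active_until)) {
      list(time = active_until, type = "migration",
           pops = list(pop1, pop2), rate = 0)
    } else NULL
  })
  events <- c(events, purrr::compact(mig_off))
  init_mig <- purrr::pmap(cd$migration, function(pop1, pop2, rate, active_until) {
    list(pops = list(pop1, pop2), rate = rate)
  })
  regions <- purrr::pmap(requests, function(id, length, mu, rec, replicates, ...) {
    extra <- list(...)
    list(id = id, length = length,
         mu = extra$mu_map %||% mu,
         rec = extra$rec_map %||% rec,
         replicates = replicates,
         seeds = as.list(derive_seeds(seed, replicates,
                                      stream = key_seed(id, seed) %% 100000)))
  })
  list(
    populations = purrr::pmap(cd$populations,
                              function(name, initial_size, growth_rate) {
                                list(name = name, initial_size = initial_size,
                                     growth_rate = growth_rate)
                              }),
    events = events,
    initial_migration = init_mig,
    samples = as.list(sample_sizes),
    regions = regions
  )
}

the_backend <- new.env(parent = emptyenv())

# Persistent backend process: the interpreter (and its imports) is started
# once per R session and fed request/output file paths over a pair of named
# pipes, which matters when a grid search issues hundreds of small batches.
backend_server <- function() {
  if (!is.null(the_backend$in_con) && isOpen(the_backend$in_con)) {
    return(the_backend)
  }
  if (.Platform$OS.type != "unix" || !nzchar(Sys.which("mkfifo"))) return(NULL)
  script <- system.file("python", "coalescent_backend.py", package = "popbaseline")
  dir <- tempfile("pbbackend")
  dir.create(dir)
  fin <- file.path(dir, "in.fifo")
  fout <- file.path(dir, "out.fifo")
  if (system2("mkfifo", c(fin, fout)) != 0L) return(NULL)
  ok <- try({
    system(sprintf("%s %s --server < %s > %s &",
                   shQuote(python_bin()), shQuote(script),
                   shQuote(fin), shQuote(fout)))
    # open order matters: the child blocks opening its stdin until we attach
    # the write end, then blocks on stdout until we attach the read end
    the_backend$in_con <- fifo(fin, open = "w", blocking = TRUE)
    the_backend$out_con <- fifo(fout, open = "r", blocking = TRUE)
    the_backend$dir <- dir
    TRUE
  }, silent = TRUE)
  if (inherits(ok, "try-error")) {
    backend_stop()
    return(NULL)
  }
  the_backend
}

backend_stop <- function() {
  for (nm in c("in_con", "out_con")) {
    con <- the_backend[[nm]]
    if (!is.null(con)) try(close(con), silent = TRUE)
    the_backend[[nm]] <- NULL
  }
  if (!is.null(the_backend$dir)) {
    unlink(the_backend$dir, recursive = TRUE)
    the_backend$dir <- NULL
  }
  invisible()
}

run_backend <- function(request) {
  script <- system.file("python", "coalescent_backend.py", package = "popbaseline")
  req_file <- tempfile(fileext = ".json")
  out_file <- tempfile(fileext = ".txt")
  on.exit(unlink(c(req_file, out_file)), add = TRUE)
  jsonlite::write_json(request, req_file, auto_unbox = TRUE, digits = NA)
  srv <- try(backend_server(), silent = TRUE)
  ok <- FALSE
  if (!inherits(srv, "try-error") && !is.null(srv)) {
    writeLines(paste(req_file, out_file, sep = "\t"), srv$in_con)
    flush(srv$in_con)
    status <- try(readLines(srv$out_con, n = 1), silent = TRUE)
    if (identical(status, "DONE")) {
      ok <- TRUE
    } else {
      backend_stop()
      if (is.character(status) && length(status) && startsWith(status, "ERR")) {
        abort(c("Coalescent backend failed.", i = status))
      }
    }
  }
  if (!ok) { # one-shot fallback
    status <- system2(python_bin(), c(script, req_file, out_file),
                      stdout = "", stderr = "")
    if (!identical(status, 0L)) {
      on.exit(unlink(out_file), add = FALSE)
      abort(c("Coalescent backend failed.",
              i = sprintf("Request preserved at %s", req_file)))
    }
  }
  readLines(out_file)
}

parse_backend_output <- function(lines, requests) {
  stopifnot(lines[1] == "#PANEL")
  pops <- strsplit(lines[2], " ", fixed = TRUE)[[1]]
  lens <- setNames(requests$length, requests$id)
  out <- lapply(setNames(nm = requests$id), function(id) list())
  i <- 3
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    stopifnot(hdr[1] == "#REP")
    id <- hdr[2]; rep_i <- as.integer(hdr[3])
    n_sites <- as.integer(hdr[4]); n_hap <- as.integer(hdr[5])
    pos <- if (n_sites > 0) {
      as.numeric(strsplit(lines[i + 1], " ", fixed = TRUE)[[1]])
    } else numeric(0)
    geno <- matrix(0L, nrow = n_hap, ncol = n_sites)
    if (n_sites > 0) {
      for (h in seq_len(n_hap)) {
        geno[h, ] <- utf8ToInt(lines[i + 1 + h]) - 48L
      }
    }
    out[[id]][[rep_i]] <- hap_sample(pos, geno, pops, lens[[id]])
    i <- i + 2 + n_hap
  }
  out
}

#' Simulate curated regions under a demographic model
#'
#' Runs replicate coalescent simulations (via the msprime backend) of each
#' requested region under the model, with a single mutation and recombination
#' rate per region, and returns present-day multi-population haplotype
#' samples. When `masks` are supplied, the empirical region's mask is applied
#' to every simulated replicate so that simulated and empirical statistics are
#' computed on the same accessible sites (the parity rule).
#'
#' @param model a validated [ooa_model()].
#' @param requests a request tibble (see [region_sim_request()]).
#' @param sample_sizes named vector of diploid sample counts per sampled
#'   population, e.g. `c(AFR = 99, EUR = 502, EAS = 104, SAS = 489)`.
#' @param seed master seed; expands deterministically to per-(region,
#'   replicate) seeds.
#' @param masks optional named list (by region id) of masked-interval tibbles
#'   (`start`, `end`, region-relative) applied to each replicate.
#' @return A named list (by region id) of lists of [hap_sample()] replicates.
#' @export
simulate_regions <- function(model, requests, sample_sizes, seed, masks = NULL) {
  model <- validate_model(model)
  assert_that(all(c("id", "length", "mu", "rec", "replicates") %in% names(requests)),
              "`requests` must come from region_sim_request()/region_requests().")
  req <- build_backend_request(model, requests, sample_sizes, seed)
  sims <- parse_backend_output(run_backend(req), requests)
  if (!is.null(masks)) {
    for (id in intersect(names(sims), names(masks))) {
      sims[[id]] <- lapply(sims[[id]], apply_mask, masked = masks[[id]])
    }
  }
  sims
}

#' Simulate a single region
#'
#' @inheritParams simulate_regions
#' @param request a one-row request tibble.
#' @return A list of [hap_sample()] replicates.
#' @export
simulate_region <- function(model, request, sample_sizes, seed, masks = NULL) {
  simulate_regions(model, request, sample_sizes, seed, masks)[[request$id[1]]]
}

#' Summary statistics across simulated replicates
#'
#' Maps [stat_vector()] over every replicate of every region and returns the
#' long table expected by [aggregate_replicates()].
#'
#' @param sims output of [simulate_regions()].
#' @param windows a [window_spec()].
#' @return A long tibble (`region`, `replicate`, `statistic`, `population`,
#'   `value`).
#' @export
sim_stats <- function(sims, windows = window_spec()) {
  blocks <- purrr::imap(sims, function(reps, id) {
    vv <- lapply(reps, stat_vector_values, windows = windows)
    v1 <- vv[[1]]
    tibble(region = id,
           replicate = rep(seq_along(vv), each = length(v1)),
           statistic = rep(attr(v1, "statistic"), length(vv)),
           population = rep(attr(v1, "population"), length(vv)),
           value = as.numeric(unlist(vv)))
  })
  bind_rows(blocks)
}
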