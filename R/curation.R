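# Region curation: choosing BGS-free nonfunctional regions for demographic
# inference (step 1) and exonic regions for DFE inference (step 2).

#' Read annotation / mask / rate-map files
#'
#' Thin readers returning tidy interval tables in 0-based half-open
#' coordinates. GFF3 (1-based closed) and BED (0-based half-open) go through
#' \pkg{rtracklayer}; rate maps are plain TSV (`chrom`, `start`, `end`,
#' `rate`, 0-based half-open).
#'
#' @param path input file.
#' @return A tibble with columns `chrom`, `start`, `end` (plus `type` for
#'   GFF3, `rate` for rate maps).
#' @name curation-io
NULL

#' @rdname curation-io
#' @export
read_gff_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = BiocGenerics::start(gr) - 1,
         end = BiocGenerics::end(gr),
         type = as.character(gr$type))
}

#' @rdname curation-io
#' @export
read_bed_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = BiocGenerics::start(gr) - 1,
         end = BiocGenerics::end(gr))
}

#' @rdname curation-io
#' @export
read_rate_map <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "rate"),
                  col_types = "ciid", comment = "#", skip = 1)
}

#' Length-weighted mean rate over a region
#'
#' @param region one-row tibble (or list) with `chrom`, `start`, `end`.
#' @param rate_map rate-map tibble (`chrom`, `start`, `end`, `rate`).
#' @return A one-row tibble with `mean_rate` (length-weighted over covered
#'   bases), `covered_bp` and `covered_fraction`. With zero coverage the
#'   region has no rate information and `mean_rate` is `NA`.
#' @export
region_mean_rate <- function(region, rate_map) {
  map <- rate_map[rate_map$chrom == region$chrom, , drop = FALSE]
  ov_start <- pmax(map$start, region$start)
  ov_end <- pmin(map$end, region$end)
  w <- pmax(0, ov_end - ov_start)
  covered <- sum(w)
  span <- region$end - region$start
  tibble(mean_rate = if (covered > 0) sum(w * map$rate) / covered else NA_real_,
         covered_bp = covered,
         covered_fraction = covered / span)
}

# Normalize annotation intervals; warn if unsorted/overlapping input needed it.
normalize_annotation <- function(ann) {
  out <- ann |> group_by(.data$chrom) |>
    dplyr::group_modify(~iv_normalize(.x)) |> ungroup()
  if (nrow(out) != nrow(ann) ||
      any(order(ann$chrom, ann$start) != seq_len(nrow(ann)))) {
    warn("Annotation intervals were unsorted or overlapping; normalized.")
  }
  out
}

curate_one <- function(chrom, candidates, masks, mu_map, rec_map, kind,
                       min_length, chrom_len) {
  if (nrow(candidates) == 0) return(NULL)
  inaccessible <- iv_setdiff(tibble(start = 0, end = chrom_len),
                             masks$accessible[masks$accessible$chrom == chrom,
                                              c("start", "end"), drop = FALSE])
  conserved <- masks$conserved[masks$conserved$chrom == chrom,
                               c("start", "end"), drop = FALSE]
  purrr::pmap_dfr(candidates, function(start, end, ...) {
    region <- tibble(chrom = chrom, start = start, end = end)
    span <- tibble(start = start, end = end)
    masked_bp <- iv_union_bp(bind_rows(iv_intersect(span, inaccessible),
                                       iv_intersect(span, conserved)))
    accessible_bp <- (end - start) - masked_bp
    mu <- region_mean_rate(region, mu_map)
    rec <- region_mean_rate(region, rec_map)
    tibble(chrom = chrom, start = start, end = end, kind = kind,
           mean_mu = mu$mean_rate, mean_rec = rec$mean_rate,
           accessible_bp = accessible_bp)
  }) |>
    filter(.data$end - .data$start >= min_length,
           !is.na(.data$mean_mu), !is.na(.data$mean_rec),
           .data$accessible_bp > 0)
}

#' Select distant nonfunctional regions for demographic inference
#'
#' Finds maximal intervals at least `min_distance` bp from every functional
#' annotation interval, at least `min_length` bp long (measured on the
#' unmasked span), with rate-map coverage; accessibility- and conserved-
#' element-masked bases within each retained region are recorded via
#' `accessible_bp` and excluded from statistic denominators downstream rather
#' than splitting the region. Regions lacking rate information, or with no
#' accessible bases at all, are removed.
#'
#' @param annotation tibble of functional intervals (`chrom`, `start`, `end`;
#'   0-based half-open), e.g. from [read_gff_annotation()].
#' @param masks list with elements `accessible` (accessible intervals) and
#'   `conserved` (conserved-element intervals), both tibbles with `chrom`,
#'   `start`, `end`. `conserved` marks sites with a conservation score > 0.
#' @param mu_map,rec_map rate-map tibbles.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param min_distance minimum gap (bp) between a region boundary and the
#'   nearest functional interval boundary (default 10 kb).
#' @param min_length minimum region length in bp (default 15 kb).
#' @return A tibble of curated regions (`region`, `chrom`, `start`, `end`,
#'   `kind`, `mean_mu`, `mean_rec`, `accessible_bp`).
#' @export
select_nonfunctional <- function(annotation, masks, mu_map, rec_map,
                                 chrom_lengths, min_distance = 10000,
                                 min_length = 15000) {
  assert_that(nrow(mu_map) > 0 && nrow(rec_map) > 0,
              "Empty rate map: no rate information available.")
  ann <- normalize_annotation(annotation[, c("chrom", "start", "end")])
  out <- purrr::map_dfr(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    fun_iv <- ann[ann$chrom == ch, c("start", "end"), drop = FALSE]
    # pad functional intervals by min_distance, then take the complement
    padded <- if (nrow(fun_iv)) {
      tibble(start = pmax(0, fun_iv$start - min_distance),
             end = pmin(L, fun_iv$end + min_distance))
    } else fun_iv
    cand <- iv_complement(padded, 0, L)
    curate_one(ch, cand, masks, mu_map, rec_map, "nonfunctional",
               min_length, L)
  })
  if (nrow(out) == 0) return(mutate(out, region = character(0)))
  mutate(out, region = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end),
         .before = 1)
}

#' Select exonic regions for DFE inference
#'
#' One curated region per cluster of overlapping exon features, with
#' length-weighted mean mutation and recombination rates; exon clusters
#' without rate-map coverage are dropped.
#'
#' @param annotation tibble with `chrom`, `start`, `end` and a `type` column
#'   containing `"exon"` features (others are ignored), or a plain interval
#'   table treated as exons.
#' @inheritParams select_nonfunctional
#' @return A tibble of curated regions with `kind = "exonic"`.
#' @export
select_exonic <- function(annotation, mu_map, rec_map) {
  assert_that(nrow(mu_map) > 0 && nrow(rec_map) > 0,
              "Empty rate map: no rate information available.")
  if ("type" %in% names(annotation)) {
    annotation <- annotation[annotation$type == "exon", , drop = FALSE]
  }
  if (nrow(annotation) == 0) {
    return(tibble(region = character(0), chrom = character(0),
                  start = numeric(0), end = numeric(0), kind = character(0),
                  mean_mu = numeric(0), mean_rec = numeric(0),
                  accessible_bp = numeric(0)))
  }
  ann <- normalize_annotation(annotation[, c("chrom", "start", "end")])
  no_mask <- list(accessible = tibble(chrom = ann$chrom, start = ann$start,
                                      end = ann$end),
                  conserved = tibble(chrom = character(0), start = numeric(0),
                                     end = numeric(0)))
  out <- purrr::map_dfr(unique(ann$chrom), function(ch) {
    cand <- ann[ann$chrom == ch, c("start", "end"), drop = FALSE]
    curate_one(ch, cand, no_mask, mu_map, rec_map, "exonic",
               min_length = 1, chrom_len = max(cand$end))
  })
  if (nrow(out) == 0) return(mutate(out, region = character(0)))
  mutate(out, region = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end),
         .before = 1)
}

#' Write / read curated regions
#'
#' @param regions curated-regions tibble.
#' @param path TSV path.
#' @return `path` (writer) or the tibble (reader).
#' @export
write_curated_regions <- function(regions, path) {
  readr::write_tsv(regions, path)
  invisible(path)
}

#' @rdname write_curated_regions
#' @export
read_curated_regions <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
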