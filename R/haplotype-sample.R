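#' Haplotype samples
#'
#' A `hap_sample` is the common currency of the simulators and the statistics:
#' a set of phased haplotypes over one genomic region, stored as derived-allele
#' indicators polarized against the ancestral state.
#'
#' @param positions numeric vector of site positions in bp within the region
#'   (0-based, strictly increasing).
#' @param geno integer matrix, haplotypes x sites, entries in `{0, 1}` (1 =
#'   derived allele).
#' @param pop character vector of population labels, one per haplotype row.
#' @param region_length region span in bp.
#' @param accessible_bp number of accessible (unmasked) bases used as the
#'   denominator of per-site statistics. Defaults to `region_length`.
#'
#' @return An object of class `hap_sample`.
#' @export
hap_sample <- function(positions, geno, pop, region_length,
                       accessible_bp = region_length) {
  geno <- as.matrix(geno)
  if (length(positions) == 0) geno <- matrix(0L, nrow = length(pop), ncol = 0)
  assert_that(ncol(geno) == length(positions),
              "`geno` must have one column per position.")
  assert_that(nrow(geno) == length(pop),
              "`pop` must have one label per haplotype row.")
  if (length(positions) > 1) {
    assert_that(all(diff(positions) > 0), "`positions` must be strictly increasing.")
  }
  assert_that(is_scalar_number(region_length) && region_length > 0,
              "`region_length` must be a positive number.")
  assert_that(is_scalar_number(accessible_bp) && accessible_bp >= 0 &&
                accessible_bp <= region_length,
              "`accessible_bp` must lie in [0, region_length].")
  structure(
    list(positions = as.numeric(positions),
         geno = matrix(as.integer(geno), nrow = nrow(geno)),
         pop = as.character(pop),
         region_length = region_length,
         accessible_bp = accessible_bp),
    class = "hap_sample"
  )
}

#' @export
print.hap_sample <- function(x, ...) {
  cat(sprintf(
    "<hap_sample> %d haplotypes (%s), %d segregating sites, %s bp (%s accessible)\n",
    nrow(x$geno),
    paste(sprintf("%s=%d", names(table(x$pop)), table(x$pop)), collapse = ", "),
    ncol(x$geno),
    format(x$region_length, big.mark = ","),
    format(x$accessible_bp, big.mark = ",")
  ))
  invisible(x)
}

#' @export
as_tibble.hap_sample <- function(x, ...) {
  tibble(position = rep(x$positions, each = nrow(x$geno)),
         haplotype = rep(seq_len(nrow(x$geno)), times = ncol(x$geno)),
         population = rep(x$pop, times = ncol(x$geno)),
         derived = as.integer(x$geno))
}

#' Subset a haplotype sample to one or more populations
#'
#' @param sample a [hap_sample()].
#' @param pops character vector of population labels to keep.
#' @param drop_monomorphic drop sites left without variation in the subset?
#' @return A `hap_sample`.
#' @export
subset_pops <- function(sample, pops, drop_monomorphic = TRUE) {
  keep <- sample$pop %in% pops
  assert_that(any(keep), "No haplotypes in the requested population(s).")
  g <- sample$geno[keep, , drop = FALSE]
  pos <- sample$positions
  if (drop_monomorphic && ncol(g) > 0) {
    cs <- colSums(g)
    poly <- cs > 0 & cs < nrow(g)
    g <- g[, poly, drop = FALSE]
    pos <- pos[poly]
  }
  hap_sample(pos, g, sample$pop[keep], sample$region_length, sample$accessible_bp)
}

#' Apply an accessibility mask to a haplotype sample
#'
#' Sites falling in masked (inaccessible) intervals are removed from the
#' genotype matrix, and the masked bases are removed from `accessible_bp`, so
#' that masked positions contribute to neither numerators nor denominators of
#' per-site statistics. This is the parity rule used to make simulated data
#' comparable to masked empirical data.
#'
#' @param sample a [hap_sample()].
#' @param masked tibble of masked intervals with columns `start`, `end`
#'   (0-based half-open, bp within the region).
#' @return A masked `hap_sample`.
#' @export
apply_mask <- function(sample, masked) {
  masked <- iv_normalize(masked)
  masked$start <- pmax(masked$start, 0)
  masked$end <- pmin(masked$end, sample$region_length)
  masked <- masked[masked$end > masked$start, , drop = FALSE]
  hit <- pos_in_intervals(sample$positions, masked)
  hap_sample(sample$positions[!hit],
             sample$geno[, !hit, drop = FALSE],
             sample$pop,
             sample$region_length,
             sample$accessible_bp - sum(masked$end - masked$start))
}

#' Write a haplotype sample to VCF (plus sample panel)
#'
#' Produces a VCFv4.2 file with phased diploid genotypes (haplotypes are paired
#' in row order), the ancestral allele recorded in `INFO/AA`, and a sidecar
#' two-column sample panel (`sample_id`, `population`). Positions are written
#' 1-based as VCF requires.
#'
#' @param sample a [hap_sample()] with an even number of haplotypes per
#'   population.
#' @param path output path; vcfR always gzip-compresses, so use `.vcf.gz`.
#' @param chrom chromosome name to write.
#' @param ref,alt optional vectors of reference (= ancestral) and alternate
#'   alleles per site; defaults to `"A"`/`"T"`.
#' @return Invisibly, a list with `vcf` and `panel` paths.
#' @export
write_sample_vcf <- function(sample, path, chrom = "chr1", ref = NULL, alt = NULL) {
  n_hap <- nrow(sample$geno)
  assert_that(n_hap %% 2 == 0, "Need an even number of haplotypes to pair into diploids.")
  n_ind <- n_hap / 2
  ind_pop <- sample$pop[seq(1, n_hap, by = 2)]
  ids <- sprintf("%s%04d", ind_pop, stats::ave(seq_len(n_ind), ind_pop, FUN = seq_along))
  S <- ncol(sample$geno)
  if (is.null(ref)) ref <- rep("A", S)
  if (is.null(alt)) alt <- rep("T", S)
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=popbaseline",
    sprintf("##contig=<ID=%s,length=%d>", chrom, ceiling(sample$region_length)),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  fix_names <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (S > 0) {
    fix <- cbind(CHROM = rep(chrom, S),
                 POS = as.character(floor(sample$positions) + 1),
                 ID = rep(".", S),
                 REF = ref, ALT = alt,
                 QUAL = rep(".", S), FILTER = rep("PASS", S),
                 INFO = paste0("AA=", ref))
    gt_body <- matrix(sprintf("%d|%d",
                              t(sample$geno[seq(1, n_hap, 2), , drop = FALSE]),
                              t(sample$geno[seq(2, n_hap, 2), , drop = FALSE])),
                      nrow = S)
    gt <- cbind(rep("GT", S), gt_body)
  } else {
    fix <- matrix(character(0), nrow = 0, ncol = 8)
    gt <- matrix(character(0), nrow = 0, ncol = 1 + n_ind)
  }
  colnames(fix) <- fix_names
  colnames(gt) <- c("FORMAT", ids)
  v <- methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  panel_path <- sub("\\.vcf(\\.gz)?$", ".panel.tsv", path)
  readr::write_tsv(tibble(sample_id = ids, population = ind_pop), panel_path)
  invisible(list(vcf = path, panel = panel_path))
}

#' Read a VCF (plus sample panel) into a haplotype sample
#'
#' Phased genotypes are split into haplotypes; alleles are polarized against
#' the ancestral allele in `INFO/AA` when present (sites where ALT is ancestral
#' are flipped), so the matrix holds derived-allele indicators.
#'
#' @param vcf_path path to a VCF file.
#' @param panel_path path to the sample panel (`sample_id`, `population`);
#'   defaults to the sidecar written by [write_sample_vcf()].
#' @param region_length,accessible_bp region span and accessible denominator;
#'   `region_length` defaults to the contig length in the header.
#' @return A [hap_sample()].
#' @export
read_sample_vcf <- function(vcf_path, panel_path = NULL, region_length = NULL,
                            accessible_bp = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (is.null(panel_path)) {
    panel_path <- sub("\\.vcf(\\.gz)?$", ".panel.tsv", vcf_path)
  }
  panel <- readr::read_tsv(panel_path, show_col_types = FALSE)
  if (is.null(region_length)) {
    ctg <- grep("^##contig", v@meta, value = TRUE)[1]
    region_length <- as.numeric(sub(".*length=(\\d+).*", "\\1", ctg))
  }
  samples <- colnames(v@gt)[-1]
  pop <- panel$population[match(samples, panel$sample_id)]
  assert_that(!anyNA(pop), "Panel is missing some VCF samples.")
  pos <- as.numeric(v@fix[, "POS"]) - 1
  S <- length(pos)
  n_hap <- 2L * length(samples)
  if (S == 0) {
    return(hap_sample(numeric(0), matrix(0L, n_hap, 0), rep(pop, each = 2),
                      region_length, accessible_bp %||% region_length))
  }
  gt <- v@gt[, -1, drop = FALSE]
  h1 <- substr(gt, 1, 1) == "1"
  h2 <- substr(gt, 3, 3) == "1"
  geno <- matrix(0L, nrow = n_hap, ncol = S)
  geno[seq(1, n_hap, 2), ] <- t(matrix(as.integer(h1), nrow = S))
  geno[seq(2, n_hap, 2), ] <- t(matrix(as.integer(h2), nrow = S))
  # polarize: if AA equals ALT, flip the indicator
  info <- v@fix[, "INFO"]
  aa <- ifelse(grepl("AA=", info), sub(".*AA=([^;]+).*", "\\1", info), NA)
  flip <- !is.na(aa) & aa == v@fix[, "ALT"]
  if (any(flip)) geno[, flip] <- 1L - geno[, flip]
  ord <- order(pos)
  hap_sample(pos[ord], geno[, ord, drop = FALSE], rep(pop, each = 2),
             region_length, accessible_bp %||% region_length)
}
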