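# Shared fixture builders (everything is generated in code; no stored data).

# haplotype matrix from strings like c("000","100","110","111")
hap_from_strings <- function(strings, pop = NULL, region_length = 1000,
                             positions = NULL) {
  geno <- do.call(rbind, lapply(strsplit(strings, ""), as.integer))
  if (is.null(pop)) pop <- rep("AFR", nrow(geno))
  if (is.null(positions)) positions <- seq_len(ncol(geno)) * 10
  hap_sample(positions, geno, pop, region_length)
}

# a small model with no migration and no growth, scaled for desk runs;
# used wherever a valid multi-population model is needed quickly
toy_model <- function(kappa = 25, ...) {
  ov <- list(r_AFR = 0, r_EUR = 0, r_EAS = 0, r_SAS = 0,
             m_AFR_EURASI = 0, m_AFR_EUR = 0, m_AFR_EAS = 0, m_AFR_SAS = 0,
             m_EUR_EAS = 0, m_EUR_SAS = 0, m_EAS_SAS = 0)
  ov[names(list(...))] <- list(...)
  scale_model(do.call(ooa_model, ov), kappa)
}

# nucleotide diversity per site of a hap_sample
sample_pi <- function(s, per_site = TRUE) {
  n <- nrow(s$geno)
  if (ncol(s$geno) == 0) return(0)
  p <- colSums(s$geno) / n
  tot <- sum(2 * p * (1 - p) * (p < 1)) * n / (n - 1)
  if (per_site) tot / s$accessible_bp else tot
}
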