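#' Per-site genomic summary statistics
#'
#' For every site: sample size, mean (+/- sd) number of alleles per locus,
#' gene-diversity-based nucleotide diversity theta (mean per-locus unbiased
#' gene diversity), pi (the *sum* over loci of the per-locus mean pairwise
#' difference probability, so its magnitude scales with the panel size),
#' and mean (+/- sd) expected and observed heterozygosity. The unbiased
#' per-locus expected heterozygosity is (2n/(2n-1)) (1 - sum p^2). Loci with
#' no typed individual at a site are skipped for that site (recorded in the
#' `skipped` attribute).
#'
#' @param g A [geno_tbl()].
#' @return Tibble with one row per site: `site`, `n`, `n_alleles`,
#'   `n_alleles_sd`, `theta`, `theta_sd`, `pi`, `he`, `he_sd`, `ho`, `ho_sd`.
#' @export
summary_stats <- function(g) {
  d <- geno_dosage(g)
  sites <- unique(g$site)
  skipped <- list()
  out <- map(sites, function(s) {
    sub <- d[g$site == s, , drop = FALSE]
    if (nrow(sub) < 2) abort(sprintf("site %s has fewer than 2 individuals", s))
    nt <- colSums(!is.na(sub))
    use <- nt > 0
    if (any(!use)) skipped[[s]] <<- colnames(d)[!use]
    nt <- nt[use]
    subu <- sub[, use, drop = FALSE]
    p <- colSums(subu, na.rm = TRUE) / (2 * nt)
    he <- (2 * nt / (2 * nt - 1)) * (1 - p^2 - (1 - p)^2)
    he[nt == 1] <- 0
    ho <- colMeans(subu == 1L, na.rm = TRUE)
    nall <- 1 + as.integer(p > 0 & p < 1)
    tibble(site = s, n = nrow(sub),
           n_alleles = mean(nall), n_alleles_sd = sd(nall),
           theta = mean(he), theta_sd = sd(he),
           pi = sum(he),
           he = mean(he), he_sd = sd(he),
           ho = mean(ho), ho_sd = sd(ho))
  })
  res <- bind_rows(out)
  attr(res, "skipped") <- skipped
  res
}
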