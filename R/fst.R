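# Weir-Cockerham theta variance components, vectorised over loci.
# Returns per-locus a, b, c sums; loci with fewer than 2 populations typed
# get NA components.
wc_components <- function(d, site) {
  sites <- unique(site)
  r_all <- length(sites)
  L <- ncol(d)
  n <- matrix(0, r_all, L)     # typed individuals per pop x locus
  p <- matrix(0, r_all, L)     # allele-2 frequency
  h <- matrix(0, r_all, L)     # observed het fraction
  for (i in seq_len(r_all)) {
    sub <- d[site == sites[i], , drop = FALSE]
    nt <- colSums(!is.na(sub))
    n[i, ] <- nt
    p[i, ] <- ifelse(nt > 0, colSums(sub, na.rm = TRUE) / (2 * nt), 0)
    h[i, ] <- ifelse(nt > 0, colSums(sub == 1L, na.rm = TRUE) / nt, 0)
  }
  typed <- n > 0
  r <- colSums(typed)
  ok <- r >= 2
  nbar <- colSums(n) / r
  nc <- (colSums(n) - colSums(n^2) / colSums(n)) / (r - 1)
  pbar <- colSums(n * p) / colSums(n)
  s2 <- colSums(n * (p - matrix(pbar, nrow(n), L, byrow = TRUE))^2) /
    ((r - 1) * nbar)
  hbar <- colSums(n * h) / colSums(n)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  list(a = a, b = b, c = cc, pbar = pbar, n = n, p = p)
}

# Multi-locus Weir-Cockerham theta: ratio of sums of variance components.
wc_theta <- function(d, site) {
  w <- wc_components(d, site)
  num <- sum(w$a, na.rm = TRUE)
  den <- sum(w$a + w$b + w$c, na.rm = TRUE)
  if (den == 0) return(NA_real_)
  num / den
}

#' Multi-locus Weir-Cockerham FST
#'
#' @param g A [geno_tbl()].
#' @return The ratio-of-sums multi-locus theta across all sites.
#' @export
overall_fst <- function(g) wc_theta(geno_dosage(g), g$site)

#' Pairwise FST between sites
#'
#' Weir-Cockerham theta for every site pair, multi-locus by ratio of sums of
#' variance components. Significance by permuting individuals between the
#' two sites; p = (1 + #\{perm >= obs\}) / (1 + n_perm). Negative estimates
#' are reported as computed.
#'
#' @param g A [geno_tbl()].
#' @param n_perm Permutations per pair (0 skips the test).
#' @param seed Integer seed.
#' @return A [pairwise_mat()] with unit `"fst"` and per-cell p-values.
#' @export
pairwise_fst <- function(g, n_perm = 999, seed = 1) {
  d <- geno_dosage(g)
  sites <- unique(g$site)
  ns <- table(factor(g$site, levels = sites))
  if (any(ns < 2)) {
    abort(sprintf("site(s) with fewer than 2 individuals: %s",
                  paste(names(ns)[ns < 2], collapse = ", ")))
  }
  k <- length(sites)
  m <- matrix(0, k, k, dimnames = list(sites, sites))
  pm <- matrix(NA_real_, k, k, dimnames = list(sites, sites))
  with_seed(seed, {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        rows <- g$site %in% sites[c(i, j)]
        dd <- d[rows, , drop = FALSE]
        lab <- g$site[rows]
        obs <- wc_theta(dd, lab)
        m[i, j] <- m[j, i] <- obs
        if (n_perm > 0) {
          cnt <- 0L
          for (b in seq_len(n_perm)) {
            if (wc_theta(dd, sample(lab)) >= obs - 1e-12) cnt <- cnt + 1L
          }
          pm[i, j] <- pm[j, i] <- (1 + cnt) / (1 + n_perm)
        }
      }
    }
  })
  pairwise_mat(m, unit = "fst", p = if (n_perm > 0) pm else NULL)
}

#' Per-locus FST and heterozygosity
#'
#' Per-locus Weir-Cockerham theta together with the mean within-deme
#' unbiased expected heterozygosity, the conditioning variable of the
#' FDIST-style outlier scan. Loci monomorphic across the panel are excluded
#' (listed in the `excluded` attribute).
#'
#' @param g A [geno_tbl()].
#' @return Tibble with `locus`, `fst`, `he`, `n_demes`.
#' @export
locus_fst_he <- function(g) {
  d <- geno_dosage(g)
  w <- wc_components(d, g$site)
  den <- w$a + w$b + w$c
  fst <- ifelse(!is.na(den) & den > 0, w$a / den, NA_real_)
  typed <- w$n > 0
  nmat <- w$n; pmat <- w$p
  he_pop <- ifelse(typed & nmat > 0.5,
                   (2 * nmat / pmax(2 * nmat - 1, 1)) *
                     (1 - pmat^2 - (1 - pmat)^2), NA)
  he <- colMeans(he_pop, na.rm = TRUE)
  poly <- !is.na(fst)
  out <- tibble(locus = colnames(d)[poly], fst = fst[poly], he = he[poly],
                n_demes = colSums(typed)[poly])
  attr(out, "excluded") <- colnames(d)[!poly]
  out
}
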