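#' Exact test of Hardy-Weinberg equilibrium
#'
#' Full enumeration of the conditional distribution of the heterozygote count
#' given the allele counts; the two-sided p-value sums the probabilities of
#' all configurations no more probable than the observed one
#' (probability-mass ordering).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts at a biallelic locus. `n_AA` may
#'   also be a length-3 vector of the three counts.
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa = NULL, n_aa = NULL) {
  if (length(n_AA) == 3 && is.null(n_Aa)) {
    n_Aa <- n_AA[2]; n_aa <- n_AA[3]; n_AA <- n_AA[1]
  }
  n <- n_AA + n_Aa + n_aa
  if (n == 0) abort("no individuals", class = "seascapr_param_error")
  nA <- 2 * n_AA + n_Aa
  probs <- hwe_conditional_probs(n, nA)
  obs <- probs$p[match(n_Aa, probs$het)]
  sum(probs$p[probs$p <= obs + 1e-12])
}

# Conditional probabilities P(n_Aa | n, nA) over all feasible het counts.
# P = n! / (nAA! nAa! naa!) * 2^nAa * nA! na! / (2n)!
hwe_conditional_probs <- function(n, nA) {
  na <- 2 * n - nA
  het <- seq(nA %% 2, min(nA, na), by = 2)
  lp <- lfactorial(n) - lfactorial((nA - het) / 2) - lfactorial(het) -
    lfactorial((na - het) / 2) + het * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  # the analytic constant nA! na! / (2n)! makes the masses sum to one
  list(het = het, p = exp(lp))
}

#' HWE exact tests across loci and sites
#'
#' @param g A [geno_tbl()].
#' @return Tibble with `site`, `locus`, genotype counts and `p`; monomorphic
#'   or untyped locus/site cells are omitted.
#' @export
hwe_tests <- function(g) {
  d <- geno_dosage(g)
  out <- list()
  for (s in unique(g$site)) {
    sub <- d[g$site == s, , drop = FALSE]
    for (l in seq_len(ncol(sub))) {
      x <- sub[, l]
      x <- x[!is.na(x)]
      if (!length(x)) next
      cnt <- c(sum(x == 0L), sum(x == 1L), sum(x == 2L))
      nA <- 2 * cnt[1] + cnt[2]
      if (nA == 0 || nA == 2 * length(x)) next
      out[[length(out) + 1L]] <- tibble(
        site = s, locus = colnames(d)[l],
        n_AA = cnt[1], n_Aa = cnt[2], n_aa = cnt[3],
        p = hwe_exact_test(cnt))
    }
  }
  bind_rows(out)
}

#' Permutation test of genotypic linkage disequilibrium
#'
#' Statistic: squared Pearson correlation of the dosage vectors at the two
#' loci within one site. Significance by permuting one locus's genotypes
#' among individuals; p = (1 + #\{perm >= obs\}) / (1 + n_perm), so p is
#' bounded below by 1/(1 + n_perm).
#'
#' @param g A [geno_tbl()].
#' @param locus_a,locus_b Locus names.
#' @param site Site label.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Tibble with `r2`, `p`, `n`, `flag` (`"ok"` or `"monomorphic"`;
#'   statistics are `NA` when flagged).
#' @export
ld_test <- function(g, locus_a, locus_b, site, n_perm = 999, seed = 1) {
  d <- geno_dosage(g)
  rows <- g$site == site
  a <- d[rows, locus_a]; b <- d[rows, locus_b]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) abort("need at least 3 typed individuals at both loci")
  if (var(a) == 0 || var(b) == 0) {
    return(tibble(r2 = NA_real_, p = NA_real_, n = length(a),
                  flag = "monomorphic"))
  }
  obs <- cor(a, b)^2
  with_seed(seed, {
    perm <- map_dbl(seq_len(n_perm), function(i) {
      bp <- sample(b)
      if (var(bp) == 0) return(0)
      cor(a, bp)^2
    })
    p <- (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm)
    tibble(r2 = obs, p = p, n = length(a), flag = "ok")
  })
}

#' Bonferroni correction
#'
#' @param p_values Numeric vector of p-values (one family of tests).
#' @param alpha Family-wise error rate, in (0, 1).
#' @return A list with `threshold` (= alpha / m), `m`, and logical `flags`
#'   marking p-values at or below the threshold.
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) abort("empty p-value vector", class = "seascapr_param_error")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0,1)",
                                      class = "seascapr_param_error")
  m <- length(p_values)
  threshold <- alpha / m
  list(threshold = threshold, m = m, flags = p_values <= threshold)
}
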