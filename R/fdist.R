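#' Simulate an FDIST-style neutral null distribution of (He, FST)
#'
#' Island-model null using the Balding-Nichols beta approximation: per
#' simulated locus an ancestral frequency is drawn uniformly (rejecting loci
#' whose ancestral expected heterozygosity exceeds `max_he`), deme
#' frequencies come from the beta distribution parameterised by a drift
#' parameter, and allele counts are binomially sampled at the observed
#' sample sizes. The drift parameter is calibrated iteratively (at most
#' `max_rounds` rounds) until the median simulated multi-deme FST falls
#' within +/- `tol` of `target_fst`. `n_demes` is recorded as null-model
#' configuration; the sampled demes are those with observed sizes.
#'
#' @param target_fst Calibration target in `[0, 1)`.
#' @param sample_sizes Integer vector of individuals per sampled deme.
#' @param n_sim Number of simulated loci (>= 1000).
#' @param n_demes Island-model deme count (configuration metadata).
#' @param max_he Maximum ancestral expected heterozygosity.
#' @param seed Integer seed.
#' @param tol Calibration tolerance on the median FST.
#' @param max_rounds Calibration round cap.
#' @return An `fdist_null`: tibble `draws` (`he`, `fst`), the calibrated
#'   drift parameter, the calibration trace and the settings.
#' @export
fdist_null <- function(target_fst, sample_sizes, n_sim = 100000,
                       n_demes = 500, max_he = 0.5, seed = 1,
                       tol = 0.01, max_rounds = 20) {
  if (target_fst < 0 || target_fst >= 1) abort("target_fst must lie in [0, 1)")
  if (n_sim < 1000) abort("n_sim must be at least 1000")
  with_seed(seed, {
    cpar <- max(target_fst, 1e-4)
    trace <- tibble(round = integer(), c = numeric(), median_fst = numeric())
    if (target_fst > 0) {
      for (round in seq_len(max_rounds)) {
        batch <- fdist_batch(cpar, sample_sizes, 4000, max_he)
        med <- median(batch$fst)
        trace <- bind_rows(trace, tibble(round = round, c = cpar,
                                         median_fst = med))
        if (abs(med - target_fst) <= tol / 2) break
        cpar <- min(max(cpar * target_fst / max(med, 1e-4), 1e-5), 0.99)
      }
      if (abs(trace$median_fst[nrow(trace)] - target_fst) > tol) {
        abort(paste0("FDIST calibration failed; trace:\n",
                     paste(capture.output(print(as.data.frame(trace))),
                           collapse = "\n")))
      }
    }
    draws <- fdist_batch(cpar, sample_sizes, n_sim, max_he)
    structure(list(draws = draws, c = cpar, target_fst = target_fst,
                   n_demes = n_demes, max_he = max_he,
                   sample_sizes = sample_sizes, trace = trace),
              class = "fdist_null")
  })
}

# One batch of simulated loci; returns polymorphic draws only, topping up
# until n valid draws are available.
fdist_batch <- function(cpar, sizes, n, max_he) {
  J <- length(sizes)
  n_al <- 2 * sizes
  out_he <- numeric(0); out_fst <- numeric(0); out_anc <- numeric(0)
  while (length(out_fst) < n) {
    m <- ceiling((n - length(out_fst)) * 1.3) + 100
    p_anc <- runif(m, 0.001, 0.999)
    keep <- 2 * p_anc * (1 - p_anc) <= max_he
    p_anc <- p_anc[keep]
    m <- length(p_anc)
    if (!m) next
    if (cpar > 1e-4) {
      sh1 <- p_anc * (1 - cpar) / cpar
      sh2 <- (1 - p_anc) * (1 - cpar) / cpar
      freqs <- matrix(rbeta(m * J, rep(sh1, J), rep(sh2, J)), m, J)
    } else {
      freqs <- matrix(rep(p_anc, J), m, J)
    }
    counts <- matrix(rbinom(m * J, rep(n_al, each = m), freqs), m, J)
    st <- fdist_stats(counts, sizes)
    ok <- !is.na(st$fst)
    out_he <- c(out_he, st$he[ok])
    out_fst <- c(out_fst, st$fst[ok])
    out_anc <- c(out_anc, 2 * p_anc[ok] * (1 - p_anc[ok]))
  }
  tibble(he = out_he[seq_len(n)], fst = out_fst[seq_len(n)],
         he_anc = out_anc[seq_len(n)])
}

# Weir-Cockerham theta and mean within-deme He from allele counts
# (loci x demes), assuming Hardy-Weinberg heterozygosity within demes.
fdist_stats <- function(counts, sizes) {
  m <- nrow(counts); J <- ncol(counts)
  nmat <- matrix(sizes, m, J, byrow = TRUE)
  p <- counts / (2 * nmat)
  h <- 2 * p * (1 - p)  # HW expected heterozygote frequency
  r <- J
  nbar <- rowMeans(nmat)
  nc <- (rowSums(nmat) - rowSums(nmat^2) / rowSums(nmat)) / (r - 1)
  pbar <- rowSums(nmat * p) / rowSums(nmat)
  s2 <- rowSums(nmat * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(nmat * h) / rowSums(nmat)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  den <- a + b + cc
  fst <- ifelse(den > 0, a / den, NA_real_)
  he <- rowMeans((2 * nmat / (2 * nmat - 1)) * (1 - p^2 - (1 - p)^2))
  list(fst = fst, he = he)
}

#' Empirical FDIST p-values by heterozygosity conditioning
#'
#' For each observed locus, the null draws whose He lies within the locus's
#' bin (half-width `he_bin_width / 2`, widened by 50% steps until at least
#' `min_draws` fall inside) provide upper-tail (divergent) and lower-tail
#' (balancing) tail fractions.
#'
#' @param locus_stats Output of [locus_fst_he()].
#' @param null An [fdist_null()].
#' @param he_bin_width Width of the He conditioning bin.
#' @param alpha Per-tail significance level used for the direction call.
#' @param min_draws Minimum null draws per bin.
#' @return Tibble: `locus`, `fst`, `he`, `p_upper`, `p_lower`, `direction`
#'   (`"divergent"`, `"balancing"` or `"neutral"`), `outlier`, `bin_widened`.
#' @export
fdist_pvalues <- function(locus_stats, null, he_bin_width = 0.05,
                          alpha = 0.05, min_draws = 200) {
  draws <- null$draws
  res <- map(seq_len(nrow(locus_stats)), function(i) {
    he <- locus_stats$he[i]; fst <- locus_stats$fst[i]
    w <- he_bin_width / 2
    widened <- FALSE
    repeat {
      sel <- abs(draws$he - he) <= w
      if (sum(sel) >= min_draws || w > 1) break
      w <- w * 1.5
      widened <- TRUE
    }
    fs <- draws$fst[sel]
    p_up <- mean(fs >= fst - 1e-12)
    p_lo <- mean(fs <= fst + 1e-12)
    dir <- if (p_up <= alpha) "divergent" else if (p_lo <= alpha) "balancing" else "neutral"
    tibble(locus = locus_stats$locus[i], fst = fst, he = he,
           p_upper = p_up, p_lower = p_lo, direction = dir,
           outlier = dir != "neutral", bin_widened = widened)
  })
  out <- bind_rows(res)
  attr(out, "alpha") <- alpha
  out
}
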