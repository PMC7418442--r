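#' Analysis of molecular variance (two-level)
#'
#' Partitions genetic variance among and within groups from sums of squared
#' allele-count differences between individuals (the squared Euclidean
#' distance on dosage vectors, halved so one allele difference at one locus
#' contributes 1/2). Missing calls are excluded pairwise, distances rescaled
#' to the full locus count. Significance of the Phi statistic comes from
#' permuting individuals among groups.
#'
#' @param g A [geno_tbl()].
#' @param grouping Character vector, one group label per individual
#'   (defaults to the site assignment).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return An `amova_result` with a `components` tibble (source, df, SS, MS,
#'   variance, percent), `phi`, `p` and `n_perm`.
#' @export
amova <- function(g, grouping = geno_sites(g), n_perm = 999, seed = 1) {
  d <- geno_dosage(g)
  N <- nrow(d)
  if (length(grouping) != N) abort("one group label per individual required")
  tab <- table(grouping)
  if (length(tab) < 2) abort("need at least 2 groups")
  if (any(tab < 2)) {
    abort(sprintf("singleton group(s): %s",
                  paste(names(tab)[tab < 2], collapse = ", ")))
  }
  D2 <- amova_dist2(d)
  obs <- amova_decompose(D2, grouping)
  p <- NA_real_
  if (n_perm > 0) {
    p <- with_seed(seed, {
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        ph <- amova_decompose(D2, sample(grouping))$phi
        if (ph >= obs$phi - 1e-12) cnt <- cnt + 1L
      }
      (1 + cnt) / (1 + n_perm)
    })
  }
  structure(list(components = obs$components, phi = obs$phi, p = p,
                 n_perm = n_perm), class = "amova_result")
}

# Squared inter-individual distances: sum over shared loci of
# (dosage difference)^2 / 2, rescaled to the panel size when calls are
# missing.
amova_dist2 <- function(d) {
  L <- ncol(d)
  obs <- !is.na(d)
  d0 <- d; d0[!obs] <- 0
  cross <- tcrossprod(d0)
  sq <- tcrossprod(d0^2, obs)
  D2 <- sq + t(sq) - 2 * cross
  shared <- tcrossprod(obs * 1)
  shared[shared == 0] <- NA
  D2 <- D2 / 2 * (L / shared)
  D2[is.na(D2)] <- 0
  D2
}

amova_decompose <- function(D2, grouping) {
  N <- nrow(D2)
  groups <- unique(grouping)
  G <- length(groups)
  ss_total <- sum(D2[lower.tri(D2)]) / N
  ss_within <- 0
  ng <- numeric(G)
  for (k in seq_len(G)) {
    idx <- which(grouping == groups[k])
    ng[k] <- length(idx)
    Dg <- D2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(Dg[lower.tri(Dg)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  df_a <- G - 1
  df_w <- N - G
  ms_a <- ss_among / df_a
  ms_w <- ss_within / df_w
  nprime <- (N - sum(ng^2) / N) / (G - 1)
  var_w <- ms_w
  var_a <- (ms_a - ms_w) / nprime
  tot <- var_a + var_w
  phi <- if (tot > 0) var_a / tot else 0
  components <- tibble(
    source = c("among_groups", "within_groups", "total"),
    df = c(df_a, df_w, df_a + df_w),
    SS = c(ss_among, ss_within, ss_total),
    MS = c(ms_a, ms_w, NA_real_),
    variance = c(var_a, var_w, tot),
    percent = 100 * c(var_a, var_w, tot) / tot
  )
  list(components = components, phi = phi)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Analysis of molecular variance\n")
  print(as.data.frame(x$components), digits = 4)
  cat(sprintf("Phi_ST = %.4f, permutation p = %s (%d permutations)\n",
              x$phi, format.pval(x$p), x$n_perm))
  invisible(x)
}

#' @export
tidy.amova_result <- function(x, ...) x$components

#' @export
glance.amova_result <- function(x, ...) {
  tibble(phi = x$phi, p = x$p, n_perm = x$n_perm,
         pct_among = x$components$percent[1],
         pct_within = x$components$percent[2])
}
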