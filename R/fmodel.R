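#' Bayesian F-model selection scan
#'
#' Locus-specific differentiation model in the BayeScan tradition: allele
#' counts a_lj ~ Binomial(n_lj, p_lj) with deme frequencies integrated out
#' under p_lj ~ Beta(theta_lj p_l, theta_lj (1 - p_l)) (a beta-binomial
#' likelihood), where logit(FST_lj) = alpha_l I_l + beta_j and
#' theta_lj = (1 - FST_lj) / FST_lj. The locus effect alpha_l carries a
#' spike-and-slab prior: the inclusion indicator I_l has prior odds
#' 1 : `prior_odds` against inclusion; given inclusion, alpha_l ~ N(0,
#' `slab_sd`^2). Sampling is Metropolis-within-Gibbs with the slab as the
#' proposal for trans-model moves. Negative alpha indicates balancing,
#' positive divergent selection.
#'
#' @param g A [geno_tbl()] (loci monomorphic everywhere are dropped first).
#' @param mcmc List with `n_iter`, `burn_in`, `thin`.
#' @param prior_odds Prior odds against inclusion (10 reproduces the usual
#'   "decisive at P >= 0.95" rule).
#' @param slab_sd Prior s.d. of alpha given inclusion.
#' @param seed Integer seed.
#' @return An `fmodel_result`: tibble `loci` (`locus`, `post_prob`,
#'   `post_odds`, `alpha_mean`, `direction`), the log-likelihood trace, a
#'   `converged` flag from a split-trace diagnostic, and the settings.
#' @export
fmodel_scan <- function(g, mcmc = list(n_iter = 50000, burn_in = 10000,
                                       thin = 10),
                        prior_odds = 10, slab_sd = 3, seed = 1) {
  if (mcmc$n_iter <= mcmc$burn_in) abort("n_iter must exceed burn_in")
  d <- geno_dosage(g)
  sites <- unique(g$site)
  if (length(sites) < 2) abort("need at least 2 demes")
  J <- length(sites)
  A <- sapply(sites, function(s) colSums(d[g$site == s, , drop = FALSE],
                                         na.rm = TRUE))
  Nn <- sapply(sites, function(s) 2 * colSums(!is.na(d[g$site == s, ,
                                                       drop = FALSE])))
  A <- matrix(A, ncol = J); Nn <- matrix(Nn, ncol = J)
  tot <- rowSums(A); totn <- rowSums(Nn)
  poly <- tot > 0 & tot < totn
  loci <- geno_loci(g)$locus[poly]
  A <- A[poly, , drop = FALSE]; Nn <- Nn[poly, , drop = FALSE]
  tot <- tot[poly]; totn <- totn[poly]
  L <- nrow(A)

  # beta-binomial loglik per locus row, given logit-freq x_l and eta_lj
  rowll <- function(x, eta) {
    p <- plogis(x)
    th <- exp(-eta)
    s1 <- th * p; s2 <- th * (1 - p)
    rowSums(lbeta(A + s1, Nn - A + s2) - lbeta(s1, s2))
  }

  with_seed(seed, {
    x <- qlogis(pmin(pmax(tot / totn, 0.02), 0.98))  # logit ancestral freq
    beta <- rep(-1, J)
    alpha <- rep(0, L)
    inc <- rep(FALSE, L)
    eta <- function(al, ic) outer(al * ic, rep(1, J)) +
      matrix(beta, L, J, byrow = TRUE)
    cur_eta <- eta(alpha, inc)
    cur_ll <- rowll(x, cur_eta)
    keep <- seq(mcmc$burn_in + 1, mcmc$n_iter, by = mcmc$thin)
    inc_sum <- numeric(L); alpha_sum <- numeric(L); alpha_n <- numeric(L)
    ll_trace <- numeric(length(keep)); ki <- 0L
    lprior_a <- function(a) dnorm(a, 0, slab_sd, log = TRUE)

    for (it in seq_len(mcmc$n_iter)) {
      ## ancestral frequencies (logit RW, vectorised over loci)
      xp <- x + rnorm(L, 0, 0.25)
      llp <- rowll(xp, cur_eta)
      # Jacobian-free: flat prior on logit scale would be improper; use the
      # uniform-on-p prior => prior density p(1-p) on logit scale
      lacc <- llp - cur_ll + log(plogis(xp) * (1 - plogis(xp))) -
        log(plogis(x) * (1 - plogis(x)))
      acc <- log(runif(L)) < lacc
      x[acc] <- xp[acc]; cur_ll[acc] <- llp[acc]

      ## deme effects beta_j
      for (j in seq_len(J)) {
        bp <- beta[j] + rnorm(1, 0, 0.15)
        eta_j <- cur_eta; eta_j[, j] <- cur_eta[, j] - beta[j] + bp
        llp <- rowll(x, eta_j)
        lacc <- sum(llp - cur_ll) + dnorm(bp, -1, 1, log = TRUE) -
          dnorm(beta[j], -1, 1, log = TRUE)
        if (log(runif(1)) < lacc) {
          beta[j] <- bp; cur_eta <- eta_j; cur_ll <- llp
        }
      }

      ## alpha refresh for included loci (RW)
      if (any(inc)) {
        ap <- alpha
        ap[inc] <- alpha[inc] + rnorm(sum(inc), 0, 0.4)
        eta_p <- eta(ap, inc)
        llp <- rowll(x, eta_p)
        lacc <- llp - cur_ll + lprior_a(ap) - lprior_a(alpha)
        acc <- inc & (log(runif(L)) < lacc)
        alpha[acc] <- ap[acc]
        if (any(acc)) {
          cur_eta <- eta(alpha, inc)
          cur_ll[acc] <- llp[acc]
        }
      }

      ## indicator flips (slab as trans-model proposal)
      a_star <- ifelse(inc, alpha, rnorm(L, 0, slab_sd))
      inc_p <- !inc
      eta_p <- eta(a_star, inc_p)
      llp <- rowll(x, eta_p)
      lacc <- llp - cur_ll + ifelse(inc_p, -log(prior_odds), log(prior_odds))
      acc <- log(runif(L)) < lacc
      if (any(acc)) {
        inc[acc] <- inc_p[acc]
        alpha[acc] <- ifelse(inc[acc], a_star[acc], 0)
        cur_eta <- eta(alpha, inc)
        cur_ll[acc] <- llp[acc]
      }

      if (it > mcmc$burn_in && ((it - mcmc$burn_in - 1) %% mcmc$thin == 0)) {
        ki <- ki + 1L
        inc_sum <- inc_sum + inc
        alpha_sum <- alpha_sum + ifelse(inc, alpha, 0)
        alpha_n <- alpha_n + inc
        if (ki <= length(ll_trace)) ll_trace[ki] <- sum(cur_ll)
      }
    }
    ll_trace <- ll_trace[seq_len(ki)]
    post <- inc_sum / ki
    alpha_mean <- ifelse(alpha_n > 0, alpha_sum / alpha_n, 0)
    half <- floor(ki / 2)
    conv <- TRUE
    if (half > 4) {
      a1 <- ll_trace[seq_len(half)]; a2 <- ll_trace[(half + 1):ki]
      se <- sqrt(var(a1) / half + var(a2) / (ki - half))
      conv <- is.finite(se) && se > 0 && abs(mean(a1) - mean(a2)) < 5 * se
      if (!conv) warn("F-model chain failed the split-trace diagnostic")
    }
    res <- tibble(locus = loci, post_prob = post,
                  post_odds = ifelse(post < 1, post / (1 - post), Inf),
                  alpha_mean = alpha_mean,
                  direction = ifelse(alpha_mean < 0, "balancing", "divergent"))
    structure(list(loci = res, ll_trace = ll_trace, converged = conv,
                   prior_odds = prior_odds, slab_sd = slab_sd, mcmc = mcmc,
                   beta = setNames(beta, sites)),
              class = "fmodel_result")
  })
}

#' @export
print.fmodel_result <- function(x, ...) {
  cat(sprintf("F-model scan: %d loci, %d kept samples, converged: %s\n",
              nrow(x$loci), length(x$ll_trace), x$converged))
  cat(sprintf("loci with P >= 0.95: %d\n", sum(x$loci$post_prob >= 0.95)))
  invisible(x)
}

#' @export
tidy.fmodel_result <- function(x, ...) x$loci

#' Consensus outlier calling across the two scans
#'
#' Loci flagged by both the FDIST-style scan (either tail at its alpha) and
#' the F-model scan (posterior probability at or above
#' `posterior_threshold`). The conservative intersection is the set carried
#' forward as candidate selected loci; percentages are of `total_loci`,
#' reported to 2 decimal places.
#'
#' @param fdist_result Output of [fdist_pvalues()].
#' @param fmodel_result An [fmodel_scan()] result.
#' @param total_loci Size of the locus universe the percentages refer to.
#' @param posterior_threshold F-model posterior probability cut-off (0.95 by
#'   default; 0.99 gives the stricter convention).
#' @return An `outlier_result` list: per-method sets, consensus set with
#'   directions, and percentage bookkeeping.
#' @export
consensus_outliers <- function(fdist_result, fmodel_result, total_loci,
                               posterior_threshold = 0.95) {
  fm <- fmodel_result$loci
  shared <- intersect(fdist_result$locus, fm$locus)
  if (!length(shared)) abort("the two scans share no loci")
  fdist_set <- fdist_result$locus[fdist_result$outlier]
  fmodel_set <- fm$locus[fm$post_prob >= posterior_threshold]
  consensus <- intersect(fdist_set, fmodel_set)
  dir <- fm$direction[match(consensus, fm$locus)]
  pct <- function(k) round(100 * k / total_loci, 2)
  structure(list(
    fdist = fdist_set, fmodel = fmodel_set,
    consensus = tibble(locus = consensus, direction = dir),
    total_loci = total_loci,
    pct_fdist = pct(length(fdist_set)),
    pct_fmodel = pct(length(fmodel_set)),
    pct_consensus = pct(length(consensus))
  ), class = "outlier_result")
}

#' @export
print.outlier_result <- function(x, ...) {
  cat(sprintf("Outliers: FDIST %d (%.2f%%), F-model %d (%.2f%%), consensus %d (%.2f%%) of %d loci\n",
              length(x$fdist), x$pct_fdist, length(x$fmodel), x$pct_fmodel,
              nrow(x$consensus), x$pct_consensus, x$total_loci))
  invisible(x)
}

#' @export
tidy.outlier_result <- function(x, ...) x$consensus
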