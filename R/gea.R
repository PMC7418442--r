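#' Among-population covariance model from neutral loci
#'
#' Estimates the neutral population-structure covariance that the
#' genotype-environment association scan controls for. Per neutral locus the
#' site frequencies are standardised linearly by the pooled-frequency
#' mean/variance proxy, y_j = (p_j - pbar) / sqrt(pbar (1 - pbar)); the
#' covariance is the average outer product across loci plus a ridge
#' `epsilon * trace` on the diagonal to guarantee positive definiteness.
#'
#' @param g A [geno_tbl()] of (putatively) neutral loci; at least 30.
#' @param epsilon Ridge regulariser as a fraction of the trace.
#' @return A `covariance_model`: `omega` (sites x sites), the site order and
#'   the locus count used.
#' @export
estimate_covariance <- function(g, epsilon = 1e-6) {
  fr <- site_freq_matrix(g)
  if (nrow(fr) < 30) abort("need at least 30 neutral loci")
  miss_by_site <- colMeans(is.na(fr))
  if (any(miss_by_site > 0.5)) {
    abort(sprintf("site(s) untyped at more than half the loci: %s",
                  paste(colnames(fr)[miss_by_site > 0.5], collapse = ", ")))
  }
  pbar <- rowMeans(fr, na.rm = TRUE)
  keep <- pbar > 0 & pbar < 1
  fr <- fr[keep, , drop = FALSE]; pbar <- pbar[keep]
  y <- (fr - pbar) / sqrt(pbar * (1 - pbar))
  y[is.na(y)] <- 0
  omega <- crossprod(y) / nrow(y)
  omega <- omega + diag(epsilon * sum(diag(omega)), ncol(omega))
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) abort("covariance not positive definite after ridge")
  structure(list(omega = omega, sites = colnames(fr), n_loci = nrow(y),
                 epsilon = epsilon),
            class = "covariance_model")
}

#' Bayes-factor genotype-environment association scan
#'
#' For each locus and environmental variable, the standardised site
#' frequencies y are modelled as multivariate normal with mean beta * x and
#' the neutral covariance Omega. The Bayes factor compares the marginal
#' likelihood with beta integrated over a symmetric grid prior
#' (N(0, `prior_sd`^2) discretised over +/- `half_width` prior s.d.)
#' against beta = 0. Loci with BF > 3 are flagged. Because the likelihood
#' is Gaussian in beta, the grid integral uses the exact quadratic form.
#'
#' @param g A [geno_tbl()] (all loci are scanned).
#' @param env Tibble with `site` plus one column per environmental
#'   variable, standardised across sites (done internally if not).
#' @param cov A [estimate_covariance()] model; its site set defines which
#'   sites enter the scan (sites without environmental data are dropped).
#' @param grid_spec List with `n` (grid points), `half_width` (in prior
#'   s.d.) and `prior_sd`.
#' @param bf_threshold Flagging threshold (3 = "substantial support").
#' @return A `gea_result` tibble: `locus`, `variable`, `beta_mean`, `bf`,
#'   `flagged`.
#' @export
bayes_factor_scan <- function(g, env, cov,
                              grid_spec = list(n = 201, half_width = 5,
                                               prior_sd = 1),
                              bf_threshold = 3) {
  sites <- intersect(cov$sites, env$site)
  if (length(sites) < 3) abort("need at least 3 sites with environment data")
  keep <- g$site %in% sites
  gsub <- geno_tbl(geno_dosage(g)[keep, , drop = FALSE], g$site[keep],
                   g$individual[keep], geno_loci(g))
  fr <- site_freq_matrix(gsub)[, sites, drop = FALSE]
  om <- cov$omega[sites, sites]
  om_inv <- solve(om)
  pbar <- rowMeans(fr, na.rm = TRUE)
  ok <- pbar > 0 & pbar < 1 & rowSums(is.na(fr)) == 0
  y <- (fr[ok, , drop = FALSE] - pbar[ok]) / sqrt(pbar[ok] * (1 - pbar[ok]))
  loci <- rownames(fr)[ok]

  grid <- seq(-grid_spec$half_width, grid_spec$half_width,
              length.out = grid_spec$n) * grid_spec$prior_sd
  w <- dnorm(grid, 0, grid_spec$prior_sd)
  w <- w / sum(w)

  vars <- setdiff(names(env), "site")
  out <- list()
  for (v in vars) {
    x <- env[[v]][match(sites, env$site)]
    if (sd(x) == 0) {
      warn(sprintf("environment variable %s is constant; skipped", v))
      next
    }
    x <- as.numeric(scale(x))
    # loglik(beta) - loglik(0) = beta * (x' Om^-1 y) - beta^2/2 * (x' Om^-1 x)
    xOx <- drop(t(x) %*% om_inv %*% x)
    xOy <- drop(y %*% om_inv %*% x)   # per locus
    ll_delta <- outer(xOy, grid) - matrix(grid^2 / 2 * xOx,
                                          length(xOy), length(grid),
                                          byrow = TRUE)
    mx <- apply(ll_delta, 1, max)
    bf <- exp(mx) * as.vector((exp(ll_delta - mx) %*% w))
    post_w <- exp(ll_delta - mx) * matrix(w, length(xOy), length(grid),
                                          byrow = TRUE)
    beta_mean <- as.vector(post_w %*% grid) / rowSums(post_w)
    out[[v]] <- tibble(locus = loci, variable = v, beta_mean = beta_mean,
                       bf = bf, flagged = bf > bf_threshold)
  }
  res <- bind_rows(out)
  class(res) <- c("gea_result", class(res))
  attr(res, "bf_threshold") <- bf_threshold
  attr(res, "sites") <- sites
  res
}

#' @export
autoplot.gea_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$variable, y = log10(.data$bf))) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.4,
                         ggplot2::aes(colour = .data$flagged)) +
    ggplot2::geom_hline(yintercept = log10(attr(object, "bf_threshold")),
                        linetype = 2) +
    ggplot2::labs(y = "log10 Bayes factor", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
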