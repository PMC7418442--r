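#' Admixture-model Bayesian clustering (Gibbs sampler)
#'
#' The classic admixture model with independent Dirichlet cluster allele
#' frequencies: each allele copy of individual i originates from cluster k
#' with probability Q_ik; copies of allele a at locus l from cluster k occur
#' with frequency P_kl(a). Gibbs updates cycle origins Z | P, Q, cluster
#' frequencies P ~ Beta(lambda + counts) and admixture rows
#' Q_i ~ Dirichlet(alpha + origin counts), with fixed hyper-parameters.
#' Missing genotypes contribute no allele draws. The per-iteration
#' log-likelihood of the data under (P, Q) is recorded; its post-burn-in
#' mean is the model-selection summary consumed by [evanno_deltaK()].
#'
#' @param g A [geno_tbl()].
#' @param K Number of clusters (>= 1, at most the number of individuals).
#' @param n_iter,burn_in Iterations and burn-in (`n_iter > burn_in`).
#' @param alpha Dirichlet admixture hyper-parameter.
#' @param lambda Beta frequency hyper-parameter.
#' @param seed Integer seed.
#' @return A `cluster_run`: `Q` (posterior-mean individual x K admixture),
#'   `P` (posterior-mean K x loci allele-2 frequencies), `ll_trace`,
#'   `mean_ll` (post-burn-in), `K`, `seed`.
#' @export
admixture_gibbs <- function(g, K, n_iter = 20000, burn_in = 5000,
                            alpha = 1, lambda = 1, seed = 1) {
  if (K < 1) abort("K must be at least 1")
  if (K > nrow(g)) abort("K exceeds the number of individuals")
  if (n_iter <= burn_in) abort("n_iter must exceed burn_in")
  d <- geno_dosage(g)
  N <- nrow(d); L <- ncol(d)
  x1 <- d; x1[is.na(x1)] <- 0L           # copies of allele 2
  x0 <- 2L - d; x0[is.na(d)] <- 0L       # copies of allele 1
  with_seed(seed, {
    Q <- matrix(1 / K, N, K)
    P <- matrix(runif(K * L, 0.2, 0.8), K, L)
    Q_acc <- matrix(0, N, K); P_acc <- matrix(0, K, L)
    ll_trace <- numeric(n_iter)
    n_kept <- 0L
    for (it in seq_len(n_iter)) {
      ## origin counts by stick-breaking multinomials over clusters
      s1 <- Q %*% P; s0 <- Q %*% (1 - P)
      rem1 <- x1; rem0 <- x0
      sr1 <- s1; sr0 <- s0
      C1 <- matrix(0, K, L); C0 <- matrix(0, K, L)
      m <- matrix(0, N, K)
      for (k in seq_len(K)) {
        if (k < K) {
          w1k <- tcrossprod(Q[, k], P[k, ])
          w0k <- tcrossprod(Q[, k], 1 - P[k, ])
          pr1 <- pmin(pmax(ifelse(sr1 > 1e-300, w1k / sr1, 0), 0), 1)
          pr0 <- pmin(pmax(ifelse(sr0 > 1e-300, w0k / sr0, 0), 0), 1)
          n1k <- matrix(rbinom(N * L, rem1, pr1), N, L)
          n0k <- matrix(rbinom(N * L, rem0, pr0), N, L)
          sr1 <- sr1 - w1k; sr0 <- sr0 - w0k
        } else {
          n1k <- rem1; n0k <- rem0
        }
        C1[k, ] <- colSums(n1k); C0[k, ] <- colSums(n0k)
        m[, k] <- rowSums(n1k) + rowSums(n0k)
        rem1 <- rem1 - n1k; rem0 <- rem0 - n0k
      }
      ## frequencies and admixture
      P <- matrix(rbeta(K * L, lambda + C1, lambda + C0), K, L)
      gdraw <- matrix(rgamma(N * K, shape = alpha + m, rate = 1), N, K)
      Q <- gdraw / rowSums(gdraw)
      ## data log-likelihood under current (P, Q)
      A <- Q %*% P; B <- Q %*% (1 - P)
      ll_trace[it] <- sum(x1 * log(pmax(A, 1e-300))) +
        sum(x0 * log(pmax(B, 1e-300)))
      if (it > burn_in) {
        Q_acc <- Q_acc + Q; P_acc <- P_acc + P; n_kept <- n_kept + 1L
      }
    }
    Qm <- Q_acc / n_kept
    rownames(Qm) <- g$individual
    structure(list(Q = Qm, P = P_acc / n_kept, ll_trace = ll_trace,
                   mean_ll = mean(ll_trace[(burn_in + 1):n_iter]),
                   K = K, seed = seed, sites = g$site),
              class = "cluster_run")
  })
}

#' @export
print.cluster_run <- function(x, ...) {
  cat(sprintf("<cluster_run> K = %d, mean post-burn-in logL = %.1f\n",
              x$K, x$mean_ll))
  invisible(x)
}

#' @export
tidy.cluster_run <- function(x, ...) {
  q <- as_tibble(x$Q, .name_repair = ~ sprintf("Q%d", seq_along(.x)))
  bind_cols(tibble(individual = rownames(x$Q), site = x$sites), q) |>
    pivot_longer(dplyr::starts_with("Q"), names_to = "cluster",
                 values_to = "proportion")
}

#' @export
autoplot.cluster_run <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$individual,
                                   y = .data$proportion,
                                   fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(~site, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "admixture proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Evanno delta-K model selection
#'
#' From replicated cluster runs over a range of K: per K the mean and s.d.
#' of the model log-likelihood L(K), the successive differences L'(K) and
#' |L''(K)|, and Delta-K = mean|L(K+1) - 2 L(K) + L(K-1)| / sd(L(K)).
#' Delta-K is defined only for interior K with positive s.d.
#'
#' @param runs List of `cluster_run` objects (several replicates per K over
#'   at least 3 consecutive K values).
#' @return An `evanno_table` tibble with attribute `best_k` (argmax Delta-K).
#' @export
evanno_deltaK <- function(runs) {
  ll <- tibble(K = map_int(runs, "K"), ll = map_dbl(runs, "mean_ll"))
  byk <- ll |> group_by(.data$K) |>
    summarise(mean_ll = mean(.data$ll), sd_ll = sd(.data$ll),
              n_rep = n(), .groups = "drop") |>
    arrange(.data$K)
  if (nrow(byk) < 3) abort("need at least 3 consecutive K values")
  if (any(diff(byk$K) != 1)) abort("K values must be consecutive")
  if (any(byk$n_rep < 2)) abort("need at least 2 replicates per K")
  k <- nrow(byk)
  lprime <- c(NA, diff(byk$mean_ll))
  lsec <- rep(NA_real_, k)
  lsec[2:(k - 1)] <- abs(byk$mean_ll[3:k] - 2 * byk$mean_ll[2:(k - 1)] +
                           byk$mean_ll[1:(k - 2)])
  deltak <- lsec / byk$sd_ll
  deltak[byk$sd_ll == 0] <- NA_real_
  out <- byk |> mutate(l_prime = lprime, l_second = lsec, delta_k = deltak)
  best <- out$K[which.max(out$delta_k)]
  attr(out, "best_k") <- best
  class(out) <- c("evanno_table", class(out))
  out
}

#' @export
autoplot.evanno_table <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$K, y = .data$delta_k)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = expression(Delta * K)) +
    ggplot2::theme_minimal()
}

#' Match cluster labels across runs
#'
#' Greedy resolution of label switching: permutes the columns of `run$Q` to
#' best match a reference Q matrix (maximal summed agreement).
#'
#' @param run A `cluster_run`.
#' @param reference Q matrix of the same shape.
#' @return The run with permuted `Q`/`P`.
#' @export
align_clusters <- function(run, reference) {
  K <- run$K
  perms <- all_perms(K)
  scores <- map_dbl(perms, function(p) sum(run$Q[, p] * reference))
  best <- perms[[which.max(scores)]]
  run$Q <- run$Q[, best, drop = FALSE]
  run$P <- run$P[best, , drop = FALSE]
  run
}

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_perms(n - 1)
    for (r in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[r])
  }
  out
}
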