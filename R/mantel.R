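#' Mantel test between two labelled distance matrices
#'
#' Pearson correlation of the off-diagonal entries, with significance from
#' permuting the site labels of the second matrix. The default alternative is
#' one-tailed positive (the isolation-by-distance convention);
#' `alternative = "two.sided"` uses |r|. p = (1 + #\{perm >= obs\}) /
#' (1 + n_perm).
#'
#' @param m1,m2 [pairwise_mat()] objects (or plain symmetric matrices) with
#'   matching labels; at least 3 sites.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A `mantel_result` with `r`, `p`, `n_perm`, `flag`.
#' @export
mantel <- function(m1, m2, n_perm = 9999, seed = 1,
                   alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  v1 <- if (inherits(m1, "pairwise_mat")) m1$values else as.matrix(m1)
  v2 <- if (inherits(m2, "pairwise_mat")) m2$values else as.matrix(m2)
  if (nrow(v1) < 3) abort("need at least 3 sites")
  if (!is.null(rownames(v1)) && !is.null(rownames(v2))) {
    if (!setequal(rownames(v1), rownames(v2))) abort("matrix labels disagree")
    v2 <- v2[rownames(v1), rownames(v1)]
  }
  lt <- lower.tri(v1)
  stat <- function(a, b) {
    if (sd(a[lt]) == 0 || sd(b[lt]) == 0) return(NA_real_)
    r <- cor(a[lt], b[lt])
    if (alternative == "two.sided") abs(r) else r
  }
  r_obs <- suppressWarnings(cor(v1[lt], v2[lt]))
  s_obs <- stat(v1, v2)
  if (is.na(s_obs)) {
    return(structure(list(r = NA_real_, p = NA_real_, n_perm = n_perm,
                          flag = "constant_matrix"), class = "mantel_result"))
  }
  n <- nrow(v1)
  with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      pp <- sample(n)
      if (stat(v1, v2[pp, pp]) >= s_obs - 1e-12) cnt <- cnt + 1L
    }
    structure(list(r = r_obs, p = (1 + cnt) / (1 + n_perm), n_perm = n_perm,
                   flag = "ok"), class = "mantel_result")
  })
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %s (%d permutations)%s\n",
              x$r, format.pval(x$p), x$n_perm,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' @export
glance.mantel_result <- function(x, ...) {
  tibble(r = x$r, p = x$p, n_perm = x$n_perm, flag = x$flag)
}

#' Neighbour-joining tree from a pairwise matrix
#'
#' Saitou-Nei neighbour joining (via the ape implementation) on a labelled
#' distance matrix. Negative branch lengths are clamped to zero (count
#' recorded in the `"clamped"` attribute), the convention used when drawing
#' FST-based trees.
#'
#' @param pm A [pairwise_mat()] (or symmetric matrix) over at least 3 sites.
#' @return An ape `phylo` tree.
#' @export
nj_tree <- function(pm) {
  v <- if (inherits(pm, "pairwise_mat")) pm$values else as.matrix(pm)
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-8, check.attributes = FALSE))) {
    abort("distance matrix must be symmetric", class = "seascapr_format_error")
  }
  if (nrow(v) < 3) abort("need at least 3 sites")
  tr <- ape::nj(stats::as.dist(v))
  clamped <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  tr
}
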