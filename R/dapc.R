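#' Discriminant analysis of principal components
#'
#' Centred allele dosages (missing calls imputed with the locus mean) are
#' reduced by PCA to `n_pc` components, then linear discriminant analysis on
#' the group labels retains `n_df` discriminant axes. Assignment is
#' evaluated by leave-one-out cross-validation of the LDA step.
#'
#' @param g A [geno_tbl()].
#' @param n_pc Principal components retained (clipped to the matrix rank).
#' @param n_df Discriminant functions retained (clipped to groups - 1 and
#'   `n_pc`, with a warning).
#' @param groups Group labels (default: site assignment).
#' @return A `dapc_result`: individual `coords` on the discriminant axes,
#'   group `centroids`, the leave-one-out `assignment` table, eigenvalues
#'   and the retained dimensions.
#' @export
dapc <- function(g, n_pc = 30, n_df = 2, groups = geno_sites(g)) {
  d <- geno_dosage(g)
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) abort("need at least 2 groups")
  X <- apply(d, 2, function(col) {
    mu <- mean(col, na.rm = TRUE)
    col[is.na(col)] <- mu
    col - mu
  })
  keep_var <- apply(X, 2, var) > 0
  X <- X[, keep_var, drop = FALSE]
  pc <- prcomp(X, center = FALSE)
  rank <- sum(pc$sdev > 1e-8)
  n_pc <- min(n_pc, rank)
  maxdf <- min(length(unique(groups)) - 1, n_pc)
  if (n_df > maxdf) {
    warn(sprintf("n_df clipped from %d to %d", n_df, maxdf))
    n_df <- maxdf
  }
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  fit <- MASS::lda(scores, grouping = groups)
  pred <- stats::predict(fit, scores)
  coords <- pred$x[, seq_len(n_df), drop = FALSE]
  centroids <- apply(coords, 2, function(col) tapply(col, groups, mean))
  cv <- MASS::lda(scores, grouping = groups, CV = TRUE)
  assignment <- table(truth = groups, assigned = cv$class)
  structure(list(
    coords = as_tibble(coords) |>
      mutate(individual = g$individual, group = groups, .before = 1),
    centroids = centroids,
    assignment = assignment,
    accuracy = sum(diag(assignment)) / sum(assignment),
    eigenvalues = fit$svd^2,
    n_pc = as.integer(n_pc), n_df = as.integer(n_df)
  ), class = "dapc_result")
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf("DAPC: %d PCs, %d discriminant axes, LOO accuracy %.1f%%\n",
              x$n_pc, x$n_df, 100 * x$accuracy))
  invisible(x)
}

#' @export
tidy.dapc_result <- function(x, ...) x$coords

#' @export
autoplot.dapc_result <- function(object, ...) {
  td <- object$coords
  if (object$n_df >= 2) {
    ggplot2::ggplot(td, ggplot2::aes(x = .data$LD1, y = .data$LD2,
                                     colour = .data$group)) +
      ggplot2::geom_point() +
      ggplot2::stat_ellipse(level = 0.67, na.rm = TRUE) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(td, ggplot2::aes(x = .data$LD1, fill = .data$group)) +
      ggplot2::geom_density(alpha = 0.5) +
      ggplot2::theme_minimal()
  }
}
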