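#' Labelled symmetric pairwise matrices
#'
#' The common currency of the differentiation and connectivity analyses:
#' a symmetric matrix over site labels, tagged with a unit ("fst", "km",
#' "resistance", ...), optionally with per-cell permutation p-values.
#'
#' @param values Symmetric numeric matrix with identical row/col labels.
#' @param unit Unit tag.
#' @param p Optional matrix of p-values, same shape.
#' @export
pairwise_mat <- function(values, unit = "value", p = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- colnames(values) <- sprintf("s%d", seq_len(nrow(values)))
  }
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    abort("pairwise matrix must be symmetric", class = "seascapr_format_error")
  }
  if (anyDuplicated(rownames(values))) abort("labels must be unique")
  diag(values) <- 0
  structure(list(values = values, unit = unit, p = p), class = "pairwise_mat")
}

#' @export
print.pairwise_mat <- function(x, ...) {
  cat(sprintf("<pairwise_mat: %s> %d sites\n", x$unit, nrow(x$values)))
  print(round(x$values, 4))
  invisible(x)
}

#' @export
tidy.pairwise_mat <- function(x, ...) {
  labs <- rownames(x$values)
  idx <- which(lower.tri(x$values), arr.ind = TRUE)
  out <- tibble(site1 = labs[idx[, 2]], site2 = labs[idx[, 1]],
                value = x$values[idx], unit = x$unit)
  if (!is.null(x$p)) out$p <- x$p[idx]
  out
}

#' Read/write a pairwise matrix as labelled TSV
#' @param x A `pairwise_mat`; `path` a file path; `unit` the unit tag on read.
#' @rdname pairwise_io
#' @export
write_pairwise <- function(x, path) {
  df <- as.data.frame(x$values)
  df <- cbind(site = rownames(x$values), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname pairwise_io
#' @export
read_pairwise <- function(path, unit = "value") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  pairwise_mat(m, unit = unit)
}

#' @export
autoplot.pairwise_mat <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$site1, y = .data$site2,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = object$unit) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
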