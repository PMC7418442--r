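#' Bundled reference tables for the honeycomb-worm study system
#'
#' Three small published summary tables for a nine-site RADseq panel of the
#' reef-building honeycomb worm ship with the package as plain TSV: per-site
#' genomic summary statistics, the combined pairwise FST (lower triangle) /
#' coastline-distance (upper triangle, km) matrix, and the sixteen thermal
#' parameters for the six temperature-logged sites. They anchor the worked
#' examples and let the aggregation utilities be checked against printed
#' values.
#'
#' @param name One of `"site_summary"`, `"fst_km"`, `"thermal"`.
#' @return The file path of the bundled TSV.
#' @export
honeycomb_table <- function(name = c("site_summary", "fst_km", "thermal")) {
  name <- match.arg(name)
  system.file("extdata", paste0("honeycomb_", name, ".tsv"),
              package = "seascapr", mustWork = TRUE)
}

#' @rdname honeycomb_table
#' @param path TSV path (defaults to the bundled table).
#' @export
read_site_summary <- function(path = honeycomb_table("site_summary")) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a combined FST / distance matrix table
#'
#' Parses the published layout in which the lower triangle holds pairwise
#' FST and the upper triangle coastline distances in km.
#'
#' @param path TSV path (defaults to the bundled table).
#' @return A list with `fst` and `km` [pairwise_mat()] objects.
#' @export
read_fst_km_table <- function(path = honeycomb_table("fst_km")) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  fst <- m; fst[upper.tri(fst)] <- t(fst)[upper.tri(fst)]
  km <- m; km[lower.tri(km)] <- t(km)[lower.tri(km)]
  diag(fst) <- 0; diag(km) <- 0
  list(fst = pairwise_mat(fst, unit = "fst"),
       km = pairwise_mat(km, unit = "km"))
}

#' @rdname honeycomb_table
#' @export
read_thermal_table <- function(path = honeycomb_table("thermal")) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Mean of the pairwise values of a symmetric matrix
#'
#' @param pm A [pairwise_mat()].
#' @return Mean over the strictly-lower-triangle entries.
#' @export
mean_pairwise <- function(pm) lower_tri_mean(pm$values)

#' Mean pairwise value involving one site
#'
#' @param pm A [pairwise_mat()].
#' @param site A site label.
#' @export
site_mean_pairwise <- function(pm, site) {
  v <- pm$values
  if (!site %in% rownames(v)) abort("unknown site")
  mean(v[site, setdiff(colnames(v), site)])
}

#' Outlier percentage bookkeeping
#'
#' @param k Number of outlier loci.
#' @param total Locus universe size.
#' @return Percentage of `total`, rounded to 2 decimal places.
#' @export
outlier_pct <- function(k, total) round(100 * k / total, 2)
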