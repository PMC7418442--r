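#' Genotype tables
#'
#' The package represents a panel of biallelic diploid SNP genotypes as a
#' `geno_tbl`: a tibble with one row per individual, an `individual` column,
#' a `site` column, and one integer column per locus holding the allele-2
#' dosage (0, 1 or 2; `NA` for a missing call). Per-locus metadata (RADtag id,
#' position within tag, simulation truth class) travels in the `loci`
#' attribute as a tibble.
#'
#' @param dosage Integer matrix, individuals x loci, values 0/1/2/NA.
#' @param sites Character vector of site labels, one per individual.
#' @param individuals Optional individual labels (default `ind_001`, ...).
#' @param loci Optional locus metadata tibble with at least a `locus` column;
#'   columns `radtag`, `pos` and `class` are filled with defaults if absent.
#' @return A `geno_tbl`.
#' @export
geno_tbl <- function(dosage, sites, individuals = NULL, loci = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  n <- nrow(dosage)
  l <- ncol(dosage)
  if (length(sites) != n) abort("`sites` must have one label per individual")
  if (is.null(individuals)) {
    individuals <- sprintf("ind_%03d", seq_len(n))
  }
  if (anyDuplicated(individuals)) abort("individual labels must be unique")
  if (is.null(loci)) {
    loci <- tibble(locus = colnames(dosage) %||% sprintf("L%04d", seq_len(l)))
  }
  loci <- as_tibble(loci)
  if (nrow(loci) != l) abort("`loci` must describe every dosage column")
  if (!"radtag" %in% names(loci)) loci$radtag <- loci$locus
  if (!"pos" %in% names(loci)) loci$pos <- 1L
  if (!"class" %in% names(loci)) loci$class <- "neutral"
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    abort("dosages must be 0, 1, 2 or NA (biallelic diploid calls)")
  }
  colnames(dosage) <- loci$locus
  out <- bind_cols(
    tibble(individual = as.character(individuals), site = as.character(sites)),
    as_tibble(dosage)
  )
  attr(out, "loci") <- loci
  class(out) <- c("geno_tbl", class(tibble()))
  out
}

#' @rdname geno_tbl
#' @param g A `geno_tbl`.
#' @export
geno_dosage <- function(g) {
  m <- as.matrix(g[, setdiff(names(g), c("individual", "site")), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- g$individual
  m
}

#' @rdname geno_tbl
#' @export
geno_sites <- function(g) g$site

#' @rdname geno_tbl
#' @export
geno_loci <- function(g) {
  lm <- attr(g, "loci")
  if (is.null(lm)) lm <- tibble(locus = setdiff(names(g), c("individual", "site")))
  lm
}

#' @rdname geno_tbl
#' @export
n_loci <- function(g) ncol(geno_dosage(g))

#' @rdname geno_tbl
#' @export
n_individuals <- function(g) nrow(g)

#' Subset a genotype table by locus
#'
#' @param g A `geno_tbl`.
#' @param loci Character vector of locus names (or logical/integer index).
#' @return A `geno_tbl` restricted to those loci, metadata kept in step.
#' @export
select_loci <- function(g, loci) {
  meta <- geno_loci(g)
  if (is.character(loci)) {
    idx <- match(loci, meta$locus)
    if (anyNA(idx)) abort("unknown locus name(s)")
  } else {
    idx <- seq_len(nrow(meta))[loci]
  }
  geno_tbl(geno_dosage(g)[, idx, drop = FALSE], g$site, g$individual,
           meta[idx, , drop = FALSE])
}

#' Per-site allele frequencies
#'
#' Frequency of allele 2 per locus and site, with the number of typed
#' individuals behind each estimate. Missing calls are excluded pairwise.
#'
#' @param g A `geno_tbl`.
#' @return A tibble with columns `locus`, `site`, `n_typed`, `freq`.
#' @export
site_allele_freqs <- function(g) {
  d <- geno_dosage(g)
  sites <- unique(g$site)
  out <- map(sites, function(s) {
    sub <- d[g$site == s, , drop = FALSE]
    n_typed <- colSums(!is.na(sub))
    freq <- ifelse(n_typed > 0, colSums(sub, na.rm = TRUE) / (2 * n_typed), NA_real_)
    tibble(locus = colnames(d), site = s, n_typed = as.integer(n_typed), freq = freq)
  })
  bind_rows(out)
}

# loci x sites matrix of allele-2 frequencies (NA where untyped)
site_freq_matrix <- function(g) {
  af <- site_allele_freqs(g)
  wide <- pivot_wider(af[, c("locus", "site", "freq")],
                      names_from = "site", values_from = "freq")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$locus
  m[, unique(g$site), drop = FALSE]
}

#' @export
print.geno_tbl <- function(x, ...) {
  cat(sprintf("<geno_tbl> %d individuals x %d loci, %d sites\n",
              nrow(x), n_loci(x), length(unique(x$site))))
  NextMethod()
}
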