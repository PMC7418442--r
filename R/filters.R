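#' Per-locus metadata used by the locus filters
#'
#' @param g A [geno_tbl()].
#' @param depth Optional numeric vector of mean read depths per locus (one
#'   per locus); defaults to `Inf` (depth not assessed), as for data that
#'   arrives already depth-filtered.
#' @return Tibble with `locus`, `radtag`, `pos`, `depth`.
#' @export
locus_meta <- function(g, depth = NULL) {
  meta <- geno_loci(g)
  depth <- depth %||% rep(Inf, nrow(meta))
  if (length(depth) != nrow(meta)) abort("`depth` must cover all loci")
  tibble(locus = meta$locus, radtag = meta$radtag, pos = meta$pos,
         depth = as.numeric(depth))
}

#' Default locus-filter thresholds
#'
#' The standard RADseq retention rules: minimum 10x read depth, locus present
#' in at least 70% of populations, at least 50% of individuals typed within a
#' population for it to count as covered, within-population minor allele
#' frequency above 0.01, and a single SNP per RADtag.
#'
#' @param min_depth Minimum mean read depth.
#' @param pop_presence Minimum fraction of populations in which the locus is
#'   present (at least one typed individual).
#' @param r Minimum fraction of typed individuals for a population to count
#'   as covered; the locus must reach this in at least `pop_presence` of the
#'   populations.
#' @param min_maf The within-population minor allele frequency must exceed
#'   this in at least one population.
#' @param one_per_radtag Keep only one SNP per RADtag (highest MAF, ties by
#'   lowest position).
#' @export
filter_thresholds <- function(min_depth = 10, pop_presence = 0.7, r = 0.5,
                              min_maf = 0.01, one_per_radtag = TRUE) {
  for (x in c(pop_presence, r, min_maf)) {
    if (x < 0 || x > 1) {
      abort("fractional thresholds must lie in [0,1]",
            class = "seascapr_param_error")
    }
  }
  list(min_depth = min_depth, pop_presence = pop_presence, r = r,
       min_maf = min_maf, one_per_radtag = one_per_radtag)
}

#' Apply the locus retention filters
#'
#' Rules are applied in order: read depth, population presence, per-population
#' typing rate, minor allele frequency, one SNP per RADtag. The report counts
#' the loci removed by each rule (a locus is charged to the first rule it
#' fails).
#'
#' @param g A [geno_tbl()].
#' @param meta A [locus_meta()] tibble covering every locus of `g`.
#' @param thresholds A [filter_thresholds()] list.
#' @return A list with `genotypes` (the filtered [geno_tbl()]) and `report`
#'   (tibble: rule, removed, remaining; plus retained counts/percentage as
#'   attributes).
#' @export
filter_loci <- function(g, meta = locus_meta(g), thresholds = filter_thresholds()) {
  th <- thresholds
  lm <- geno_loci(g)
  if (!all(lm$locus %in% meta$locus)) abort("`meta` must cover all loci")
  meta <- meta[match(lm$locus, meta$locus), ]
  d <- geno_dosage(g)
  sites <- unique(g$site)
  n_pop <- length(sites)
  typed_frac <- sapply(sites, function(s) {
    sub <- d[g$site == s, , drop = FALSE]
    colMeans(!is.na(sub))
  })  # loci x pops
  typed_frac <- matrix(typed_frac, ncol = n_pop)
  pop_maf <- sapply(sites, function(s) {
    sub <- d[g$site == s, , drop = FALSE]
    nt <- colSums(!is.na(sub))
    p <- ifelse(nt > 0, colSums(sub, na.rm = TRUE) / (2 * nt), NA_real_)
    pmin(p, 1 - p)
  })
  pop_maf <- matrix(pop_maf, ncol = n_pop)

  L <- ncol(d)
  alive <- rep(TRUE, L)
  report <- tibble(rule = character(), removed = integer(), remaining = integer())
  log_rule <- function(rule, fail) {
    fail <- fail & alive
    alive <<- alive & !fail
    report <<- bind_rows(report, tibble(rule = rule,
                                        removed = sum(fail),
                                        remaining = sum(alive)))
  }
  log_rule("depth", meta$depth < th$min_depth)
  log_rule("pop_presence", rowMeans(typed_frac > 0) < th$pop_presence)
  log_rule("ind_typed_r", rowMeans(typed_frac >= th$r) < th$pop_presence)
  maf_max <- apply(pop_maf, 1, function(x) suppressWarnings(max(x, na.rm = TRUE)))
  maf_max[!is.finite(maf_max)] <- 0
  # min_maf = 0 disables the rule (a strict "> threshold" retention test)
  log_rule("min_maf", if (th$min_maf > 0) maf_max <= th$min_maf else
    rep(FALSE, L))
  if (isTRUE(th$one_per_radtag)) {
    keep <- rep(FALSE, L)
    surv <- which(alive)
    if (length(surv)) {
      ord <- surv[order(lm$radtag[surv], -maf_max[surv], lm$pos[surv])]
      keep[ord[!duplicated(lm$radtag[ord])]] <- TRUE
    }
    log_rule("one_per_radtag", alive & !keep)
  }
  stopifnot(sum(report$removed) + sum(alive) == L)
  out <- select_loci(g, which(alive))
  attr(report, "input") <- L
  attr(report, "retained") <- sum(alive)
  attr(report, "retained_pct") <- round(100 * sum(alive) / L, 2)
  list(genotypes = out, report = report)
}
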