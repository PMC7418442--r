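#' Read and write genotype panels
#'
#' Three dialects are supported, matching the interchange formats common in
#' RADseq population genetics:
#' * `"genepop"`: two-digit allele codes (`01`/`02`, `0000` missing), one
#'   `Pop` block per site. The individual-name field is written as
#'   `site|individual` so that site assignment survives a round trip.
#' * `"structure"`: the 2-row-per-individual layout with a locus-name header;
#'   alleles coded 1/2, missing -9; column 2 carries the site label.
#' * `"vcf"`: minimal VCF v4.2, GT field only; sample ids are
#'   `site|individual`. Reading uses the vcfR parser when installed, with a
#'   plain-text fallback.
#'
#' @param path File path.
#' @param format One of `"genepop"`, `"structure"`, `"vcf"`.
#' @return `read_genotypes()` returns a [geno_tbl()]; `write_genotypes()`
#'   returns `path` invisibly.
#' @export
read_genotypes <- function(path, format = c("genepop", "structure", "vcf")) {
  format <- match.arg(format)
  switch(format,
         genepop = read_genepop(path),
         structure = read_structure(path),
         vcf = read_vcf_min(path))
}

#' @rdname read_genotypes
#' @param g A [geno_tbl()].
#' @export
write_genotypes <- function(g, path, format = c("genepop", "structure", "vcf")) {
  format <- match.arg(format)
  switch(format,
         genepop = write_genepop(g, path),
         structure = write_structure(g, path),
         vcf = write_vcf_min(g, path))
  invisible(path)
}

split_label <- function(x, i) {
  parts <- strsplit(x, "|", fixed = TRUE)
  has <- lengths(parts) == 2
  site <- ifelse(has, map_chr(parts, 1), sprintf("pop%d", i))
  ind <- ifelse(has, map_chr(parts, function(p) p[2]), x)
  list(site = site, ind = ind)
}

write_genepop <- function(g, path) {
  d <- geno_dosage(g)
  code <- function(x) {
    ifelse(is.na(x), "0000", c("0101", "0102", "0202")[x + 1])
  }
  lines <- c("seascapr genepop export", colnames(d))
  for (s in unique(g$site)) {
    lines <- c(lines, "Pop")
    rows <- which(g$site == s)
    for (r in rows) {
      lines <- c(lines, paste0(s, "|", g$individual[r], " ,  ",
                               paste(code(d[r, ]), collapse = " ")))
    }
  }
  writeLines(lines, path)
}

read_genepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  pop_idx <- which(toupper(trimws(lines)) == "POP")
  if (!length(pop_idx)) abort("not a genepop file: no Pop line")
  header <- lines[2:(pop_idx[1] - 1)]
  # locus names may be one-per-line or comma separated
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  ind <- character(); site <- character(); rows <- list()
  blocks <- c(pop_idx, length(lines) + 1L)
  for (b in seq_along(pop_idx)) {
    for (k in seq.int(blocks[b] + 1L, blocks[b + 1L] - 1L)) {
      parts <- strsplit(lines[k], ",")[[1]]
      if (length(parts) < 2) abort(sprintf("malformed genepop line %d", k))
      lab <- split_label(trimws(parts[1]), b)
      calls <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[ \t]+")[[1]]
      if (length(calls) != length(loci)) {
        abort(sprintf("individual %s has %d calls for %d loci",
                      lab$ind, length(calls), length(loci)))
      }
      dos <- map_int(seq_along(calls), function(i) {
        cc <- calls[i]
        a1 <- substr(cc, 1, 2); a2 <- substr(cc, 3, 4)
        if (a1 == "00" || a2 == "00") return(NA_integer_)
        if (!a1 %in% c("01", "02") || !a2 %in% c("01", "02")) {
          abort(sprintf("locus %s is not biallelic (allele code %s)",
                        loci[i], cc), class = "seascapr_format_error")
        }
        as.integer((a1 == "02") + (a2 == "02"))
      })
      ind <- c(ind, lab$ind); site <- c(site, lab$site)
      rows[[length(rows) + 1L]] <- dos
    }
  }
  geno_tbl(do.call(rbind, rows), site, ind, tibble(locus = loci))
}

write_structure <- function(g, path) {
  d <- geno_dosage(g)
  a1 <- ifelse(is.na(d), -9L, ifelse(d == 2L, 2L, 1L))
  a2 <- ifelse(is.na(d), -9L, ifelse(d >= 1L, 2L, 1L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(d), collapse = "\t"), con)
  for (r in seq_len(nrow(d))) {
    writeLines(paste(c(g$individual[r], g$site[r], a1[r, ]), collapse = "\t"), con)
    writeLines(paste(c(g$individual[r], g$site[r], a2[r, ]), collapse = "\t"), con)
  }
}

read_structure <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  loci <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (length(body) %% 2 != 0) abort("structure file must have 2 rows per individual")
  n <- length(body) / 2
  ind <- character(n); site <- character(n)
  dosage <- matrix(NA_integer_, n, length(loci))
  for (i in seq_len(n)) {
    r1 <- body[[2 * i - 1]]; r2 <- body[[2 * i]]
    if (r1[1] != r2[1]) abort("row pair labels disagree")
    ind[i] <- r1[1]; site[i] <- r1[2]
    al <- rbind(as.integer(r1[-(1:2)]), as.integer(r2[-(1:2)]))
    bad <- al[!al %in% c(-9L, 1L, 2L)]
    if (length(bad)) {
      abort(sprintf("locus %s is not biallelic (allele code %d)",
                    loci[which(!al[1, ] %in% c(-9L, 1L, 2L) |
                                 !al[2, ] %in% c(-9L, 1L, 2L))[1]], bad[1]),
            class = "seascapr_format_error")
    }
    miss <- al[1, ] == -9L | al[2, ] == -9L
    dos <- colSums(al == 2L)
    dos[miss] <- NA_integer_
    dosage[i, ] <- dos
  }
  geno_tbl(dosage, site, ind, tibble(locus = loci))
}

write_vcf_min <- function(g, path) {
  d <- geno_dosage(g)
  meta <- geno_loci(g)
  gt <- ifelse(is.na(d), "./.", c("0/0", "0/1", "1/1")[d + 1])
  samples <- paste0(g$site, "|", g$individual)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=seascapr",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  for (l in seq_len(ncol(d))) {
    writeLines(paste(c(meta$radtag[l], meta$pos[l], meta$locus[l], "A", "C",
                       ".", ".", ".", "GT", gt[, l]), collapse = "\t"), con)
  }
}

read_vcf_min <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    vv <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vv@fix
    gt <- vv@gt[, -1, drop = FALSE]
    samples <- colnames(gt)
    loci <- tibble(locus = fix[, "ID"], radtag = fix[, "CHROM"],
                   pos = as.integer(fix[, "POS"]))
  } else {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#CHROM")]
    cols <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
    samples <- cols[-(1:9)]
    body <- strsplit(lines[!startsWith(lines, "#")], "\t", fixed = TRUE)
    loci <- tibble(locus = map_chr(body, 3), radtag = map_chr(body, 1),
                   pos = as.integer(map_chr(body, 2)))
    gt <- do.call(rbind, map(body, function(r) r[-(1:9)]))
    colnames(gt) <- samples
  }
  gtfield <- sub(":.*$", "", gt)
  dos <- matrix(NA_integer_, ncol(gt), nrow(gt))
  for (l in seq_len(nrow(gt))) {
    x <- gtfield[l, ]
    alleles <- strsplit(x, "[/|]")
    dos[, l] <- map_int(alleles, function(a) {
      if (!length(a) || anyNA(a) || any(a == ".")) return(NA_integer_)
      ai <- suppressWarnings(as.integer(a))
      if (any(is.na(ai)) || any(ai > 1)) {
        abort(sprintf("locus %s is not biallelic", loci$locus[l]),
              class = "seascapr_format_error")
      }
      sum(ai)
    })
  }
  lab <- split_label(samples, 1L)
  geno_tbl(dos, lab$site, lab$ind, loci)
}

#' Write simulation truth labels to a sidecar TSV
#'
#' @param g A [geno_tbl()] from [simulate_genotypes()].
#' @param path Output TSV path.
#' @export
write_truth_labels <- function(g, path) {
  readr::write_tsv(geno_loci(g), path)
  invisible(path)
}
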