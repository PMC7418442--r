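# Small builders shared across the suite.

# Hand-built panel: dosage matrix + site labels.
tiny_panel <- function() {
  d <- rbind(c(0L, 1L, 2L, 0L),
             c(1L, 1L, 2L, 0L),
             c(2L, 0L, 2L, 1L),
             c(0L, 2L, 2L, 1L))
  colnames(d) <- paste0("L", 1:4)
  geno_tbl(d, sites = c("a", "a", "b", "b"),
           individuals = paste0("i", 1:4))
}

# Balding-Nichols panel with plain defaults for tests.
bn_panel <- function(n_sites = 2, n_per_site = 20, n_loci = 100,
                     target_fst = 0.2, inbreeding_f = 0, seed = 1, ...) {
  simulate_genotypes(sim_params(
    n_sites = n_sites, n_per_site = n_per_site, n_loci = n_loci,
    target_fst = target_fst, inbreeding_f = inbreeding_f,
    frac_balancing = 0, isolated_site = NULL, missing_rate = 0,
    seed = seed, ...))
}

# Panel built from explicit per-site allele-2 frequencies
# (loci x sites matrix), HW genotypes, n individuals per site.
panel_from_freqs <- function(freqs, n_per_site, seed = 1) {
  withr::with_seed(seed, {
    J <- ncol(freqs); L <- nrow(freqs)
    dos <- NULL; sites <- character()
    for (j in seq_len(J)) {
      pj <- freqs[, j]
      block <- t(replicate(n_per_site, rbinom(L, 2, pj)))
      dos <- rbind(dos, block)
      sites <- c(sites, rep(sprintf("site%d", j), n_per_site))
    }
    colnames(dos) <- sprintf("L%04d", seq_len(L))
    geno_tbl(dos, sites)
  })
}

# A forged trajectory_set for settlement-geometry tests.
forge_traj <- function(lon, lat, source, config, release_time = 0) {
  P <- nrow(lon)
  structure(list(
    lon = lon, lat = lat,
    release = tibble::tibble(particle = seq_len(P), source = source,
                             time = as.POSIXct(release_time, tz = "UTC",
                                               origin = "1970-01-01")),
    exit_step = rep(NA_integer_, P), config = config,
    n_steps = ncol(lon) - 1L), class = "trajectory_set")
}
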