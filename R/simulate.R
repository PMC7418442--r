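#' Simulation parameters for the synthetic RADseq panel
#'
#' Bundles the parameters of the Balding-Nichols genotype generator. The
#' defaults emulate the statistical structure of the honeycomb-worm panel the
#' package was designed around: 9 reef sites with 4-12 individuals each,
#' 482 biallelic SNPs, mean differentiation around FST = 0.28 with one
#' strongly isolated deme, a strong heterozygote deficit (F = 0.8, so
#' Ho/He is about 0.2), and a 5% minority of low-FST "balancing" loci.
#'
#' @param n_sites Number of demes.
#' @param n_per_site Individuals per deme (recycled to `n_sites`).
#' @param n_loci Number of biallelic loci.
#' @param target_fst Drift parameter of neutral loci (the generator's FST
#'   target), in (0, 1).
#' @param ancestral_maf_range Range of the uniform ancestral minor-allele
#'   frequency, within (0, 0.5].
#' @param inbreeding_f Within-deme inbreeding coefficient F in `[0, 1)`;
#'   P(het) = 2pq(1-F).
#' @param frac_balancing,frac_divergent,frac_env_assoc Proportions of loci
#'   whose drift parameter is scaled down (balancing: target/5), up
#'   (divergent: min(5 x target, 0.9)), or tied to the environment.
#' @param env_effect Logit-scale slope of deme allele frequency per standard
#'   deviation of the environmental variable, for env-associated loci.
#' @param env Optional per-site environmental values used by env-associated
#'   loci; defaults to a standardised linear gradient over sites.
#' @param missing_rate Proportion of calls set to missing, uniformly at random.
#' @param isolated_site Index of the deme given inflated private drift (the
#'   "isolated reef" of the study system), or `NULL` for none.
#' @param isolated_multiplier Drift multiplier for the isolated deme.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_sites = 9,
                       n_per_site = c(6, 8, 9, 11, 12, 7, 4, 5, 6),
                       n_loci = 482,
                       target_fst = 0.28,
                       ancestral_maf_range = c(0.05, 0.5),
                       inbreeding_f = 0.8,
                       frac_balancing = 0.05,
                       frac_divergent = 0,
                       frac_env_assoc = 0,
                       env_effect = 0,
                       env = NULL,
                       missing_rate = 0.02,
                       isolated_site = 2,
                       isolated_multiplier = 2,
                       seed = 1) {
  n_per_site <- rep_len(as.integer(n_per_site), n_sites)
  fracs <- c(frac_balancing, frac_divergent, frac_env_assoc)
  if (any(fracs < 0) || any(fracs > 1) || sum(fracs) > 1) {
    abort("locus-class proportions must lie in [0,1] and sum to at most 1",
          class = "seascapr_param_error")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("missing_rate must lie in [0, 1)", class = "seascapr_param_error")
  }
  if (target_fst <= 0 || target_fst >= 1) {
    abort("target_fst must lie in (0, 1)", class = "seascapr_param_error")
  }
  if (inbreeding_f < 0 || inbreeding_f >= 1) {
    abort("inbreeding_f must lie in [0, 1)", class = "seascapr_param_error")
  }
  if (ancestral_maf_range[1] <= 0 || ancestral_maf_range[2] > 0.5 ||
      ancestral_maf_range[1] > ancestral_maf_range[2]) {
    abort("ancestral_maf_range must lie within (0, 0.5]",
          class = "seascapr_param_error")
  }
  if (!is.null(isolated_site) &&
      (isolated_site < 1 || isolated_site > n_sites)) {
    abort("isolated_site out of range", class = "seascapr_param_error")
  }
  structure(list(
    n_sites = n_sites, n_per_site = n_per_site, n_loci = n_loci,
    target_fst = target_fst, ancestral_maf_range = ancestral_maf_range,
    inbreeding_f = inbreeding_f, frac_balancing = frac_balancing,
    frac_divergent = frac_divergent, frac_env_assoc = frac_env_assoc,
    env_effect = env_effect, env = env, missing_rate = missing_rate,
    isolated_site = isolated_site, isolated_multiplier = isolated_multiplier,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' Simulate a biallelic SNP panel under the Balding-Nichols model
#'
#' Per locus, an ancestral frequency p is drawn uniformly from
#' `ancestral_maf_range`; each deme's frequency is drawn from
#' Beta(p(1-c)/c, (1-p)(1-c)/c) where c is the drift parameter of the locus
#' class (neutral: `target_fst`; balancing: `target_fst/5`; divergent:
#' `min(5 * target_fst, 0.9)`). Genotypes are then drawn with within-deme
#' inbreeding F: P(het) = 2pq(1-F). One deme may receive inflated private
#' drift to mimic an isolated reef. Environment-associated loci additionally
#' shift deme frequencies on the logit scale by `env_effect` per standard
#' deviation of the site environment.
#'
#' @param params A [sim_params()] object.
#' @return A [geno_tbl()] whose locus metadata carries the truth `class`
#'   labels; the per-deme true frequencies are attached as attribute
#'   `"site_freqs"` (loci x sites) for calibration tests.
#' @export
simulate_genotypes <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  with_seed(p$seed, {
    L <- p$n_loci
    n_bal <- floor(p$frac_balancing * L)
    n_div <- floor(p$frac_divergent * L)
    n_env <- floor(p$frac_env_assoc * L)
    class <- rep("neutral", L)
    idx <- sample.int(L, n_bal + n_div + n_env)
    class[idx[seq_len(n_bal)]] <- "balancing"
    if (n_div > 0) class[idx[n_bal + seq_len(n_div)]] <- "divergent"
    if (n_env > 0) class[idx[n_bal + n_div + seq_len(n_env)]] <- "env_assoc"

    c_locus <- rep(p$target_fst, L)
    c_locus[class == "balancing"] <- p$target_fst / 5
    c_locus[class == "divergent"] <- min(5 * p$target_fst, 0.9)

    p_anc <- runif(L, p$ancestral_maf_range[1], p$ancestral_maf_range[2])
    env <- p$env %||% as.numeric(scale(seq_len(p$n_sites)))
    env <- rep_len(env, p$n_sites)

    # loci x sites deme frequencies
    freqs <- matrix(NA_real_, L, p$n_sites)
    for (j in seq_len(p$n_sites)) {
      cj <- c_locus
      if (!is.null(p$isolated_site) && j == p$isolated_site) {
        cj <- pmin(cj * p$isolated_multiplier, 0.95)
      }
      freqs[, j] <- rbeta(L, p_anc * (1 - cj) / cj, (1 - p_anc) * (1 - cj) / cj)
    }
    if (n_env > 0 && p$env_effect != 0) {
      ei <- which(class == "env_assoc")
      for (j in seq_len(p$n_sites)) {
        f <- pmin(pmax(freqs[ei, j], 1e-6), 1 - 1e-6)
        freqs[ei, j] <- plogis(qlogis(f) + p$env_effect * env[j])
      }
    }

    sites <- rep(sprintf("site%d", seq_len(p$n_sites)), p$n_per_site)
    N <- length(sites)
    dosage <- matrix(NA_integer_, N, L)
    Fin <- p$inbreeding_f
    row0 <- 0L
    for (j in seq_len(p$n_sites)) {
      nj <- p$n_per_site[j]
      pj <- freqs[, j]
      qj <- 1 - pj
      p2 <- pj^2 + Fin * pj * qj        # P(dosage 2)
      p1 <- 2 * pj * qj * (1 - Fin)     # P(het)
      u <- matrix(runif(nj * L), nj, L)
      g <- matrix(0L, nj, L)
      g[u < rep(p2, each = nj) + rep(p1, each = nj)] <- 1L
      g[u < rep(p2, each = nj)] <- 2L
      dosage[row0 + seq_len(nj), ] <- g
      row0 <- row0 + nj
    }
    if (p$missing_rate > 0) {
      dosage[runif(length(dosage)) < p$missing_rate] <- NA_integer_
    }
    loci <- tibble(
      locus = sprintf("L%04d", seq_len(L)),
      radtag = sprintf("tag%04d", seq_len(L)),
      pos = 1L,
      class = class
    )
    g <- geno_tbl(dosage, sites, loci = loci)
    attr(g, "site_freqs") <- freqs
    attr(g, "ancestral_freq") <- p_anc
    attr(g, "params") <- p
    g
  })
}

#' Site thermal profile for the temperature generator
#'
#' @param mean Annual mean temperature (degC).
#' @param annual_amp Amplitude of the annual sinusoid (degC).
#' @param water_sd,air_sd Reading noise s.d. for submerged (high-tide) and
#'   emersed (low-tide) readings; intertidal air readings are far noisier.
#' @param air_offset Mean offset of air readings relative to water (degC).
#' @export
temp_profile <- function(mean = 12, annual_amp = 5, water_sd = 1, air_sd = 4,
                         air_offset = 0) {
  list(mean = mean, annual_amp = annual_amp, water_sd = water_sd,
       air_sd = air_sd, air_offset = air_offset)
}

#' Simulate an intertidal temperature series
#'
#' Emulates a mid-intertidal logger with 0.5 degC resolution whose readings
#' alternate between submerged (high tide, "water") and emersed (low tide,
#' "air") on a fixed 6-hour schedule. Air readings are noisier than water
#' readings; both ride an annual sinusoid.
#'
#' @param profile A [temp_profile()].
#' @param start,end POSIXct (or coercible) range; `end` must exceed `start`.
#' @param interval_h Reading interval in hours; must divide the 6-h tide
#'   half-cycle.
#' @param seed Integer seed.
#' @return Tibble with `timestamp`, `temp` (degC, quantised to 0.5) and
#'   `tide` ("water"/"air").
#' @export
simulate_temperature <- function(profile = temp_profile(),
                                 start = "2013-01-01", end = "2014-01-01",
                                 interval_h = 1, seed = 1) {
  start <- as.POSIXct(start, tz = "UTC")
  end <- as.POSIXct(end, tz = "UTC")
  if (end <= start) abort("`end` must be after `start`", class = "seascapr_range_error")
  if (6 %% interval_h != 0) {
    abort("interval_h must divide the 6-hour tide half-cycle",
          class = "seascapr_param_error")
  }
  with_seed(seed, {
    ts <- seq(start, end, by = interval_h * 3600)
    hours <- as.numeric(difftime(ts, start, units = "hours"))
    tide <- ifelse(floor(hours / 6) %% 2 == 0, "water", "air")
    seasonal <- profile$mean +
      profile$annual_amp * sin(2 * pi * hours / (365.25 * 24))
    noise_sd <- ifelse(tide == "water", profile$water_sd, profile$air_sd)
    temp <- seasonal + ifelse(tide == "air", profile$air_offset, 0) +
      rnorm(length(ts), 0, noise_sd)
    tibble(timestamp = ts, temp = quantise(temp, 0.5), tide = tide)
  })
}

#' Synthetic site coordinates
#'
#' Lays sites out along a roughly meridional coastline inside the default
#' ocean model domain, mirroring a latitudinal sampling design.
#'
#' @param n Number of sites.
#' @param lon,lat_range Longitude of the coastline and latitude span.
#' @return Tibble with `site`, `lon`, `lat`.
#' @export
synthetic_sites <- function(n = 9, lon = -6, lat_range = c(34, 54)) {
  tibble(
    site = sprintf("site%d", seq_len(n)),
    lon = lon + 0.3 * sin(seq_len(n)),
    lat = seq(lat_range[2], lat_range[1], length.out = n)
  )
}

#' Simulate per-site environmental covariates
#'
#' Builds the covariate table used by the genotype-environment association
#' power tests. By default a single standardised latitudinal gradient.
#'
#' @param sites Tibble with `site` and `lat` columns (e.g.
#'   [synthetic_sites()]), or a character vector of site names.
#' @param gradient Either `"latitude"` (default), a numeric vector with one
#'   value per site, or a named list of such vectors (one variable each).
#' @return Tibble with `site` plus one column per variable.
#' @export
simulate_environment <- function(sites, gradient = "latitude") {
  if (is.character(sites)) sites <- tibble(site = sites, lat = seq_along(sites))
  n <- nrow(sites)
  as_var <- function(gr) {
    if (identical(gr, "latitude")) {
      as.numeric(scale(sites$lat))
    } else {
      if (length(gr) != n) abort("one value per site required")
      as.numeric(gr)
    }
  }
  if (!is.list(gradient)) gradient <- list(env = gradient)
  vars <- map(gradient, as_var)
  bind_cols(tibble(site = sites$site), as_tibble(vars))
}
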