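test_that("constant series have zero spread in every metric", {
  ts <- simulate_temperature(temp_profile(mean = 10, annual_amp = 0,
                                          water_sd = 0, air_sd = 0),
                             start = "2013-01-01", end = "2013-03-01")
  tm <- thermal_metrics(ts)
  expect_equal(tm$mean, 10)
  expect_equal(tm$sd, 0)
  expect_equal(tm$range, 0)
  expect_equal(tm$p95_p5, 0)
  expect_equal(tm$daily_range, 0)
  expect_equal(tm$water_mean, 10)
  expect_equal(tm$air_range, 0)
})

test_that("every metric equals an independently coded oracle", {
  s <- simulate_temperature(temp_profile(), start = "2013-01-01",
                            end = "2014-01-01", seed = 14)
  tm <- thermal_metrics(s)
  x <- s$temp
  expect_equal(tm$mean, sum(x) / length(x))
  expect_equal(tm$max, max(x)); expect_equal(tm$min, min(x))
  expect_equal(tm$range, max(x) - min(x))
  expect_equal(tm$sd, sqrt(sum((x - mean(x))^2) / (length(x) - 1)))
  qs <- quantile(x, c(0.05, 0.95), names = FALSE)
  expect_equal(tm$p95_p5, qs[2] - qs[1])
  days <- split(x, as.Date(s$timestamp, tz = "UTC"))
  days <- days[lengths(days) >= 12]
  expect_equal(tm$daily_range, mean(vapply(days, function(v) max(v) - min(v),
                                           numeric(1))))
  expect_equal(tm$daily_sd, mean(vapply(days, sd, numeric(1))))
  for (fl in c("water", "air")) {
    v <- x[s$tide == fl]
    expect_equal(tm[[paste0(fl, "_mean")]], mean(v))
    expect_equal(tm[[paste0(fl, "_max")]], max(v))
    expect_equal(tm[[paste0(fl, "_min")]], min(v))
    expect_equal(tm[[paste0(fl, "_range")]], max(v) - min(v))
  }
})

test_that("metrics are invariant to record order", {
  s <- simulate_temperature(temp_profile(), seed = 15)
  shuffled <- s[withr::with_seed(1, sample(nrow(s))), ]
  expect_equal(thermal_metrics(shuffled), thermal_metrics(s),
               ignore_attr = TRUE)
})

test_that("the published thermal table reproduces its own ranges", {
  tab <- read_thermal_table()
  for (st in setdiff(names(tab), c("block", "parameter"))) {
    blk <- tab[tab$block == "all", ]
    expect_equal(blk[[st]][blk$parameter == "range"],
                 blk[[st]][blk$parameter == "max"] -
                   blk[[st]][blk$parameter == "min"],
                 tolerance = 0.015, label = st)
  }
})

test_that("independent demes leave no covariance beyond the centering term", {
  # centring on the cross-site mean fixes off-diagonal correlations at
  # -1/(J-1) for exchangeable demes; equal drift adds nothing beyond it
  g <- bn_panel(n_sites = 9, n_per_site = 30, n_loci = 1000,
                target_fst = 0.15, seed = 71)
  cm <- estimate_covariance(g)
  rho <- stats::cov2cor(cm$omega)
  off <- rho[lower.tri(rho)]
  expect_lt(abs(mean(off) - (-1 / 8)), 0.02)
  expect_true(all(abs(off - (-1 / 8)) < 0.09))  # ~3 sd at 1000 loci
  dg <- diag(cm$omega)
  expect_lt(max(dg) / min(dg), 1.3)   # equal drift, equal diagonal
  expect_true(all(eigen(cm$omega, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("duplicated site columns yield identical covariance rows", {
  g <- bn_panel(n_sites = 3, n_per_site = 10, n_loci = 60, seed = 72)
  d <- geno_dosage(g)
  twin_rows <- which(g$site == "site3")
  g2 <- geno_tbl(rbind(d, d[twin_rows, ]),
                 c(g$site, rep("twin", length(twin_rows))),
                 c(g$individual, paste0("t", seq_along(twin_rows))))
  cm <- estimate_covariance(g2)
  expect_equal(unname(cm$omega["twin", c("site1", "site2")]),
               unname(cm$omega["site3", c("site1", "site2")]))
  expect_error(estimate_covariance(select_loci(g, 1:10)), "at least 30")
})

test_that("the BF scan is calibrated under the null and powered on clines", {
  env <- simulate_environment(synthetic_sites(6))
  g0 <- bn_panel(n_sites = 6, n_per_site = 12, n_loci = 400,
                 target_fst = 0.15, seed = 51)
  cov0 <- estimate_covariance(g0)
  scan0 <- bayes_factor_scan(g0, env, cov0)
  expect_lte(mean(scan0$flagged), 0.05)
  gp <- simulate_genotypes(sim_params(
    n_sites = 6, n_per_site = 12, n_loci = 200, target_fst = 0.15,
    inbreeding_f = 0, frac_balancing = 0, frac_env_assoc = 0.15,
    env_effect = 2, isolated_site = NULL, missing_rate = 0, seed = 52))
  covp <- estimate_covariance(select_loci(gp, geno_loci(gp)$class == "neutral"))
  scanp <- bayes_factor_scan(gp, env, covp)
  truth <- geno_loci(gp)$locus[geno_loci(gp)$class == "env_assoc"]
  expect_gt(mean(scanp$flagged[match(truth, scanp$locus)], na.rm = TRUE), 0.5)
})

test_that("the Bayes factor is invariant to the sign of the environment", {
  env <- simulate_environment(synthetic_sites(6))
  g <- bn_panel(n_sites = 6, n_per_site = 10, n_loci = 100,
                target_fst = 0.15, seed = 53)
  cov <- estimate_covariance(g)
  s1 <- bayes_factor_scan(g, env, cov)
  env$env <- -env$env
  s2 <- bayes_factor_scan(g, env, cov)
  expect_equal(s2$bf, s1$bf)
})

test_that("grid integration matches a fine-grid oracle within 1%", {
  env <- simulate_environment(synthetic_sites(6))
  g <- bn_panel(n_sites = 6, n_per_site = 10, n_loci = 80,
                target_fst = 0.15, seed = 54)
  cov <- estimate_covariance(g)
  coarse <- bayes_factor_scan(g, env, cov,
                              grid_spec = list(n = 201, half_width = 5,
                                               prior_sd = 1))
  fine <- bayes_factor_scan(g, env, cov,
                            grid_spec = list(n = 4001, half_width = 5,
                                             prior_sd = 1))
  expect_lt(max(abs(coarse$bf - fine$bf) / fine$bf), 0.01)
})

test_that("GEA results are invariant to locus order", {
  env <- simulate_environment(synthetic_sites(6))
  g <- bn_panel(n_sites = 6, n_per_site = 10, n_loci = 60,
                target_fst = 0.15, seed = 55)
  cov <- estimate_covariance(g)
  s1 <- bayes_factor_scan(g, env, cov)
  gp <- select_loci(g, rev(seq_len(n_loci(g))))
  s2 <- bayes_factor_scan(gp, env, cov)
  m <- match(s1$locus, s2$locus)
  expect_equal(s2$bf[m], s1$bf)
})

test_that("constant environment variables are skipped with a warning", {
  g <- bn_panel(n_sites = 4, n_per_site = 10, n_loci = 60,
                target_fst = 0.15, seed = 56)
  cov <- estimate_covariance(g)
  env <- tibble::tibble(site = sprintf("site%d", 1:4), flat = rep(1, 4),
                        ok = c(1, 2, 3, 4))
  expect_warning(res <- bayes_factor_scan(g, env, cov), "flat")
  expect_setequal(unique(res$variable), "ok")
})
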