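test_that("per-locus FST/He behaves at the fixation extremes", {
  d <- cbind(L1 = c(rep(0L, 5), rep(2L, 5)),   # fixed for opposite alleles
             L2 = rep(c(0L, 1L, 1L, 2L, 1L), 2),
             L3 = rep(1L, 10))                 # het everywhere
  g <- geno_tbl(d, rep(c("a", "b"), each = 5))
  lf <- locus_fst_he(g)
  l1 <- lf[lf$locus == "L1", ]
  expect_gt(l1$fst, 0.9)
  expect_equal(l1$he, 0)   # no within-deme diversity
  l2 <- lf[lf$locus == "L2", ]
  expect_lt(abs(l2$fst), 0.15)
})

test_that("monomorphic loci are excluded and logged", {
  d <- cbind(L1 = rep(0L, 6), L2 = c(0L, 1L, 2L, 0L, 1L, 2L))
  g <- geno_tbl(d, rep(c("a", "b"), each = 3))
  lf <- locus_fst_he(g)
  expect_identical(lf$locus, "L2")
  expect_identical(attr(lf, "excluded"), "L1")
})

test_that("the FDIST null self-calibrates to its target median", {
  sizes <- c(6, 8, 9, 11, 12, 7, 4, 5, 6)
  null <- fdist_null(0.28, sizes, n_sim = 20000, seed = 5)
  expect_lt(abs(median(null$draws$fst) - 0.28), 0.01)
  null0 <- fdist_null(0, sizes, n_sim = 5000, seed = 6)
  expect_lt(abs(median(null0$draws$fst)), 0.02)
})

test_that("ancestral heterozygosity honours the rejection bound", {
  null <- fdist_null(0.2, c(10, 10, 10), n_sim = 2000, max_he = 0.3,
                     seed = 7)
  expect_true(all(null$draws$he_anc <= 0.3))
})

test_that("fdist p-values equal a direct tail count over the stored draws", {
  g <- bn_panel(n_sites = 4, n_per_site = 12, n_loci = 60,
                target_fst = 0.2, seed = 8)
  lf <- locus_fst_he(g)
  null <- fdist_null(0.2, rep(12, 4), n_sim = 5000, seed = 9)
  fp <- fdist_pvalues(lf, null, he_bin_width = 0.1, min_draws = 100)
  for (i in c(1, 17, 42)) {
    w <- 0.05
    repeat {
      sel <- abs(null$draws$he - lf$he[i]) <= w
      if (sum(sel) >= 100) break
      w <- w * 1.5
    }
    expect_equal(fp$p_upper[i],
                 mean(null$draws$fst[sel] >= lf$fst[i] - 1e-12))
    expect_equal(fp$p_lower[i],
                 mean(null$draws$fst[sel] <= lf$fst[i] + 1e-12))
  }
  mid <- which.min(abs(lf$fst - median(null$draws$fst)))
  expect_gt(fp$p_upper[mid], 0.2)
  expect_gt(fp$p_lower[mid], 0.2)
})

test_that("balancing loci are caught in the lower tail with good power", {
  g <- simulate_genotypes(sim_params(
    n_sites = 9, n_per_site = 50, n_loci = 400, target_fst = 0.28,
    inbreeding_f = 0, frac_balancing = 0.25, isolated_site = NULL,
    missing_rate = 0, seed = 33))
  lf <- locus_fst_he(g)
  null <- fdist_null(0.28, rep(50, 9), n_sim = 20000, seed = 34)
  fp <- fdist_pvalues(lf, null)
  truth <- geno_loci(g)$locus[geno_loci(g)$class == "balancing"]
  hit <- fp$direction[match(truth, fp$locus)] == "balancing"
  expect_gt(mean(hit, na.rm = TRUE), 0.5)
})

test_that("the F-model flags almost nothing on neutral panels", {
  g <- bn_panel(n_sites = 9, n_per_site = 10, n_loci = 150,
                target_fst = 0.1, seed = 21)
  fm <- fmodel_scan(g, mcmc = list(n_iter = 3000, burn_in = 1000, thin = 5),
                    seed = 2)
  expect_lte(mean(fm$loci$post_prob >= 0.95), 0.01)
})

test_that("strong divergent loci earn high inclusion with positive alpha", {
  g <- simulate_genotypes(sim_params(
    n_sites = 9, n_per_site = 15, n_loci = 150, target_fst = 0.18,
    inbreeding_f = 0, frac_balancing = 0, frac_divergent = 0.1,
    isolated_site = NULL, missing_rate = 0, seed = 22))
  fm <- fmodel_scan(g, mcmc = list(n_iter = 4000, burn_in = 1500, thin = 5),
                    seed = 3)
  truth <- geno_loci(g)$locus[geno_loci(g)$class == "divergent"]
  rows <- match(truth, fm$loci$locus)
  hit <- fm$loci$post_prob[rows] >= 0.95 & fm$loci$alpha_mean[rows] > 0
  expect_gt(mean(hit, na.rm = TRUE), 0.5)
  neutral <- setdiff(fm$loci$locus, truth)
  expect_lte(mean(fm$loci$post_prob[match(neutral, fm$loci$locus)] >= 0.95),
             0.01)
})

test_that("posterior inclusion rises along a graded effect ladder", {
  # loci drawn at drift c = 0.1 / 0.45 / 0.85 against a c = 0.1 background
  freqs_at <- function(cc, L, seed) {
    withr::with_seed(seed, {
      p <- runif(L, 0.2, 0.5)
      matrix(rbeta(L * 6, rep(p * (1 - cc) / cc, 6),
                   rep((1 - p) * (1 - cc) / cc, 6)), L, 6)
    })
  }
  fr <- rbind(freqs_at(0.1, 60, 1), freqs_at(0.45, 15, 2),
              freqs_at(0.85, 15, 3))
  g <- panel_from_freqs(fr, n_per_site = 15, seed = 4)
  fm <- fmodel_scan(g, mcmc = list(n_iter = 3000, burn_in = 1000, thin = 5),
                    seed = 5)
  grp <- rep(c("bg", "mid", "high"), c(60, 15, 15))
  mean_p <- tapply(fm$loci$post_prob[match(sprintf("L%04d", 1:90),
                                           fm$loci$locus)],
                   grp, mean, na.rm = TRUE)
  expect_lt(mean_p[["bg"]], mean_p[["mid"]])
  expect_lt(mean_p[["mid"]], mean_p[["high"]])
})

test_that("monomorphic loci never enter the chain", {
  d <- cbind(L1 = rep(0L, 8), L2 = rep(c(0L, 1L, 2L, 1L), 2))
  g <- geno_tbl(d, rep(c("a", "b"), each = 4))
  fm <- fmodel_scan(g, mcmc = list(n_iter = 200, burn_in = 50, thin = 2))
  expect_identical(fm$loci$locus, "L2")
})

test_that("consensus calling is the conservative intersection", {
  fd <- tibble::tibble(locus = c("A", "B", "C", "D"),
                       outlier = c(TRUE, TRUE, TRUE, FALSE),
                       direction = c("balancing", "balancing", "divergent",
                                     "neutral"))
  fm <- structure(list(loci = tibble::tibble(
    locus = c("A", "B", "C", "D"),
    post_prob = c(0.2, 0.99, 0.97, 0.99),
    direction = c("balancing", "balancing", "divergent", "divergent"))),
    class = "fmodel_result")
  res <- consensus_outliers(fd, fm, total_loci = 482)
  expect_setequal(res$consensus$locus, c("B", "C"))
  expect_true(all(res$consensus$locus %in% res$fdist))
  expect_true(all(res$consensus$locus %in% res$fmodel))
  # percentage bookkeeping at the published panel size
  expect_equal(outlier_pct(27, 482), 5.60)
  expect_equal(outlier_pct(191, 482), 39.63)
  fm_disjoint <- structure(list(loci = tibble::tibble(
    locus = "Z", post_prob = 1, direction = "divergent")),
    class = "fmodel_result")
  expect_error(consensus_outliers(fd, fm_disjoint, 482), "no loci")
})

test_that("removing consensus outliers moves FST toward the neutral truth", {
  g <- simulate_genotypes(sim_params(
    n_sites = 6, n_per_site = 20, n_loci = 120, target_fst = 0.18,
    inbreeding_f = 0, frac_divergent = 0.15, frac_balancing = 0,
    isolated_site = NULL, missing_rate = 0, seed = 55))
  loci <- geno_loci(g)
  fst_all <- overall_fst(g)
  fst_neutral_truth <- overall_fst(select_loci(g, loci$class == "neutral"))
  lf <- locus_fst_he(g)
  null <- fdist_null(median(lf$fst), rep(20, 6), n_sim = 10000, seed = 56)
  fd <- fdist_pvalues(lf, null)
  fm <- fmodel_scan(g, mcmc = list(n_iter = 3000, burn_in = 1000, thin = 5),
                    seed = 57)
  cons <- consensus_outliers(fd, fm, n_loci(g))
  expect_gt(nrow(cons$consensus), 0)
  fst_trim <- overall_fst(select_loci(g, setdiff(loci$locus,
                                                 cons$consensus$locus)))
  expect_lt(abs(fst_trim - fst_neutral_truth),
            abs(fst_all - fst_neutral_truth) + 1e-9)
})
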