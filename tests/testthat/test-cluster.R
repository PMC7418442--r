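test_that("K = 1 forces a degenerate admixture matrix", {
  g <- bn_panel(n_sites = 2, n_per_site = 6, n_loci = 20, seed = 2)
  r <- admixture_gibbs(g, K = 1, n_iter = 80, burn_in = 30, seed = 1)
  expect_true(all(r$Q == 1))
  expect_error(admixture_gibbs(g, K = 13, n_iter = 10, burn_in = 2),
               "exceeds")
  expect_error(admixture_gibbs(g, K = 2, n_iter = 10, burn_in = 20),
               "burn_in")
})

test_that("two well-separated demes are assigned with >= 95% accuracy", {
  g <- bn_panel(n_sites = 2, n_per_site = 20, n_loci = 80,
                target_fst = 0.3, seed = 41)
  r <- admixture_gibbs(g, K = 2, n_iter = 600, burn_in = 200, seed = 5)
  assign <- apply(r$Q, 1, which.max)
  acc <- max(mean((assign == 1) == (g$site == "site1")),
             mean((assign == 2) == (g$site == "site1")))
  expect_gte(acc, 0.95)
  expect_equal(unname(rowSums(r$Q)), rep(1, nrow(r$Q)),
               tolerance = 1e-9)
  expect_length(r$ll_trace, 600)
})

test_that("cluster assignments are equivariant to individual order", {
  g <- bn_panel(n_sites = 2, n_per_site = 15, n_loci = 80,
                target_fst = 0.35, seed = 43)
  d <- geno_dosage(g)
  perm <- withr::with_seed(2, sample(nrow(d)))
  gp <- geno_tbl(d[perm, ], g$site[perm], g$individual[perm])
  r1 <- admixture_gibbs(g, 2, n_iter = 500, burn_in = 200, seed = 6)
  r2 <- admixture_gibbs(gp, 2, n_iter = 500, burn_in = 200, seed = 7)
  a1 <- apply(r1$Q, 1, which.max)[g$individual]
  a2 <- apply(r2$Q, 1, which.max)[g$individual]
  agree <- max(mean(a1 == a2), mean(a1 != a2))  # up to label switching
  expect_gte(agree, 0.95)
})

test_that("posterior admixture tracks a graded truth ladder", {
  # individuals mixing two deme frequency vectors with known weights
  withr::with_seed(11, {
    L <- 120
    pA <- runif(L, 0.05, 0.35); pB <- runif(L, 0.65, 0.95)
    q_true <- rep(c(1, 0.75, 0.5, 0.25, 0), each = 8)
    dos <- t(vapply(q_true, function(q) {
      z1 <- rbinom(L, 1, q); z2 <- rbinom(L, 1, q)
      a1 <- rbinom(L, 1, ifelse(z1 == 1, pA, pB))
      a2 <- rbinom(L, 1, ifelse(z2 == 1, pA, pB))
      as.integer(a1 + a2)
    }, integer(L)))
    colnames(dos) <- sprintf("L%03d", seq_len(L))
    g <- geno_tbl(dos, sites = rep("mix", length(q_true)))
  })
  r <- admixture_gibbs(g, K = 2, n_iter = 800, burn_in = 300, seed = 8)
  corr <- abs(cor(r$Q[, 1], q_true))
  expect_gt(corr, 0.9)
})

test_that("Evanno delta-K picks the planted two-cluster structure", {
  g <- bn_panel(n_sites = 2, n_per_site = 20, n_loci = 80,
                target_fst = 0.3, seed = 41)
  runs <- list()
  for (K in 1:5) {
    for (rep in 1:3) {
      runs[[length(runs) + 1L]] <- admixture_gibbs(
        g, K, n_iter = 400, burn_in = 150, seed = 100 * K + rep)
    }
  }
  ev <- evanno_deltaK(runs)
  expect_identical(attr(ev, "best_k"), 2L)
  expect_true(is.na(ev$delta_k[ev$K == 1]))
  expect_true(is.na(ev$delta_k[ev$K == 5]))
  # replicate order invariance
  ev2 <- evanno_deltaK(rev(runs))
  expect_equal(ev2$delta_k, ev$delta_k)
  expect_error(evanno_deltaK(runs[1:5]), "consecutive")
})

test_that("DAPC separates distinct clusters and not identical ones", {
  g <- bn_panel(n_sites = 2, n_per_site = 20, n_loci = 100,
                target_fst = 0.4, seed = 61)
  dp <- suppressWarnings(dapc(g, n_pc = 10, n_df = 2))
  expect_equal(dp$accuracy, 1)
  expect_identical(dp$n_df, 1L)  # clipped to groups - 1, with a warning
  expect_warning(dapc(g, n_pc = 10, n_df = 2), "clipped")
  g0 <- bn_panel(n_sites = 2, n_per_site = 20, n_loci = 100,
                 target_fst = 1e-4, seed = 62)
  dp0 <- suppressWarnings(dapc(g0, n_pc = 10, n_df = 2))
  expect_lt(dp0$accuracy, 0.75)
})

test_that("DAPC centroids are invariant to duplicating every individual", {
  g <- bn_panel(n_sites = 3, n_per_site = 10, n_loci = 60,
                target_fst = 0.3, seed = 63)
  d <- geno_dosage(g)
  g2 <- geno_tbl(rbind(d, d), c(g$site, g$site),
                 c(g$individual, paste0(g$individual, "_dup")))
  dp1 <- dapc(g, n_pc = 8, n_df = 2)
  dp2 <- dapc(g2, n_pc = 8, n_df = 2)
  # axes are defined up to sign and an overall scale; normalise both by the
  # spread of the individual coordinates before comparing
  for (j in 1:2) {
    ax <- colnames(dp1$centroids)[j]
    s1 <- sd(dp1$coords[[ax]]); s2 <- sd(dp2$coords[[ax]])
    expect_equal(abs(dp2$centroids[rownames(dp1$centroids), j]) / s2,
                 abs(dp1$centroids[, j]) / s1, tolerance = 0.02)
  }
})

test_that("DAPC coordinates are invariant (up to sign) to locus order", {
  g <- bn_panel(n_sites = 2, n_per_site = 12, n_loci = 50,
                target_fst = 0.3, seed = 64)
  d <- geno_dosage(g)
  gp <- geno_tbl(d[, rev(seq_len(ncol(d)))], g$site, g$individual)
  dp1 <- suppressWarnings(dapc(g, n_pc = 6, n_df = 1))
  dp2 <- suppressWarnings(dapc(gp, n_pc = 6, n_df = 1))
  expect_equal(abs(dp2$coords$LD1), abs(dp1$coords$LD1), tolerance = 1e-6)
})
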