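zero_field <- function(res = 0.5) {
  make_velocity_field(field_spec(flow_kind = "zero", resolution = res))
}
one_site <- tibble::tibble(site = "s1", lon = -8, lat = 44)

test_that("release schedules carry the exact event counts", {
  s9 <- synthetic_sites(9)
  cons <- build_release_schedule("conservative", s9)
  expect_identical(nrow(cons), 9L * 28L)      # 6-hourly over 7 days
  opt <- build_release_schedule("optimistic", s9, n_days = 365)
  expect_identical(nrow(opt), 9L * 365L)
  single <- build_release_schedule("optimistic", one_site, n_days = 1)
  expect_identical(nrow(single), 1L)
  expect_error(build_release_schedule("reckless", s9))
})

test_that("dispersal configuration enforces its invariants", {
  expect_error(dispersal_config(competency_weeks = 12, max_pld_weeks = 12),
               class = "seascapr_param_error")
  expect_error(dispersal_config(checkpoints_weeks = 14),
               class = "seascapr_param_error")
  expect_error(dispersal_config(settlement_radius_km = 0),
               class = "seascapr_param_error")
})

test_that("still water and zero diffusivity hold particles in place", {
  cfg <- dispersal_config(kh = 0, competency_weeks = 0.5, max_pld_weeks = 1,
                          checkpoints_weeks = 1, propagules_per_event = 2)
  sched <- build_release_schedule("optimistic", one_site, n_days = 1)
  tr <- advect_particles(zero_field(), sched, cfg)
  expect_true(all(tr$lon == -8) && all(tr$lat == 44))
})

test_that("constant-flow advection is exact (RK4 on a uniform field)", {
  fld <- make_velocity_field(field_spec(flow_kind = "uniform",
                                        amplitude = c(0.1, 0),
                                        resolution = 0.5))
  cfg <- dispersal_config(kh = 0, competency_weeks = 0.5, max_pld_weeks = 1,
                          checkpoints_weeks = 1, propagules_per_event = 1)
  sched <- build_release_schedule("optimistic", one_site, n_days = 1)
  tr <- advect_particles(fld, sched, cfg)
  h <- 24
  disp_m <- (tr$lon[1, h + 1] - tr$lon[1, 1]) * pi * 6371000 / 180 *
    cos(44 * pi / 180)
  expect_equal(disp_m, 0.1 * h * 3600, tolerance = 1e-6)
  expect_equal(max(abs(tr$lat[1, ] - 44)), 0)
})

test_that("the diffusive kick reproduces the 2-D diffusion law", {
  cfg <- dispersal_config(kh = 15, competency_weeks = 0.5, max_pld_weeks = 1,
                          checkpoints_weeks = 1,
                          propagules_per_event = 10000, seed = 3)
  sched <- build_release_schedule("optimistic", one_site, n_days = 1)
  tr <- advect_particles(zero_field(), sched, cfg)
  h <- 24
  m_per_deg <- pi * 6371000 / 180
  dx <- (tr$lon[, h + 1] - tr$lon[, 1]) * m_per_deg * cos(tr$lat[, h + 1] * pi / 180)
  dy <- (tr$lat[, h + 1] - tr$lat[, 1]) * m_per_deg
  msd <- mean(dx^2 + dy^2)
  expect_lt(abs(msd / (4 * 15 * h * 3600) - 1), 0.05)
})

test_that("release on land is rejected", {
  land_west <- function(lon, lat) lon < -6
  fld <- make_velocity_field(field_spec(land = land_west))
  sched <- build_release_schedule("optimistic", one_site, n_days = 1)
  expect_error(advect_particles(fld, sched, dispersal_config()),
               class = "seascapr_placement_error")
})

test_that("a stationary particle at a reef self-recruits at first competency", {
  cfg <- dispersal_config(kh = 0, competency_weeks = 0.5, max_pld_weeks = 1,
                          checkpoints_weeks = 1, propagules_per_event = 4)
  sched <- build_release_schedule("optimistic", one_site, n_days = 1)
  tr <- advect_particles(zero_field(), sched, cfg)
  cm <- settle_and_count(tr, one_site, cfg)
  expect_equal(cm$self_recruitment$self_recruitment, 1)
  expect_true(all(cm$fates$fate == "settled"))
  expect_equal(unique(cm$fates$age_h), ceiling(0.5 * 7 * 24))
})

test_that("settlement respects competency in a hand-built geometry", {
  # particle 1 crosses the 5-km disc before competency only; particle 2
  # after; particle 3 never
  cfg <- dispersal_config(kh = 0, competency_weeks = 4, max_pld_weeks = 12,
                          propagules_per_event = 1)
  n <- cfg$max_pld_weeks * 7 * 24
  comp <- 4 * 7 * 24
  far <- -6; near <- -8.01   # ~0.8 km from the reef at -8
  lon <- rbind(c(rep(near, comp - 10), rep(far, n + 1 - (comp - 10))),
               c(rep(far, comp + 5), rep(near, n + 1 - (comp + 5))),
               rep(far, n + 1))
  lat <- matrix(44, 3, n + 1)
  tr <- forge_traj(lon, lat, source = c("s1", "s1", "s1"), config = cfg)
  cm <- settle_and_count(tr, one_site, cfg)
  expect_identical(cm$fates$fate, c("expired", "settled", "expired"))
  expect_identical(cm$fates$age_h[2], as.double(comp + 5))
})

test_that("connectivity counts are cumulative and conserve particles", {
  s4 <- synthetic_sites(4)
  fld <- make_velocity_field(field_spec(flow_kind = "coastal_retention",
                                        reef_sites = s4, resolution = 0.25,
                                        amplitude = 0.3))
  cfg <- dispersal_config(propagules_per_event = 2, max_pld_weeks = 6,
                          checkpoints_weeks = c(5, 6), seed = 4)
  sched <- build_release_schedule("conservative", s4)
  tr <- advect_particles(fld, sched, cfg)
  cm <- settle_and_count(tr, s4, cfg)
  expect_true(all(cm$counts[, , 2] >= cm$counts[, , 1]))
  tab <- table(factor(cm$fates$fate,
                      levels = c("settled", "expired", "exited")),
               factor(cm$fates$source, levels = cm$sources))
  expect_identical(as.integer(colSums(tab)), cm$released)
  expect_true(all(cm$proportions >= 0 & cm$proportions <= 1))
})

test_that("identical seeds give identical fates", {
  s2 <- synthetic_sites(2)
  fld <- make_velocity_field(field_spec(flow_kind = "coastal_retention",
                                        reef_sites = s2, resolution = 0.5))
  cfg <- dispersal_config(propagules_per_event = 3, max_pld_weeks = 5,
                          checkpoints_weeks = 5, seed = 9)
  sched <- build_release_schedule("conservative", s2)
  f1 <- settle_and_count(advect_particles(fld, sched, cfg), s2, cfg)$fates
  f2 <- settle_and_count(advect_particles(fld, sched, cfg), s2, cfg)$fates
  expect_identical(f1, f2)
})

test_that("diffusivity erodes retention in a closed-eddy field", {
  s1 <- synthetic_sites(1)
  fld <- make_velocity_field(field_spec(flow_kind = "coastal_retention",
                                        reef_sites = s1, resolution = 0.25,
                                        amplitude = 0.3))
  sched <- build_release_schedule("conservative", s1)
  self_at <- function(kh) {
    cfg <- dispersal_config(kh = kh, propagules_per_event = 4,
                            max_pld_weeks = 6, checkpoints_weeks = 6,
                            seed = 10)
    cm <- settle_and_count(advect_particles(fld, sched, cfg), s1, cfg)
    cm$self_recruitment$self_recruitment
  }
  ladder <- c(self_at(0), self_at(15), self_at(60))
  expect_gte(ladder[1] + 0.05, ladder[2])
  expect_gte(ladder[2] + 0.05, ladder[3])
  expect_equal(ladder[1], 1)   # zero diffusivity: the eddy never lets go
})

test_that("resistance is one minus the settlement proportion, symmetrised", {
  cm <- structure(list(
    counts = array(c(80L, 15L, 25L, 70L), c(2, 2, 1),
                   dimnames = list(c("a", "b"), c("a", "b"), "wk5")),
    proportions = array(c(0.8, 0.15, 0.25, 0.7), c(2, 2, 1),
                        dimnames = list(c("a", "b"), c("a", "b"), "wk5")),
    released = c(100L, 100L), sources = c("a", "b"),
    destinations = c("a", "b"), checkpoints_weeks = 5), class = "connectivity")
  R <- resistance(cm, 5)
  expect_equal(R$values["a", "b"], 1 - (0.25 + 0.15) / 2)  # 0.80
  expect_true(all(R$values >= 0 & R$values <= 1))
  cm$released <- c(0L, 100L)
  expect_error(resistance(cm, 5), class = "seascapr_param_error")
  expect_error(resistance(cm, 9), "checkpoint")
})

test_that("full retention gives unit off-diagonal resistance", {
  pr <- diag(2); dimnames(pr) <- list(c("a", "b"), c("a", "b"))
  cm <- structure(list(
    counts = array(100L * pr, c(2, 2, 1),
                   dimnames = list(c("a", "b"), c("a", "b"), "wk5")),
    proportions = array(pr, c(2, 2, 1),
                        dimnames = list(c("a", "b"), c("a", "b"), "wk5")),
    released = c(100L, 100L), sources = c("a", "b"),
    destinations = c("a", "b"), checkpoints_weeks = 5), class = "connectivity")
  R <- resistance(cm, 5)
  expect_equal(R$values["a", "b"], 1)
  expect_equal(R$values["b", "a"], 1)
})

test_that("density maps conserve sampled mass and trace the plume", {
  # stationary particle, hourly sampling: all mass in one cell
  cfg <- dispersal_config(kh = 0, competency_weeks = 0.5, max_pld_weeks = 1,
                          checkpoints_weeks = 1, propagules_per_event = 1)
  sched <- build_release_schedule("optimistic", one_site, n_days = 1)
  fld <- zero_field()
  tr <- advect_particles(fld, sched, cfg)
  dm <- density_map(tr, fld, every_h = 1)
  expect_identical(sum(dm$counts > 0), 1L)
  expect_equal(sum(dm$counts), dm$total)
  expect_equal(dm$total, tr$n_steps + 1)
  # uniform flow: occupied cells form a band along the flow axis
  fldu <- make_velocity_field(field_spec(flow_kind = "uniform",
                                         amplitude = c(0.5, 0),
                                         resolution = 0.5))
  tru <- advect_particles(fldu, sched, cfg)
  dmu <- density_map(tru, fldu, every_h = 24)
  occ <- which(dmu$counts > 0, arr.ind = TRUE)
  expect_identical(length(unique(occ[, 2])), 1L)   # single latitude row
  expect_gt(length(unique(occ[, 1])), 3)           # spread across longitudes
  expect_equal(sum(dmu$counts), dmu$total)
})
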