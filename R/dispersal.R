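#' Larval dispersal configuration
#'
#' Defaults follow the standard passive-larva setup for reef-building
#' polychaetes: hourly time steps, horizontal diffusivity 15 m^2 s^-1
#' (vertical 0.05 m^2 s^-1, held for a future 3-D extension and unused by
#' the 2-D core), competency to settle from 4 weeks of age, a maximum
#' planktonic larval duration (PLD) of 12 weeks, settlement within 5 km of
#' a known reef site, connectivity checkpoints at 5, 8, 10 and 12 weeks,
#' and 100 propagules per release event.
#'
#' @param step_h Time step in hours.
#' @param kh,kv Horizontal/vertical diffusivity (m^2 s^-1).
#' @param competency_weeks Age at which settlement becomes possible.
#' @param max_pld_weeks Maximum PLD.
#' @param settlement_radius_km Settlement radius around a reef site.
#' @param checkpoints_weeks PLD checkpoints for connectivity counts.
#' @param propagules_per_event Particles released per release event.
#' @param seed Integer seed.
#' @export
dispersal_config <- function(step_h = 1, kh = 15, kv = 0.05,
                             competency_weeks = 4, max_pld_weeks = 12,
                             settlement_radius_km = 5,
                             checkpoints_weeks = c(5, 8, 10, 12),
                             propagules_per_event = 100, seed = 1) {
  if (competency_weeks >= max_pld_weeks) {
    abort("competency must precede the maximum PLD",
          class = "seascapr_param_error")
  }
  if (any(checkpoints_weeks > max_pld_weeks)) {
    abort("checkpoints must not exceed the maximum PLD",
          class = "seascapr_param_error")
  }
  if (settlement_radius_km <= 0) {
    abort("settlement radius must be positive", class = "seascapr_param_error")
  }
  structure(list(step_h = step_h, kh = kh, kv = kv,
                 competency_weeks = competency_weeks,
                 max_pld_weeks = max_pld_weeks,
                 settlement_radius_km = settlement_radius_km,
                 checkpoints_weeks = sort(checkpoints_weeks),
                 propagules_per_event = propagules_per_event,
                 seed = as.integer(seed)),
            class = "dispersal_config")
}

#' Build a release schedule
#'
#' Two scenarios: `"conservative"` -- releases every 6 h over 7 days (28
#' events per site), a single spawning week; `"optimistic"` -- one release
#' per day over the simulated year (`n_days` events per site), year-round
#' spawning.
#'
#' @param scenario `"conservative"` or `"optimistic"`.
#' @param sites Tibble with `site`, `lon`, `lat`.
#' @param anchor Start of the release window (POSIXct or coercible).
#' @param n_days Days in the optimistic window (default 365).
#' @return Tibble `site`, `lon`, `lat`, `time`, with the scenario recorded
#'   as an attribute.
#' @export
build_release_schedule <- function(scenario = c("conservative", "optimistic"),
                                   sites, anchor = "2012-04-01",
                                   n_days = 365) {
  scenario <- match.arg(scenario)
  anchor <- as.POSIXct(anchor, tz = "UTC")
  offsets_h <- if (scenario == "conservative") {
    seq(0, 7 * 24 - 1, by = 6)
  } else {
    seq(0, (n_days - 1) * 24, by = 24)
  }
  out <- tidyr::crossing(sites, offset_h = offsets_h) |>
    mutate(time = anchor + .data$offset_h * 3600) |>
    select("site", "lon", "lat", "time")
  attr(out, "scenario") <- scenario
  out
}

#' Advect larvae through a velocity field
#'
#' Hourly 4th-order Runge-Kutta advection on the bilinearly interpolated
#' velocity field, followed by a Gaussian diffusive kick per horizontal axis
#' with standard deviation sqrt(2 Kh dt), converted from metres to degrees
#' at the particle's latitude. A step that would land on a land cell has its
#' kick redrawn up to 5 times, after which the particle holds position for
#' that hour; a particle leaving the grid is marked as exited and frozen.
#'
#' @param field A `velocity_field` from [make_velocity_field()].
#' @param schedule A [build_release_schedule()] tibble.
#' @param config A [dispersal_config()].
#' @return A `trajectory_set`: `lon`/`lat` matrices (particle x step,
#'   including the release position), the per-particle `source` site and
#'   release time, `exit_step` (`NA` if the particle never left the domain)
#'   and the configuration.
#' @export
advect_particles <- function(field, schedule, config = dispersal_config()) {
  cfg <- config
  npr <- cfg$propagules_per_event
  src <- rep(schedule$site, each = npr)
  lon0 <- rep(schedule$lon, each = npr)
  lat0 <- rep(schedule$lat, each = npr)
  t0 <- rep(as.numeric(schedule$time), each = npr)
  P <- length(src)
  if (!all(is_sea(field, lon0, lat0))) {
    bad <- unique(src[!is_sea(field, lon0, lat0)])
    abort(sprintf("release site(s) on land: %s", paste(bad, collapse = ", ")),
          class = "seascapr_placement_error")
  }
  dt <- cfg$step_h * 3600
  n_steps <- as.integer(cfg$max_pld_weeks * 7 * 24 / cfg$step_h)
  LON <- matrix(NA_real_, P, n_steps + 1)
  LAT <- matrix(NA_real_, P, n_steps + 1)
  LON[, 1] <- lon0; LAT[, 1] <- lat0
  exit_step <- rep(NA_integer_, P)
  sig_m <- sqrt(2 * cfg$kh * dt)

  deg_step <- function(lon, lat, t) {
    # RK4 in degree space with latitude-dependent metre conversion
    vel <- function(lo, la) {
      uv <- field_uv(field, lo, la, t)
      list(dlon = uv$u / (.M_PER_DEG * cos(la * pi / 180)),
           dlat = uv$v / .M_PER_DEG)
    }
    k1 <- vel(lon, lat)
    k2 <- vel(lon + dt / 2 * k1$dlon, lat + dt / 2 * k1$dlat)
    k3 <- vel(lon + dt / 2 * k2$dlon, lat + dt / 2 * k2$dlat)
    k4 <- vel(lon + dt * k3$dlon, lat + dt * k3$dlat)
    list(dlon = dt / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon),
         dlat = dt / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat))
  }

  with_seed(cfg$seed, {
    active <- rep(TRUE, P)
    for (s in seq_len(n_steps)) {
      if (!any(active)) {
        LON[, s + 1] <- LON[, s]; LAT[, s + 1] <- LAT[, s]
        next
      }
      ia <- which(active)
      lon <- LON[ia, s]; lat <- LAT[ia, s]
      adv <- deg_step(lon, lat, t0[ia] + (s - 1) * dt)
      out_now <- is.na(adv$dlon)
      base_lon <- lon + ifelse(out_now, 0, adv$dlon)
      base_lat <- lat + ifelse(out_now, 0, adv$dlat)
      new_lon <- base_lon; new_lat <- base_lat
      if (cfg$kh > 0) {
        kx <- rnorm(length(ia), 0, sig_m)
        ky <- rnorm(length(ia), 0, sig_m)
        new_lon <- base_lon + kx / (.M_PER_DEG * cos(base_lat * pi / 180))
        new_lat <- base_lat + ky / .M_PER_DEG
        inside <- new_lon >= field$lon[1] & new_lon <= field$lon[length(field$lon)] &
          new_lat >= field$lat[1] & new_lat <= field$lat[length(field$lat)]
        beached <- inside & !is_sea(field, new_lon, new_lat)
        tries <- 0
        while (any(beached) && tries < 5) {
          nb <- sum(beached)
          new_lon[beached] <- base_lon[beached] +
            rnorm(nb, 0, sig_m) / (.M_PER_DEG * cos(base_lat[beached] * pi / 180))
          new_lat[beached] <- base_lat[beached] + rnorm(nb, 0, sig_m) / .M_PER_DEG
          inside_b <- new_lon[beached] >= field$lon[1] &
            new_lon[beached] <= field$lon[length(field$lon)] &
            new_lat[beached] >= field$lat[1] &
            new_lat[beached] <= field$lat[length(field$lat)]
          still <- rep(FALSE, length(beached))
          still[beached] <- inside_b & !is_sea(field, new_lon[beached], new_lat[beached])
          beached <- still
          tries <- tries + 1
        }
        # unlucky particles hold position for this hour
        new_lon[beached] <- lon[beached]
        new_lat[beached] <- lat[beached]
      }
      gone <- new_lon < field$lon[1] | new_lon > field$lon[length(field$lon)] |
        new_lat < field$lat[1] | new_lat > field$lat[length(field$lat)]
      gone <- gone | out_now
      if (any(gone)) {
        idx <- ia[gone]
        exit_step[idx] <- s
        active[idx] <- FALSE
        new_lon[gone] <- lon[gone]; new_lat[gone] <- lat[gone]
      }
      LON[, s + 1] <- LON[, s]; LAT[, s + 1] <- LAT[, s]
      LON[ia, s + 1] <- new_lon; LAT[ia, s + 1] <- new_lat
    }
  })
  structure(list(lon = LON, lat = LAT,
                 release = tibble(particle = seq_len(P), source = src,
                                  time = as.POSIXct(t0, tz = "UTC",
                                                    origin = "1970-01-01")),
                 exit_step = exit_step, config = cfg,
                 n_steps = n_steps),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d particles x %d hourly steps (%d exited)\n",
              nrow(x$lon), x$n_steps, sum(!is.na(x$exit_step))))
  invisible(x)
}

#' Apply settlement rules and count connectivity
#'
#' A particle settles at the first hourly position at which its age is at
#' least the competency age and it lies within the settlement radius of any
#' reef site (nearest site wins). Counts are cumulative at each PLD
#' checkpoint; proportions divide by the number released per source.
#' Particles that neither settle nor exit are "at large" until the maximum
#' PLD, after which they expire.
#'
#' @param traj A `trajectory_set`.
#' @param reef_sites Tibble with `site`, `lon`, `lat`; must include the
#'   release sites and may add non-release settlement habitat.
#' @param config A [dispersal_config()] (defaults to the one in `traj`).
#' @return A `connectivity` object: `counts` and `proportions` arrays
#'   (source x destination x checkpoint), released counts, per-source
#'   self-recruitment at the final checkpoint, and per-particle fates.
#' @export
settle_and_count <- function(traj, reef_sites, config = traj$config) {
  cfg <- config
  P <- nrow(traj$lon)
  steps_per_h <- cfg$step_h
  comp_step <- as.integer(ceiling(cfg$competency_weeks * 7 * 24 / steps_per_h))
  settle_site <- rep(NA_integer_, P)
  settle_step <- rep(NA_integer_, P)
  radius <- cfg$settlement_radius_km
  for (s in comp_step:traj$n_steps) {
    open <- which(is.na(settle_site) &
                    (is.na(traj$exit_step) | traj$exit_step >= s))
    if (!length(open)) break
    lon <- traj$lon[open, s + 1]; lat <- traj$lat[open, s + 1]
    dmat <- sapply(seq_len(nrow(reef_sites)), function(k) {
      haversine_km(lon, lat, reef_sites$lon[k], reef_sites$lat[k])
    })
    dmat <- matrix(dmat, ncol = nrow(reef_sites))
    nearest <- max.col(-dmat, ties.method = "first")
    within <- dmat[cbind(seq_along(open), nearest)] <= radius
    hit <- open[within]
    settle_site[hit] <- nearest[within]
    settle_step[hit] <- s
  }
  sources <- unique(traj$release$source)
  dest <- reef_sites$site
  cps <- cfg$checkpoints_weeks
  cp_steps <- as.integer(cps * 7 * 24 / steps_per_h)
  counts <- array(0L, c(length(sources), length(dest), length(cps)),
                  dimnames = list(sources, dest, paste0("wk", cps)))
  released <- as.integer(table(factor(traj$release$source, levels = sources)))
  for (ci in seq_along(cps)) {
    sel <- !is.na(settle_site) & settle_step <= cp_steps[ci]
    if (any(sel)) {
      tab <- table(factor(traj$release$source[sel], levels = sources),
                   factor(dest[settle_site[sel]], levels = dest))
      counts[, , ci] <- as.integer(tab)
    }
  }
  props <- sweep(counts, 1, pmax(released, 1L), "/")
  fates <- tibble(
    particle = seq_len(P),
    source = traj$release$source,
    fate = dplyr::case_when(
      !is.na(settle_site) ~ "settled",
      !is.na(traj$exit_step) ~ "exited",
      TRUE ~ "expired"),
    settled_at = ifelse(is.na(settle_site), NA_character_,
                        dest[settle_site]),
    age_h = dplyr::coalesce(settle_step, traj$exit_step, traj$n_steps) *
      steps_per_h
  )
  last <- length(cps)
  self_rec <- tibble(
    source = sources,
    released = released,
    self_recruitment = map_dbl(seq_along(sources), function(i) {
      j <- match(sources[i], dest)
      if (is.na(j)) 0 else props[i, j, last]
    })
  )
  structure(list(counts = counts, proportions = props, released = released,
                 sources = sources, destinations = dest,
                 checkpoints_weeks = cps, fates = fates,
                 self_recruitment = self_rec),
            class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  cat(sprintf("<connectivity> %d sources x %d destinations, checkpoints %s weeks\n",
              length(x$sources), length(x$destinations),
              paste(x$checkpoints_weeks, collapse = "/")))
  cat(sprintf("mean self-recruitment at final checkpoint: %.1f%%\n",
              100 * mean(x$self_recruitment$self_recruitment)))
  invisible(x)
}

#' @export
tidy.connectivity <- function(x, ...) {
  out <- list()
  for (ci in seq_along(x$checkpoints_weeks)) {
    idx <- which(x$counts[, , ci] >= 0, arr.ind = TRUE)
    out[[ci]] <- tibble(
      source = x$sources[idx[, 1]], destination = x$destinations[idx[, 2]],
      checkpoint_weeks = x$checkpoints_weeks[ci],
      count = x$counts[, , ci][idx], proportion = x$proportions[, , ci][idx])
  }
  bind_rows(out)
}

#' Pairwise dispersal resistance
#'
#' Resistance is one minus the settlement proportion: R_ij = 1 - p(i -> j),
#' the proportion of larvae released at i that did *not* reach j by the
#' checkpoint. For use with symmetric-matrix methods (Mantel, trees) the
#' directed values are symmetrised by the mean of R_ij and R_ji.
#'
#' @param cm A `connectivity` object.
#' @param checkpoint_weeks Which PLD checkpoint to use.
#' @return A [pairwise_mat()] with unit `"resistance"`, restricted to the
#'   release sites.
#' @export
resistance <- function(cm, checkpoint_weeks = max(cm$checkpoints_weeks)) {
  ci <- match(checkpoint_weeks, cm$checkpoints_weeks)
  if (is.na(ci)) abort("checkpoint not present in the connectivity object")
  if (any(cm$released == 0)) {
    abort("source(s) with zero released larvae", class = "seascapr_param_error")
  }
  keep <- match(cm$sources, cm$destinations)
  if (anyNA(keep)) abort("release sites missing from the destination set")
  pr <- cm$proportions[, keep, ci, drop = FALSE][, , 1]
  R <- 1 - pr
  Rs <- (R + t(R)) / 2
  dimnames(Rs) <- list(cm$sources, cm$sources)
  pairwise_mat(Rs, unit = "resistance")
}

#' Cumulative larval density map
#'
#' Counts sampled particle positions (default: daily) per grid cell over
#' each particle's lifetime (release until settlement, exit or expiry).
#'
#' @param traj A `trajectory_set`.
#' @param grid A `velocity_field` or [bathymetry_grid()] supplying the cell
#'   grid, or a list with `lon` and `lat` cell-centre vectors.
#' @param every_h Sampling interval in hours.
#' @param fates Optional fates tibble from [settle_and_count()] to stop
#'   counting at settlement; by default particles count until exit/expiry.
#' @return A `density_map`: `lon`, `lat`, `counts` matrix and the total
#'   sampled mass.
#' @export
density_map <- function(traj, grid, every_h = 24, fates = NULL) {
  lon_g <- grid$lon; lat_g <- grid$lat
  res_x <- if (length(lon_g) > 1) lon_g[2] - lon_g[1] else 1
  res_y <- if (length(lat_g) > 1) lat_g[2] - lat_g[1] else 1
  counts <- matrix(0L, length(lon_g), length(lat_g))
  last_step <- ifelse(is.na(traj$exit_step), traj$n_steps, traj$exit_step)
  if (!is.null(fates)) {
    st <- fates$age_h / traj$config$step_h
    last_step <- pmin(last_step, ifelse(fates$fate == "settled", st,
                                        last_step))
  }
  steps <- seq(0, traj$n_steps, by = every_h / traj$config$step_h)
  total <- 0L
  for (s in steps) {
    alive <- last_step >= s
    if (!any(alive)) break
    lon <- traj$lon[alive, s + 1]; lat <- traj$lat[alive, s + 1]
    i <- round((lon - lon_g[1]) / res_x) + 1
    j <- round((lat - lat_g[1]) / res_y) + 1
    ok <- i >= 1 & i <= length(lon_g) & j >= 1 & j <= length(lat_g)
    if (any(ok)) {
      tt <- table(factor(i[ok], levels = seq_along(lon_g)),
                  factor(j[ok], levels = seq_along(lat_g)))
      counts <- counts + as.integer(tt)
    }
    total <- total + sum(ok)
  }
  structure(list(lon = lon_g, lat = lat_g, counts = counts, total = total),
            class = "density_map")
}

#' @export
autoplot.density_map <- function(object, ...) {
  df <- expand.grid(lon = object$lon, lat = object$lat)
  df$count <- as.vector(object$counts)
  ggplot2::ggplot(df[df$count > 0, ],
                  ggplot2::aes(x = .data$lon, y = .data$lat,
                               fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::coord_quickmap() +
    ggplot2::theme_minimal()
}
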