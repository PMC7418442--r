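#' Specification of an analytic coastal velocity field
#'
#' The dispersal simulator runs on gridded 2-D velocity fields. Rather than
#' ingesting operational ocean-model output, the package generates analytic
#' flows on a regular lon/lat grid: still water, uniform drift, the classic
#' (time-dependent) double-gyre stream function, or a "coastal retention"
#' field that embeds a closed eddy beside every reef site.
#'
#' @param lon_range,lat_range Domain extent in decimal degrees.
#' @param resolution Grid spacing in degrees.
#' @param flow_kind One of `"zero"`, `"uniform"`, `"double_gyre"`,
#'   `"coastal_retention"`.
#' @param amplitude Peak speed scale in m s^-1. For `"uniform"` a length-2
#'   vector gives (u, v) directly.
#' @param land A function `f(lon, lat)` returning `TRUE` on land, or `NULL`
#'   for an all-sea domain.
#' @param reef_sites Tibble with `site`, `lon`, `lat`; required for
#'   `"coastal_retention"`. Sites must fall on sea cells.
#' @param eddy_sigma_km Eddy radius scale for the retention field.
#' @param gyre_eps,gyre_period_h Double-gyre unsteadiness and period.
#' @return A `field_spec` list.
#' @export
field_spec <- function(lon_range = c(-12, -2), lat_range = c(33, 55),
                       resolution = 0.25, flow_kind = "zero",
                       amplitude = 0.1, land = NULL, reef_sites = NULL,
                       eddy_sigma_km = 25, gyre_eps = 0.25,
                       gyre_period_h = 240) {
  flow_kind <- match.arg(flow_kind,
                         c("zero", "uniform", "double_gyre", "coastal_retention"))
  structure(list(lon_range = lon_range, lat_range = lat_range,
                 resolution = resolution, flow_kind = flow_kind,
                 amplitude = amplitude, land = land, reef_sites = reef_sites,
                 eddy_sigma_km = eddy_sigma_km, gyre_eps = gyre_eps,
                 gyre_period_h = gyre_period_h),
            class = "field_spec")
}

#' Build a gridded velocity field from a specification
#'
#' Rotational flows (`double_gyre`, `coastal_retention`) are derived from a
#' stream function by *central differences on the grid*, so the discrete
#' divergence of the stored (u, v) vanishes identically at interior cells --
#' the gridded field is nondivergent by construction, not merely to
#' truncation error.
#'
#' @param spec A [field_spec()].
#' @return A `velocity_field`: cell-centre `lon`/`lat` vectors, `u`/`v`
#'   matrices (nlon x nlat, m s^-1, `NA` on land), a logical `sea` mask and
#'   the metre-per-degree constants used.
#' @export
make_velocity_field <- function(spec = field_spec()) {
  stopifnot(inherits(spec, "field_spec"))
  lon <- seq(spec$lon_range[1] + spec$resolution / 2, spec$lon_range[2],
             by = spec$resolution)
  lat <- seq(spec$lat_range[1] + spec$resolution / 2, spec$lat_range[2],
             by = spec$resolution)
  nx <- length(lon); ny <- length(lat)
  midlat <- mean(spec$lat_range)
  my <- .M_PER_DEG                       # metres per degree latitude
  mx <- .M_PER_DEG * cos(midlat * pi / 180)  # metres per degree longitude
  sea <- matrix(TRUE, nx, ny)
  if (!is.null(spec$land)) {
    sea <- !outer(lon, lat, spec$land)
  }
  if (!any(sea)) abort("land mask leaves no sea cells")

  X <- matrix(lon, nx, ny)
  Y <- matrix(lat, nx, ny, byrow = TRUE)
  u <- matrix(0, nx, ny); v <- matrix(0, nx, ny)

  psi_from <- NULL
  if (spec$flow_kind == "uniform") {
    uv <- rep_len(spec$amplitude, 2)
    if (length(spec$amplitude) == 1) uv <- c(spec$amplitude, 0)
    u[] <- uv[1]; v[] <- uv[2]
  } else if (spec$flow_kind == "double_gyre") {
    psi_from <- function(lon, lat, t = 0) {
      dg_psi(lon, lat, t, spec, mx, my)
    }
  } else if (spec$flow_kind == "coastal_retention") {
    if (is.null(spec$reef_sites)) {
      abort("coastal_retention requires reef_sites")
    }
    psi_from <- function(lon, lat, t = 0) {
      eddy_psi(lon, lat, spec, mx, my)
    }
  }
  if (!is.null(psi_from)) {
    psi <- psi_from(X, Y)
    # u = -dpsi/dy, v = dpsi/dx, centred; nondivergent discretely
    dx2 <- 2 * spec$resolution * mx
    dy2 <- 2 * spec$resolution * my
    ii <- 2:(nx - 1); jj <- 2:(ny - 1)
    u[, jj] <- -(psi[, jj + 1] - psi[, jj - 1]) / dy2
    v[ii, ] <- (psi[ii + 1, ] - psi[ii - 1, ]) / dx2
    # one-sided at the boundary ring
    u[, 1] <- -(psi[, 2] - psi[, 1]) / (dy2 / 2)
    u[, ny] <- -(psi[, ny] - psi[, ny - 1]) / (dy2 / 2)
    v[1, ] <- (psi[2, ] - psi[1, ]) / (dx2 / 2)
    v[nx, ] <- (psi[nx, ] - psi[nx - 1, ]) / (dx2 / 2)
  }
  u[!sea] <- NA_real_; v[!sea] <- NA_real_
  if (any(!is.finite(u[sea])) || any(!is.finite(v[sea]))) {
    abort("velocities must be finite on sea cells")
  }
  fld <- structure(list(lon = lon, lat = lat, u = u, v = v, sea = sea,
                        mx = mx, my = my, spec = spec),
                   class = "velocity_field")
  if (!is.null(spec$reef_sites)) {
    onsea <- is_sea(fld, spec$reef_sites$lon, spec$reef_sites$lat)
    if (!all(onsea)) {
      abort(paste("reef site(s) on land:",
                  paste(spec$reef_sites$site[!onsea], collapse = ", ")),
            class = "seascapr_placement_error")
    }
  }
  fld
}

# Double-gyre stream function over the domain mapped to x in [0,2], y in [0,1].
dg_psi <- function(lon, lat, t, spec, mx, my) {
  x <- 2 * (lon - spec$lon_range[1]) / diff(spec$lon_range)
  y <- (lat - spec$lat_range[1]) / diff(spec$lat_range)
  om <- 2 * pi / (spec$gyre_period_h * 3600)
  a <- spec$gyre_eps * sin(om * t)
  b <- 1 - 2 * a
  f <- a * x^2 + b * x
  Ly <- diff(spec$lat_range) * my
  A <- spec$amplitude * Ly / pi
  A * sin(pi * f) * sin(pi * y)
}

# Sum of Gaussian eddies centred on the reef sites (closed local circulation).
eddy_psi <- function(lon, lat, spec, mx, my) {
  sig <- spec$eddy_sigma_km * 1000
  A <- spec$amplitude * sig * exp(0.5)
  psi <- 0 * lon
  for (k in seq_len(nrow(spec$reef_sites))) {
    dxm <- (lon - spec$reef_sites$lon[k]) * mx
    dym <- (lat - spec$reef_sites$lat[k]) * my
    psi <- psi + A * exp(-(dxm^2 + dym^2) / (2 * sig^2))
  }
  psi
}

# TRUE where the nearest grid cell is sea (FALSE outside the domain).
is_sea <- function(field, lon, lat) {
  i <- round((lon - field$lon[1]) / field$spec$resolution) + 1
  j <- round((lat - field$lat[1]) / field$spec$resolution) + 1
  ok <- i >= 1 & i <= length(field$lon) & j >= 1 & j <= length(field$lat)
  out <- rep(FALSE, length(lon))
  out[ok] <- field$sea[cbind(i[ok], j[ok])]
  out
}

# Bilinear interpolation of a grid matrix at arbitrary points; NA outside.
bilinear <- function(xg, yg, M, x, y) {
  nx <- length(xg); ny <- length(yg)
  i <- findInterval(x, xg, rightmost.closed = TRUE)
  j <- findInterval(y, yg, rightmost.closed = TRUE)
  out <- rep(NA_real_, length(x))
  ok <- i >= 1 & i < nx & j >= 1 & j < ny
  if (!any(ok)) return(out)
  i <- pmin(pmax(i, 1), nx - 1); j <- pmin(pmax(j, 1), ny - 1)
  tx <- (x - xg[i]) / (xg[i + 1] - xg[i])
  ty <- (y - yg[j]) / (yg[j + 1] - yg[j])
  m00 <- M[cbind(i, j)]; m10 <- M[cbind(i + 1, j)]
  m01 <- M[cbind(i, j + 1)]; m11 <- M[cbind(i + 1, j + 1)]
  val <- (1 - tx) * (1 - ty) * m00 + tx * (1 - ty) * m10 +
    (1 - tx) * ty * m01 + tx * ty * m11
  out[ok] <- val[ok]
  out
}

#' Evaluate a velocity field at points
#'
#' Bilinear interpolation of the gridded (u, v); points outside the grid hull
#' return `NA` (treated as domain exit by the particle tracker). Land cells
#' carry `NA` velocities; interpolation near the coast substitutes zero flow
#' for the land corners so particles shear along the coastline.
#'
#' @param field A `velocity_field`.
#' @param lon,lat Point coordinates (vectors).
#' @param t Time in seconds (used by the time-dependent double gyre).
#' @return A list with numeric vectors `u` and `v` (m s^-1).
#' @export
field_uv <- function(field, lon, lat, t = 0) {
  if (field$spec$flow_kind == "double_gyre" && field$spec$gyre_eps != 0) {
    # analytic evaluation keeps the unsteady gyre exact in time
    h <- 1e-4
    psi <- function(lo, la) dg_psi(lo, la, t, field$spec, field$mx, field$my)
    u <- -(psi(lon, lat + h) - psi(lon, lat - h)) / (2 * h * field$my)
    v <- (psi(lon + h, lat) - psi(lon - h, lat)) / (2 * h * field$mx)
    inside <- lon >= field$lon[1] & lon <= field$lon[length(field$lon)] &
      lat >= field$lat[1] & lat <= field$lat[length(field$lat)]
    u[!inside] <- NA_real_; v[!inside] <- NA_real_
    return(list(u = u, v = v))
  }
  u0 <- field$u; v0 <- field$v
  u0[is.na(u0)] <- 0; v0[is.na(v0)] <- 0
  list(u = bilinear(field$lon, field$lat, u0, lon, lat),
       v = bilinear(field$lon, field$lat, v0, lon, lat))
}

#' Discrete divergence of a gridded field
#'
#' Central-difference divergence at interior cells, in s^-1. Used to verify
#' that stream-function-derived fields are nondivergent on the grid.
#'
#' @param field A `velocity_field`.
#' @return Matrix (nlon-2) x (nlat-2) of divergence values.
#' @export
field_divergence <- function(field) {
  nx <- length(field$lon); ny <- length(field$lat)
  dx2 <- 2 * field$spec$resolution * field$mx
  dy2 <- 2 * field$spec$resolution * field$my
  ii <- 2:(nx - 1); jj <- 2:(ny - 1)
  (field$u[ii + 1, jj] - field$u[ii - 1, jj]) / dx2 +
    (field$v[ii, jj + 1] - field$v[ii, jj - 1]) / dy2
}
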