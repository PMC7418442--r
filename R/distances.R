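#' Great-circle distances between sites
#'
#' Haversine distances (Earth radius 6371 km) between all site pairs.
#'
#' @param coords Tibble with `site`, `lon`, `lat` (decimal degrees).
#' @return A [pairwise_mat()] in km.
#' @export
greatcircle_distances <- function(coords) {
  if (any(abs(coords$lat) > 90)) abort("latitudes must lie in [-90, 90]")
  k <- nrow(coords)
  m <- matrix(0, k, k, dimnames = list(coords$site, coords$site))
  for (i in seq_len(k - 1)) {
    d <- haversine_km(coords$lon[i], coords$lat[i],
                      coords$lon[(i + 1):k], coords$lat[(i + 1):k])
    m[i, (i + 1):k] <- d
    m[(i + 1):k, i] <- d
  }
  pairwise_mat(m, unit = "km")
}

#' Bathymetry raster
#'
#' @param lon,lat Cell-centre coordinate vectors (regular grid).
#' @param z Elevation matrix (nlon x nlat, metres; sea where z <= 0).
#' @export
bathymetry_grid <- function(lon, lat, z) {
  stopifnot(nrow(z) == length(lon), ncol(z) == length(lat))
  structure(list(lon = lon, lat = lat, z = z), class = "bathymetry_grid")
}

#' Least-cost ocean distance between sites
#'
#' Shortest-path distance over the 8-connected graph of sea cells (cells with
#' elevation <= 0), edge weights being haversine distances between cell
#' centres. Sites are snapped to the nearest sea cell within 2 cells;
#' pairs with no sea path get `Inf` (flagged in the `no_path` attribute).
#'
#' @param coords Tibble with `site`, `lon`, `lat`.
#' @param bathymetry A [bathymetry_grid()].
#' @return A [pairwise_mat()] in km.
#' @export
least_cost_sea_distance <- function(coords, bathymetry) {
  b <- bathymetry
  nx <- length(b$lon); ny <- length(b$lat)
  sea <- b$z <= 0
  cell_id <- matrix(NA_integer_, nx, ny)
  sea_idx <- which(sea, arr.ind = TRUE)
  cell_id[sea_idx] <- seq_len(nrow(sea_idx))
  # 8-neighbour edges (E, N, NE, NW offsets cover each pair once)
  offs <- rbind(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))
  from <- integer(); to <- integer(); w <- numeric()
  for (k in seq_len(nrow(offs))) {
    di <- offs[k, 1]; dj <- offs[k, 2]
    i <- sea_idx[, 1]; j <- sea_idx[, 2]
    i2 <- i + di; j2 <- j + dj
    ok <- i2 >= 1 & i2 <= nx & j2 >= 1 & j2 <= ny
    ok[ok] <- sea[cbind(i2[ok], j2[ok])]
    if (!any(ok)) next
    from <- c(from, cell_id[cbind(i[ok], j[ok])])
    to <- c(to, cell_id[cbind(i2[ok], j2[ok])])
    w <- c(w, haversine_km(b$lon[i[ok]], b$lat[j[ok]],
                           b$lon[i2[ok]], b$lat[j2[ok]]))
  }
  gr <- igraph::make_empty_graph(n = nrow(sea_idx), directed = FALSE)
  gr <- igraph::add_edges(gr, rbind(from, to))
  igraph::E(gr)$weight <- w

  # snap each site to the nearest sea cell within 2 cells
  res_x <- if (nx > 1) b$lon[2] - b$lon[1] else 1
  res_y <- if (ny > 1) b$lat[2] - b$lat[1] else 1
  site_cell <- map_int(seq_len(nrow(coords)), function(s) {
    dx <- (b$lon[sea_idx[, 1]] - coords$lon[s]) / res_x
    dy <- (b$lat[sea_idx[, 2]] - coords$lat[s]) / res_y
    dd <- dx^2 + dy^2
    best <- which.min(dd)
    if (sqrt(dd[best]) > 2 + 1e-9) {
      abort(sprintf("site %s is more than 2 cells from the sea",
                    coords$site[s]), class = "seascapr_placement_error")
    }
    best
  })
  dm <- igraph::distances(gr, v = site_cell, to = site_cell)
  dimnames(dm) <- list(coords$site, coords$site)
  diag(dm) <- 0
  out <- pairwise_mat(dm, unit = "km")
  attr(out, "no_path") <- which(is.infinite(dm), arr.ind = TRUE)
  out
}
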