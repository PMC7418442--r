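#' Derive a reproducible stage seed from a global seed
#'
#' Each pipeline stage consumes its own RNG stream, derived deterministically
#' from the global seed and the stage name so that toggling one stage on or
#' off never shifts the randomness of another.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 31 + cp) %% 1000000007
  as.integer((abs(seed) + h) %% 2147483647)
}

# Haversine distance in km between lon/lat points (decimal degrees).
# Earth radius 6371 km throughout the package.
.EARTH_RADIUS_KM <- 6371
.M_PER_DEG <- pi * .EARTH_RADIUS_KM * 1000 / 180  # metres per degree latitude

haversine_km <- function(lon1, lat1, lon2, lat2) {
  if (any(abs(c(lat1, lat2)) > 90)) {
    abort("latitudes must lie in [-90, 90]")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = .EARTH_RADIUS_KM * 1000) / 1000
}

# Mean of the strictly-lower-triangle entries of a square matrix.
lower_tri_mean <- function(m) mean(m[lower.tri(m)], na.rm = TRUE)

# Quantise values to a fixed measurement resolution (e.g. a 0.5 degC logger).
quantise <- function(x, resolution = 0.5) round(x / resolution) * resolution

# Evaluate under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- rlang::`%||%`
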