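#' The sixteen per-site thermal metrics
#'
#' From a tide-flagged temperature series: over all readings the mean, max,
#' min, range (max - min), standard deviation, 95th minus 5th percentile,
#' average daily range and average daily standard deviation; then mean,
#' max, min and range separately for water (high-tide) and air (low-tide)
#' readings. Daily metrics are computed per calendar day and averaged; days
#' with fewer than half of the expected readings are excluded.
#'
#' @param series Tibble with `timestamp`, `temp` and `tide`
#'   ("water"/"air"), as from [simulate_temperature()].
#' @param expected_per_day Expected readings per day (for the 50% daily
#'   completeness rule); inferred from the median timestamp spacing when
#'   `NULL`.
#' @return A one-row tibble of the 16 metrics: `mean`, `max`, `min`,
#'   `range`, `sd`, `p95_p5`, `daily_range`, `daily_sd`, `water_mean`,
#'   `water_max`, `water_min`, `water_range`, `air_mean`, `air_max`,
#'   `air_min`, `air_range`.
#' @export
thermal_metrics <- function(series, expected_per_day = NULL) {
  s <- arrange(series, .data$timestamp)
  if (nrow(s) < 2) abort("need at least one full day of data")
  x <- s$temp
  if (is.null(expected_per_day)) {
    dt_h <- median(as.numeric(diff(s$timestamp), units = "hours"))
    expected_per_day <- max(1, round(24 / dt_h))
  }
  day <- as.Date(s$timestamp, tz = "UTC")
  per_day <- s |> mutate(day = day) |> group_by(.data$day) |>
    summarise(n = n(), rng = max(.data$temp) - min(.data$temp),
              dsd = sd(.data$temp), .groups = "drop") |>
    filter(.data$n >= expected_per_day / 2)
  q <- quantile(x, c(0.05, 0.95), names = FALSE)
  block <- function(v) {
    if (!length(v)) {
      return(tibble(mean = NA_real_, max = NA_real_, min = NA_real_,
                    range = NA_real_))
    }
    tibble(mean = mean(v), max = max(v), min = min(v),
           range = max(v) - min(v))
  }
  all_b <- block(x)
  water_b <- block(x[s$tide == "water"])
  air_b <- block(x[s$tide == "air"])
  out <- tibble(
    mean = all_b$mean, max = all_b$max, min = all_b$min, range = all_b$range,
    sd = sd(x), p95_p5 = q[2] - q[1],
    daily_range = mean(per_day$rng), daily_sd = mean(per_day$dsd, na.rm = TRUE),
    water_mean = water_b$mean, water_max = water_b$max,
    water_min = water_b$min, water_range = water_b$range,
    air_mean = air_b$mean, air_max = air_b$max,
    air_min = air_b$min, air_range = air_b$range
  )
  if (!all(c("water", "air") %in% s$tide)) {
    attr(out, "tide_blocks") <- "unavailable"
  }
  out
}

#' Thermal metrics for several sites
#'
#' @param series_by_site Named list of temperature series (one per site).
#' @return Tibble with a `site` column plus the 16 metrics.
#' @export
thermal_metrics_by_site <- function(series_by_site) {
  bind_rows(imap(series_by_site,
                 function(s, nm) mutate(thermal_metrics(s), site = nm,
                                        .before = 1)))
}
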