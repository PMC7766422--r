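#' Speed / power band specifications
#'
#' A band is a labelled, possibly open-ended interval on speed (km/h) or
#' metabolic power (W/kg). With only a lower bound the predicate is strict
#' (`value > lower`, matching ">" labels such as "v > 6 km/h"); with both
#' bounds the interval is half-open (`lower <= value < upper`, so "20-35"
#' means \[20, 35)). Overlapping bands are allowed and reported as given.
#'
#' @param label Band label.
#' @param var `"speed"` (km/h) or `"power"` (W/kg).
#' @param lower,upper Bounds; `NA` for open-ended.
#' @return A one-row tibble; rbind rows to build a band table.
#' @export
band_spec <- function(label, var = c("speed", "power"),
                      lower = NA_real_, upper = NA_real_) {
  var <- match.arg(var)
  if (!is.na(lower) && !is.na(upper) && lower >= upper) {
    stop("`lower` must be below `upper`", call. = FALSE)
  }
  tibble::tibble(label = label, var = var,
                 lower = as.numeric(lower), upper = as.numeric(upper))
}

#' Default external-load bands
#'
#' The standard reporting bands: speed above 6, 11, 16 and 20 km/h, and
#' metabolic power 0-10, 10-20, above 20, 20-35 and above 55 W/kg (the power
#' bands deliberately overlap).
#'
#' @return A band tibble for [band_occupancy()].
#' @export
default_bands <- function() {
  rbind(
    band_spec("v > 6 km/h",  "speed", lower = 6),
    band_spec("v > 11 km/h", "speed", lower = 11),
    band_spec("v > 16 km/h", "speed", lower = 16),
    band_spec("v > 20 km/h", "speed", lower = 20),
    band_spec("P 0-10 W/kg",  "power", lower = 0, upper = 10),
    band_spec("P 10-20 W/kg", "power", lower = 10, upper = 20),
    band_spec("P > 20 W/kg",  "power", lower = 20),
    band_spec("P 20-35 W/kg", "power", lower = 20, upper = 35),
    band_spec("P > 55 W/kg",  "power", lower = 55)
  )
}

#' Read band specifications from YAML
#'
#' A list of entries with keys `label`, `var`, `lower`, `upper`.
#'
#' @param path YAML path.
#' @return A band tibble.
#' @export
read_bands <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(rbind, lapply(y, function(b) {
    band_spec(b$label, b$var,
              lower = b$lower %||% NA_real_, upper = b$upper %||% NA_real_)
  }))
}

#' Time and distance spent in speed / power bands
#'
#' Sums per-sample durations and `v * dt` distances over the samples where
#' each band predicate holds.
#'
#' @param series A `kinematic_series` with `power` populated (see
#'   [process_gps()]).
#' @param bands A band tibble, default [default_bands()].
#' @return The band tibble with `time_s` and `distance_m` columns added.
#' @export
band_occupancy <- function(series, bands = default_bands()) {
  if (nrow(series) == 0L) stop("empty series", call. = FALSE)
  if (any(bands$var == "power") && !"power" %in% names(series)) {
    stop("power bands requested but `power` is not populated", call. = FALSE)
  }
  dt <- sample_dt(series$t)
  v_kmh <- series$v_s * 3.6
  bands$time_s <- NA_real_
  bands$distance_m <- NA_real_
  for (i in seq_len(nrow(bands))) {
    val <- if (bands$var[i] == "speed") v_kmh else series$power
    sel <- !is.na(val)
    if (!is.na(bands$lower[i]) && !is.na(bands$upper[i])) {
      sel <- sel & val >= bands$lower[i] & val < bands$upper[i]
    } else if (!is.na(bands$lower[i])) {
      sel <- sel & val > bands$lower[i]
    } else if (!is.na(bands$upper[i])) {
      sel <- sel & val < bands$upper[i]
    }
    bands$time_s[i] <- sum(dt[sel])
    bands$distance_m[i] <- sum((series$v_s * dt)[sel])
  }
  bands
}

#' Maximum attainable acceleration as a function of initial speed
#'
#' Linear decay of maximal forward acceleration with the speed at which the
#' acceleration is initiated, floored at zero (no positive acceleration
#' capacity above ~32.8 km/h).
#'
#' @param v_init Initial speed, km/h.
#' @param intercept,slope Model coefficients (m/s^2 and m/s^2 per km/h).
#' @return Maximal acceleration, m/s^2.
#' @examples
#' a_max(0)    # 5.91
#' a_max(10)   # 4.11
#' @export
a_max <- function(v_init, intercept = 5.91, slope = -0.18) {
  if (any(v_init < 0)) stop("`v_init` must be non-negative", call. = FALSE)
  pmax(0, intercept + slope * v_init)
}

#' Percentage of time at high acceleration / deceleration
#'
#' High acceleration: `a > 0.5 * a_max(v)` with `v` the current speed in
#' km/h. High deceleration: `a < decel_threshold` (default -2 m/s^2).
#'
#' @param series A `kinematic_series` with acceleration populated.
#' @param accel_fraction Fraction of `a_max` defining "high", default 0.5.
#' @param decel_threshold Deceleration threshold, m/s^2.
#' @return A list with `pct_high_accel` and `pct_high_decel` (0-100).
#' @export
high_intensity_fractions <- function(series, accel_fraction = 0.5,
                                     decel_threshold = -2) {
  if (!"a" %in% names(series)) stop("acceleration not populated", call. = FALSE)
  dt <- sample_dt(series$t)
  total <- sum(dt)
  thr <- accel_fraction * a_max(series$v_s * 3.6)
  hi_a <- !is.na(series$a) & series$a > thr
  hi_d <- !is.na(series$a) & series$a < decel_threshold
  list(pct_high_accel = 100 * sum(dt[hi_a]) / total,
       pct_high_decel = 100 * sum(dt[hi_d]) / total)
}

#' Supra-threshold power bouts per minute
#'
#' A bout is a maximal run of consecutive samples above the power threshold
#' lasting at least `min_duration` seconds (the default 0.6 s, three samples
#' at 5 Hz, suppresses single-sample noise).
#'
#' @param series A `kinematic_series` with `power`.
#' @param threshold Power threshold, W/kg (default 20).
#' @param min_duration Minimum bout duration, s (default 0.6).
#' @return Bouts per minute of session time.
#' @export
bouts_per_min <- function(series, threshold = 20, min_duration = 0.6) {
  if (!"power" %in% names(series)) stop("power not populated", call. = FALSE)
  dt <- sample_dt(series$t)
  above <- !is.na(series$power) & series$power > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n_bouts <- 0L
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    if (sum(dt[seq(starts[j], ends[j])]) >= min_duration) n_bouts <- n_bouts + 1L
  }
  n_bouts / (sum(dt) / 60)
}

#' Changes of direction per minute
#'
#' Counts events where the cumulative absolute heading change within a short
#' look-ahead window exceeds the angular threshold while moving faster than
#' the speed gate; successive events are separated by at least one window.
#'
#' @param series A `kinematic_series` with `heading` populated.
#' @param angle_threshold Degrees, default 30.
#' @param window Look-ahead window, s, default 0.5.
#' @param speed_gate Minimum speed, m/s, default 1.
#' @return Changes of direction per minute of session time.
#' @export
cod_per_min <- function(series, angle_threshold = 30, window = 0.5,
                        speed_gate = 1) {
  if (!"heading" %in% names(series)) {
    stop("heading not populated (needs coordinates)", call. = FALSE)
  }
  t <- series$t; h <- series$heading; v <- series$v_s
  n <- length(t)
  ## wrapped heading increments in (-180, 180]
  dh <- diff(h)
  dh <- ((dh + 180) %% 360) - 180
  dh[is.na(dh)] <- 0
  events <- 0L
  i <- 1L
  while (i < n) {
    if (!is.na(v[i]) && v[i] > speed_gate) {
      j_end <- i
      while (j_end < n && t[j_end + 1L] - t[i] <= window) j_end <- j_end + 1L
      turn <- sum(abs(dh[i:max(i, j_end - 1L)]))
      if (turn > angle_threshold) {
        events <- events + 1L
        ## skip one full window past the event
        while (i < n && t[i + 1L] - t[j_end] < window) i <- i + 1L
        i <- max(i, j_end)
      }
    }
    i <- i + 1L
  }
  events / ((t[n] - t[1L]) / 60)
}

#' External-load summary of a processed session
#'
#' Bundles band occupancy, total distance, mean power, high-intensity time
#' fractions, power bouts and (when heading is available) changes of
#' direction into one report.
#'
#' @param series A `kinematic_series` from [process_gps()].
#' @param bands Band tibble, default [default_bands()].
#' @param es_speed_kmh "Endurance speed" threshold in km/h for the
#'   `v > ES` time fraction (no standard value exists; 16 km/h by default).
#' @return A list of class `metrics_report`.
#' @export
circuit_metrics <- function(series, bands = default_bands(),
                            es_speed_kmh = 16) {
  dt <- sample_dt(series$t)
  hif <- high_intensity_fractions(series)
  cod <- if ("heading" %in% names(series)) cod_per_min(series) else NA_real_
  structure(
    list(
      bands = band_occupancy(series, bands),
      total_distance_m = sum(series$v_s * dt),
      duration_s = sum(dt),
      mean_power = sum(series$power * dt, na.rm = TRUE) /
        sum(dt[!is.na(series$power)]),
      pct_high_accel = hif$pct_high_accel,
      pct_high_decel = hif$pct_high_decel,
      pct_above_es = 100 * sum(dt[series$v_s * 3.6 > es_speed_kmh]) / sum(dt),
      bouts_per_min = bouts_per_min(series),
      cod_per_min = cod
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  total distance : %.0f m in %.0f s (mean power %.1f W/kg)\n",
              x$total_distance_m, x$duration_s, x$mean_power))
  cat(sprintf("  high accel     : %.1f %% time   high decel: %.1f %% time\n",
              x$pct_high_accel, x$pct_high_decel))
  cat(sprintf("  bouts > 20 W/kg: %.1f per min\n", x$bouts_per_min))
  if (!is.na(x$cod_per_min)) {
    cat(sprintf("  CoD > 30 deg   : %.1f per min\n", x$cod_per_min))
  }
  cat("  band occupancy:\n")
  print(as.data.frame(x$bands), row.names = FALSE)
  invisible(x)
}
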