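#' Synchronise a trace to the first movement
#'
#' Drops all samples before the first one with speed above 0 m/s and
#' re-zeroes the clock at that sample, the convention used to align GPS
#' speed with breath-by-breath gas-exchange output.
#'
#' @param trace A [gps_trace()].
#' @return A [gps_trace()] starting at the first moving sample, `t = 0`.
#' @export
sync_to_first_movement <- function(trace) {
  stopifnot(inherits(trace, "gps_trace"))
  i <- which(trace$v > 0)[1L]
  if (is.na(i)) stop("no movement detected: all speeds are zero", call. = FALSE)
  out <- trace[seq(i, nrow(trace)), ]
  out$t <- out$t - out$t[1L]
  out$gap[1L] <- FALSE
  out
}

new_kinematic_series <- function(df, hz) {
  structure(df, class = c("kinematic_series", class(tibble::tibble())),
            hz = hz)
}

#' Smooth (reduce) a 10 Hz speed trace to 5 Hz
#'
#' The default reduction is a non-overlapping two-sample moving mean, halving
#' the sampling rate from 10 to 5 Hz. This preserves total displacement
#' exactly (rectangle-rule integral of speed over time) while suppressing
#' sample-to-sample Doppler noise. A sliding (overlapping) moving mean that
#' keeps the 10 Hz grid is available via `method = "rolling"`.
#'
#' @param trace A [gps_trace()].
#' @param method `"decimate"` (default, 10 to 5 Hz) or `"rolling"`
#'   (centred 3-sample mean, rate preserved).
#' @return A `kinematic_series` tibble with columns `t`, `v_s`, any
#'   positional/QC columns carried over (pairwise-averaged under
#'   `"decimate"`), and a `flag_partial` marker on a trailing odd sample.
#' @export
smooth_speed <- function(trace, method = c("decimate", "rolling")) {
  stopifnot(inherits(trace, "gps_trace"))
  method <- match.arg(method)
  n <- nrow(trace)
  if (n < 2L) stop("need at least 2 samples to smooth", call. = FALSE)
  carry <- intersect(c("lat", "lon", "hdop", "nsat"), names(trace))
  if (method == "decimate") {
    m <- n %/% 2L
    i1 <- seq(1L, by = 2L, length.out = m)
    i2 <- i1 + 1L
    df <- tibble::tibble(
      t = (trace$t[i1] + trace$t[i2]) / 2,
      v_s = (trace$v[i1] + trace$v[i2]) / 2
    )
    for (col in carry) df[[col]] <- (trace[[col]][i1] + trace[[col]][i2]) / 2
    df$flag_partial <- FALSE
    if (n %% 2L == 1L) {
      tail <- tibble::tibble(t = trace$t[n], v_s = trace$v[n])
      for (col in carry) tail[[col]] <- trace[[col]][n]
      tail$flag_partial <- TRUE
      df <- rbind(df, tail)
    }
    hz <- 1 / stats::median(diff(df$t))
  } else {
    v_s <- stats::filter(trace$v, rep(1 / 3, 3), sides = 2)
    v_s[1L] <- mean(trace$v[1:2]); v_s[n] <- mean(trace$v[(n - 1L):n])
    df <- tibble::tibble(t = trace$t, v_s = as.numeric(v_s))
    for (col in carry) df[[col]] <- trace[[col]]
    df$flag_partial <- FALSE
    hz <- 1 / stats::median(diff(df$t))
  }
  new_kinematic_series(df, hz = hz)
}

#' Differentiate smoothed speed into acceleration
#'
#' Finite difference of the smoothed speed over a time window, centred as
#' evenly as the sampling grid allows (the window is rounded to the nearest
#' whole number of sample intervals; one-sided differences are used at the
#' edges). The equivalent slope `es = a/g` and equivalent mass
#' `em = sqrt(es^2 + 1)` are populated alongside; samples whose `|es|`
#' exceeds the artefact bound of 4 are set to `NA` and flagged.
#'
#' @param series A `kinematic_series` from [smooth_speed()].
#' @param window_s Differentiation window in seconds (default 0.3; 0.2 is the
#'   other value in common use for 10 Hz devices).
#' @param g Gravitational acceleration, m/s^2.
#' @return The series with `a`, `es`, `em`, `flag_es_extrapolated` and
#'   `flag_artefact` columns added.
#' @export
add_acceleration <- function(series, window_s = 0.3, g = GRAVITY) {
  stopifnot(inherits(series, "kinematic_series"))
  t <- series$t; v <- series$v_s
  n <- length(v)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  dt <- stats::median(diff(t))
  if (window_s < dt) {
    stop("`window_s` shorter than the sample spacing (", signif(dt, 3), " s)",
         call. = FALSE)
  }
  ## symmetric half-window: an off-centre difference phase-shifts the
  ## acceleration against the speed it multiplies
  half <- max(1L, as.integer(round(window_s / (2 * dt))))
  a <- rep(NA_real_, n)
  idx <- seq_len(n)
  i_lo <- pmax(idx - half, 1L)
  i_hi <- pmin(idx + half, n)
  span <- t[i_hi] - t[i_lo]
  ok <- span > 0
  a[ok] <- (v[i_hi][ok] - v[i_lo][ok]) / span[ok]
  es <- a / g
  artefact <- !is.na(es) & abs(es) > ES_SANITY_BOUND
  a[artefact] <- NA_real_
  es[artefact] <- NA_real_
  series$a <- a
  series$es <- es
  series$em <- sqrt(es^2 + 1)
  series$flag_es_extrapolated <- !is.na(es) &
    (es < ES_FIT_RANGE[1L] | es > ES_FIT_RANGE[2L])
  series$flag_artefact <- artefact
  attr(series, "window_s") <- 2 * half * dt
  series
}

#' Heading from successive positions
#'
#' Populates a `heading` column (degrees clockwise from north, \[0, 360))
#' from the bearing between successive positions. Samples whose displacement
#' from the previous position is below `min_disp` metres have an undefined
#' heading (`NA`, flagged), as bearing is numerically meaningless when
#' stationary.
#'
#' @param series A `kinematic_series` (or [gps_trace()]) with `lat`/`lon`.
#' @param min_disp Minimum displacement in metres for a defined heading.
#' @return The series with `heading` and `flag_heading_undefined` added.
#' @export
add_heading <- function(series, min_disp = 0.2) {
  if (!all(c("lat", "lon") %in% names(series))) {
    stop("no coordinates present: use speed-only mode (skip heading metrics)",
         call. = FALSE)
  }
  p <- cbind(series$lon, series$lat)
  n <- nrow(p)
  heading <- rep(NA_real_, n)
  if (n >= 2L) {
    d <- geosphere::distGeo(p[-n, , drop = FALSE], p[-1L, , drop = FALSE])
    b <- geosphere::bearing(p[-n, , drop = FALSE], p[-1L, , drop = FALSE])
    b <- (b + 360) %% 360
    b[d < min_disp] <- NA_real_
    heading[-1L] <- b
    heading[1L] <- b[1L]
  }
  series$heading <- heading
  series$flag_heading_undefined <- is.na(heading)
  series
}

#' Fix-quality filtering of a GPS trace
#'
#' Flags samples failing HDOP / satellite-count thresholds. Isolated bad
#' runs (shorter than `max_gap_s`) are linearly interpolated in speed;
#' longer runs are dropped, leaving a flagged sampling gap that is never
#' fabricated. Traces without QC fields pass through with a warning.
#'
#' @param trace A [gps_trace()].
#' @param hdop_max Maximum acceptable HDOP (default 2.0).
#' @param nsat_min Minimum satellites used (default 6).
#' @param max_gap_s Longest bad run to repair by interpolation (default 0.5 s).
#' @return The filtered [gps_trace()] with a `qc_report` attribute:
#'   a list with counts `n_retained`, `n_interpolated`, `n_dropped`.
#' @export
quality_filter <- function(trace, hdop_max = 2.0, nsat_min = 6,
                           max_gap_s = 0.5) {
  stopifnot(inherits(trace, "gps_trace"))
  if (!any(c("hdop", "nsat") %in% names(trace))) {
    warning("no QC fields present; trace passed through unfiltered")
    attr(trace, "qc_report") <- list(n_retained = nrow(trace),
                                     n_interpolated = 0L, n_dropped = 0L)
    return(trace)
  }
  bad <- rep(FALSE, nrow(trace))
  if ("hdop" %in% names(trace)) bad <- bad | (!is.na(trace$hdop) & trace$hdop > hdop_max)
  if ("nsat" %in% names(trace)) bad <- bad | (!is.na(trace$nsat) & trace$nsat < nsat_min)
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  interp <- rep(FALSE, nrow(trace))
  drop <- rep(FALSE, nrow(trace))
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    run <- seq(starts[j], ends[j])
    dur <- trace$t[min(ends[j] + 1L, nrow(trace))] - trace$t[max(starts[j] - 1L, 1L)]
    isolated <- (trace$t[ends[j]] - trace$t[starts[j]]) < max_gap_s &&
      starts[j] > 1L && ends[j] < nrow(trace) && dur < 2 * max_gap_s
    if (isolated) interp[run] <- TRUE else drop[run] <- TRUE
  }
  out <- trace
  if (any(interp)) {
    good <- !bad
    out$v[interp] <- stats::approx(out$t[good], out$v[good],
                                   xout = out$t[interp])$y
  }
  if (any(drop)) out <- out[!drop, , drop = FALSE]
  out$gap <- c(FALSE, diff(out$t) > 0.15)
  out <- structure(out, class = class(trace))
  attr(out, "qc_report") <- list(
    n_retained = nrow(out) - sum(interp),
    n_interpolated = sum(interp),
    n_dropped = sum(drop)
  )
  out
}

#' Full GPS-to-power processing pipeline
#'
#' Chains [sync_to_first_movement()], [quality_filter()], [smooth_speed()],
#' [add_acceleration()], optionally [add_heading()], and per-sample
#' metabolic power under the chosen energy-cost model.
#'
#' @param trace A [gps_trace()].
#' @param model A [cost_model()].
#' @param window_s Acceleration window, seconds.
#' @param smooth_method Passed to [smooth_speed()].
#' @param heading Add heading when coordinates are present? Default `TRUE`.
#' @param qc Apply [quality_filter()]? Default `TRUE`.
#' @return A `kinematic_series` with `cost` (J/kg/m) and `power` (W/kg)
#'   columns; attributes `qc_report`, `model`, `total_distance_m`,
#'   `duration_s` and `mean_power` summarise the session.
#' @export
process_gps <- function(trace, model = cost_model("new"), window_s = 0.3,
                        smooth_method = "decimate", heading = TRUE, qc = TRUE) {
  trace <- sync_to_first_movement(trace)
  qc_report <- NULL
  if (qc && any(c("hdop", "nsat") %in% names(trace))) {
    trace <- quality_filter(trace)
    qc_report <- attr(trace, "qc_report")
  }
  ks <- smooth_speed(trace, method = smooth_method)
  ks <- add_acceleration(ks, window_s = window_s)
  if (heading && all(c("lat", "lon") %in% names(ks))) ks <- add_heading(ks)
  ok <- !is.na(ks$es)
  ks$cost <- NA_real_
  ks$cost[ok] <- energy_cost(model, ks$es[ok])
  ks$power <- ks$cost * ks$em * ks$v_s
  dt <- sample_dt(ks$t)
  attr(ks, "model") <- model
  attr(ks, "qc_report") <- qc_report
  attr(ks, "total_distance_m") <- sum(ks$v_s * dt)
  attr(ks, "duration_s") <- sum(dt)
  attr(ks, "mean_power") <- sum(ks$power * dt, na.rm = TRUE) / sum(dt[!is.na(ks$power)])
  ks
}

## Per-sample durations from a time grid (last sample gets the median step).
sample_dt <- function(t) {
  if (length(t) == 1L) return(1)
  d <- diff(t)
  c(d, stats::median(d))
}
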