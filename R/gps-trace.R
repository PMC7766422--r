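#' Construct a GPS trace
#'
#' A `gps_trace` is a tibble of raw positional / Doppler-speed samples at a
#' nominal 10 Hz with optional fix-quality fields. Time must be strictly
#' increasing and speed non-negative; sampling gaps (dt > 0.15 s at a nominal
#' 10 Hz) are flagged in the `gap` column.
#'
#' @param t Time from session start, seconds, strictly increasing.
#' @param v Doppler speed, m/s, non-negative.
#' @param lat,lon Optional WGS-84 decimal degrees.
#' @param hdop Optional horizontal dilution of precision.
#' @param nsat Optional count of satellites used.
#' @return A tibble of class `gps_trace`.
#' @examples
#' gps_trace(t = seq(0, 1, 0.1), v = rep(2.5, 11))
#' @export
gps_trace <- function(t, v, lat = NULL, lon = NULL, hdop = NULL, nsat = NULL) {
  if (length(t) == 0L) stop("empty trace", call. = FALSE)
  if (length(t) != length(v)) stop("`t` and `v` lengths differ", call. = FALSE)
  if (anyNA(t) || any(!is.finite(t))) stop("`t` must be finite", call. = FALSE)
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing", call. = FALSE)
  if (anyNA(v) || any(v < 0)) stop("`v` must be non-negative", call. = FALSE)
  x <- tibble::tibble(t = as.numeric(t), v = as.numeric(v))
  for (col in c("lat", "lon", "hdop", "nsat")) {
    val <- get(col)
    if (!is.null(val)) {
      if (length(val) != nrow(x)) stop("`", col, "` length differs", call. = FALSE)
      x[[col]] <- as.numeric(val)
    }
  }
  x$gap <- c(FALSE, diff(x$t) > 0.15)
  structure(x, class = c("gps_trace", class(tibble::tibble())))
}

#' Coerce a data frame to a GPS trace
#' @param x A data frame with at least `t` and `v` (or `t_s`/`v_ms`) columns.
#' @return A [gps_trace()].
#' @export
as_gps_trace <- function(x) {
  nm <- names(x)
  pick <- function(...) {
    for (cand in c(...)) if (cand %in% nm) return(x[[cand]])
    NULL
  }
  t <- pick("t", "t_s"); v <- pick("v", "v_ms")
  if (is.null(t) || is.null(v)) {
    stop("need `t`/`t_s` and `v`/`v_ms` columns", call. = FALSE)
  }
  gps_trace(t, v, lat = pick("lat"), lon = pick("lon"),
            hdop = pick("hdop"), nsat = pick("nsat"))
}

#' Read a GPS trace from CSV
#'
#' Column dialect: `t_s,v_ms[,lat,lon,hdop,nsat]`.
#'
#' @param path CSV file path.
#' @return A [gps_trace()].
#' @export
read_gps_csv <- function(path) {
  as_gps_trace(utils::read.csv(path))
}

#' Write a GPS trace to CSV
#' @param x A [gps_trace()].
#' @param path Output path.
#' @export
write_gps_csv <- function(x, path) {
  out <- as.data.frame(x)
  names(out)[names(out) == "t"] <- "t_s"
  names(out)[names(out) == "v"] <- "v_ms"
  out$gap <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

KNOT_MS <- 0.514444

nmea_checksum <- function(body) {
  cs <- 0L
  for (ch in utf8ToInt(body)) cs <- bitwXor(cs, ch)
  sprintf("%02X", cs)
}

nmea_lat <- function(field, hemi) {
  if (field == "") return(NA_real_)
  deg <- floor(as.numeric(field) / 100)
  min <- as.numeric(field) - deg * 100
  out <- deg + min / 60
  if (hemi %in% c("S", "W")) out <- -out
  out
}

nmea_time_s <- function(field) {
  # hhmmss.sss -> seconds of day
  if (field == "") return(NA_real_)
  h <- as.numeric(substr(field, 1, 2))
  m <- as.numeric(substr(field, 3, 4))
  s <- as.numeric(substring(field, 5))
  h * 3600 + m * 60 + s
}

#' Read a GPS trace from an NMEA 0183 stream
#'
#' Parses `RMC` (time, position, speed over ground in knots), `VTG` (speed
#' over ground) and `GGA` (time, position, satellites used, HDOP) sentences;
#' sentences with an invalid checksum are dropped with a warning. Speed is
#' converted from knots to m/s, and time is re-zeroed to the first fix.
#'
#' @param path Path to a text file of NMEA sentences.
#' @return A [gps_trace()].
#' @export
read_nmea <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[startsWith(lines, "$")]
  if (length(lines) == 0L) stop("no NMEA sentences found", call. = FALSE)
  ok <- vapply(lines, function(l) {
    star <- regexpr("\\*", l)
    if (star < 0) return(TRUE)  # checksum optional
    body <- substr(l, 2, star - 1L)
    identical(toupper(substr(l, star + 1L, star + 2L)), nmea_checksum(body))
  }, logical(1), USE.NAMES = FALSE)
  if (any(!ok)) {
    warning(sum(!ok), " NMEA sentence(s) failed checksum; dropped")
    lines <- lines[ok]
  }
  recs <- list()  # keyed by time-of-day string
  for (l in lines) {
    body <- sub("\\*..$", "", substring(l, 2))
    f <- strsplit(body, ",", fixed = TRUE)[[1L]]
    type <- substr(f[1L], 3, 5)
    if (type == "RMC" && length(f) >= 8) {
      key <- f[2L]
      rec <- recs[[key]] %||% list(t = nmea_time_s(f[2L]))
      if (f[3L] == "A") {
        rec$v <- as.numeric(f[8L]) * KNOT_MS
        rec$lat <- nmea_lat(f[4L], f[5L])
        rec$lon <- nmea_lat(f[6L], f[7L])
        rec$course <- suppressWarnings(as.numeric(f[9L]))
      }
      recs[[key]] <- rec
    } else if (type == "GGA" && length(f) >= 9) {
      key <- f[2L]
      rec <- recs[[key]] %||% list(t = nmea_time_s(f[2L]))
      rec$lat <- nmea_lat(f[3L], f[4L])
      rec$lon <- nmea_lat(f[5L], f[6L])
      rec$nsat <- as.numeric(f[8L])
      rec$hdop <- as.numeric(f[9L])
      recs[[key]] <- rec
    }
  }
  recs <- Filter(function(r) !is.null(r$v), recs)
  if (length(recs) == 0L) stop("no speed-carrying NMEA sentences", call. = FALSE)
  grab <- function(fld) vapply(recs, function(r) r[[fld]] %||% NA_real_, 0)
  t <- grab("t")
  o <- order(t)
  t <- t[o] - t[o][1L]
  gps_trace(t = t, v = grab("v")[o], lat = grab("lat")[o], lon = grab("lon")[o],
            hdop = grab("hdop")[o], nsat = grab("nsat")[o])
}

#' Write a GPS trace as NMEA 0183 sentences
#'
#' Emits one `GPRMC` and one `GPGGA` sentence per sample (checksummed), the
#' inverse of [read_nmea()] up to coordinate rounding.
#'
#' @param x A [gps_trace()] with `lat`/`lon` present.
#' @param path Output path.
#' @export
write_nmea <- function(x, path) {
  if (!all(c("lat", "lon") %in% names(x))) {
    stop("NMEA output needs lat/lon", call. = FALSE)
  }
  fmt_time <- function(t) {
    h <- floor(t / 3600); m <- floor((t - h * 3600) / 60)
    s <- t - h * 3600 - m * 60
    sprintf("%02d%02d%06.3f", h, m, s)
  }
  fmt_ll <- function(dd, lat = TRUE) {
    hemi <- if (lat) c("N", "S") else c("E", "W")
    h <- if (dd >= 0) hemi[1L] else hemi[2L]
    dd <- abs(dd)
    deg <- floor(dd)
    minutes <- (dd - deg) * 60
    c(sprintf(if (lat) "%02d%08.5f" else "%03d%08.5f", deg, minutes), h)
  }
  out <- character(0)
  for (i in seq_len(nrow(x))) {
    tt <- fmt_time(x$t[i] + 10 * 3600)  # arbitrary 10:00:00 session start
    la <- fmt_ll(x$lat[i], TRUE); lo <- fmt_ll(x$lon[i], FALSE)
    kn <- sprintf("%.3f", x$v[i] / KNOT_MS)
    rmc <- paste("GPRMC", tt, "A", la[1L], la[2L], lo[1L], lo[2L], kn,
                 "0.0", "010120", "", "", sep = ",")
    hdop <- if ("hdop" %in% names(x)) sprintf("%.1f", x$hdop[i]) else "1.0"
    nsat <- if ("nsat" %in% names(x)) sprintf("%02d", round(x$nsat[i])) else "09"
    gga <- paste("GPGGA", tt, la[1L], la[2L], lo[1L], lo[2L], "1", nsat,
                 hdop, "50.0,M,45.0,M,,", sep = ",")
    out <- c(out,
             paste0("$", rmc, "*", nmea_checksum(rmc)),
             paste0("$", gga, "*", nmea_checksum(gga)))
  }
  writeLines(out, path)
  invisible(path)
}
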