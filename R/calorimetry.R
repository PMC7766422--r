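## Fixed energetic equivalents. 20.9 J per mL O2 corresponds to a non-protein
## respiratory exchange ratio of 0.96; 3 mL O2 per kg per mM is the classical
## energy equivalent of net blood-lactate accumulation.
J_PER_ML_O2 <- 20.9
O2_PER_MM_LACTATE <- 3
REST_VO2_DEFAULT <- 3.5  # mL/kg/min

#' Construct a breath-by-breath oxygen-uptake series
#'
#' Time-stamped VO2 records with an explicit unit tag and an exercise phase
#' label. Phases must be contiguous and ordered rest, exercise, recovery
#' (any of them may be absent). Absolute (mL/min) records require a body
#' mass to be interpretable per kilogram; unit guessing is never attempted.
#'
#' @param t Time, seconds, strictly increasing.
#' @param vo2 Oxygen uptake, non-negative, in the unit given by `unit`.
#' @param phase Character/factor: `"rest"`, `"exercise"` or `"recovery"`.
#' @param unit `"ml_kg_min"` (relative) or `"ml_min"` (absolute).
#' @param mass Body mass in kg; mandatory when `unit = "ml_min"`.
#' @return A tibble of class `breath_series` with `vo2` in mL/kg/min.
#' @export
breath_series <- function(t, vo2, phase = "exercise",
                          unit = c("ml_kg_min", "ml_min"), mass = NULL) {
  unit <- match.arg(unit)
  if (length(t) != length(vo2)) stop("`t`/`vo2` lengths differ", call. = FALSE)
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing", call. = FALSE)
  if (anyNA(vo2) || any(vo2 < 0)) stop("`vo2` must be non-negative", call. = FALSE)
  phase <- rep_len(as.character(phase), length(t))
  allowed <- c("rest", "exercise", "recovery")
  if (!all(phase %in% allowed)) {
    stop("phases must be rest/exercise/recovery", call. = FALSE)
  }
  seen <- rle(phase)$values
  if (anyDuplicated(seen) || is.unsorted(match(seen, allowed))) {
    stop("phases must be contiguous and ordered rest -> exercise -> recovery",
         call. = FALSE)
  }
  if (unit == "ml_min") {
    if (is.null(mass)) {
      stop("absolute VO2 (mL/min) requires `mass` in kg", call. = FALSE)
    }
    vo2 <- vo2 / mass
  }
  structure(
    tibble::tibble(t = as.numeric(t), vo2 = as.numeric(vo2), phase = phase),
    class = c("breath_series", class(tibble::tibble())),
    mass = mass
  )
}

#' Read a breath series from CSV
#'
#' Column dialect: `t_s,vo2_mlmin[,vo2_mlkgmin],phase`. When both VO2 columns
#' are present the relative one is used.
#'
#' @param path CSV path.
#' @param mass Body mass (kg), required if only `vo2_mlmin` is present.
#' @return A [breath_series()].
#' @export
read_breath_csv <- function(path, mass = NULL) {
  x <- utils::read.csv(path)
  if ("vo2_mlkgmin" %in% names(x)) {
    breath_series(x$t_s, x$vo2_mlkgmin, phase = x$phase, unit = "ml_kg_min")
  } else if ("vo2_mlmin" %in% names(x)) {
    breath_series(x$t_s, x$vo2_mlmin, phase = x$phase, unit = "ml_min",
                  mass = mass)
  } else {
    stop("need a `vo2_mlkgmin` or `vo2_mlmin` column", call. = FALSE)
  }
}

phase_slice <- function(breaths, which) {
  out <- breaths[breaths$phase == which, , drop = FALSE]
  if (nrow(out) == 0L) stop("no `", which, "` phase in series", call. = FALSE)
  out
}

## Time-weighted trapezoidal integral of y over t (units of y times seconds).
trapz_s <- function(t, y) pracma::trapz(t, y)

#' Average a breath series over 1-minute bins
#'
#' Time-weighted mean per non-overlapping 60 s bin, computed within each
#' phase separately (bins restart at phase boundaries). A trailing bin
#' shorter than 60 s is kept but flagged `partial`.
#'
#' @param breaths A [breath_series()].
#' @return A tibble with `t` (bin start, s), `vo2` (mL/kg/min), `phase`,
#'   `partial`.
#' @export
minute_average <- function(breaths) {
  stopifnot(inherits(breaths, "breath_series"))
  if (diff(range(breaths$t)) < 60) stop("need at least 60 s of data", call. = FALSE)
  out <- list()
  for (ph in unique(breaths$phase)) {
    b <- breaths[breaths$phase == ph, , drop = FALSE]
    t0 <- b$t[1L]
    span <- b$t[nrow(b)] - t0
    nbin <- max(1L, ceiling(span / 60))
    for (k in seq_len(nbin)) {
      lo <- t0 + (k - 1L) * 60
      hi <- lo + 60
      sel <- b$t >= lo & b$t <= hi
      if (sum(sel) < 2L) next
      tt <- b$t[sel]; yy <- b$vo2[sel]
      m <- trapz_s(tt, yy) / (tt[length(tt)] - tt[1L])
      out[[length(out) + 1L]] <- tibble::tibble(
        t = lo, vo2 = m, phase = ph,
        partial = (tt[length(tt)] - tt[1L]) < 59
      )
    }
  }
  do.call(rbind, out)
}

#' Steady-state oxygen uptake of a constant-speed run
#'
#' Mean of the 1-minute averages over the final 3 minutes of the exercise
#' phase; the exercise phase must last at least 4 minutes so that the
#' on-transient is excluded.
#'
#' @param breaths A [breath_series()] with an exercise phase.
#' @return Steady-state VO2, mL/kg/min.
#' @export
steady_state_vo2 <- function(breaths) {
  ex <- phase_slice(breaths, "exercise")
  dur <- ex$t[nrow(ex)] - ex$t[1L]
  if (dur < 240) stop("exercise phase shorter than 4 min", call. = FALSE)
  t_end <- ex$t[nrow(ex)]
  sel <- ex$t >= t_end - 180
  mins <- minute_average(breath_series(ex$t[sel], ex$vo2[sel], "exercise"))
  mean(mins$vo2)
}

#' Energy cost of constant-speed linear running (Cr)
#'
#' `Cr = net VO2 / v`, with net VO2 the steady-state uptake above rest
#' converted to J/kg/s through the 20.9 J/mL O2 equivalent.
#'
#' @param vo2_ss Steady-state VO2, mL/kg/min.
#' @param vo2_rest Resting VO2, mL/kg/min (default 3.5).
#' @param v Running speed, m/s.
#' @param j_per_ml Energy equivalent of oxygen, J/mL.
#' @return Energy cost in J/kg/m.
#' @examples
#' linear_cost_cr(41.75, 3.5, 2.86)
#' @export
linear_cost_cr <- function(vo2_ss, vo2_rest = REST_VO2_DEFAULT, v,
                           j_per_ml = J_PER_ML_O2) {
  if (v <= 0) stop("speed must be positive", call. = FALSE)
  net <- vo2_ss - vo2_rest
  if (net <= 0) stop("steady-state VO2 must exceed rest", call. = FALSE)
  (net / 60) * j_per_ml / v
}

#' Aerobic energy above rest over the exercise phase
#'
#' Trapezoidal integral of net VO2 (uptake minus rest, clipped at zero
#' per sample) from exercise onset to the end of the exercise phase,
#' converted to J/kg.
#'
#' @param breaths A [breath_series()].
#' @param rest Resting VO2, mL/kg/min.
#' @param j_per_ml Energy equivalent of oxygen, J/mL.
#' @return Aerobic energy in J/kg.
#' @export
aerobic_energy <- function(breaths, rest = REST_VO2_DEFAULT,
                           j_per_ml = J_PER_ML_O2) {
  ex <- phase_slice(breaths, "exercise")
  net <- pmax(ex$vo2 - rest, 0)
  trapz_s(ex$t, net) / 60 * j_per_ml
}

#' Anaerobic alactic energy from the fast oxygen debt
#'
#' Estimates the fast (phosphocreatine) component of the oxygen debt from the
#' first 6 minutes of recovery. The default estimator subtracts a slow-
#' component baseline — the time-weighted mean of net VO2 over the 4th to 6th
#' minute of recovery — times 6 minutes from the total 0-6 min net recovery
#' integral, and floors the result at zero. A mono-exponential fit of the
#' net recovery curve (`A * exp(-t/tau)`, debt `A * tau`) is available with
#' `method = "exponential"`.
#'
#' @param breaths A [breath_series()] with at least 6 min of recovery.
#' @param rest Resting VO2, mL/kg/min.
#' @param method `"baseline"` (default) or `"exponential"`.
#' @param j_per_ml Energy equivalent of oxygen, J/mL.
#' @return Alactic energy in J/kg.
#' @export
alactic_debt <- function(breaths, rest = REST_VO2_DEFAULT,
                         method = c("baseline", "exponential"),
                         j_per_ml = J_PER_ML_O2) {
  method <- match.arg(method)
  rec <- phase_slice(breaths, "recovery")
  t <- rec$t - rec$t[1L]
  if (t[length(t)] < 360) stop("need at least 6 min of recovery", call. = FALSE)
  net <- pmax(rec$vo2 - rest, 0)
  sel6 <- t <= 360
  if (method == "baseline") {
    total_ml <- trapz_s(t[sel6], net[sel6]) / 60            # mL/kg
    selb <- t >= 180 & t <= 360                             # minutes 4-6
    base <- trapz_s(t[selb], net[selb]) / (t[selb][sum(selb)] - t[selb][1L])
    debt_ml <- max(0, total_ml - base * 6)
  } else {
    d <- data.frame(t = t[sel6], net = net[sel6])
    fit <- minpack.lm::nlsLM(net ~ A * exp(-t / tau), data = d,
                             start = list(A = max(d$net), tau = 40),
                             lower = c(0, 1), upper = c(Inf, 600))
    cf <- stats::coef(fit)
    debt_ml <- cf[["A"]] * cf[["tau"]] / 60                 # mL/kg
  }
  debt_ml * j_per_ml
}

#' Anaerobic lactic energy from net blood-lactate accumulation
#'
#' Net post-exercise lactate rise converted through ~3 mL O2/kg per mM and
#' 20.9 J/mL O2.
#'
#' @param la_post,la_pre Blood lactate, mmol/L.
#' @param o2_per_mm Oxygen equivalent of lactate, mL/kg per mM.
#' @param j_per_ml Energy equivalent of oxygen, J/mL.
#' @return Lactic energy in J/kg.
#' @examples
#' lactic_energy(7.2, 1.0)
#' @export
lactic_energy <- function(la_post, la_pre, o2_per_mm = O2_PER_MM_LACTATE,
                          j_per_ml = J_PER_ML_O2) {
  if (la_post < 0 || la_pre < 0) stop("lactate must be non-negative", call. = FALSE)
  max(0, la_post - la_pre) * o2_per_mm * j_per_ml
}

#' Three-compartment energy partition and direct metabolic power
#'
#' Combines aerobic, anaerobic alactic and anaerobic lactic energy into the
#' total energy expenditure above rest, the session energy cost
#' `C = total / distance` (J/kg/m) and the direct metabolic power
#' `P_VO2 = C * mean speed` (W/kg).
#'
#' @param aer,anal,anl Energy components, J/kg (each >= 0).
#' @param distance Distance covered, m (> 0).
#' @param duration Session duration, s (> 0).
#' @param mass Optional body mass, kg (metadata).
#' @param delta_la Optional net lactate rise, mM (metadata).
#' @return An object of class `energy_partition`: a list with `aer`, `anal`,
#'   `anl`, `total` (J/kg), `c` (J/kg/m), `pvo2` (W/kg), `distance`,
#'   `duration`, `mass`, `delta_la`.
#' @examples
#' energy_partition(aer = 6855, anal = 410, anl = 389,
#'                  distance = 1168, duration = 480)
#' @export
energy_partition <- function(aer, anal, anl, distance, duration,
                             mass = NA_real_, delta_la = NA_real_) {
  if (distance <= 0 || duration <= 0) {
    stop("distance and duration must be positive", call. = FALSE)
  }
  if (any(c(aer, anal, anl) < 0)) {
    stop("energy components must be non-negative", call. = FALSE)
  }
  total <- aer + anal + anl
  cc <- total / distance
  structure(
    list(aer = aer, anal = anal, anl = anl, total = total,
         c = cc, pvo2 = cc * distance / duration,
         distance = distance, duration = duration,
         mass = mass, delta_la = delta_la),
    class = "energy_partition"
  )
}

#' @export
print.energy_partition <- function(x, ...) {
  cat("<energy_partition>\n")
  cat(sprintf("  aerobic        : %8.1f J/kg (%.0f%%)\n", x$aer, 100 * x$aer / x$total))
  cat(sprintf("  alactic (AnAl) : %8.1f J/kg (%.0f%%)\n", x$anal, 100 * x$anal / x$total))
  cat(sprintf("  lactic  (AnL)  : %8.1f J/kg (%.0f%%)\n", x$anl, 100 * x$anl / x$total))
  cat(sprintf("  total          : %8.1f J/kg over %.0f m in %.0f s\n",
              x$total, x$distance, x$duration))
  cat(sprintf("  energy cost C  : %8.2f J/kg/m\n", x$c))
  cat(sprintf("  direct power   : %8.2f W/kg\n", x$pvo2))
  invisible(x)
}

#' Direct-calorimetry partition of a full session
#'
#' Convenience wrapper running [aerobic_energy()], [alactic_debt()] and
#' [lactic_energy()] on a breath series with exercise and recovery phases,
#' and assembling the [energy_partition()].
#'
#' @param breaths A [breath_series()] with exercise and >= 6 min recovery.
#' @param la_pre,la_post Blood lactate before/after, mM.
#' @param distance Distance covered, m.
#' @param duration Exercise duration, s; default the exercise-phase span.
#' @param rest Resting VO2, mL/kg/min; default the time-weighted mean of the
#'   rest phase when present, else 3.5.
#' @param anal_method Passed to [alactic_debt()].
#' @return An [energy_partition()].
#' @export
calorimetry_partition <- function(breaths, la_pre, la_post, distance,
                                  duration = NULL, rest = NULL,
                                  anal_method = "baseline") {
  stopifnot(inherits(breaths, "breath_series"))
  if (is.null(rest)) {
    rest <- if ("rest" %in% breaths$phase) {
      r <- phase_slice(breaths, "rest")
      if (nrow(r) >= 2L) trapz_s(r$t, r$vo2) / (r$t[nrow(r)] - r$t[1L]) else mean(r$vo2)
    } else {
      REST_VO2_DEFAULT
    }
  }
  ex <- phase_slice(breaths, "exercise")
  if (is.null(duration)) duration <- ex$t[nrow(ex)] - ex$t[1L]
  energy_partition(
    aer = aerobic_energy(breaths, rest = rest),
    anal = alactic_debt(breaths, rest = rest, method = anal_method),
    anl = lactic_energy(la_post, la_pre),
    distance = distance, duration = duration,
    mass = attr(breaths, "mass") %||% NA_real_,
    delta_la = la_post - la_pre
  )
}
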