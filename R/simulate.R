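#' Describe one phase of the intermittent circuit
#'
#' A phase is a chain of straight segments separated by instantaneous turns,
#' run at a target speed (or flat-out for `speed = Inf`), starting from and
#' ending at a complete stop, followed by a passive recovery break that may
#' contain a short repositioning walk to the next phase's start.
#'
#' @param label Phase label.
#' @param segments Segment lengths, m (all > 0).
#' @param turns Turn angles between consecutive segments, degrees
#'   (length `length(segments) - 1`). Turns of 150 degrees or more force a
#'   full stop at the corner; gentler turns are taken at a reduced speed.
#' @param speed Target speed, m/s; `Inf` for a maximal sprint.
#' @param recovery_s Passive recovery after the phase, s.
#' @param reposition_m Walking distance to the next start, covered inside the
#'   recovery break, m.
#' @return A list of class `circuit_phase`.
#' @export
circuit_phase <- function(label, segments, turns = numeric(0), speed,
                          recovery_s = 0, reposition_m = 0) {
  if (any(segments <= 0)) stop("segment lengths must be positive", call. = FALSE)
  if (length(turns) != length(segments) - 1L) {
    stop("need one turn per internal segment boundary", call. = FALSE)
  }
  structure(list(label = label, segments = segments, turns = turns,
                 speed = speed, recovery_s = recovery_s,
                 reposition_m = reposition_m),
            class = "circuit_phase")
}

#' Soccer-specific intermittent circuit specification
#'
#' The default spec encodes one ~1-minute lap with four phases — a maximal
#' sprint triangle (21.2 m with two changes of direction > 60 degrees),
#' 40 m of linear striding at 14.4 km/h, a 28 m slalom at 10.1 km/h and a
#' 20 + 20 m shuttle at 14.4 km/h — with the ~25 s of passive recovery per
#' lap fractioned into breaks shorter than 10 s (6 s after the sprint, 9 s
#' after the slalom, 10 s after the shuttle). Laps are mirrored: each lap
#' starts where the previous one ended and runs the sequence in the opposite
#' direction. Default 8 laps, about 8 minutes of exercise.
#'
#' @param laps Number of laps, default 8.
#' @param mirror Alternate direction each lap? Default `TRUE`.
#' @param phases List of [circuit_phase()] objects; default as above.
#' @return A list of class `circuit_spec`.
#' @export
circuit_spec <- function(laps = 8, mirror = TRUE, phases = NULL) {
  if (is.null(phases)) {
    ## cruise speeds are set so that each phase covers its marked distance in
    ## its nominal time from a standing start to a full stop — the nominal
    ## intensities (14.4, 10.1, 14.4 km/h) are phase-average speeds
    ## (distance / time), so the cruise portion must run faster
    phases <- list(
      circuit_phase("sprint_triangle", segments = c(7.1, 7.1, 7.0),
                    turns = c(110, 110), speed = Inf,
                    recovery_s = 6, reposition_m = 7),
      circuit_phase("linear_striding", segments = 40, speed = 4.8),
      circuit_phase("slalom", segments = rep(4, 7),
                    turns = c(55, -55, 55, -55, 55, -55), speed = 3.3,
                    recovery_s = 9, reposition_m = 6),
      circuit_phase("shuttle", segments = c(20, 20), turns = 180,
                    speed = 5.4, recovery_s = 10, reposition_m = 7)
    )
  }
  stopifnot(all(vapply(phases, inherits, TRUE, "circuit_phase")))
  structure(list(laps = as.integer(laps), mirror = isTRUE(mirror),
                 phases = phases),
            class = "circuit_spec")
}

#' Scale the target speeds of a circuit spec
#'
#' Multiplies all finite phase target speeds by a factor — a simple model of
#' between-player differences in circuit execution.
#'
#' @param spec A [circuit_spec()].
#' @param factor Positive scale factor.
#' @return The scaled spec.
#' @export
scale_speeds <- function(spec, factor) {
  stopifnot(inherits(spec, "circuit_spec"), factor > 0)
  spec$phases <- lapply(spec$phases, function(p) {
    if (is.finite(p$speed)) p$speed <- p$speed * factor
    p
  })
  spec
}

#' Read a circuit spec from YAML
#' @param path YAML file with keys `laps`, `mirror`, `phases` (each phase:
#'   `label`, `segments`, `turns`, `speed_kmh` or `max: true`,
#'   `recovery_s`, `reposition_m`).
#' @return A [circuit_spec()].
#' @export
read_circuit_spec <- function(path) {
  y <- yaml::read_yaml(path)
  phases <- lapply(y$phases, function(p) {
    circuit_phase(p$label, unlist(p$segments), unlist(p$turns) %||% numeric(0),
                  speed = if (isTRUE(p$max)) Inf else p$speed_kmh / 3.6,
                  recovery_s = p$recovery_s %||% 0,
                  reposition_m = p$reposition_m %||% 0)
  })
  circuit_spec(laps = y$laps %||% 8, mirror = y$mirror %||% TRUE,
               phases = phases)
}

#' Physiological parameters of the simulated player
#'
#' @param mass Body mass, kg.
#' @param vo2max Maximal oxygen uptake, mL/kg/min.
#' @param vo2_rest Resting oxygen uptake, mL/kg/min.
#' @param tau_on,tau_off On/off first-order VO2 time constants, s.
#' @param tau_pcr Time constant of phosphocreatine (fast oxygen-debt)
#'   repayment, s: the outstanding fast debt drives extra uptake at
#'   `debt * 60 / tau_pcr` mL/kg/min.
#' @param tau_slow Time constant of the slow (lactate-linked) recovery
#'   component, s.
#' @param la_gain Blood-lactate rise per J/kg of supra-maximal energy
#'   demand, mM per J/kg.
#' @param la_rest Resting blood lactate, mM.
#' @param gps_noise_sd Gaussian noise sd on GPS Doppler speed, m/s.
#' @param breath_noise Multiplicative breath-level noise sd (fraction).
#' @return A list of class `physio_params`.
#' @export
physio_params <- function(mass = 76.5, vo2max = 61.1, vo2_rest = 3.5,
                          tau_on = 25, tau_off = 30, tau_pcr = 100,
                          tau_slow = 1800, la_gain = 0.003,
                          la_rest = 1.0, gps_noise_sd = 0.1,
                          breath_noise = 0.03) {
  p <- list(mass = mass, vo2max = vo2max, vo2_rest = vo2_rest,
            tau_on = tau_on, tau_off = tau_off, tau_pcr = tau_pcr,
            tau_slow = tau_slow, la_gain = la_gain,
            la_rest = la_rest, gps_noise_sd = gps_noise_sd,
            breath_noise = breath_noise)
  strict <- c("mass", "vo2max", "vo2_rest", "tau_on", "tau_off",
              "tau_pcr", "tau_slow", "la_rest")
  if (any(unlist(p[strict]) <= 0)) {
    stop("physiological parameters must be positive", call. = FALSE)
  }
  if (any(unlist(p[c("la_gain", "gps_noise_sd", "breath_noise")]) < 0)) {
    stop("noise and gain parameters must be non-negative", call. = FALSE)
  }
  structure(p, class = "physio_params")
}

## ---- trajectory integrator -------------------------------------------------

## mutable recorder: time, speed, accel, heading, x, y appended in blocks
new_recorder <- function() {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$cap <- 65536L
  for (f in c("t", "v", "a", "h", "x", "y")) env[[f]] <- numeric(env$cap)
  env$time <- 0; env$speed <- 0; env$heading <- 0; env$px <- 0; env$py <- 0
  env$accel <- 0
  env
}

## append a block of steps sharing one heading (straight-line motion)
rec_push_block <- function(env, dur, v1, a) {
  m <- length(dur)
  if (m == 0L) return(invisible(NULL))
  v_prev <- c(env$speed, v1[-m])
  ds <- (v_prev + v1) / 2 * dur
  rad <- env$heading * pi / 180
  x <- env$px + cumsum(ds) * sin(rad)
  y <- env$py + cumsum(ds) * cos(rad)
  t <- env$time + cumsum(dur)
  while (env$n + m > env$cap) {
    env$cap <- env$cap * 2L
    for (f in c("t", "v", "a", "h", "x", "y")) {
      tmp <- numeric(env$cap); tmp[seq_len(env$n)] <- env[[f]][seq_len(env$n)]
      env[[f]] <- tmp
    }
  }
  i <- env$n + seq_len(m)
  env$t[i] <- t; env$v[i] <- v1; env$a[i] <- a
  env$h[i] <- env$heading %% 360; env$x[i] <- x; env$y[i] <- y
  env$n <- env$n + m
  env$time <- t[m]; env$speed <- v1[m]
  env$px <- x[m]; env$py <- y[m]
  invisible(NULL)
}

## corner speed allowed through a turn of `angle` degrees
corner_speed <- function(angle) {
  angle <- abs(angle)
  if (angle >= 150) 0 else 7 * (1 - angle / 180)
}

## march one straight segment: accelerate toward v_target under a_fun(v)
## with an exponential ease-in near the target, brake so as to exit at
## v_exit when the segment ends. Braking magnitude scales with the speed at
## braking onset (clamped to [1, brake] m/s^2 — people do not brake at
## 4 m/s^2 out of a walk) and is frozen for the whole event; all
## acceleration changes are jerk-limited so force application is continuous.
march_segment <- function(env, L, v_target, v_exit, a_fun, brake, dt = 0.01,
                          gain = 2, jerk = 8) {
  cap <- 1024L
  durs <- numeric(cap); vs <- numeric(cap); as_ <- numeric(cap)
  m <- 0L
  s <- 0
  v <- env$speed
  a_prev <- env$accel
  b_frozen <- NA_real_
  guard <- 0L
  while (L - s > 1e-9) {
    guard <- guard + 1L
    if (guard > 1e6) stop("integrator failed to converge", call. = FALSE)
    d_rem <- L - s
    b_cand <- if (is.na(b_frozen)) min(brake, max(1, 0.7 * v)) else b_frozen
    ## anticipate the jerk-limited ramp onto the brake
    ramp_d <- v * (a_prev + b_cand) / jerk / 2
    if (v > v_exit &&
        d_rem <= (v^2 - v_exit^2) / (2 * b_cand) + max(0, ramp_d)) {
      if (is.na(b_frozen)) b_frozen <- b_cand
      a_des <- -b_frozen
    } else if (v < v_target) {
      a_des <- min(a_fun(v), gain * (v_target - v))
    } else if (v > v_target) {
      a_des <- max(-b_cand, gain * (v_target - v))
    } else {
      a_des <- 0
    }
    a <- a_prev + max(-jerk * dt, min(jerk * dt, a_des - a_prev))
    a_state <- a
    if (a < 0 && v > v_exit && v + a * dt < v_exit) {
      a <- (v_exit - v) / dt
      a_state <- 0
    }
    v1 <- max(0, v + a * dt)
    if (v1 < 1e-6 && v < 1e-6) {
      ## stalled short of the segment end (discretisation): creep forward
      v1 <- min(0.5, if (is.finite(v_target)) v_target else 0.5)
      a <- (v1 - v) / dt
      a_state <- 0
    }
    ds <- (v + v1) / 2 * dt
    dur <- dt
    if (ds > d_rem) {
      frac <- d_rem / ds
      dur <- dt * frac
      v1 <- v + a * dur
      ds <- d_rem
    }
    m <- m + 1L
    if (m > cap) {
      cap <- cap * 2L
      durs <- c(durs, numeric(cap / 2L)); vs <- c(vs, numeric(cap / 2L))
      as_ <- c(as_, numeric(cap / 2L))
    }
    durs[m] <- dur; vs[m] <- v1; as_[m] <- a
    s <- s + ds
    v <- v1
    a_prev <- a_state
  }
  env$accel <- a_prev
  idx <- seq_len(m)
  rec_push_block(env, durs[idx], vs[idx], as_[idx])
  invisible(s)
}

stand <- function(env, dur, dt = 0.05) {
  env$speed <- 0
  env$accel <- 0
  n_full <- floor(dur / dt)
  durs <- rep(dt, n_full)
  rem <- dur - n_full * dt
  if (rem > 1e-9) durs <- c(durs, rem)
  rec_push_block(env, durs, numeric(length(durs)), numeric(length(durs)))
}

#' Simulate GPS kinematics of the intermittent circuit
#'
#' Generates a piecewise speed profile over the circuit geometry with
#' acceleration limited by the speed-dependent maximum [a_max()], braking to
#' a complete stop at the end of each marked phase (and at corners sharper
#' than 150 degrees), short repositioning walks inside the recovery breaks,
#' and mirrored lap direction. The noise-free trajectory is kept as ground
#' truth; the GPS view adds Gaussian speed noise and realistic fix-quality
#' fields (HDOP ~ 1.0, ~9 satellites), both sampled at 10 Hz.
#'
#' @param spec A [circuit_spec()].
#' @param noise_sd Gaussian sd on GPS speed, m/s (0 for a noise-free view).
#' @param seed Optional RNG seed.
#' @param brake Braking deceleration magnitude, m/s^2 (default 4, keeping
#'   the equivalent slope within the fitted range).
#' @param walk_speed Repositioning walk speed, m/s.
#' @param origin Latitude/longitude of the local origin, decimal degrees.
#' @return A list of class `circuit_sim_kinematics`: `gps` (a [gps_trace()]),
#'   `truth` (a noise-free `kinematic_series` at 10 Hz with exact speed,
#'   acceleration, heading and new-model power), `spec`, and `summary`
#'   (total distance m, duration s, energy J/kg, mean power W/kg).
#' @export
simulate_kinematics <- function(spec = circuit_spec(), noise_sd = 0.1,
                                seed = NULL, brake = 4, walk_speed = 1.4,
                                origin = c(lat = 43.781, lon = 11.282)) {
  stopifnot(inherits(spec, "circuit_spec"))
  if (!is.null(seed)) set.seed(seed)
  for (p in spec$phases) {
    if (is.finite(p$speed) && p$speed^2 / (2 * brake) > sum(p$segments)) {
      stop("infeasible phase `", p$label,
           "`: target speed unreachable within its distance", call. = FALSE)
    }
  }
  run_afun <- function(v) max(0.2, a_max(v * 3.6))
  walk_afun <- function(v) 1.5
  env <- new_recorder()
  for (lap in seq_len(spec$laps)) {
    dir_sign <- if (spec$mirror && lap %% 2L == 0L) -1 else 1
    for (p in spec$phases) {
      env$heading <- (env$heading + dir_sign * 45) %% 360
      nseg <- length(p$segments)
      for (i in seq_len(nseg)) {
        v_exit <- if (i == nseg) 0 else corner_speed(p$turns[i])
        march_segment(env, p$segments[i], p$speed, v_exit, run_afun, brake)
        if (i < nseg) env$heading <- (env$heading + dir_sign * p$turns[i]) %% 360
      }
      if (p$reposition_m > 0) {
        env$heading <- (env$heading + dir_sign * 75) %% 360
        t0 <- env$time
        march_segment(env, p$reposition_m, walk_speed, 0, walk_afun, 1.5)
        walk_t <- env$time - t0
        if (p$recovery_s > walk_t) stand(env, p$recovery_s - walk_t)
      } else if (p$recovery_s > 0) {
        stand(env, p$recovery_s)
      }
    }
  }
  n <- env$n
  idx <- seq_len(n)
  fine <- list(t = env$t[idx], v = env$v[idx], h = env$h[idx])

  ## resample to a uniform 100 Hz grid and smooth the speed over ~0.3 s:
  ## the bang-bang control profile of the integrator has instantaneous
  ## acceleration steps, whereas a runner's acceleration ramps over a few
  ## tenths of a second; the moving mean imposes that jerk limit
  du <- 0.01
  tu <- seq(0, fine$t[n], by = du)
  vu <- stats::approx(fine$t, fine$v, xout = tu, rule = 2)$y
  hu <- stats::approx(fine$t, fine$h, xout = tu, method = "constant",
                      rule = 2)$y
  vs <- pmax(0, running_mean(vu, 31L))
  nu <- length(tu)
  au <- c(vs[2L] - vs[1L],
          (vs[3:nu] - vs[1:(nu - 2L)]) / 2,
          vs[nu] - vs[nu - 1L]) / du
  ## positions along the recorded headings, consistent with smoothed speed
  rad <- hu * pi / 180
  ds <- c(0, (vs[-1L] + vs[-nu]) / 2 * du)
  xu <- cumsum(ds * sin(rad))
  yu <- cumsum(ds * cos(rad))
  ## energy under the new grass model
  esu <- au / GRAVITY
  p_fine <- cost_new(esu) * sqrt(esu^2 + 1) * vs
  energy <- sum(p_fine) * du
  distance <- sum(vs) * du

  ## 10 Hz sampling of the trajectory
  keep <- seq(1L, nu, by = 10L)
  t10 <- tu[keep]; v10 <- vs[keep]; a10 <- au[keep]
  h10 <- hu[keep]; x10 <- xu[keep]; y10 <- yu[keep]
  es10 <- a10 / GRAVITY
  truth <- new_kinematic_series(tibble::tibble(
    t = t10, v_s = v10, a = a10, es = es10, em = sqrt(es10^2 + 1),
    heading = h10, cost = cost_new(es10),
    power = cost_new(es10) * sqrt(es10^2 + 1) * v10
  ), hz = 10)

  lat <- origin[["lat"]] + y10 / 111320
  lon <- origin[["lon"]] + x10 / (111320 * cos(origin[["lat"]] * pi / 180))
  m <- length(t10)
  v_gps <- pmax(0, v10 + stats::rnorm(m, 0, noise_sd))
  gps <- gps_trace(
    t = t10, v = v_gps, lat = lat, lon = lon,
    hdop = round(pmax(0.6, 1 + stats::rnorm(m, 0, 0.1)), 1),
    nsat = pmin(12, pmax(7, round(9 + stats::rnorm(m, 0, 0.5))))
  )
  structure(
    list(gps = gps, truth = truth, spec = spec,
         summary = list(distance_m = distance, duration_s = fine$t[n],
                        energy_j_kg = energy, mean_power = energy / fine$t[n])),
    class = "circuit_sim_kinematics"
  )
}

## centred running mean with shrinking windows at the edges
running_mean <- function(x, k) {
  half <- k %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Simulate the breath-by-breath oxygen-uptake response
#'
#' Drives a first-order VO2 model with the ground-truth metabolic demand.
#' Uptake relaxes toward a target — demand plus the repayment drive of the
#' outstanding fast (phosphocreatine) oxygen debt, capped at VO2max — with
#' `tau_on` on the way up and `tau_off` on the way down. Demand not met
#' aerobically accrues as oxygen deficit in two pools: a fraction of the
#' demand above VO2max (set by `la_gain`) accrues as lactic energy, measured
#' post-exercise as blood lactate and repaid only slowly; the remainder
#' accrues as fast debt, which actively drives extra uptake during the
#' low-intensity breaks (time constant `tau_pcr`) and is repaid during
#' recovery as the fast component of excess post-exercise oxygen
#' consumption, on top of a small slow component (time constant `tau_slow`).
#'
#' @param sim A `circuit_sim_kinematics` (or its `truth` series).
#' @param params A [physio_params()].
#' @param recovery_s Recovery to append after exercise, s (>= 360).
#' @param breath_dt Sampling interval of the emitted series, s.
#' @param noise Multiplicative breath noise sd (fraction); 0 for noise-free.
#' @param seed Optional RNG seed.
#' @return A [breath_series()] (rest 60 s, exercise, recovery) in mL/kg/min,
#'   with attribute `truth`: list with `aer`, `alactic`, `lactic`,
#'   `deficit` (all J/kg; `deficit = alactic + lactic` equals demand energy
#'   minus aerobic supply), `supra_max`, `energy` (J/kg), `delta_la` (mM)
#'   and `vo2_mean_exercise`.
#' @export
simulate_breaths <- function(sim, params = physio_params(), recovery_s = 420,
                             breath_dt = 2, noise = params$breath_noise,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- if (inherits(sim, "circuit_sim_kinematics")) sim$truth else sim
  if (recovery_s < 360) stop("need at least 6 min of recovery", call. = FALSE)
  rest <- params$vo2_rest
  dt <- 0.1
  t_ex <- truth$t
  demand <- stats::approx(t_ex, truth$power, xout = seq(0, max(t_ex), dt),
                          rule = 2)$y * 60 / J_PER_ML_O2    # net, mL/kg/min
  ## lactic fraction of instantaneous supra-maximal demand (J per J)
  kappa <- params$la_gain * O2_PER_MM_LACTATE * J_PER_ML_O2
  nstep <- length(demand)
  vo2 <- numeric(nstep)
  vo2[1L] <- rest
  pf <- 0  # fast (phosphocreatine) debt pool, mL/kg
  ps <- 0  # slow (lactic) pool, mL/kg
  for (i in seq_len(nstep - 1L)) {
    target <- min(rest + demand[i] + pf * 60 / params$tau_pcr, params$vo2max)
    tau <- if (target >= vo2[i]) params$tau_on else params$tau_off
    vo2[i + 1L] <- vo2[i] + (target - vo2[i]) / tau * dt
    supra_i <- max(rest + demand[i] - params$vo2max, 0)
    ps <- ps + kappa * supra_i * dt / 60
    pf <- max(0, pf + (demand[i] - (vo2[i] - rest) - kappa * supra_i) * dt / 60)
  }
  e_demand <- sum(demand) * dt / 60 * J_PER_ML_O2
  aer <- sum(vo2 - rest) * dt / 60 * J_PER_ML_O2
  deficit <- max(0, e_demand - aer)
  supra <- sum(pmax(rest + demand - params$vo2max, 0)) * dt / 60 * J_PER_ML_O2
  lactic <- min(ps * J_PER_ML_O2, deficit)
  alactic <- deficit - lactic
  ## recovery: a fast exponential repaying exactly the outstanding alactic
  ## debt (time constant derived from debt / amplitude, keeping uptake
  ## continuous at exercise end) riding on a near-constant slow component
  ## tied to the lactic pool — the slow background the 4th-6th-minute
  ## baseline of the debt estimator is designed to remove
  slow_const <- lactic / J_PER_ML_O2 * 60 / params$tau_slow   # mL/kg/min
  amp_fast <- max(0, vo2[nstep] - rest - slow_const)
  alactic_ml <- alactic / J_PER_ML_O2
  tau_fast <- if (amp_fast > 1e-9 && alactic_ml > 1e-9) {
    alactic_ml * 60 / amp_fast
  } else {
    NA_real_
  }
  ## assemble the sampled series: 60 s rest, exercise, recovery
  t_r <- seq(-60, -breath_dt, by = breath_dt)
  t_e <- seq(0, max(t_ex), by = breath_dt)
  ## recovery starts at the exercise-end instant (tiny offset keeps the time
  ## axis strictly increasing) so the fast debt is fully sampled
  t_c <- seq(0, recovery_s, by = breath_dt)
  vo2_e <- stats::approx(seq(0, max(t_ex), dt), vo2, xout = t_e, rule = 2)$y
  vo2_c <- rep(rest + slow_const, length(t_c))
  if (!is.na(tau_fast)) vo2_c <- vo2_c + amp_fast * exp(-t_c / tau_fast)
  tt <- c(t_r, t_e, max(t_ex) + 0.01 + t_c)
  yy <- c(rep(rest, length(t_r)), vo2_e, vo2_c)
  if (noise > 0) yy <- pmax(0, yy * (1 + stats::rnorm(length(yy), 0, noise)))
  out <- breath_series(
    t = tt - tt[1L], vo2 = yy,
    phase = rep(c("rest", "exercise", "recovery"),
                c(length(t_r), length(t_e), length(t_c))),
    unit = "ml_kg_min", mass = params$mass
  )
  attr(out, "t_offset") <- tt[1L]
  attr(out, "truth") <- list(
    aer = aer, alactic = alactic, lactic = lactic, deficit = deficit,
    supra_max = supra, energy = e_demand,
    delta_la = lactic / (O2_PER_MM_LACTATE * J_PER_ML_O2),
    vo2_mean_exercise = mean(vo2)
  )
  out
}

#' Simulate pre/post blood lactate from the lactic energy share
#'
#' Inverse of [lactic_energy()]: the net rise equals the lactic energy
#' divided by the 3 mL O2/kg per mM and 20.9 J/mL equivalents, so that the
#' calorimetry partition recovers the simulated lactic share exactly.
#'
#' @param lactic_j Lactic energy share, J/kg (>= 0).
#' @param params A [physio_params()] (supplies the resting lactate).
#' @return A list with `la_pre` and `la_post`, mM.
#' @export
simulate_lactate <- function(lactic_j, params = physio_params()) {
  if (lactic_j < 0) stop("lactic energy must be non-negative", call. = FALSE)
  delta <- lactic_j / (O2_PER_MM_LACTATE * J_PER_ML_O2)
  list(la_pre = params$la_rest, la_post = params$la_rest + delta)
}

#' Simulate a full circuit session
#'
#' One call producing the coupled GPS trace, ground-truth kinematics,
#' breath-by-breath VO2 and blood lactate of a simulated player performing
#' the soccer-specific intermittent circuit.
#'
#' @param seed RNG seed (mandatory: seeded runs are byte-identical).
#' @param spec A [circuit_spec()].
#' @param params A [physio_params()].
#' @param noise_sd GPS speed noise sd, m/s; defaults to the value in
#'   `params`.
#' @param breath_noise Breath noise fraction; defaults to `params`.
#' @param recovery_s Post-exercise recovery, s.
#' @param breath_dt Breath sampling interval, s.
#' @return A list of class `circuit_sim`: `gps`, `truth`, `breaths`,
#'   `lactate`, `spec`, `params`, `summary`.
#' @examples
#' sim <- simulate_circuit(seed = 7)
#' sim$summary$mean_power
#' @export
simulate_circuit <- function(seed, spec = circuit_spec(),
                             params = physio_params(),
                             noise_sd = params$gps_noise_sd,
                             breath_noise = params$breath_noise,
                             recovery_s = 420, breath_dt = 2) {
  if (missing(seed)) stop("`seed` is mandatory for reproducibility", call. = FALSE)
  set.seed(seed)
  kin <- simulate_kinematics(spec, noise_sd = noise_sd)
  breaths <- simulate_breaths(kin, params, recovery_s = recovery_s,
                              breath_dt = breath_dt, noise = breath_noise)
  lact <- simulate_lactate(attr(breaths, "truth")$lactic, params)
  structure(
    list(gps = kin$gps, truth = kin$truth, breaths = breaths,
         lactate = lact, spec = spec, params = params,
         summary = kin$summary),
    class = "circuit_sim"
  )
}

#' @export
print.circuit_sim <- function(x, ...) {
  s <- x$summary
  tr <- attr(x$breaths, "truth")
  cat("<circuit_sim>\n")
  cat(sprintf("  %d laps, %.0f m in %.0f s; ground-truth mean power %.1f W/kg\n",
              x$spec$laps, s$distance_m, s$duration_s, s$mean_power))
  cat(sprintf("  energy %.0f J/kg = aerobic %.0f + alactic %.0f + lactic %.0f\n",
              tr$energy, tr$aer, tr$alactic, tr$lactic))
  cat(sprintf("  lactate %.1f -> %.1f mM\n", x$lactate$la_pre, x$lactate$la_post))
  invisible(x)
}
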