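#' @keywords internal
"_PACKAGE"

## Standard gravity used throughout the equivalent-slope transformation.
GRAVITY <- 9.81

## Energy cost of running vs. gradient, ascending polynomial coefficients,
## J.kg-1.m-1 with the gradient expressed as a dimensionless fraction
## (0.45 == 45%).
##
## "new": quartic re-parameterisation for elite soccer players on grass,
##        flat-running constant 4.66 J.kg-1.m-1, no terrain factor.
## "original": Minetti et al. (2002), J Appl Physiol 93:1039-1046, quintic
##        treadmill model, flat constant 3.6 J.kg-1.m-1, usually multiplied
##        by the Pinnington & Dawson grass terrain factor KT = 1.29.
COST_COEFFICIENTS <- list(
  new      = c(4.66, 17.696, 46.3, -5.0975, 30.4),
  original = c(3.6, 19.5, 46.3, -43.3, -30.4, 155.4)
)

## Validity range of the gradient fit; beyond it the polynomials are
## extrapolated as-is but samples are flagged.
ES_FIT_RANGE <- c(-0.45, 0.45)

## Equivalent slopes beyond +-4 (about 4 g of forward acceleration) are
## treated as sensor artefacts.
ES_SANITY_BOUND <- 4

polyval_asc <- function(coef, x) {
  ## Horner evaluation with ascending coefficients.
  out <- rep(coef[length(coef)], length(x))
  if (length(coef) > 1L) {
    for (k in (length(coef) - 1L):1L) out <- out * x + coef[k]
  }
  out
}

#' Energy cost of running at a given equivalent slope (new grass model)
#'
#' Quartic energy-cost model for elite soccer players running on natural
#' grass, as a function of the equivalent slope (dimensionless gradient
#' fraction; accelerated level running at forward acceleration `a` is
#' treated as uphill running at gradient `a / g`). At zero slope the model
#' returns the measured flat-running cost of 4.66 J/kg/m. The polynomial is
#' strictly positive over \[-1, 1\], so decelerations never receive a
#' negative cost.
#'
#' @param es Equivalent slope(s), dimensionless fraction (0.45 means 45%).
#' @return Energy cost in J/kg/m, same length as `es`.
#' @examples
#' cost_new(0)      # 4.66, flat running on grass
#' cost_new(0.10)   # uphill-equivalent: moderate acceleration
#' cost_new(-0.18)  # downhill-equivalent: deceleration, near the minimum
#' @seealso [cost_original()], [metabolic_power()]
#' @export
cost_new <- function(es) {
  if (!is.numeric(es) || anyNA(es) || any(!is.finite(es))) {
    stop("`es` must be finite numeric", call. = FALSE)
  }
  polyval_asc(COST_COEFFICIENTS$new, es)
}

#' Energy cost of running at a given equivalent slope (original model)
#'
#' The classical quintic gradient/energy-cost polynomial of Minetti et al.
#' (2002) measured on a treadmill (flat constant 3.6 J/kg/m), optionally
#' multiplied by the terrain factor KT = 1.29 that converts treadmill cost
#' to natural grass.
#'
#' @param es Equivalent slope(s), dimensionless fraction.
#' @param apply_terrain Multiply by KT = 1.29? Default `TRUE` (grass).
#' @return Energy cost in J/kg/m.
#' @examples
#' cost_original(0, apply_terrain = FALSE)  # 3.6, treadmill flat
#' cost_original(0)                         # 4.644 on grass
#' @export
cost_original <- function(es, apply_terrain = TRUE) {
  if (!is.numeric(es) || anyNA(es) || any(!is.finite(es))) {
    stop("`es` must be finite numeric", call. = FALSE)
  }
  kt <- if (isTRUE(apply_terrain)) 1.29 else 1
  kt * polyval_asc(COST_COEFFICIENTS$original, es)
}

#' Construct an energy-cost model
#'
#' Bundles a gradient/energy-cost polynomial with its terrain factor so the
#' rest of the pipeline can be run with either the new grass model, the
#' original treadmill model, or a custom coefficient table (e.g. for
#' sensitivity studies, see [read_cost_model()]).
#'
#' @param name `"new"` or `"original"`, or any label when `coefficients`
#'   are supplied explicitly.
#' @param coefficients Optional ascending polynomial coefficients
#'   (J/kg/m at unit powers of the equivalent slope).
#' @param terrain_factor Optional terrain multiplier (>= 1). Defaults: 1 for
#'   `"new"` (4.66 was measured on grass directly), 1.29 for `"original"`.
#' @return An object of class `cost_model`.
#' @examples
#' cost_model("new")
#' cost_model("original")
#' @export
cost_model <- function(name = c("new", "original"),
                       coefficients = NULL, terrain_factor = NULL) {
  if (is.null(coefficients)) {
    name <- match.arg(name)
    coefficients <- COST_COEFFICIENTS[[name]]
    if (is.null(terrain_factor)) {
      terrain_factor <- if (name == "new") 1 else 1.29
    }
  } else {
    name <- as.character(name[1L])
    if (is.null(terrain_factor)) terrain_factor <- 1
  }
  stopifnot(is.numeric(coefficients), length(coefficients) >= 1,
            all(is.finite(coefficients)))
  if (!is.numeric(terrain_factor) || length(terrain_factor) != 1 ||
      terrain_factor < 1) {
    stop("`terrain_factor` must be a single number >= 1", call. = FALSE)
  }
  structure(
    list(name = name,
         coefficients = as.numeric(coefficients),
         terrain_factor = as.numeric(terrain_factor),
         flat_constant = as.numeric(coefficients[1L])),
    class = "cost_model"
  )
}

#' @export
print.cost_model <- function(x, ...) {
  cat("<cost_model> ", x$name, "\n", sep = "")
  cat("  degree        :", length(x$coefficients) - 1L, "\n")
  cat("  flat constant :", format(x$flat_constant), "J/kg/m\n")
  cat("  terrain factor:", format(x$terrain_factor), "\n")
  invisible(x)
}

#' Load a custom energy-cost model from YAML
#'
#' Expected keys: `name`, `coefficients` (ascending), optional
#' `terrain_factor`.
#'
#' @param path Path to a YAML file.
#' @return A [cost_model()].
#' @export
read_cost_model <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$coefficients)) {
    stop("YAML cost model needs a `coefficients` entry", call. = FALSE)
  }
  cost_model(name = y$name %||% "custom",
             coefficients = unlist(y$coefficients),
             terrain_factor = y$terrain_factor)
}

#' Evaluate an energy-cost model
#'
#' @param model A [cost_model()].
#' @param es Equivalent slope(s), dimensionless.
#' @return Energy cost in J/kg/m (terrain factor applied).
#' @export
energy_cost <- function(model, es) {
  stopifnot(inherits(model, "cost_model"))
  if (!is.numeric(es) || anyNA(es) || any(!is.finite(es))) {
    stop("`es` must be finite numeric", call. = FALSE)
  }
  model$terrain_factor * polyval_asc(model$coefficients, es)
}

#' Metabolic power from speed and acceleration
#'
#' Converts speed and forward acceleration into metabolic power per kilogram
#' of body mass via the equivalent-slope framework: an accelerating runner on
#' the level is treated as running uphill at gradient `es = a / g`, with an
#' apparent ("equivalent") body mass multiplier `em = sqrt(es^2 + 1)`.
#' Instantaneous power is `P = C(es) * em * v` in W/kg.
#'
#' @param v Speed(s), m/s, non-negative.
#' @param a Forward acceleration(s), m/s^2 (recycled against `v`).
#' @param model A [cost_model()]; default the new grass model.
#' @param g Gravitational acceleration, m/s^2.
#' @return A tibble with columns `v`, `a`, `es`, `em`, `cost` (J/kg/m),
#'   `power` (W/kg) and `es_extrapolated` (`TRUE` where `|es|` falls outside
#'   the \[-0.45, 0.45\] range over which the cost polynomials were fitted;
#'   values there are extrapolations of the polynomial, not clamped).
#' @examples
#' metabolic_power(2.86, 0)                       # steady running on grass
#' metabolic_power(2.86, 0, cost_model("original"))
#' @export
metabolic_power <- function(v, a = 0, model = cost_model("new"), g = GRAVITY) {
  stopifnot(inherits(model, "cost_model"))
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
    stop("`v` must be finite numeric", call. = FALSE)
  }
  if (any(v < 0)) stop("speed `v` must be non-negative", call. = FALSE)
  if (!is.numeric(a) || anyNA(a) || any(!is.finite(a))) {
    stop("`a` must be finite numeric", call. = FALSE)
  }
  n <- max(length(v), length(a))
  v <- rep_len(v, n); a <- rep_len(a, n)
  es <- a / g
  if (any(abs(es) > ES_SANITY_BOUND)) {
    stop("|equivalent slope| > ", ES_SANITY_BOUND,
         ": acceleration beyond the sensor-artefact bound", call. = FALSE)
  }
  em <- sqrt(es^2 + 1)
  cost <- energy_cost(model, es)
  tibble::tibble(
    v = v, a = a, es = es, em = em, cost = cost,
    power = cost * em * v,
    es_extrapolated = es < ES_FIT_RANGE[1L] | es > ES_FIT_RANGE[2L]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
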