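# Mechanism framework. Every mechanism type stores its instances in a
# Structure-of-Arrays pool: one contiguous vector per parameter and per state
# variable, plus an ascending node-index map. Kernels are vectorized over the
# instance axis and must be pure functions of their inputs.

.mech_registry <- new.env(parent = emptyenv())

#' Define a mechanism type
#'
#' @param name unique mechanism name.
#' @param kind `"density"` (current per membrane area, mA/cm^2), `"point"`
#'   (absolute current, nA), or `"artificial"` (event-only, no membrane).
#' @param params named list of default parameter values.
#' @param units named character vector documenting parameter units.
#' @param states named numeric of state variables and initial values.
#' @param has_net_receive can this mechanism receive events? Density
#'   mechanisms cannot.
#' @param current `function(pool, v, t)` returning `list(g, i)` per instance:
#'   conductance (uS) and current (nA) at voltage `v`, such that the current
#'   at voltage `w` is approximated by `i + g * (w - v)` (linearized-current
#'   contract). Density kernels convert via the instance area internally.
#' @param state `function(pool, v, dt, v_all)` returning updated states.
#' @param net_receive `function(pool, k, weight)` returning updated states
#'   after an event of size `weight` on instance `k`.
#' @param init `function(pool, v, v_all)` returning initialized states.
#' @return a `mechanism_spec`.
#' @export
mechanism_spec <- function(name, kind, params = list(), units = character(),
                           states = numeric(), has_net_receive = FALSE,
                           current = NULL, state = NULL, net_receive = NULL,
                           init = NULL) {
  kind <- match.arg(kind, c("density", "point", "artificial"))
  if (kind == "density" && has_net_receive)
    nc_stop("nc_registration_error", "density mechanism '%s' cannot have net_receive", name)
  if (kind == "artificial" && (!is.null(current) || !is.null(state)))
    nc_stop("nc_registration_error",
            "artificial mechanism '%s' cannot have voltage kernels", name)
  structure(list(name = name, kind = kind, params = params, units = units,
                 states = states, has_net_receive = has_net_receive,
                 current = current, state = state, net_receive = net_receive,
                 init = init),
            class = "mechanism_spec")
}

#' Register a mechanism type
#'
#' @param spec a [mechanism_spec()].
#' @return the dense integer type id assigned to the mechanism.
#' @export
register_mechanism <- function(spec) {
  stopifnot(inherits(spec, "mechanism_spec"))
  if (!is.null(.mech_registry[[spec$name]]))
    nc_stop("nc_registration_error", "mechanism '%s' already registered", spec$name)
  id <- length(ls(.mech_registry)) + 1L
  spec$type_id <- id
  assign(spec$name, spec, envir = .mech_registry)
  id
}

#' @rdname register_mechanism
#' @param name mechanism name.
#' @export
get_mechanism <- function(name) {
  spec <- .mech_registry[[name]]
  if (is.null(spec)) nc_stop("nc_registration_error", "unknown mechanism '%s'", name)
  spec
}

#' List registered mechanisms
#' @return tibble of name, kind, type id.
#' @export
list_mechanisms <- function() {
  nms <- ls(.mech_registry)
  specs <- lapply(nms, get_mechanism)
  out <- tibble::tibble(
    name = vapply(specs, `[[`, character(1), "name"),
    kind = vapply(specs, `[[`, character(1), "kind"),
    type_id = vapply(specs, `[[`, integer(1), "type_id"))
  out[order(out$type_id), ]
}

#' Reset the registry to the built-in mechanism set
#' @export
reset_mechanism_registry <- function() {
  rm(list = ls(.mech_registry), envir = .mech_registry)
  register_builtin_mechanisms()
  invisible(NULL)
}

# mA/cm^2 * um^2 -> nA, and S/cm^2 * um^2 -> uS, share the same 1e-2 factor.
.density_to_abs <- 1e-2

#' Hodgkin-Huxley rate constants
#'
#' Classic squid-axon forms (1/ms, v in mV):
#' `alpha_m = 0.1 (v+40) / (1 - exp(-(v+40)/10))`, `beta_m = 4 exp(-(v+65)/18)`,
#' `alpha_h = 0.07 exp(-(v+65)/20)`, `beta_h = 1 / (1 + exp(-(v+35)/10))`,
#' `alpha_n = 0.01 (v+55) / (1 - exp(-(v+55)/10))`, `beta_n = 0.125 exp(-(v+65)/80)`.
#' The removable singularities at v = -40 (alpha_m) and v = -55 (alpha_n) are
#' evaluated by a two-term Taylor expansion when the scaled argument is within
#' 1e-6 of zero, giving the exact limits (1.0 and 0.1 respectively).
#'
#' @param v membrane potential, mV; vectorized.
#' @return list with `alpha_m`, `beta_m`, `alpha_h`, `beta_h`, `alpha_n`,
#'   `beta_n`.
#' @export
hh_rates <- function(v) {
  list(
    alpha_m = linoid(v, 40, 0.1, 10),
    beta_m  = 4 * exp(-(v + 65) / 18),
    alpha_h = 0.07 * exp(-(v + 65) / 20),
    beta_h  = 1 / (1 + exp(-(v + 35) / 10)),
    alpha_n = linoid(v, 55, 0.01, 10),
    beta_n  = 0.125 * exp(-(v + 65) / 80)
  )
}

# c * (v+a) / (1 - exp(-(v+a)/k)) with the removable singularity at v = -a
# replaced by the 2-term Taylor expansion c * (k + (v+a)/2) when
# |(v+a)/k| < 1e-6 (limit value c*k at v = -a exactly).
linoid <- function(v, a, c, k) {
  u <- v + a
  x <- u / k
  out <- ifelse(abs(x) < 1e-6, c * (k + u / 2), c * u / (1 - exp(-x)))
  out
}

hh_steady <- function(v) {
  r <- hh_rates(v)
  list(m = r$alpha_m / (r$alpha_m + r$beta_m),
       h = r$alpha_h / (r$alpha_h + r$beta_h),
       n = r$alpha_n / (r$alpha_n + r$beta_n))
}

# Exponential state update toward the voltage-dependent steady state:
# x <- x_inf + (x - x_inf) exp(-dt (alpha+beta)); keeps x in [0,1] for any dt.
gate_update <- function(x, alpha, beta, dt) {
  xinf <- alpha / (alpha + beta)
  xinf + (x - xinf) * exp(-dt * (alpha + beta))
}

#' Event times of a stochastic stimulus source
#'
#' With `noise = 0` the train is regular: `start + k * interval`. With
#' `noise = 1` inter-event intervals are exponential with mean `interval`,
#' drawn from the counter-based stream `key` (counter = event index), so the
#' train is reproducible and independent of call order. Intermediate `noise`
#' mixes: interval = `(1 - noise) * interval + noise * Exp(interval)`.
#'
#' @param start first event time (noise = 0) / offset, ms.
#' @param interval mean interval, ms (> 0).
#' @param number number of events (>= 0).
#' @param noise in `[0, 1]`.
#' @param key 4-integer stream key (see [counter_rng()]).
#' @return numeric vector of event times, ms.
#' @export
netstim_events <- function(start, interval, number, noise = 0, key = c(1L, 0L, 11L, 1013904223L)) {
  if (interval <= 0) nc_stop("nc_parameter_error", "netstim: interval must be > 0")
  number <- as.integer(number)
  if (number < 0) nc_stop("nc_parameter_error", "netstim: number must be >= 0")
  if (number == 0) return(numeric(0))
  if (noise == 0) return(start + (seq_len(number) - 1) * interval)
  # first event at `start`; subsequent inter-event intervals mix a fixed part
  # with exponential draws from the counter stream (counter = interval index)
  u <- counter_rng(key, seq_len(number)[-number] - 1)
  iv <- (1 - noise) * interval + noise * (-interval * log1p(-u))
  start + c(0, cumsum(iv))
}

register_builtin_mechanisms <- function() {
  register_mechanism(mechanism_spec(
    "pas", "density",
    params = list(g = 1e-3, e = -70),
    units = c(g = "S/cm2", e = "mV"),
    current = function(pool, v, t) {
      gabs <- pool$params$g * pool$area * .density_to_abs
      list(g = gabs, i = gabs * (v - pool$params$e))
    }))

  register_mechanism(mechanism_spec(
    "hh", "density",
    params = list(gnabar = 0.12, gkbar = 0.036, gl = 3e-4,
                  ena = 50, ek = -77, el = -54.3),
    units = c(gnabar = "S/cm2", gkbar = "S/cm2", gl = "S/cm2",
              ena = "mV", ek = "mV", el = "mV"),
    states = c(m = 0, h = 0, n = 0),
    current = function(pool, v, t) {
      s <- pool$states
      gna <- pool$params$gnabar * s$m^3 * s$h
      gk <- pool$params$gkbar * s$n^4
      gl <- pool$params$gl
      f <- pool$area * .density_to_abs
      list(g = (gna + gk + gl) * f,
           i = (gna * (v - pool$params$ena) + gk * (v - pool$params$ek) +
                  gl * (v - pool$params$el)) * f)
    },
    state = function(pool, v, dt, v_all) {
      r <- hh_rates(v)
      list(m = gate_update(pool$states$m, r$alpha_m, r$beta_m, dt),
           h = gate_update(pool$states$h, r$alpha_h, r$beta_h, dt),
           n = gate_update(pool$states$n, r$alpha_n, r$beta_n, dt))
    },
    init = function(pool, v, v_all) hh_steady(v)))

  register_mechanism(mechanism_spec(
    "expsyn", "point",
    params = list(tau = 2, e = 0),
    units = c(tau = "ms", e = "mV"),
    states = c(g = 0),
    has_net_receive = TRUE,
    current = function(pool, v, t) {
      if (any(pool$params$tau <= 0))
        nc_stop("nc_parameter_error", "expsyn: tau must be > 0")
      list(g = pool$states$g, i = pool$states$g * (v - pool$params$e))
    },
    state = function(pool, v, dt, v_all) {
      list(g = pool$states$g * exp(-dt / pool$params$tau))
    },
    net_receive = function(pool, k, weight) {
      s <- pool$states
      s$g[k] <- s$g[k] + weight
      s
    }))

  register_mechanism(mechanism_spec(
    "iclamp", "point",
    params = list(del = 0, dur = 0, amp = 0),
    units = c(del = "ms", dur = "ms", amp = "nA"),
    current = function(pool, v, t) {
      on <- t >= pool$params$del - .nc_tol & t < pool$params$del + pool$params$dur - .nc_tol
      list(g = numeric(length(v)), i = -pool$params$amp * as.numeric(on))
    }))

  register_mechanism(mechanism_spec(
    "gap", "point",
    params = list(g = 0, peer_node = NA_real_),
    units = c(g = "uS", peer_node = "node index"),
    states = c(vpeer = 0),
    current = function(pool, v, t) {
      # explicit coupling: only the self conductance enters the matrix, the
      # peer voltage is last step's snapshot
      list(g = pool$params$g, i = pool$params$g * (v - pool$states$vpeer))
    },
    state = function(pool, v, dt, v_all) {
      list(vpeer = v_all[pool$params$peer_node])
    },
    init = function(pool, v, v_all) {
      if (anyNA(pool$params$peer_node))
        nc_stop("nc_wiring_error", "gap junction instance has no peer node")
      list(vpeer = v_all[pool$params$peer_node])
    }))

  register_mechanism(mechanism_spec(
    "netstim", "artificial",
    params = list(start = 0, interval = 1, number = 0, noise = 0),
    units = c(start = "ms", interval = "ms", number = "count", noise = "fraction"),
    has_net_receive = TRUE))
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  if (length(ls(.mech_registry)) == 0) register_builtin_mechanisms()
}
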