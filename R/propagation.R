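#' Build a discrete Markov-chain propagator
#'
#' Each walker's payload is a state index; one resampling interval tau
#' advances the chain by `steps_per_tau` jumps sampled from the transition
#' matrix. The single progress coordinate is the state index itself, so
#' exact occupancies, mean first-passage times, and stationary
#' distributions are available in closed form as oracles.
#'
#' @param transition row-stochastic transition matrix.
#' @param steps_per_tau chain steps per resampling interval (default 1).
#' @return an object of class `we_propagator`.
#' @export
markov_propagator <- function(transition, steps_per_tau = 1L) {
  transition <- as.matrix(transition)
  if (nrow(transition) != ncol(transition) ||
      any(transition < 0) ||
      any(abs(rowSums(transition) - 1) > 1e-12))
    stop("transition matrix must be square and row-stochastic")
  cum <- t(apply(transition, 1L, cumsum))
  structure(list(
    kind = "markov_chain",
    coordinate_names = "state",
    parameters = list(transition = transition,
                      steps_per_tau = as.integer(steps_per_tau)),
    # payloads: integer state vector (one per walker)
    advance = function(payloads, tau) {
      s <- as.integer(unlist(payloads))
      for (step in seq_len(as.integer(steps_per_tau))) {
        u <- stats::runif(length(s))
        s <- rowSums(cum[s, , drop = FALSE] < u) + 1L
      }
      list(payloads = as.list(s), coords = matrix(as.numeric(s), ncol = 1L))
    }), class = "we_propagator")
}

#' Build a 1-D double-well Langevin propagator
#'
#' Overdamped Langevin dynamics on the bistable potential
#' `U(x) = h (x^2 - 1)^2` (wells at x = -1 and x = +1, barrier height h at
#' x = 0), integrated with the Euler-Maruyama scheme:
#' `dx = -U'(x)/gamma dt + sqrt(2 kT dt / gamma) xi`. One resampling
#' interval is `steps_per_tau` integrator steps. The payload is the
#' position x, which is also the single progress coordinate.
#'
#' @param h barrier height (energy units of kT at `kT = 1`). Default 5.
#' @param kT thermal energy. Default 1.
#' @param dt integrator step. Default 1e-3.
#' @param friction friction coefficient gamma. Default 1.
#' @param steps_per_tau integrator steps per resampling interval. Default 10.
#' @return an object of class `we_propagator`.
#' @export
double_well_propagator <- function(h = 5, kT = 1, dt = 1e-3, friction = 1,
                                   steps_per_tau = 10L) {
  stopifnot(h >= 0, kT > 0, dt > 0, friction > 0, steps_per_tau >= 1)
  sig <- sqrt(2 * kT * dt / friction)
  structure(list(
    kind = "double_well_1d",
    coordinate_names = "x",
    parameters = list(h = h, kT = kT, dt = dt, friction = friction,
                      steps_per_tau = as.integer(steps_per_tau)),
    advance = function(payloads, tau) {
      x <- as.numeric(unlist(payloads))
      for (step in seq_len(as.integer(steps_per_tau))) {
        grad <- 4 * h * x * (x^2 - 1)
        x <- x - grad * dt / friction + sig * stats::rnorm(length(x))
      }
      list(payloads = as.list(x), coords = matrix(x, ncol = 1L))
    }), class = "we_propagator")
}

# surrogate-unbinding landscape constants (fixture values, see vignette):
# double well along the separation axis x (bound well at 0, unbound well at
# 8, barrier hx at x = 4), harmonic confinement in the lateral axis y, and
# a deep off-pathway trap pocket at (3.2, 1.8) on the bound-side slope.
# Climbing walkers that stray to y ~ 1 cascade into the pocket; its lowest
# rim points back toward the bound state, so escape requires backward
# motion along the rmsd-like coordinate. The rmsd y-weighting places the
# pocket inside the [10, 13] region-scaling window while the productive
# y ~ 0 channel stays below it until past the barrier top.
unbind2d_defaults <- function() {
  list(hx = 12, x0 = 4, halfwidth = 4, ky = 2,
       trap_depth = 10, trap_x = 3.2, trap_y = 1.8, trap_sigma = 0.55,
       kT = 1, dt = 5e-3, friction = 1, steps_per_tau = 20L,
       rmsd_scale = 2.0, rmsd_ywt = 6,
       bump_height = 250, bump_x = 7, bump_sigma2 = 2)
}

# derived observables: rmsd-like displacement norm, energy-like score with
# a repulsive bump near the exit channel (eint rises above 0 just before
# the unbound region, so productive paths show backward eint progress),
# and the separation distance itself
unbind2d_coords <- function(x, y, p) {
  rmsd <- p$rmsd_scale * sqrt(x^2 + p$rmsd_ywt * y^2)
  eint <- 550 * exp(-x / 2) - 200 +
    p$bump_height * exp(-((x - p$bump_x)^2 + y^2) / p$bump_sigma2)
  cbind(rmsd = rmsd, eint = eint, dist = x)
}

#' Build the 2-D surrogate-unbinding propagator
#'
#' A desk-scale stand-in for a ligand-unbinding process: overdamped
#' Langevin dynamics on a 2-D landscape with a bound basin, an off-pathway
#' trap at intermediate progress, and an unbound basin. Three derived
#' progress coordinates mimic the observables used for real unbinding runs:
#' `rmsd` (a displacement norm, range ~0-25), `eint` (an energy-like score
#' decaying from 350 toward -200 with a repulsive bump near the exit
#' channel, so productive paths show *backward* progress in `eint` while
#' passing it), and `dist` (the separation axis itself, range ~0-10).
#' The payload is the position `c(x, y)`.
#'
#' @param parameters named list overriding the fixture defaults (see
#'   `binlesswe:::unbind2d_defaults()`).
#' @return an object of class `we_propagator`.
#' @export
unbind2d_propagator <- function(parameters = list()) {
  p <- utils::modifyList(unbind2d_defaults(), parameters)
  sig <- sqrt(2 * p$kT * p$dt / p$friction)
  b2 <- p$halfwidth^2
  structure(list(
    kind = "surrogate_unbinding_2d",
    coordinate_names = c("rmsd", "eint", "dist"),
    parameters = p,
    advance = function(payloads, tau) {
      pos <- do.call(rbind, payloads)
      x <- pos[, 1]; y <- pos[, 2]
      for (step in seq_len(as.integer(p$steps_per_tau))) {
        u <- (x - p$x0)^2 / b2 - 1
        g <- exp(-((x - p$trap_x)^2 + (y - p$trap_y)^2) / (2 * p$trap_sigma^2))
        gx <- p$hx * 2 * u * 2 * (x - p$x0) / b2 +
          p$trap_depth * g * (x - p$trap_x) / p$trap_sigma^2
        gy <- p$ky * y + p$trap_depth * g * (y - p$trap_y) / p$trap_sigma^2
        n <- stats::rnorm(2 * length(x))
        x <- x - gx * p$dt / p$friction + sig * n[seq_along(x)]
        y <- y - gy * p$dt / p$friction + sig * n[-seq_along(x)]
      }
      list(payloads = lapply(seq_along(x), function(i) c(x[i], y[i])),
           coords = unbind2d_coords(x, y, p))
    }), class = "we_propagator")
}

#' Propagate every walker by one resampling interval
#'
#' Advances all payloads by exactly tau through the propagator and
#' refreshes the walkers' progress coordinates from the new payloads.
#' Propagation never touches weights or the walker count: dynamics and
#' statistical bookkeeping are strictly separated in WE.
#'
#' @param e a `we_ensemble`.
#' @param p a `we_propagator`.
#' @return the propagated `we_ensemble` (same iteration index; the
#'   iteration counter is advanced by the resampling step).
#' @export
propagate_ensemble <- function(e, p) {
  stopifnot(inherits(e, "we_ensemble"), inherits(p, "we_propagator"))
  payloads <- lapply(e$walkers, function(w) w$payload)
  if (any(vapply(payloads, is.null, logical(1))))
    stop("walker payload missing or incompatible with the propagator")
  adv <- p$advance(payloads, e$tau)
  for (j in seq_along(e$walkers)) {
    e$walkers[[j]]$payload <- adv$payloads[[j]]
    e$walkers[[j]]$coords <- as.numeric(adv$coords[j, ])
  }
  e
}

#' Define a named state by interval conditions on coordinates
#'
#' @param name state name (e.g. `"bound"`, `"unbound"`, `"encounter"`).
#' @param conditions named list: each entry is `c(lo, hi)` (closed interval,
#'   `-Inf`/`Inf` allowed) for the coordinate of that name. A walker is in
#'   the state when every condition holds.
#' @return an object of class `we_statedef`.
#' @export
state_def <- function(name, conditions) {
  stopifnot(is.character(name), length(conditions) >= 1L,
            !is.null(names(conditions)))
  for (cc in conditions) stopifnot(length(cc) == 2L, cc[1] <= cc[2])
  structure(list(name = name, conditions = conditions),
            class = "we_statedef")
}

#' Classify a coordinate vector against state definitions
#'
#' States are checked in declaration order; the first match wins (states
#' need not partition the space). Interval bounds are closed: a value
#' exactly on a boundary is inside.
#'
#' @param coords named numeric vector (or unnamed, with `coord_names`).
#' @param defs list of [state_def()] objects.
#' @param coord_names names for `coords` if unnamed.
#' @return the matching state name, or `NA_character_` if none.
#' @export
classify_state <- function(coords, defs, coord_names = names(coords)) {
  if (is.null(coord_names))
    stop("coordinate names are required to evaluate state predicates")
  names(coords) <- coord_names
  for (d in defs) {
    ok <- TRUE
    for (cn in names(d$conditions)) {
      if (!cn %in% coord_names)
        stop("state '", d$name, "' references unknown coordinate '", cn, "'")
      cc <- d$conditions[[cn]]
      v <- coords[[cn]]
      if (v < cc[1] || v > cc[2]) { ok <- FALSE; break }
    }
    if (ok) return(d$name)
  }
  NA_character_
}

#' Recycle walkers that reached a target state
#'
#' The standard nonequilibrium steady-state boundary condition: every walker
#' inside the target state is reset to the source configuration, keeping its
#' weight, and the total recycled weight is returned for the flux series
#' (by the Hill relation the mean recycled weight per unit time converges to
#' the source-to-target rate). Off by default in run configurations.
#'
#' @param e a `we_ensemble`.
#' @param target a [state_def()].
#' @param source_payload payload to reset recycled walkers to.
#' @param source_coords coordinate vector matching the source payload.
#' @param coord_names the ensemble's coordinate names.
#' @return list with `ensemble` and `recycled_weight`.
#' @export
recycle_walkers <- function(e, target, source_payload, source_coords,
                            coord_names) {
  recycled <- 0
  for (j in seq_along(e$walkers)) {
    w <- e$walkers[[j]]
    if (identical(classify_state(w$coords, list(target), coord_names),
                  target$name)) {
      recycled <- recycled + w$weight
      e$walkers[[j]]$payload <- source_payload
      e$walkers[[j]]$coords <- as.numeric(source_coords)
    }
  }
  list(ensemble = e, recycled_weight = recycled)
}

#' Construct a ready-to-run toy system
#'
#' Bundles a propagator, sensible state definitions, a recommended progress
#' score specification, and the initial payload/coordinates for one of the
#' built-in systems:
#'
#' * `"markov_chain"`: parameters `transition` (row-stochastic matrix),
#'   optional `start` (initial state, default 1), `target_state` (default:
#'   the last state), `steps_per_tau`. Score: progress of the state index
#'   from start to target.
#' * `"double_well_1d"`: parameters as [double_well_propagator()], optional
#'   `start` (default -1). States: reactant x <= -0.8, product x >= 0.8.
#'   Score: progress of x from -1 to +1.
#' * `"surrogate_unbinding_2d"`: parameters as [unbind2d_propagator()],
#'   plus optional `region_scaling` (`c(lo, hi, factor)` on the rmsd-like
#'   coordinate; default `c(10, 13, 0.8)`, the trap window) and
#'   `use_region_scaling` (default TRUE). States: bound (dist <= 1.5),
#'   unbound (dist >= 8.5), encounter (rmsd in the trap window and dist
#'   < 6). Score: rmsd 0 -> 25, eint 350 -> -200, dist 0 -> 10 with unit
#'   scale factors.
#'
#' @param kind system kind.
#' @param parameters named list of parameters (see above).
#' @return list with `propagator`, `states`, `score_spec`, `init`
#'   (`payload`, `coords`), and `parameters`.
#' @export
make_toy_system <- function(kind = c("markov_chain", "double_well_1d",
                                     "surrogate_unbinding_2d"),
                            parameters = list()) {
  kind <- match.arg(kind)
  if (kind == "markov_chain") {
    if (is.null(parameters$transition))
      stop("markov_chain requires a 'transition' matrix parameter")
    Tm <- as.matrix(parameters$transition)
    prop <- markov_propagator(Tm, parameters$steps_per_tau %||% 1L)
    ns <- nrow(Tm)
    start <- parameters$start %||% 1L
    tgt <- parameters$target_state %||% ns
    states <- list(state_def("target", list(state = c(tgt, tgt))))
    spec <- score_spec(list(coordinate_spec("state", q_init = start,
                                            q_target = tgt)))
    init <- list(payload = as.integer(start), coords = as.numeric(start))
  } else if (kind == "double_well_1d") {
    prop <- do.call(double_well_propagator,
                    parameters[names(parameters) %in%
                               names(formals(double_well_propagator))])
    start <- parameters$start %||% -1
    states <- list(state_def("reactant", list(x = c(-Inf, -0.8))),
                   state_def("product", list(x = c(0.8, Inf))))
    spec <- score_spec(list(coordinate_spec("x", q_init = -1, q_target = 1)))
    init <- list(payload = start, coords = start)
  } else {
    prop <- unbind2d_propagator(parameters)
    p <- prop$parameters
    rs <- parameters$region_scaling %||% c(10, 13, 0.8)
    use_rs <- parameters$use_region_scaling %||% TRUE
    regions <- if (isTRUE(use_rs)) list(rs) else list()
    states <- list(
      state_def("unbound", list(dist = c(8.5, Inf))),
      state_def("bound", list(dist = c(-Inf, 1.5))),
      state_def("encounter", list(rmsd = c(rs[1], rs[2]),
                                  dist = c(-Inf, 6))))
    spec <- score_spec(list(
      coordinate_spec("rmsd", q_init = 0, q_target = 25, regions = regions),
      coordinate_spec("eint", q_init = 350, q_target = -200),
      coordinate_spec("dist", q_init = 0, q_target = 10)))
    start <- parameters$start %||% c(0, 0)
    init <- list(payload = start,
                 coords = as.numeric(unbind2d_coords(start[1], start[2], p)))
  }
  list(propagator = prop, states = states, score_spec = spec, init = init,
       parameters = prop$parameters, kind = kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
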