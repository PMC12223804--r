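#' Define one progress coordinate
#'
#' A progress coordinate is any scalar observable tracking advancement from
#' an initial value toward a target value (for ligand unbinding: ligand RMSD,
#' ligand-receptor interaction energy, separation distance). Progress along
#' the coordinate is normalized to \[0, 1\] between `q_init` and `q_target`;
#' the direction is implied by the two values, so decreasing observables
#' (e.g. an interaction energy relaxing from a high initial value to a low
#' target) are handled with no extra flag.
#'
#' Region scalings implement soft discouragement of known kinetic traps: a
#' walker whose value of this coordinate lies inside a window `[lo, hi]`
#' (closed, matching the usual "between a and b" reading) has its whole
#' progress score multiplied by `factor`.
#'
#' @param name coordinate name.
#' @param q_init user-defined initial value.
#' @param q_target user-defined target value (must differ from `q_init`).
#' @param scale multiplicative scaling factor C > 0 tuning the influence of
#'   this coordinate on the overall score.
#' @param regions list of region scalings, each `c(lo, hi, factor)` with
#'   `lo < hi` and `factor` in (0, 1].
#' @return an object of class `we_coordspec`.
#' @export
coordinate_spec <- function(name, q_init, q_target, scale = 1, regions = list()) {
  stopifnot(is.character(name), length(name) == 1L,
            is.finite(q_init), is.finite(q_target))
  if (q_init == q_target) stop("q_init must differ from q_target")
  if (!is.finite(scale) || scale <= 0) stop("scale factor must be > 0")
  regions <- lapply(regions, function(r) {
    r <- as.numeric(r)
    if (length(r) != 3L || r[1] >= r[2] || r[3] <= 0 || r[3] > 1)
      stop("each region scaling must be c(lo, hi, factor) with lo < hi, factor in (0,1]")
    r
  })
  structure(list(name = name, q_init = q_init, q_target = q_target,
                 scale = scale, regions = regions),
            class = "we_coordspec")
}

#' Define a progress-score specification
#'
#' The binless resampler ranks walkers by a scalar progress score S: the
#' product over coordinates of scaled normalized progress, times a
#' weight-dependent balance ("soft threshold") term, times any triggered
#' region-scaling factors. The balance term `1/(-ln P)` is strictly
#' increasing in the weight P, so higher-weight walkers are favored for
#' splitting and lower-weight walkers drift toward the merge pool —
#' a soft replacement for hard weight cutoffs.
#'
#' @param coordinates list of [coordinate_spec()] objects (length M >= 1).
#' @param balance balance-term convention: `"inverse_neg_log"` (default,
#'   `1/(-ln P)` capped at `balance_cap`), `"one_minus_log"` (the literal
#'   form `1 - ln P`, kept for comparison; note it *increases* as P
#'   decreases), or `"none"` (constant 1).
#' @param balance_cap positive cap on the balance term; `1/(-ln P)` diverges
#'   as P approaches 1 (the very first iteration has P = 1), so the cap
#'   keeps S finite. Default 1e3.
#' @param clamp_progress clamp each raw progress term into \[0, 1\] (default
#'   TRUE); overshoot past the target or backtrack past the initial value
#'   otherwise takes the term outside \[0, 1\].
#' @return an object of class `we_scorespec`.
#' @export
score_spec <- function(coordinates,
                       balance = c("inverse_neg_log", "one_minus_log", "none"),
                       balance_cap = 1e3, clamp_progress = TRUE) {
  balance <- match.arg(balance)
  if (inherits(coordinates, "we_coordspec")) coordinates <- list(coordinates)
  stopifnot(length(coordinates) >= 1L,
            all(vapply(coordinates, inherits, logical(1), "we_coordspec")),
            is.finite(balance_cap), balance_cap > 0)
  structure(list(coordinates = coordinates, balance = balance,
                 balance_cap = balance_cap,
                 clamp_progress = isTRUE(clamp_progress)),
            class = "we_scorespec")
}

#' Normalized progress along one coordinate
#'
#' Returns `1 - |q - q_target| / |q_init - q_target|`: 1 at the target,
#' 0 at the initial value, linear in between. With `clamp = TRUE` the value
#' is clamped into \[0, 1\].
#'
#' @param q current coordinate value(s); vectorized.
#' @param cs a [coordinate_spec()].
#' @param clamp clamp into \[0, 1\] (default TRUE).
#' @return numeric vector of progress values (before the scale factor C).
#' @export
coordinate_progress <- function(q, cs, clamp = TRUE) {
  if (any(!is.finite(q))) stop("coordinate value must be finite")
  p <- 1 - abs(q - cs$q_target) / abs(cs$q_init - cs$q_target)
  if (clamp) p <- pmin(1, pmax(0, p))
  p
}

#' Weight-balance ("soft threshold") term
#'
#' @param P statistical weight(s) in (0, 1]; vectorized.
#' @param spec a [score_spec()] (supplies the convention and cap).
#' @return positive numeric vector.
#' @export
balance_term <- function(P, spec) {
  if (any(!is.finite(P)) || any(P <= 0) || any(P > 1))
    stop("weight P must lie in (0, 1]")
  b <- switch(spec$balance,
    inverse_neg_log = ifelse(P == 1, Inf, 1 / (-log(P))),
    one_minus_log   = 1 - log(P),
    none            = rep.int(1, length(P)))
  pmin(b, spec$balance_cap)
}

#' Compute the progress score S for one walker
#'
#' `S = [prod_m C_m * progress_m] * balance(P) * prod(triggered region factors)`.
#' S is 0 whenever any coordinate sits at its initial value (the product
#' annihilates), and S is deterministic in (coords, P, spec).
#'
#' @param coords numeric vector of length M, ordered as `spec$coordinates`.
#' @param P the walker's statistical weight in (0, 1].
#' @param spec a [score_spec()].
#' @return scalar score S >= 0.
#' @export
compute_score <- function(coords, P, spec) {
  M <- length(spec$coordinates)
  if (length(coords) != M)
    stop("coords has length ", length(coords), " but the score spec has ",
         M, " coordinates")
  s <- balance_term(P, spec)
  for (m in seq_len(M)) {
    cs <- spec$coordinates[[m]]
    s <- s * cs$scale * coordinate_progress(coords[m], cs, spec$clamp_progress)
    for (r in cs$regions)
      if (coords[m] >= r[1] && coords[m] <= r[2]) s <- s * r[3]
  }
  s
}

#' Score every walker in an ensemble
#'
#' @param e a `we_ensemble`.
#' @param spec a [score_spec()].
#' @return numeric vector of scores, in walker order.
#' @export
score_ensemble <- function(e, spec) {
  vapply(e$walkers, function(w) compute_score(w$coords, w$weight, spec),
         numeric(1))
}

#' Update a score specification on the fly
#'
#' Progress scores only rank walkers; weights are independent of the
#' coordinate definition, so the spec can be adjusted mid-run (widening a
#' target, adding a region-scaling window) without touching any weight.
#' The run loop logs the iteration at which a change takes effect.
#'
#' @param spec a [score_spec()].
#' @param changes named list: names are coordinate names, values are lists
#'   with any of `q_init`, `q_target`, `scale`, `regions`.
#' @return a new `we_scorespec`; the input is not modified.
#' @export
update_spec <- function(spec, changes) {
  stopifnot(inherits(spec, "we_scorespec"), is.list(changes))
  nm <- vapply(spec$coordinates, function(cs) cs$name, character(1))
  for (cname in names(changes)) {
    m <- match(cname, nm)
    if (is.na(m)) stop("unknown coordinate '", cname, "'")
    cs <- spec$coordinates[[m]]
    ch <- changes[[cname]]
    for (f in names(ch)) {
      if (!f %in% c("q_init", "q_target", "scale", "regions"))
        stop("unknown coordinate field '", f, "'")
      cs[[f]] <- ch[[f]]
    }
    # revalidate through the constructor
    spec$coordinates[[m]] <- coordinate_spec(cs$name, cs$q_init, cs$q_target,
                                             cs$scale, cs$regions)
  }
  spec
}
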