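#' Create a walker
#'
#' A walker is one weighted trajectory segment of a weighted-ensemble (WE)
#' simulation: a statistical weight, a vector of progress-coordinate values,
#' a lineage pointer into the previous iteration, and an opaque propagator
#' payload (the full dynamical state, e.g. a phase-space point for Langevin
#' dynamics or a state index for a Markov chain).
#'
#' @param id integer id, unique within an iteration.
#' @param parent_id id of the parent walker in the previous iteration;
#'   use `0L` (the sentinel) for iteration-0 walkers.
#' @param weight statistical weight in (0, 1].
#' @param coords numeric vector of progress-coordinate values (all finite).
#' @param payload opaque propagator state; never inspected by the resampling
#'   machinery.
#' @return an object of class `we_walker`.
#' @export
we_walker <- function(id, parent_id, weight, coords, payload = NULL) {
  stopifnot(is.numeric(weight), length(weight) == 1L)
  if (!is.finite(weight) || weight <= 0 || weight > 1)
    stop("walker weight must lie in (0, 1], got ", weight)
  if (!all(is.finite(coords)))
    stop("walker coords must all be finite")
  structure(
    list(id = as.integer(id), parent_id = as.integer(parent_id),
         weight = weight, coords = as.numeric(coords), payload = payload),
    class = "we_walker")
}

#' Create an ensemble of walkers
#'
#' The ensemble is the full set of weighted trajectory segments at one WE
#' iteration. Total weight is conserved at 1 across propagation and
#' resampling; this is the first of the two statistical rules every
#' resampler must respect.
#'
#' @param walkers list of [we_walker()] objects with unique ids.
#' @param iteration non-negative iteration index.
#' @param tau resampling time interval in toy time units (> 0).
#' @return an object of class `we_ensemble`.
#' @export
we_ensemble <- function(walkers, iteration = 0L, tau = 1) {
  stopifnot(length(walkers) >= 1L, tau > 0, iteration >= 0)
  ids <- vapply(walkers, function(w) w$id, integer(1))
  if (anyDuplicated(ids))
    stop("walker ids must be unique within an iteration")
  structure(list(iteration = as.integer(iteration), tau = tau,
                 walkers = walkers),
            class = "we_ensemble")
}

#' @export
print.we_ensemble <- function(x, ...) {
  cat(sprintf("<we_ensemble> iteration %d: %d walkers, total weight %.15g\n",
              x$iteration, length(x$walkers), sum(ens_weights(x))))
  invisible(x)
}

#' Extract walker weights
#' @param e a `we_ensemble`.
#' @return numeric vector of weights, in walker order.
#' @export
ens_weights <- function(e) vapply(e$walkers, function(w) w$weight, numeric(1))

#' Extract walker ids
#' @param e a `we_ensemble`.
#' @return integer vector of ids, in walker order.
#' @export
ens_ids <- function(e) vapply(e$walkers, function(w) w$id, integer(1))

#' Extract the coordinate matrix
#' @param e a `we_ensemble`.
#' @return numeric matrix, one row per walker, one column per coordinate.
#' @export
ens_coords <- function(e) {
  do.call(rbind, lapply(e$walkers, function(w) w$coords))
}

#' Split a walker into k equal-weight children
#'
#' Splitting replicates an under-sampled trajectory, dividing its statistical
#' weight among the children so the ensemble remains unbiased. Children carry
#' identical coordinates and payload and point back to the parent. The child
#' weights are `w/k` with the division done once; the last child absorbs the
#' floating-point residual so the child-weight sum equals the parent weight
#' bit-exactly.
#'
#' @param w a `we_walker` with positive weight.
#' @param k integer number of children, at least 2.
#' @param ids optional integer vector of k ids for the children; defaults to
#'   `w$id` repeated (callers renumber after resampling).
#' @return list of k `we_walker` children, each with `parent_id = w$id`.
#' @export
split_walker <- function(w, k = 2L, ids = NULL) {
  if (!is.numeric(k) || length(k) != 1L || k < 2L)
    stop("split requires k >= 2")
  k <- as.integer(k)
  if (!is.finite(w$weight) || w$weight <= 0)
    stop("cannot split a walker with nonpositive weight")
  if (is.null(ids)) ids <- rep.int(w$id, k)
  base <- w$weight / k
  wts <- rep.int(base, k)
  wts[k] <- w$weight - (k - 1L) * base  # bit-exact sum
  lapply(seq_len(k), function(j) {
    ch <- w
    ch$id <- as.integer(ids[j])
    ch$parent_id <- w$id
    ch$weight <- wts[j]
    ch
  })
}

#' Merge walkers, choosing the survivor by weight
#'
#' Merging terminates redundant trajectories. To keep the ensemble unbiased
#' the survivor must be chosen with probability proportional to its
#' statistical weight (the second statistical rule of WE resampling); the
#' survivor keeps its own coordinates and payload and absorbs the weight of
#' every candidate. The survivor index is drawn from the R random number
#' stream, so results are reproducible under `set.seed()`.
#'
#' @param ws list of at least two `we_walker` objects with positive weights.
#' @return the surviving `we_walker` with `weight = sum(weights)`; the event
#'   detail (survivor id, absorbed ids, pre-merge weights) is attached as
#'   attribute `"merge_event"`.
#' @export
merge_walkers <- function(ws) {
  if (length(ws) < 2L)
    stop("merge requires at least 2 walkers")
  wts <- vapply(ws, function(w) w$weight, numeric(1))
  if (any(!is.finite(wts)) || any(wts <= 0))
    stop("merge candidates must all have positive weight")
  i <- sample.int(length(ws), 1L, prob = wts)
  surv <- ws[[i]]
  ids <- vapply(ws, function(w) w$id, integer(1))
  surv$weight <- sum(wts)
  attr(surv, "merge_event") <- list(
    survivor_id = surv$id, absorbed_ids = ids[-i], pre_weights = wts)
  surv
}

#' Check that ensemble weight is conserved
#'
#' Trajectory weights must always sum to a total probability of one; this is
#' checked after every propagation and resampling step. Violation raises a
#' condition of class `we_conservation_error` carrying the observed sum and
#' the iteration index.
#'
#' @param e a `we_ensemble`.
#' @param tol positive tolerance on `|sum(weights) - 1|` (default 1e-12).
#' @return invisibly, the observed weight sum.
#' @export
assert_conservation <- function(e, tol = 1e-12) {
  stopifnot(tol > 0)
  s <- sum(ens_weights(e))
  if (abs(s - 1) > tol) {
    cond <- structure(
      class = c("we_conservation_error", "error", "condition"),
      list(message = sprintf(
             "weight conservation violated at iteration %d: sum = %.17g (tol %g)",
             e$iteration, s, tol),
           call = sys.call(-1), sum = s, iteration = e$iteration))
    stop(cond)
  }
  invisible(s)
}

#' Trace a walker's lineage back to iteration 0
#'
#' Follows parent pointers through a run record, returning the unbroken
#' ancestor chain that realizes one continuous pathway of the WE ensemble.
#'
#' @param rec a `we_run` record (see [run_simulation()]).
#' @param walker_id id of the walker at `iteration`.
#' @param iteration recorded iteration (1-based) to start from; defaults to
#'   the last recorded iteration.
#' @return data.frame with columns `iteration`, `walker_id`, `weight`, and
#'   one column per progress coordinate, ordered from iteration 1 up to
#'   `iteration`; consecutive rows differ by exactly one iteration.
#' @export
trace_lineage <- function(rec, walker_id, iteration = length(rec$iterations)) {
  stopifnot(inherits(rec, "we_run"))
  if (iteration < 1L || iteration > length(rec$iterations))
    stop("iteration ", iteration, " not recorded")
  chain <- vector("list", iteration)
  id <- as.integer(walker_id)
  for (t in seq(iteration, 1L)) {
    it <- rec$iterations[[t]]
    j <- match(id, it$ids)
    if (is.na(j))
      stop("walker id ", id, " not found at iteration ", t)
    chain[[t]] <- c(iteration = t, walker_id = id, weight = it$weights[j],
                    it$coords[j, ])
    id <- it$parents[j]
  }
  out <- as.data.frame(do.call(rbind, chain))
  names(out) <- c("iteration", "walker_id", "weight", rec$coordinate_names)
  out
}
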