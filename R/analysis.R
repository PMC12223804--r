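#' Exact n-step distribution of a discrete Markov chain
#'
#' Brute-force oracle: advances an initial distribution by repeated
#' multiplication with the transition matrix.
#'
#' @param transition row-stochastic matrix.
#' @param p0 initial distribution (sums to 1).
#' @param n number of steps (>= 0).
#' @return the distribution after n steps.
#' @export
exact_markov <- function(transition, p0, n) {
  transition <- as.matrix(transition)
  if (any(abs(rowSums(transition) - 1) > 1e-12))
    stop("transition matrix must be row-stochastic")
  if (abs(sum(p0) - 1) > 1e-12) stop("p0 must sum to 1")
  p <- as.numeric(p0)
  for (k in seq_len(n)) p <- as.numeric(p %*% transition)
  p
}

#' Mean first-passage time of a discrete Markov chain
#'
#' Fundamental-matrix oracle: with the target state(s) made absorbing,
#' `N = (I - Q)^{-1}` and the expected number of steps from each transient
#' state is `rowSums(N)`.
#'
#' @param transition row-stochastic matrix.
#' @param source source state index.
#' @param target target state index (or vector of indices).
#' @return mean first-passage time in chain steps.
#' @export
markov_mfpt <- function(transition, source, target) {
  transition <- as.matrix(transition)
  if (any(abs(rowSums(transition) - 1) > 1e-12))
    stop("transition matrix must be row-stochastic")
  if (source %in% target) return(0)
  keep <- setdiff(seq_len(nrow(transition)), target)
  Q <- transition[keep, keep, drop = FALSE]
  Nmat <- solve(diag(length(keep)) - Q)
  steps <- rowSums(Nmat)
  steps[match(source, keep)]
}

#' Stationary distribution of a discrete Markov chain
#' @param transition row-stochastic matrix.
#' @return the stationary distribution (left eigenvector for eigenvalue 1).
#' @export
markov_stationary <- function(transition) {
  transition <- as.matrix(transition)
  ev <- eigen(t(transition))
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  v / sum(v)
}

# evaluate a recorded iteration's coords against a state definition
record_in_state <- function(it, def, coord_names) {
  vapply(seq_along(it$ids), function(j)
    identical(classify_state(it$coords[j, ], list(def), coord_names),
              def$name),
    logical(1))
}

#' Weighted histogram of recorded progress coordinates
#'
#' The probability mass of each bin is the sum of walker weights falling in
#' it, averaged over the requested iteration range; without recycling losses
#' the total mass is 1. Supports one or two coordinates (the 2-D form is
#' the standard probability-landscape view over, e.g., interaction energy
#' and separation distance).
#'
#' @param rec a `we_run` record.
#' @param coordinates one or two recorded coordinate names.
#' @param breaks list of break vectors (one per coordinate); values outside
#'   are clamped into the end bins.
#' @param iterations integer vector of recorded iterations to average over
#'   (default: all).
#' @param log_prob return log10 mass (floored at 1e-300) instead of mass.
#' @return for one coordinate, a numeric vector of bin masses with the
#'   breaks as attribute `"breaks"`; for two, a matrix (first coordinate in
#'   rows).
#' @export
weighted_histogram <- function(rec, coordinates, breaks,
                               iterations = seq_along(rec$iterations),
                               log_prob = FALSE) {
  stopifnot(inherits(rec, "we_run"), length(coordinates) %in% 1:2)
  ci <- match(coordinates, rec$coordinate_names)
  if (anyNA(ci))
    stop("unknown coordinate(s): ",
         paste(coordinates[is.na(ci)], collapse = ", "))
  if (!is.list(breaks)) breaks <- list(breaks)
  nb <- vapply(breaks, length, integer(1)) - 1L
  acc <- if (length(ci) == 1L) numeric(nb[1]) else matrix(0, nb[1], nb[2])
  for (t in iterations) {
    it <- rec$iterations[[t]]
    idx <- lapply(seq_along(ci), function(d) {
      i <- findInterval(it$coords[, ci[d]], breaks[[d]],
                        rightmost.closed = TRUE, all.inside = TRUE)
      i
    })
    if (length(ci) == 1L) {
      for (j in seq_along(it$weights))
        acc[idx[[1]][j]] <- acc[idx[[1]][j]] + it$weights[j]
    } else {
      for (j in seq_along(it$weights))
        acc[idx[[1]][j], idx[[2]][j]] <-
          acc[idx[[1]][j], idx[[2]][j]] + it$weights[j]
    }
  }
  acc <- acc / length(iterations)
  if (log_prob) acc <- log10(pmax(acc, 1e-300))
  attr(acc, "breaks") <- breaks
  acc
}

#' Aggregate simulation time to the first target-state event
#'
#' The efficiency metric for rare-event sampling: the total sampling cost
#' (sum over iterations of walker count times tau) accrued up to and
#' including the first iteration at which any walker satisfies the target
#' state. Every propagated walker-tau from iteration 1 is counted,
#' whether or not it belongs to the successful lineage.
#'
#' @param rec a `we_run` record.
#' @param target a [state_def()].
#' @return aggregate time in walker-time units, or `NA_real_` if no walker
#'   ever reaches the target ("no event").
#' @export
first_event_aggregate_time <- function(rec, target) {
  stopifnot(inherits(rec, "we_run"))
  agg <- 0
  for (t in seq_along(rec$iterations)) {
    it <- rec$iterations[[t]]
    agg <- agg + length(it$ids) * rec$tau
    if (any(record_in_state(it, target, rec$coordinate_names)))
      return(agg)
  }
  NA_real_
}

#' Rate estimate from the recycled-flux series
#'
#' Under recycling, the mean recycled probability per unit time converges
#' (after a burn-in) to the source-to-target rate, i.e. 1/MFPT (the Hill
#' relation). The standard error is estimated by a moving-block bootstrap
#' over the post-burn-in series.
#'
#' @param flux numeric vector of per-iteration recycled weights.
#' @param tau resampling interval (time per iteration). Default 1.
#' @param burn_in iterations discarded from the front. Default 0.
#' @param block_length bootstrap block length in iterations. Default 10.
#' @param n_boot bootstrap resamples. Default 1000.
#' @return list with `rate`, `se`, and `n_used`.
#' @export
flux_rate_estimate <- function(flux, tau = 1, burn_in = 0,
                               block_length = 10L, n_boot = 1000L) {
  stopifnot(burn_in >= 0, burn_in < length(flux))
  f <- flux[(burn_in + 1L):length(flux)]
  if (length(f) == 0L) stop("empty post-burn-in flux series")
  rate <- mean(f) / tau
  if (all(f == 0)) return(list(rate = 0, se = 0, n_used = length(f)))
  nb <- max(1L, floor(length(f) / block_length))
  starts <- seq_len(length(f) - min(block_length, length(f)) + 1L)
  bl <- min(block_length, length(f))
  boots <- vapply(seq_len(n_boot), function(b) {
    s <- sample(starts, nb, replace = TRUE)
    idx <- as.vector(outer(0:(bl - 1L), s, `+`))
    mean(f[idx]) / tau
  }, numeric(1))
  list(rate = rate, se = stats::sd(boots), n_used = length(f))
}

#' Per-bin walker-weight profile along a coordinate
#'
#' The rule-violation audit of WE resampling: under correct (weight-
#' proportional) merging across a free-energy barrier, the maximum walker
#' weight near the target state is far below the maximum near the source;
#' under score-based merging the weight of heavy walkers rides to the
#' target and the gap collapses.
#'
#' @param rec a `we_run` record.
#' @param coordinate recorded coordinate name.
#' @param breaks bin break vector; values outside are clamped into the end
#'   bins.
#' @param iterations iterations to aggregate over (default: all).
#' @return data.frame with `lo`, `hi`, `mean_weight`, `min_weight`,
#'   `max_weight`, `occupancy` (walker-iterations observed in the bin);
#'   empty bins carry `NA` summaries.
#' @export
weight_profile <- function(rec, coordinate, breaks,
                           iterations = seq_along(rec$iterations)) {
  ci <- match(coordinate, rec$coordinate_names)
  if (is.na(ci)) stop("unknown coordinate '", coordinate, "'")
  nb <- length(breaks) - 1L
  s <- rep(0, nb); mn <- rep(Inf, nb); mx <- rep(-Inf, nb); cnt <- rep(0L, nb)
  for (t in iterations) {
    it <- rec$iterations[[t]]
    idx <- findInterval(it$coords[, ci], breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    for (j in seq_along(it$weights)) {
      b <- idx[j]; w <- it$weights[j]
      s[b] <- s[b] + w
      if (w < mn[b]) mn[b] <- w
      if (w > mx[b]) mx[b] <- w
      cnt[b] <- cnt[b] + 1L
    }
  }
  data.frame(lo = breaks[-length(breaks)], hi = breaks[-1],
             mean_weight = ifelse(cnt > 0, s / cnt, NA_real_),
             min_weight = ifelse(cnt > 0, mn, NA_real_),
             max_weight = ifelse(cnt > 0, mx, NA_real_),
             occupancy = cnt)
}

#' Weighted state occupancy at one recorded iteration
#'
#' @param rec a `we_run` record.
#' @param def a [state_def()].
#' @param iteration recorded iteration index.
#' @return total weight of walkers inside the state.
#' @export
state_occupancy <- function(rec, def, iteration) {
  it <- rec$iterations[[iteration]]
  sum(it$weights[record_in_state(it, def, rec$coordinate_names)])
}
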