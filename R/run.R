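#' Validate a run configuration
#'
#' Checks a configuration list (typically loaded from YAML with
#' [read_run_config()]) against the published schema: known keys only,
#' required fields present, resampler parameters consistent (including the
#' rule that the MABL split/merge number N cannot exceed 50% of the walker
#' count).
#'
#' @param cfg configuration list.
#' @return invisibly, the validated (normalized) configuration; errors
#'   describe the offending key.
#' @export
validate_config <- function(cfg) {
  allowed <- c("system", "score", "resampler", "states", "walker_count",
               "tau", "iterations", "seed", "recycling", "score_updates",
               "stop_state", "output")
  extra <- setdiff(names(cfg), allowed)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  for (req in c("system", "resampler", "walker_count", "iterations", "seed"))
    if (is.null(cfg[[req]])) stop("missing required key '", req, "'")
  if (is.null(cfg$system$kind)) stop("system block needs a 'kind'")
  if (!cfg$system$kind %in% c("markov_chain", "double_well_1d",
                              "surrogate_unbinding_2d"))
    stop("unknown system kind '", cfg$system$kind, "'")
  if (cfg$walker_count < 1) stop("walker_count must be >= 1")
  if (cfg$iterations < 0) stop("iterations must be >= 0")
  if (!is.null(cfg$tau) && cfg$tau <= 0) stop("tau must be > 0")
  rtypes <- c("mabl", "mab", "multimab", "fixedbin", "violating_demo", "none")
  rt <- cfg$resampler$type
  if (is.null(rt) || !rt %in% rtypes)
    stop("resampler type must be one of: ", paste(rtypes, collapse = ", "))
  if (rt %in% c("mabl", "violating_demo")) {
    N <- cfg$resampler$n_split_merge
    if (is.null(N)) stop("mabl resampler needs 'n_split_merge'")
    if (N > floor(cfg$walker_count / 2))
      stop("n_split_merge N = ", N, " violates the 50% rule: ",
           "N cannot exceed half the walker count (", cfg$walker_count, ")")
  }
  if (rt == "violating_demo" && !isTRUE(cfg$resampler$allow_biased))
    stop("violating_demo requires 'allow_biased: true' in the resampler ",
         "block (it is statistically biased by construction)")
  invisible(cfg)
}

#' Read a run configuration from YAML
#' @param path YAML file following the schema in [validate_config()].
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}

# build the score spec from a config block, or fall back to the toy
# system's recommended spec
config_score_spec <- function(cfg, sys) {
  if (is.null(cfg[["score"]]) || identical(cfg[["score"]], "default"))
    return(sys$score_spec)
  sc <- cfg[["score"]]
  coords <- lapply(sc$coordinates, function(cc)
    coordinate_spec(cc$name, cc$initial, cc$target,
                    scale = cc$scale %||% 1,
                    regions = lapply(cc$regions %||% list(), as.numeric)))
  score_spec(coords,
             balance = sc$balance %||% "inverse_neg_log",
             balance_cap = sc$balance_cap %||% 1e3,
             clamp_progress = sc$clamp %||% TRUE)
}

config_states <- function(cfg, sys) {
  if (is.null(cfg$states) || identical(cfg$states, "default"))
    return(sys$states)
  lapply(cfg$states, function(s)
    state_def(s$name, lapply(s$conditions, as.numeric)))
}

config_resampler <- function(cfg, spec) {
  rt <- cfg$resampler$type
  rb <- cfg$resampler
  switch(rt,
    mabl = {
      mc <- mabl_config(rb$n_split_merge, cfg$walker_count,
                        merge_policy = rb$merge_policy %||% "absorb_up",
                        split_children = rb$split_children %||% 2L)
      function(e, scores) mabl_resample(e, spec, mc, scores = scores)
    },
    violating_demo = {
      mc <- mabl_config(rb$n_split_merge, cfg$walker_count,
                        merge_policy = rb$merge_policy %||% "absorb_up",
                        split_children = rb$split_children %||% 2L)
      function(e, scores)
        violating_merge_resample(e, spec, mc, scores = scores,
                                 allow_biased = TRUE)
    },
    mab = {
      mc <- mab_config(unlist(rb$bins_per_dim),
                       direction = unlist(rb$direction %||%
                                          rep(1, length(rb$bins_per_dim))),
                       bottleneck_enabled = rb$bottleneck %||% TRUE,
                       target_per_bin = rb$target_per_bin %||% 4L)
      function(e, scores) mab_resample(e, mc)
    },
    multimab = {
      schemes <- lapply(rb$schemes, function(s)
        list(placement = as.numeric(unlist(s$placement)),
             mab = mab_config(unlist(s$bins_per_dim),
                              direction = unlist(s$direction %||%
                                rep(1, length(s$bins_per_dim))),
                              bottleneck_enabled = s$bottleneck %||% TRUE,
                              target_per_bin = s$target_per_bin %||% 4L)))
      mc <- multimab_config(lapply(rb$outer_boundaries, function(b)
        as.numeric(unlist(b))), schemes)
      function(e, scores) multimab_resample(e, mc)
    },
    fixedbin = {
      mc <- fixedbin_config(lapply(rb$boundaries, function(b)
        as.numeric(unlist(b))), rb$target_per_bin %||% 4L)
      function(e, scores) fixedbin_resample(e, mc)
    },
    none = function(e, scores) {
      out <- renumber_ensemble(
        lapply(e$walkers, function(w) { w$parent_id <- w$id; w }),
        e$iteration + 1L, e$tau)
      attr(out, "events") <- list(splits = list(), merges = list())
      out
    })
}

#' Run a weighted-ensemble simulation
#'
#' The WE iteration loop: propagate every walker by tau, optionally recycle
#' walkers that reached the target state back to the source (recording the
#' recycled weight as flux), score, resample, and check weight
#' conservation. Fully reproducible: all randomness comes from R's RNG
#' seeded once with `cfg$seed`, and draws happen in a fixed order
#' (propagation noise first, then merge-survivor selections in rank order).
#'
#' @param cfg configuration list (see [validate_config()]); the same
#'   structure as the YAML schema. The optional `stop_state` key names a
#'   state definition: the run ends at the close of the first iteration in
#'   which any walker is inside that state (first-passage studies).
#' @param verbose print per-iteration walker count and weight sum.
#' @return an object of class `we_run`: config snapshot, seed, tau,
#'   coordinate names, state definitions, per-iteration records (`ids`,
#'   `parents`, `weights`, `coords`, `scores`, `events`), the flux series,
#'   and any logged score-spec updates.
#' @export
run_simulation <- function(cfg, verbose = FALSE) {
  validate_config(cfg)
  set.seed(cfg$seed)
  sys <- make_toy_system(cfg$system$kind,
                         cfg$system$parameters %||% list())
  spec <- config_score_spec(cfg, sys)
  states <- config_states(cfg, sys)
  tau <- cfg$tau %||% 1
  n <- cfg$walker_count

  recycling_on <- isTRUE(cfg$recycling) ||
    identical(cfg$recycling, "on") || is.list(cfg$recycling)
  recycle_target <- NULL
  if (recycling_on) {
    tname <- if (is.list(cfg$recycling)) cfg$recycling$target else NULL
    tname <- tname %||% states[[1]]$name
    ti <- match(tname, vapply(states, function(s) s$name, character(1)))
    if (is.na(ti)) stop("recycling target state '", tname, "' not defined")
    recycle_target <- states[[ti]]
  }

  stop_def <- NULL
  if (!is.null(cfg$stop_state)) {
    si <- match(cfg$stop_state,
                vapply(states, function(s) s$name, character(1)))
    if (is.na(si)) stop("stop_state '", cfg$stop_state, "' not defined")
    stop_def <- states[[si]]
  }

  updates <- cfg$score_updates %||% list()
  upd_iters <- vapply(updates, function(u) as.integer(u$iteration),
                      integer(1))

  walkers <- lapply(seq_len(n), function(j)
    we_walker(j, 0L, 1 / n, sys$init$coords, sys$init$payload))
  e <- we_ensemble(walkers, iteration = 0L, tau = tau)
  resample <- config_resampler(cfg, spec)

  rec <- structure(list(
    config = cfg, seed = cfg$seed, tau = tau,
    coordinate_names = sys$propagator$coordinate_names,
    states = lapply(states, unclass),
    iterations = vector("list", cfg$iterations),
    flux = numeric(cfg$iterations),
    spec_updates = list()), class = "we_run")

  for (t in seq_len(cfg$iterations)) {
    if (any(upd_iters == t)) {
      for (u in updates[upd_iters == t]) {
        spec <- update_spec(spec, u$changes)
        rec$spec_updates[[length(rec$spec_updates) + 1L]] <-
          list(iteration = t, changes = u$changes)
      }
      resample <- config_resampler(cfg, spec)
    }
    e <- propagate_ensemble(e, sys$propagator)
    assert_conservation(e, 1e-12)
    if (recycling_on) {
      r <- recycle_walkers(e, recycle_target, sys$init$payload,
                           sys$init$coords,
                           sys$propagator$coordinate_names)
      e <- r$ensemble
      rec$flux[t] <- r$recycled_weight
    }
    scores <- score_ensemble(e, spec)
    e2 <- resample(e, scores)
    ev <- attr(e2, "events")
    rec$iterations[[t]] <- list(
      ids = ens_ids(e), parents = vapply(e$walkers,
                                         function(w) w$parent_id, integer(1)),
      weights = ens_weights(e), coords = ens_coords(e), scores = scores,
      events = list(splits = ev$splits, merges = ev$merges))
    assert_conservation(e2, 1e-12)
    if (verbose)
      message(sprintf("iteration %4d: %d walkers, weight sum %.15f",
                      t, length(e2$walkers), sum(ens_weights(e2))))
    e <- e2
    if (!is.null(stop_def)) {
      it <- rec$iterations[[t]]
      hit <- any(vapply(seq_along(it$ids), function(j)
        identical(classify_state(it$coords[j, ], list(stop_def),
                                 rec$coordinate_names), stop_def$name),
        logical(1)))
      if (hit) {
        rec$iterations <- rec$iterations[seq_len(t)]
        rec$flux <- rec$flux[seq_len(t)]
        break
      }
    }
  }
  rec
}
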