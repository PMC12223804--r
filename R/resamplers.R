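#' MABL (minimal adaptive binless) resampler configuration
#'
#' @param n_split_merge N, the number of walkers split and the number merged
#'   per resampling step; N = 0 is the identity. N cannot exceed 50% of the
#'   walker count, since a walker cannot be selected both for splitting and
#'   for merging in the same step. Choosing N around 10-20% of the walker
#'   count works well in practice.
#' @param walker_count fixed total number of walkers per iteration.
#' @param merge_policy `"absorb_up"` (default): each of the bottom-N walkers
#'   is merged pairwise with the lowest-ranked walker above the bottom-N
#'   cutoff not already consumed; `"pairwise_bottom"`: the bottom 2N walkers
#'   are merged pairwise among themselves.
#' @param split_children children per split (default 2).
#' @return an object of class `we_mabl_config`.
#' @export
mabl_config <- function(n_split_merge, walker_count,
                        merge_policy = c("absorb_up", "pairwise_bottom"),
                        split_children = 2L) {
  merge_policy <- match.arg(merge_policy)
  stopifnot(n_split_merge >= 0, walker_count >= 1, split_children >= 2)
  if (n_split_merge > floor(walker_count / 2))
    stop("N (", n_split_merge, ") cannot exceed 50% of the walker count (",
         walker_count, ")")
  structure(list(n_split_merge = as.integer(n_split_merge),
                 walker_count = as.integer(walker_count),
                 merge_policy = merge_policy,
                 split_children = as.integer(split_children)),
            class = "we_mabl_config")
}

# deterministic rank: score desc, then weight desc, then id asc
rank_walkers <- function(scores, weights, ids) {
  order(-scores, -weights, ids)
}

renumber_ensemble <- function(walkers, iteration, tau) {
  for (j in seq_along(walkers)) walkers[[j]]$id <- j
  we_ensemble(walkers, iteration = iteration, tau = tau)
}

#' MABL binless resampling step
#'
#' Ranks every walker by its progress score S (descending, ties broken by
#' weight then id), splits each of the top N into children, then restores
#' the walker count with N merges: under the default `absorb_up` policy the
#' ranking is refreshed on the post-split ensemble and each current-bottom
#' walker is merged with the lowest-ranked walker above the bottom-N cutoff,
#' the survivor chosen probabilistically by weight. Output walker count
#' equals input count; total weight is conserved; walkers are renumbered
#' 1..n with `parent_id` set to their origin walker's id in the input
#' ensemble.
#'
#' @param e a `we_ensemble` with `cfg$walker_count` walkers.
#' @param spec a [score_spec()].
#' @param cfg a [mabl_config()].
#' @param scores optional precomputed score vector (walker order).
#' @return a `we_ensemble` at `e$iteration + 1`, with an attribute
#'   `"events"`: list with `scores`, `ranking` (input ids best-first),
#'   `splits` (list of parent id + child count) and `merges` (list of
#'   survivor id, absorbed ids, pre-merge weights).
#' @export
mabl_resample <- function(e, spec, cfg, scores = NULL) {
  mabl_resample_impl(e, spec, cfg, scores, merge_fun = merge_walkers)
}

mabl_resample_impl <- function(e, spec, cfg, scores = NULL, merge_fun) {
  stopifnot(inherits(e, "we_ensemble"), inherits(cfg, "we_mabl_config"))
  n <- length(e$walkers)
  if (n == 0L) stop("cannot resample an empty ensemble")
  if (n != cfg$walker_count)
    stop("ensemble has ", n, " walkers but the config expects ",
         cfg$walker_count)
  N <- cfg$n_split_merge
  if (2L * N > n) stop("2N exceeds the walker count")
  if (is.null(scores)) scores <- score_ensemble(e, spec)
  ids <- ens_ids(e)
  wts <- ens_weights(e)
  ord <- rank_walkers(scores, wts, ids)

  events <- list(scores = scores, ranking = ids[ord],
                 splits = list(), merges = list())
  # walkers leave with parent_id = their id in the *input* ensemble
  pool <- lapply(e$walkers, function(w) { w$parent_id <- w$id; w })

  if (N > 0L) {
    # split the top N (ranked on the input ensemble)
    for (r in ord[seq_len(N)]) {
      ch <- split_walker(pool[[r]], cfg$split_children)
      for (j in seq_along(ch)) ch[[j]]$parent_id <- ids[r]
      pool[[r]] <- ch[[1L]]
      pool <- c(pool, ch[-1L])
      events$splits[[length(events$splits) + 1L]] <-
        list(parent_id = ids[r], children = cfg$split_children)
    }
    # merge back down to n walkers. The walkers *selected* for merging are
    # the bottom N of the input ranking — provably disjoint from the split
    # set whenever 2N <= n, which is exactly why N may not exceed 50%.
    # absorb_up: each selected walker is merged (survivor by weight) with
    # the lowest-ranked walker above the bottom block in the post-split
    # pool (possibly a fresh split child, as in the five-walker worked
    # example) not already consumed. pairwise_bottom: the bottom 2N of the
    # input ranking are merged pairwise among themselves (needs 3N <= n to
    # stay clear of the split set).
    n_remove <- length(pool) - n
    selected <- if (cfg$merge_policy == "absorb_up") {
      if (N + n_remove > n)
        stop("merge selection would overlap the split set; ",
             "reduce N or split_children")
      ord[seq.int(n, by = -1L, length.out = n_remove)]
    } else {
      if (N + 2L * n_remove > n)
        stop("pairwise_bottom merge selection would overlap the split set; ",
             "reduce N or split_children")
      ord[seq.int(n, by = -1L, length.out = 2L * n_remove)]
    }
    sc <- vapply(pool, function(w)
      compute_score(w$coords, w$weight, spec), numeric(1))
    pw <- vapply(pool, function(w) w$weight, numeric(1))
    pid <- vapply(pool, function(w) w$parent_id, integer(1))
    asc <- rev(rank_walkers(sc, pw, pid))  # worst first
    keep <- rep.int(TRUE, length(pool))
    if (cfg$merge_policy == "absorb_up") {
      sel_pos <- match(ids[selected], pid)  # selected walkers, worst first
      consumed <- rep.int(FALSE, length(pool))
      consumed[sel_pos] <- TRUE
      for (j in seq_len(n_remove)) {
        partner <- asc[which(!consumed[asc])[1L]]
        consumed[partner] <- TRUE
        pair <- c(partner, sel_pos[j])
        surv <- merge_fun(pool[pair])
        ev <- attr(surv, "merge_event")
        ev$survivor_id <- surv$parent_id
        ev$selected_id <- pid[sel_pos[j]]
        ev$absorbed_ids <- setdiff(pid[pair], surv$parent_id)
        attr(surv, "merge_event") <- NULL
        events$merges[[length(events$merges) + 1L]] <- ev
        pool[[partner]] <- surv
        keep[sel_pos[j]] <- FALSE
        # the survivor (now in the partner slot) may not be consumed again
      }
    } else {
      sel_pos <- match(ids[selected], pid)
      for (j in seq_len(n_remove)) {
        pair <- c(sel_pos[2L * j], sel_pos[2L * j - 1L])
        surv <- merge_fun(pool[pair])
        ev <- attr(surv, "merge_event")
        ev$survivor_id <- surv$parent_id
        ev$selected_id <- pid[pair[2L]]
        ev$absorbed_ids <- setdiff(pid[pair], surv$parent_id)
        attr(surv, "merge_event") <- NULL
        events$merges[[length(events$merges) + 1L]] <- ev
        pool[[pair[1L]]] <- surv
        keep[pair[2L]] <- FALSE
      }
    }
    pool <- pool[keep]
  }
  out <- renumber_ensemble(pool, e$iteration + 1L, e$tau)
  attr(out, "events") <- events
  out
}

#' MAB (minimal adaptive binning) configuration
#'
#' @param bins_per_dim integer vector, interior bins per coordinate
#'   dimension (each >= 1).
#' @param direction vector of +1/-1 per dimension: +1 means progress is
#'   toward larger values (the leading edge is the maximum), -1 the reverse.
#' @param bottleneck_enabled dedicate a bin to the bottleneck walker
#'   (default TRUE).
#' @param target_per_bin walkers per occupied bin after resampling
#'   (default 4).
#' @return an object of class `we_mab_config`.
#' @export
mab_config <- function(bins_per_dim, direction = rep(1, length(bins_per_dim)),
                       bottleneck_enabled = TRUE, target_per_bin = 4L) {
  stopifnot(all(bins_per_dim >= 1), length(direction) == length(bins_per_dim),
            all(direction %in% c(-1, 1)), target_per_bin >= 1)
  structure(list(bins_per_dim = as.integer(bins_per_dim),
                 direction = as.integer(direction),
                 bottleneck_enabled = isTRUE(bottleneck_enabled),
                 target_per_bin = as.integer(target_per_bin)),
            class = "we_mab_config")
}

#' Adaptive (MAB) bin layout along one dimension
#'
#' Finds the lagging edge (least-progressed walker with respect to the
#' progress direction) and the leading edge (most-progressed walker), lays
#' `nbins` equal-width interior bins between them, and assigns the edge
#' walkers to dedicated lagging-edge and leading-edge bins beyond the
#' interior span. If enabled, one further bin isolates the bottleneck
#' walker: the highest-weight walker in the occupied interior bin just
#' before the largest increase of `-ln(bin weight)` between adjacent
#' occupied bins along the progress direction (a barrier signature). The
#' layout is recomputed from scratch at every resampling interval.
#'
#' @param positions numeric vector of walker positions along this dimension.
#' @param weights walker weights (used for the bottleneck criterion).
#' @param nbins number of interior bins.
#' @param direction +1 or -1.
#' @param bottleneck_enabled logical.
#' @return list with `boundaries` (ascending, length nbins+1 spanning the
#'   occupied range) and `assignment`: integer codes per walker, 1..nbins
#'   for interior bins, nbins+1 lagging edge, nbins+2 leading edge,
#'   nbins+3 bottleneck. All-identical positions collapse to a single
#'   interior bin.
#' @export
mab_layout <- function(positions, weights, nbins, direction = 1,
                       bottleneck_enabled = TRUE) {
  stopifnot(length(positions) >= 1L, length(weights) == length(positions),
            nbins >= 1, direction %in% c(-1, 1))
  lo <- min(positions); hi <- max(positions)
  if (lo == hi) {  # degenerate: everyone in one interior bin
    return(list(boundaries = c(lo, hi),
                assignment = rep.int(1L, length(positions))))
  }
  bnd <- seq(lo, hi, length.out = nbins + 1L)
  prog <- direction * positions
  lead_val <- max(prog); lag_val <- min(prog)
  assignment <- findInterval(positions, bnd, rightmost.closed = TRUE,
                             all.inside = TRUE)
  assignment[prog == lag_val] <- nbins + 1L   # lagging-edge bin
  assignment[prog == lead_val] <- nbins + 2L  # leading-edge bin

  if (bottleneck_enabled) {
    interior <- which(assignment <= nbins)
    if (length(interior) > 0L) {
      occ <- sort(unique(assignment[interior]))
      if (direction < 0) occ <- rev(occ)  # order along the progress direction
      if (length(occ) >= 2L) {
        wbin <- vapply(occ, function(b)
          sum(weights[interior][assignment[interior] == b]), numeric(1))
        drop_ <- diff(-log(wbin))
        k <- which.max(drop_)
        if (drop_[k] > 0) {
          b <- occ[k]  # bin just before the weight drop
          cand <- interior[assignment[interior] == b]
          bw <- cand[which.max(weights[cand])]
          assignment[bw] <- nbins + 3L  # bottleneck bin
        }
      }
    }
  }
  list(boundaries = bnd, assignment = assignment)
}

# combined multi-dimensional MAB bin labels ("code,code,...")
mab_labels <- function(coords, weights, cfg) {
  D <- length(cfg$bins_per_dim)
  stopifnot(ncol(coords) >= D)
  codes <- vapply(seq_len(D), function(d) {
    lay <- mab_layout(coords[, d], weights, cfg$bins_per_dim[d],
                      cfg$direction[d], cfg$bottleneck_enabled)
    lay$assignment
  }, integer(nrow(coords)))
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1L)
  apply(codes, 1L, paste, collapse = ",")
}

#' Multi-MAB configuration: independent MAB schemes nested in outer regions
#'
#' The coordinate space is divided by per-dimension outer boundaries into
#' relatively large regions; a separate MAB scheme is nested within each
#' region of interest so that leading walkers in one region cannot soak up
#' all the splitting (oversplitting) that walkers elsewhere need. Each
#' scheme is registered by a placement key, a coordinate vector falling in
#' the outer cell the scheme serves.
#'
#' @param outer_boundaries list (one entry per dimension) of strictly
#'   increasing boundary vectors; `-Inf`/`Inf` are allowed at the ends.
#' @param schemes list of `list(placement = <coordinate vector>, mab =
#'   <mab_config()>)`.
#' @return an object of class `we_multimab_config`.
#' @export
multimab_config <- function(outer_boundaries, schemes) {
  stopifnot(is.list(outer_boundaries), length(outer_boundaries) >= 1L,
            is.list(schemes), length(schemes) >= 1L)
  for (b in outer_boundaries) {
    if (length(b) < 2L || is.unsorted(b, strictly = TRUE))
      stop("outer boundaries must be strictly increasing, length >= 2")
  }
  keys <- vapply(schemes, function(s)
    paste(outer_cell(s$placement, outer_boundaries), collapse = ","),
    character(1))
  if (anyDuplicated(keys))
    stop("two schemes resolve to the same outer cell")
  structure(list(outer_boundaries = outer_boundaries, schemes = schemes,
                 scheme_cells = keys),
            class = "we_multimab_config")
}

# per-dimension outer-cell indices (1-based), half-open cells [lo, hi)
outer_cell <- function(coords, boundaries) {
  D <- length(boundaries)
  vapply(seq_len(D), function(d) {
    i <- findInterval(coords[d], boundaries[[d]])
    if (i < 1L || i >= length(boundaries[[d]]))
      stop("coordinate ", d, " = ", coords[d],
           " lies outside the outer grid")
    i
  }, integer(1))
}

#' Assign a walker to its outer region and nested MAB bin
#'
#' Outer cells are half-open `[lo, hi)` per dimension (a value exactly on a
#' boundary belongs to the upper cell); the nested bin comes from the MAB
#' layout of the scheme registered for that cell, computed over the walkers
#' sharing the cell.
#'
#' @param coords one walker's coordinate vector.
#' @param cfg a [multimab_config()].
#' @param cell_coords optional matrix of coordinates of all walkers sharing
#'   the outer cell (defaults to just this walker, as row `which_row`),
#'   used to build the nested layout.
#' @param cell_weights weights matching `cell_coords`.
#' @param which_row row of `cell_coords` corresponding to this walker.
#' @return list with `outer` (per-dimension 1-based cell indices),
#'   `scheme` (index into `cfg$schemes`), and `inner` (nested bin label).
#' @export
multi_mab_assign <- function(coords, cfg, cell_coords = NULL,
                             cell_weights = NULL, which_row = 1L) {
  cell <- outer_cell(coords, cfg$outer_boundaries)
  key <- paste(cell, collapse = ",")
  s <- match(key, cfg$scheme_cells)
  if (is.na(s))
    stop("no MAB scheme registered for outer cell (", key, ")")
  if (is.null(cell_coords)) {
    cell_coords <- matrix(as.numeric(coords), nrow = 1L)
    cell_weights <- 1
    which_row <- 1L
  }
  lab <- mab_labels(cell_coords, cell_weights, cfg$schemes[[s]]$mab)
  list(outer = cell, scheme = s, inner = lab[which_row])
}

#' Fixed-bin configuration
#'
#' @param boundaries list (one entry per dimension) of strictly increasing
#'   bin boundary vectors; `Inf` allowed as the last boundary. Cells are
#'   half-open `[lo, hi)`.
#' @param target_per_bin walkers per occupied bin after resampling.
#' @return an object of class `we_fixedbin_config`.
#' @export
fixedbin_config <- function(boundaries, target_per_bin = 4L) {
  stopifnot(target_per_bin >= 1)
  if (!is.list(boundaries)) boundaries <- list(boundaries)
  for (b in boundaries)
    if (length(b) < 2L || is.unsorted(b, strictly = TRUE))
      stop("bin boundaries must be strictly increasing, length >= 2")
  structure(list(boundaries = boundaries,
                 target_per_bin = as.integer(target_per_bin)),
            class = "we_fixedbin_config")
}

#' Resample to a target count per bin
#'
#' In each occupied bin: while below target, split the largest-weight walker
#' in two (reducing weight variance fastest); while above target, merge the
#' two smallest-weight walkers, the survivor chosen probabilistically by
#' weight. Per-bin and global weight are conserved. This is the classic
#' binned WE resampling step used by the fixed-bin, MAB, and multi-MAB
#' strategies; only the bin assignment differs between them.
#'
#' @param e a `we_ensemble`.
#' @param assignment character or integer vector, one bin label per walker.
#' @return a `we_ensemble` at `e$iteration + 1` with renumbered ids and an
#'   `"events"` attribute (splits and merges as in [mabl_resample()]).
#' @param target_per_bin walkers per occupied bin.
#' @export
binned_resample <- function(e, assignment, target_per_bin) {
  stopifnot(length(assignment) == length(e$walkers), target_per_bin >= 1)
  pool <- lapply(e$walkers, function(w) { w$parent_id <- w$id; w })
  events <- list(splits = list(), merges = list())
  out <- list()
  for (lab in unique(assignment)) {
    grp <- pool[assignment == lab]
    while (length(grp) < target_per_bin) {
      wts <- vapply(grp, function(w) w$weight, numeric(1))
      i <- which.max(wts)
      ch <- split_walker(grp[[i]], 2L)
      for (j in seq_along(ch)) ch[[j]]$parent_id <- grp[[i]]$parent_id
      events$splits[[length(events$splits) + 1L]] <-
        list(parent_id = grp[[i]]$parent_id, children = 2L)
      grp[[i]] <- ch[[1L]]
      grp <- c(grp, ch[2L])
    }
    while (length(grp) > target_per_bin) {
      wts <- vapply(grp, function(w) w$weight, numeric(1))
      pair <- order(wts)[1:2]
      surv <- merge_walkers(grp[pair])
      ev <- attr(surv, "merge_event")
      pid <- vapply(grp[pair], function(w) w$parent_id, integer(1))
      ev$survivor_id <- surv$parent_id
      ev$absorbed_ids <- setdiff(pid, surv$parent_id)
      attr(surv, "merge_event") <- NULL
      events$merges[[length(events$merges) + 1L]] <- ev
      grp[[min(pair)]] <- surv
      grp[[max(pair)]] <- NULL
    }
    out <- c(out, grp)
  }
  res <- renumber_ensemble(out, e$iteration + 1L, e$tau)
  attr(res, "events") <- events
  res
}

#' MAB resampling step
#' @param e a `we_ensemble`.
#' @param cfg a [mab_config()].
#' @return a resampled `we_ensemble` (see [binned_resample()]).
#' @export
mab_resample <- function(e, cfg) {
  labs <- mab_labels(ens_coords(e), ens_weights(e), cfg)
  binned_resample(e, labs, cfg$target_per_bin)
}

#' Multi-MAB resampling step
#'
#' Walkers are grouped by outer region; within each occupied region the
#' registered nested MAB scheme lays its bins over that region's walkers
#' only, and the per-bin target of that scheme is enforced.
#'
#' @param e a `we_ensemble`.
#' @param cfg a [multimab_config()].
#' @return a resampled `we_ensemble`.
#' @export
multimab_resample <- function(e, cfg) {
  coords <- ens_coords(e)
  wts <- ens_weights(e)
  cells <- apply(coords, 1L, function(x)
    paste(outer_cell(x, cfg$outer_boundaries), collapse = ","))
  labs <- character(length(cells))
  tgt <- integer(length(cells))
  for (key in unique(cells)) {
    s <- match(key, cfg$scheme_cells)
    if (is.na(s))
      stop("no MAB scheme registered for outer cell (", key, ")")
    in_cell <- cells == key
    inner <- mab_labels(coords[in_cell, , drop = FALSE], wts[in_cell],
                        cfg$schemes[[s]]$mab)
    labs[in_cell] <- paste(key, inner, sep = "|")
    tgt[in_cell] <- cfg$schemes[[s]]$mab$target_per_bin
  }
  # per-bin targets are constant within a cell; resample cell by cell
  pool_parts <- list()
  events <- list(splits = list(), merges = list())
  for (key in unique(cells)) {
    in_cell <- cells == key
    sub <- we_ensemble(e$walkers[in_cell], e$iteration, e$tau)
    r <- binned_resample(sub, labs[in_cell], tgt[which(in_cell)[1]])
    ev <- attr(r, "events")
    events$splits <- c(events$splits, ev$splits)
    events$merges <- c(events$merges, ev$merges)
    pool_parts <- c(pool_parts, r$walkers)
  }
  res <- renumber_ensemble(pool_parts, e$iteration + 1L, e$tau)
  attr(res, "events") <- events
  res
}

#' Fixed-bin resampling step
#' @param e a `we_ensemble`.
#' @param cfg a [fixedbin_config()].
#' @return a resampled `we_ensemble`.
#' @export
fixedbin_resample <- function(e, cfg) {
  coords <- ens_coords(e)
  D <- length(cfg$boundaries)
  codes <- vapply(seq_len(D), function(d) {
    i <- findInterval(coords[, d], cfg$boundaries[[d]])
    if (any(i < 1L) || any(i >= length(cfg$boundaries[[d]])))
      stop("walker outside the fixed-bin grid in dimension ", d)
    i
  }, integer(nrow(coords)))
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1L)
  labs <- apply(codes, 1L, paste, collapse = ",")
  binned_resample(e, labs, cfg$target_per_bin)
}

#' Rule-violating merge resampler (bias demonstration)
#'
#' Identical to [mabl_resample()] except that the merge survivor is chosen
#' deterministically as the higher-scoring candidate instead of
#' probabilistically by weight. This breaks the second statistical rule of
#' WE resampling: weight from a terminated high-weight walker is piled onto
#' a low-weight, high-progress survivor, so a few heavy walkers make a
#' "bee-line" to the target with no weight reduction across the barrier.
#' Kept only to demonstrate and test that pathology; refuses to run unless
#' `allow_biased = TRUE`.
#'
#' @inheritParams mabl_resample
#' @param allow_biased must be set to TRUE explicitly.
#' @return a `we_ensemble`; statistically biased by construction.
#' @export
violating_merge_resample <- function(e, spec, cfg, scores = NULL,
                                     allow_biased = FALSE) {
  if (!isTRUE(allow_biased))
    stop("violating_merge_resample is intentionally biased; ",
         "set allow_biased = TRUE to run the demonstration")
  # survivor by highest score (ties: higher weight, lower id) — biased
  biased_merge <- function(ws) {
    wts <- vapply(ws, function(w) w$weight, numeric(1))
    sc <- vapply(ws, function(w) compute_score(w$coords, w$weight, spec),
                 numeric(1))
    ids <- vapply(ws, function(w) w$id, integer(1))
    i <- rank_walkers(sc, wts, ids)[1]
    surv <- ws[[i]]
    surv$weight <- sum(wts)
    attr(surv, "merge_event") <- list(survivor_id = surv$id,
                                      absorbed_ids = ids[-i],
                                      pre_weights = wts)
    surv
  }
  mabl_resample_impl(e, spec, cfg, scores, merge_fun = biased_merge)
}
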