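simple_spec <- function() score_spec(list(coordinate_spec("x", 0, 10)),
                                     balance = "none")

test_that("MABL keeps the walker count fixed for the worked five-walker case", {
  set.seed(1)
  # five walkers ranked by progress along x; top 2 split, bottom 2 merged
  e <- weighted_ensemble(rep(0.2, 5), coords = c(9, 7, 5, 3, 1))
  out <- mabl_resample(e, simple_spec(), mabl_config(2L, 5L))
  expect_length(out$walkers, 5)
  expect_lt(abs(sum(ens_weights(out)) - 1), 1e-12)
  ev <- attr(out, "events")
  expect_length(ev$splits, 2)
  expect_length(ev$merges, 2)
  # the two split parents are the two most-progressed walkers
  expect_setequal(vapply(ev$splits, `[[`, integer(1), "parent_id"),
                  c(1L, 2L))
})

test_that("N = 0 returns the ensemble unchanged", {
  e <- weighted_ensemble(c(0.5, 0.3, 0.2), coords = c(1, 2, 3))
  out <- mabl_resample(e, simple_spec(), mabl_config(0L, 3L))
  expect_length(out$walkers, 3)
  expect_equal(ens_weights(out), ens_weights(e))
  expect_equal(unname(ens_coords(out)), unname(ens_coords(e)))
})

test_that("the 50% rule is enforced at configuration time", {
  expect_error(mabl_config(3L, 5L), "50%")
  expect_error(mabl_config(21L, 40L), "50%")
  expect_silent(mabl_config(20L, 40L))
})

test_that("MABL production shape holds count and weight over 100 iterations", {
  set.seed(23)
  spec <- simple_spec()
  cfg <- mabl_config(5L, 40L)
  e <- uniform_ensemble(40)
  counts <- integer(100); devs <- numeric(100)
  for (t in 1:100) {
    # random-walk coordinates stand in for dynamics
    for (j in seq_along(e$walkers)) {
      x <- e$walkers[[j]]$coords + rnorm(1, 0.05, 0.5)
      e$walkers[[j]]$coords <- min(max(x, 0), 10)
    }
    e <- mabl_resample(e, spec, cfg)
    counts[t] <- length(e$walkers)
    devs[t] <- abs(sum(ens_weights(e)) - 1)
  }
  expect_true(all(counts == 40L))
  expect_lt(max(devs), 1e-12)
})

test_that("split set and merge-removed set are disjoint", {
  set.seed(4)
  spec <- simple_spec()
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    N <- sample.int(floor(n / 2), 1)
    wts <- runif(n); wts <- wts / sum(wts)
    e <- weighted_ensemble(wts, coords = runif(n, 0, 10))
    out <- mabl_resample(e, spec, mabl_config(N, n))
    expect_length(out$walkers, n)
    ev <- attr(out, "events")
    split_ids <- vapply(ev$splits, `[[`, integer(1), "parent_id")
    selected <- vapply(ev$merges, `[[`, integer(1), "selected_id")
    # no walker is selected both for splitting and for merging in the same
    # resampling step (the reason N may not exceed 50% of the count)
    expect_length(intersect(split_ids, selected), 0)
    # all lineage pointers resolve to input walkers
    out_parents <- vapply(out$walkers, function(w) w$parent_id, integer(1))
    expect_true(all(out_parents %in% ens_ids(e)))
  }
})

test_that("pairwise_bottom merge policy also preserves count and weight", {
  set.seed(8)
  e <- weighted_ensemble(rep(0.1, 10), coords = 10:1)
  out <- mabl_resample(e, simple_spec(),
                       mabl_config(3L, 10L, merge_policy = "pairwise_bottom"))
  expect_length(out$walkers, 10)
  expect_lt(abs(sum(ens_weights(out)) - 1), 1e-12)
})

test_that("MAB layout spaces interior bins evenly between the edges", {
  lay <- mab_layout(c(0, 2.5, 4.5, 6.5, 10), rep(0.2, 5), nbins = 5,
                    bottleneck_enabled = FALSE)
  expect_equal(lay$boundaries, seq(0, 10, by = 2))
  # edge walkers go to the dedicated edge bins
  expect_equal(lay$assignment[1], 6L)   # lagging edge
  expect_equal(lay$assignment[5], 7L)   # leading edge
  expect_true(all(lay$assignment[2:4] %in% 1:5))

  # direction -1 swaps the roles of the edges
  lay2 <- mab_layout(c(0, 2.5, 4.5, 6.5, 10), rep(0.2, 5), nbins = 5,
                     direction = -1, bottleneck_enabled = FALSE)
  expect_equal(lay2$assignment[1], 7L)  # now the leading edge
  expect_equal(lay2$assignment[5], 6L)

  # degenerate: all walkers at one point collapse to a single interior bin
  lay3 <- mab_layout(rep(2, 4), rep(0.25, 4), nbins = 5)
  expect_equal(lay3$assignment, rep(1L, 4))
})

test_that("bottleneck bin isolates the walker before the weight cliff", {
  # weight drops by e^-6 between adjacent occupied bins: a barrier signature
  pos <- c(0.5, 1.5, 2.5, 3.5, 9.9, 0.01)
  wts <- c(0.4, 0.3, 0.2, 0.2 * exp(-6), 1e-9, 0.1)
  lay <- mab_layout(pos, wts, nbins = 10, bottleneck_enabled = TRUE)
  # the bin holding position 2.5 precedes the largest -ln(weight) increase
  expect_equal(lay$assignment[3], 13L)  # nbins + 3
  lay_off <- mab_layout(pos, wts, nbins = 10, bottleneck_enabled = FALSE)
  expect_true(all(lay_off$assignment <= 12L))
})

test_that("outer-region assignment uses half-open cells over printed boundaries", {
  # four-dimensional outer grid with the published boundary lists
  ob <- list(c(0, 7.5, 10.5, Inf), c(-Inf, 10, Inf), c(0, 6, Inf),
             c(0, 6, Inf))
  mk <- function() mab_config(c(1L, 1L, 1L, 1L))
  schemes <- list(list(placement = c(3, 55, 5, 5), mab = mk()),
                  list(placement = c(8, 55, 5, 5), mab = mk()),
                  list(placement = c(11, 55, 5, 5), mab = mk()),
                  list(placement = c(11, 5, 5, 5), mab = mk()))
  cfg <- multimab_config(ob, schemes)
  # the four placement keys resolve to four distinct outer cells
  expect_length(unique(cfg$scheme_cells), 4)
  # rmsd-like value 8 falls in the second cell [7.5, 10.5)
  a <- multi_mab_assign(c(8, 55, 5, 5), cfg)
  expect_equal(a$outer[1], 2L)
  expect_equal(a$scheme, 2L)
  # a value exactly on a boundary belongs to the upper cell
  a2 <- multi_mab_assign(c(7.5, 55, 5, 5), cfg)
  expect_equal(a2$outer[1], 2L)
  a3 <- multi_mab_assign(c(10.5, 55, 5, 5), cfg)
  expect_equal(a3$outer[1], 3L)
  # unregistered cell is a configuration error naming the cell
  expect_error(multi_mab_assign(c(3, 5, 5, 5), cfg), "no MAB scheme")
})

test_that("binned resampling reaches the per-bin target and conserves weight", {
  set.seed(12)
  # one under-populated bin: repeated splitting of the largest walker
  e1 <- we_ensemble(list(we_walker(1L, 0L, 0.4, 1),
                         we_walker(2L, 0L, 0.6, 5)))
  out1 <- binned_resample(e1, c("a", "b"), target_per_bin = 4L)
  wa <- vapply(out1$walkers, function(w) w$weight, numeric(1))
  ca <- as.numeric(ens_coords(out1))
  expect_equal(sort(wa[ca == 1]), rep(0.1, 4))
  expect_equal(sum(wa[ca == 5]), 0.6)
  expect_length(out1$walkers, 8)

  # a bin already at target is untouched
  e2 <- uniform_ensemble(4)
  out2 <- binned_resample(e2, rep("a", 4), 4L)
  expect_equal(ens_weights(out2), ens_weights(e2))

  # over-populated bin merges down, conserving bin weight
  e3 <- we_ensemble(lapply(1:9, function(j)
    we_walker(j, 0L, c(rep(0.05, 8), 0.6)[j], 2)))
  out3 <- binned_resample(e3, rep("a", 9), 4L)
  expect_length(out3$walkers, 4)
  expect_lt(abs(sum(ens_weights(out3)) - 1), 1e-12)
})

test_that("per-bin weight is conserved exactly under binned resampling", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(8:30, 1)
    wts <- runif(n); wts <- wts / sum(wts)
    coords <- runif(n, 0, 10)
    labs <- as.character(findInterval(coords, c(0, 3, 6, 10)))
    e <- weighted_ensemble(wts, coords = coords)
    out <- binned_resample(e, labs, sample(2:5, 1))
    oc <- as.numeric(ens_coords(out))
    olabs <- as.character(findInterval(oc, c(0, 3, 6, 10)))
    for (lab in unique(labs)) {
      w_in <- sum(wts[labs == lab])
      w_out <- sum(ens_weights(out)[olabs == lab])
      expect_lt(abs(w_in - w_out), 1e-12)
    }
  }
})

test_that("violating merge keeps the higher-scoring walker deterministically", {
  # 4 walkers; N=1: top walker split, worst two-ish merged. Construct so the
  # merge pair is {weight 0.3 scoring low, weight 0.1 scoring higher}: the
  # biased rule must keep the 0.1 walker and hand it the 0.4 total.
  spec <- simple_spec()
  e <- weighted_ensemble(c(0.3, 0.3, 0.1, 0.3), coords = c(9, 8, 2, 1))
  cfg <- mabl_config(1L, 4L)
  expect_error(violating_merge_resample(e, spec, cfg), "allow_biased")
  out <- violating_merge_resample(e, spec, cfg, allow_biased = TRUE)
  ev <- attr(out, "events")
  expect_length(ev$merges, 1)
  # survivor is input walker 3 (score 2 > score 1) despite lower weight
  expect_equal(ev$merges[[1]]$survivor_id, 3L)
  expect_equal(ev$merges[[1]]$absorbed_ids, 4L)
  expect_equal(sum(ev$merges[[1]]$pre_weights), 0.4)
  surv <- out$walkers[[which(vapply(out$walkers, function(w) w$parent_id,
                                    integer(1)) == 3L)]]
  expect_equal(surv$weight, 0.4)

  # with equal weights and equal scores the choice is degenerate: any
  # survivor carries the same state, so the biased rule is harmless
  e2 <- weighted_ensemble(rep(0.25, 4), coords = c(5, 5, 1, 1))
  out2 <- violating_merge_resample(e2, spec, cfg, allow_biased = TRUE)
  expect_lt(abs(sum(ens_weights(out2)) - 1), 1e-12)
})

test_that("removing the balance term reorders ranks but never breaks invariants", {
  set.seed(77)
  spec_b <- score_spec(list(coordinate_spec("x", 0, 10)))
  spec_n <- score_spec(list(coordinate_spec("x", 0, 10)), balance = "none")
  wts <- runif(12); wts <- wts / sum(wts)
  e <- weighted_ensemble(wts, coords = runif(12, 0.1, 9.9))
  for (spec in list(spec_b, spec_n)) {
    out <- mabl_resample(e, spec, mabl_config(3L, 12L))
    expect_length(out$walkers, 12)
    expect_lt(abs(sum(ens_weights(out)) - 1), 1e-12)
  }
})
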