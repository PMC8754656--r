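# a tiny percentage table with known per-round values:
# 2 tiles, 3 replicates, rounds 1/4/7/10
toy_pct <- function(ne_a = c(0.008, 0.006, 0.004, 0.002)) {
  grid <- tidyr::expand_grid(
    tile_id = c("a", "b"), library_id = 1L,
    condition = c("buffer", "NE"), round = c(1L, 4L, 7L, 10L),
    replicate = 1:3
  )
  jitter <- rep(c(-1e-4, 0, 1e-4), length.out = nrow(grid))
  base <- ifelse(
    grid$condition == "NE" & grid$tile_id == "a",
    ne_a[match(grid$round, c(1, 4, 7, 10))],
    0.01
  )
  dplyr::mutate(grid, fraction = base + jitter)
}

test_that("condition means average replicates and demand a complete grid", {
  pct <- toy_pct()
  means <- condition_means(pct)
  expect_equal(
    means$mean_fraction[means$tile_id == "b"],
    rep(0.01, 8)
  )
  # permutation of replicate labels changes nothing
  perm <- dplyr::mutate(pct, replicate = c(2L, 3L, 1L)[replicate])
  expect_equal(condition_means(perm), means)
  expect_error(condition_means(pct[-1, ]), "missing replicate cell")
})

test_that("ratio trajectories divide NE by buffer per round", {
  means <- condition_means(toy_pct())
  traj <- ratio_trajectory(means) |> dplyr::arrange(tile_id, round)
  expect_equal(traj$ratio[traj$tile_id == "a"], c(0.8, 0.6, 0.4, 0.2))
  expect_equal(traj$ratio[traj$tile_id == "b"], rep(1, 4))
  # a common per-round scale factor cancels
  scaled <- dplyr::mutate(means,
    mean_fraction = mean_fraction * (1 + round / 10)
  )
  expect_equal(ratio_trajectory(scaled)$ratio, ratio_trajectory(means)$ratio)
})

test_that("fit_slope matches closed forms and a normal-equations oracle", {
  expect_equal(fit_slope(c(1, 1, 1, 1)), 0)
  expect_equal(fit_slope(c(1.0, 0.9, 0.8, 0.7)), -1 / 30)
  expect_equal(fit_slope(rev(c(1.0, 0.9, 0.8, 0.7))), 1 / 30)

  set.seed(4)
  for (i in 1:200) {
    k <- sample(3:8, 1)
    x <- sort(runif(k, 0, 20))
    y <- rnorm(k)
    ours <- fit_slope(y, x)
    # normal equations via solve()
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(ours, beta[2], tolerance = 1e-12, ignore_attr = TRUE)
    # and lm() as a second, independent route
    expect_equal(ours, unname(coef(lm(y ~ x))[2]), tolerance = 1e-12)
  }
  expect_error(fit_slope(c(1, NA, 1, 1)), "non-finite")
})

test_that("per-round t-test matches hand computation and stats::t.test", {
  same <- per_round_test(c(0.01, 0.01, 0.01), c(0.01, 0.01, 0.01))
  expect_equal(same$p_value, 1)
  expect_false(same$degenerate)

  res <- per_round_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3.674235, tolerance = 1e-6)
  expect_identical(res$df, 4)
  expect_equal(res$p_value, 0.02131164, tolerance = 1e-6)
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(res$p_value, ref$p.value)

  # two-sided: label swap leaves p unchanged
  expect_equal(
    per_round_test(c(4, 5, 6), c(1, 2, 3))$p_value, res$p_value
  )

  w <- per_round_test(c(1, 2, 3), c(4, 5, 7), test = "welch")
  refw <- t.test(c(1, 2, 3), c(4, 5, 7))
  expect_equal(w$p_value, refw$p.value)
  expect_equal(w$df, unname(refw$parameter))

  deg <- per_round_test(c(1, 1, 1), c(2, 2, 2))
  expect_true(deg$degenerate)
  expect_gt(deg$p_value, 0)
  expect_lt(deg$p_value, 1e-100)
})

test_that("candidate calling is the conjunction of slope sign and all rounds", {
  pct <- toy_pct()
  records <- depletion_records(pct)
  calls <- call_candidates(records)
  a <- calls[calls$tile_id == "a", ]
  b <- calls[calls$tile_id == "b", ]
  expect_true(a$is_candidate)
  expect_lt(a$slope, 0)
  expect_false(b$is_candidate)

  # one failing round breaks the call even with a negative slope:
  # NE round 7 overlaps buffer exactly
  pct2 <- toy_pct(ne_a = c(0.008, 0.006, 0.010, 0.002))
  calls2 <- call_candidates(depletion_records(pct2))
  expect_false(calls2$is_candidate[calls2$tile_id == "a"])
  expect_lt(calls2$slope[calls2$tile_id == "a"], 0)

  # positive slope is never called, however significant the rounds
  pct3 <- toy_pct(ne_a = c(0.002, 0.004, 0.006, 0.0099))
  calls3 <- call_candidates(depletion_records(pct3))
  expect_true(all(calls3$p_r1[calls3$tile_id == "a"] < 0.05))
  expect_gt(calls3$slope[calls3$tile_id == "a"], 0)
  expect_false(calls3$is_candidate[calls3$tile_id == "a"])

  g <- glance(calls)
  expect_identical(g$n_tested, 2L)
  expect_identical(g$n_candidates, 1L)
})

test_that("BH-adjusted columns are reported but never gate the call", {
  pct <- toy_pct()
  calls <- call_candidates(depletion_records(pct))
  expect_true(all(c("p_bh_r1", "p_bh_r4", "p_bh_r7", "p_bh_r10") %in% names(calls)))
  expect_true(all(calls$p_bh_r1 >= calls$p_r1))
})

test_that("combined-test mode calls on one pooled test across rounds", {
  pct <- toy_pct()
  rec <- depletion_records(pct, test_scope = "combined")
  expect_true("p_combined" %in% names(rec))
  calls <- call_candidates(rec)
  expect_true(calls$is_candidate[calls$tile_id == "a"])
  expect_false(calls$is_candidate[calls$tile_id == "b"])
})

test_that("calls are invariant to replicate relabeling and depth rescaling", {
  tiles <- dplyr::filter(design_tiling(rand_region(35 * 60, seed = 12)), library_id == 1)
  scr <- simulate_screen(
    tiles, design = screen_design(depth = 5e4, pool_size = 5e5),
    n_functional = 6, seed = 21
  )
  counts <- scr$counts
  base <- call_candidates(depletion_records(to_percentages(counts, pseudocount = 0)))

  relabel <- dplyr::mutate(counts, replicate = c(3L, 1L, 2L)[replicate])
  again <- call_candidates(depletion_records(to_percentages(relabel, pseudocount = 0)))
  expect_identical(
    base$is_candidate[order(base$tile_id)],
    again$is_candidate[order(again$tile_id)]
  )

  # deterministic limit of uniform depth rescaling: counts scaled exactly
  scaled <- dplyr::mutate(counts, count = count * 13L)
  resc <- call_candidates(depletion_records(to_percentages(scaled, pseudocount = 0)))
  expect_identical(
    base$is_candidate[order(base$tile_id)],
    resc$is_candidate[order(resc$tile_id)]
  )
})
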