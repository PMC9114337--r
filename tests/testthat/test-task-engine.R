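test_that("reward walks respect bounds, rounding, and determinism", {
  w <- generate_reward_walk(seed = 11, n_trials = 10000)
  expect_true(all(w$displayed >= 0 & w$displayed <= 9))
  expect_true(all(w$latent >= 0 & w$latent <= 9))
  expect_identical(w$displayed, matrix(as.integer(round(w$latent)), ncol = 2,
                                       dimnames = dimnames(w$displayed)))
  # bit-for-bit reproducibility
  w2 <- generate_reward_walk(seed = 11, n_trials = 10000)
  expect_identical(w$latent, w2$latent)
  # distinct substreams: the two planets' walks differ
  expect_false(all(w$latent[, 1] == w$latent[, 2]))
})

test_that("zero-noise walk stays constant at the rounded start", {
  w <- generate_reward_walk(seed = 3, n_trials = 50, sd = 0, start = 6.3)
  expect_true(all(w$displayed == 6L))
  expect_true(all(w$latent == 6.3))
  expect_error(generate_reward_walk(1, 10, sd = -1), "non-negative")
})

test_that("long-run walk mean matches the discretized-chain oracle", {
  target <- oracle_walk_stationary_mean(sd = 2, lower = 0, upper = 9)
  w <- generate_reward_walk(seed = 7, n_trials = 100000)
  expect_lt(abs(mean(w$latent[, 1]) - target), 0.1)
  expect_lt(abs(mean(w$latent[, 2]) - target), 0.1)
})

test_that("study layouts encode the two session structures", {
  l1 <- study_layout("study1")
  expect_identical(l1$n_trials, 320L)
  expect_identical(l1$block_length, 80L)
  expect_identical(sort(unique(l1$transition_condition_per_block)),
                   c("stable", "variable"))
  l2 <- study_layout("study2")
  expect_identical(l2$n_trials, 280L)
  expect_identical(l2$transition_condition_per_block, "stable")
  expect_identical(l1$stakes_multipliers, c(low = 1L, high = 5L))
})

test_that("study-2 plans balance stakes 140/140", {
  plan <- generate_trial_plan(study_layout("study2"), 1, seed = 2)
  expect_identical(nrow(plan), 280L)
  expect_identical(unname(table(plan$stakes)["low"]), 140L)
  expect_identical(unname(table(plan$stakes)["high"]), 140L)
  expect_true(all(plan$transition_condition == "stable"))
  expect_identical(nrow(attr(plan, "swap_trials")), 0L)
})

test_that("study-1 plans alternate conditions with swaps only in variable blocks", {
  for (cb in 1:4) {
    plan <- generate_trial_plan(study_layout("study1"), cb, seed = 13)
    conds <- tapply(plan$transition_condition, plan$block, unique)
    expect_length(conds, 4L)
    expect_true(all(conds[c(1, 3)] == conds[1]))
    expect_true(all(conds[c(2, 4)] != conds[1]))
    swaps <- attr(plan, "swap_trials")
    swap_cond <- plan$transition_condition[match(swaps$trial, plan$trial)]
    expect_true(all(swap_cond == "variable"))
    # balanced stakes within every condition cell
    expect_true(all(table(plan$transition_condition, plan$stakes) == 80L))
  }
})

test_that("inter-swap gaps lie in 6..14 and swaps toggle exactly one pair", {
  for (seed in 1:200) {
    plan <- generate_trial_plan(study_layout("study1"), 1, seed = seed)
    swaps <- attr(plan, "swap_trials")
    for (b in unique(plan$block[plan$transition_condition == "variable"])) {
      first <- min(plan$trial[plan$block == b])
      st <- sort(swaps$trial[swaps$trial >= first &
                               swaps$trial < first + 80])
      gaps <- diff(c(first - 1L, st))
      expect_true(all(gaps >= 6 & gaps <= 14))
    }
  }
  plan <- generate_trial_plan(study_layout("study1"), 1, seed = 20)
  swaps <- attr(plan, "swap_trials")
  expect_gt(nrow(swaps), 0L)
  maps <- as.matrix(plan[, c("map1", "map2")])
  for (i in seq_len(nrow(swaps))) {
    t <- swaps$trial[i]
    if (sum(swaps$trial == t) > 1L) next # two pairs swapped the same trial
    changed <- maps[t, ] != maps[t - 1L, ]
    expect_identical(unname(which(changed)), swaps$pair[i])
  }
})

test_that("shared randomness depends only on the seed, not the cell", {
  p1 <- generate_trial_plan(study_layout("study1"), 1, seed = 5)
  p2 <- generate_trial_plan(study_layout("study1"), 4, seed = 5)
  expect_identical(p1$reward_red, p2$reward_red)
  expect_identical(p1$s1, p2$s1)
  # complemented stakes in the flipped cell
  expect_true(all(p1$stakes != p2$stakes))
  expect_error(generate_trial_plan(study_layout("study2"), 3, seed = 1),
               "counterbalance")
})

test_that("trial plans round-trip through CSV", {
  plan <- generate_trial_plan(study_layout("study1"), 2, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_plan(plan, path)
  back <- read_trial_plan(path)
  expect_identical(back$first_stage_state, plan$s1)
  expect_identical(back$map_state1, plan$map1)
  expect_identical(back$reward_planet_red, plan$reward_red)
  # the two actions always lead to different planets
  expect_true(all(back$action0_dest != back$action1_dest))
})
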