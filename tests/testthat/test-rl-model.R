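params_s1 <- function(...) {
  defaults <- list(alpha = 0.3, lam = 0.6, eta = 0.4, eta_cf = 0.25,
                   omega = c(stable.low = 0.2, stable.high = 0.9,
                             variable.low = 0.45, variable.high = 0.55),
                   beta = 1.7, pi = 0.3, rho = -0.2)
  do.call(model_params, utils::modifyList(defaults, list(...)))
}

params_s2 <- function(...) {
  defaults <- list(alpha = 0.5, lam = 0, omega = c(low = 0.2, high = 0.7),
                   beta = 2, pi = 0.2, rho = 0.1)
  do.call(model_params, utils::modifyList(defaults, list(...)))
}

test_that("the initial agent state encodes neutral beliefs", {
  st <- init_agent_state(study_layout("study1"))
  expect_true(all(st$q1 == 4.5))
  expect_true(all(st$q2 == 4.5))
  expect_true(all(st$trans == 0.5))
  # red and purple probabilities are complementary
  expect_true(all(st$trans + (1 - st$trans) == 1))
  expect_true(all(st$elig1 == 0) && all(st$elig2 == 0))
})

test_that("model-free updates follow the eligibility-trace TD rule", {
  st <- init_agent_state()
  # zero learning rate leaves values untouched
  st0 <- mf_update(st, list(stage = 2L, s = 1L, r = 9, next_value = 0),
                   alpha = 0, lam = 0.5)
  expect_identical(st0$q1, st$q1)
  expect_identical(st0$q2, st$q2)
  # full learning rate jumps to the observed reward
  st1 <- mf_update(st, list(stage = 2L, s = 1L, r = 9, next_value = 0),
                   alpha = 1, lam = 0)
  expect_equal(unname(st1$q2["red"]), 9)
  expect_equal(unname(st1$q2["purple"]), 4.5)
})

test_that("transition updates renormalize and respect their rates", {
  st <- init_agent_state()
  # eta = 1 jumps to certainty
  s1 <- transition_update(st, 1L, 1L, observed_planet = 1L,
                          eta = 1, eta_cf = 1)
  expect_equal(s1$trans[1, 1], 1)
  expect_equal(s1$trans[1, 2], 0) # counterfactual action -> other planet
  # zero rates change nothing
  s0 <- transition_update(st, 1L, 1L, 1L, eta = 0, eta_cf = 0)
  expect_identical(s0$trans, st$trans)
  # hand-evaluated half update from the neutral state
  sh <- transition_update(st, 2L, 1L, observed_planet = 1L,
                          eta = 0.5, eta_cf = 0.3)
  expect_equal(sh$trans[2, 1], 0.75)      # 0.5 + 0.5 * (1 - 0.5)
  expect_equal(1 - sh$trans[2, 1], 0.25)  # complement rescaled by (1 - eta)
})

test_that("model-based values are the transition-weighted planet values", {
  st <- init_agent_state()
  st$q2 <- c(red = 3, purple = 7)
  expect_true(all(mb_first_stage_values(st) == 5))
  st$trans[1, 1] <- 1
  st$q2 <- c(red = 8, purple = 0)
  expect_equal(mb_first_stage_values(st)[1, 1], 8)
  # random instances vs. a 2-term enumeration
  for (i in 1:25) {
    st$trans <- matrix(runif(4), 2, 2)
    st$q2 <- c(red = runif(1, 0, 9), purple = runif(1, 0, 9))
    direct <- matrix(NA_real_, 2, 2)
    for (s in 1:2) for (a in 1:2) {
      direct[s, a] <- sum(c(st$trans[s, a], 1 - st$trans[s, a]) *
                            c(st$q2["red"], st$q2["purple"]))
    }
    expect_equal(mb_first_stage_values(st), direct, tolerance = 1e-12)
  }
})

test_that("choice probabilities mix values, stickiness and temperature", {
  st <- init_agent_state()
  st$q1[1, ] <- c(9, 0)
  p <- params_s1(beta = 0)
  expect_equal(unname(choice_probabilities(st, 1L, "stable.low", p)),
               c(0.5, 0.5))
  # pure planner ignores arbitrary first-stage model-free values
  p_mb <- params_s1(omega = c(stable.low = 1, stable.high = 1,
                              variable.low = 1, variable.high = 1),
                    pi = 0, rho = 0)
  st2 <- st
  st2$q1[1, ] <- c(-100, 100)
  expect_equal(choice_probabilities(st, 1L, "stable.low", p_mb),
               choice_probabilities(st2, 1L, "stable.low", p_mb))
  expect_error(choice_probabilities(st, 1L, "nonsense", p), "unknown")
  # direct softmax formula, independent transcription
  set.seed(42)
  for (i in 1:20) {
    st$q1 <- matrix(runif(4, 0, 9), 2, 2)
    st$q2 <- c(red = runif(1, 0, 9), purple = runif(1, 0, 9))
    st$trans <- matrix(runif(4), 2, 2)
    st$prev_s1 <- sample(1:2, 1)
    st$prev_a <- sample(1:2, 1)
    st$prev_key <- sample(1:2, 1)
    a_left <- sample(1:2, 1)
    pp <- params_s1()
    got <- choice_probabilities(st, 1L, "variable.high", pp, a_left)
    w <- pp$omega[["variable.high"]]
    v <- numeric(2)
    for (a in 1:2) {
      qmb <- st$trans[1, a] * st$q2[["red"]] +
        (1 - st$trans[1, a]) * st$q2[["purple"]]
      q <- (1 - w) * st$q1[1, a] + w * qmb
      rep_i <- as.numeric(st$prev_s1 == 1 && st$prev_a == a)
      key_a <- if (a == a_left) 1L else 2L
      resp_i <- as.numeric(key_a == st$prev_key)
      v[a] <- pp$beta * (q + pp$pi * rep_i + pp$rho * resp_i)
    }
    expect_equal(unname(got), exp(v) / sum(exp(v)), tolerance = 1e-12)
  }
})

test_that("likelihood replay matches the straight-line transcript oracle", {
  # study-1 layout with transition learning and injected missing responses
  plan <- generate_trial_plan(study_layout("study1"), 2, seed = 5)
  p <- params_s1()
  b <- simulate_agent(p, plan, seed = 9, missing_rate = 0.05)
  o <- oracle_replay(params_as_list(p), behavior_with_cells(b))
  expect_equal(log_likelihood(p, b), o$loglik, tolerance = 1e-10)
  det <- log_likelihood(p, b, details = TRUE)
  n <- nrow(b)
  expect_equal(det$q1[n, ], as.vector(t(o$Q1)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(det$q2[n, ], o$Q2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(det$trans[n, ], as.vector(t(o$Tr)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(det$p_chosen, o$p_chosen, tolerance = 1e-12)

  # study-2 layout: known transition map, no transition learning
  plan2 <- generate_trial_plan(study_layout("study2"), 1, seed = 6)
  p2 <- params_s2()
  b2 <- simulate_agent(p2, plan2, seed = 10, missing_rate = 0.03)
  o2 <- oracle_replay(params_as_list(p2), behavior_with_cells(b2),
                      known = TRUE)
  expect_equal(log_likelihood(p2, b2), o2$loglik, tolerance = 1e-10)
})

test_that("replay reproduces the simulator's internal state sequence", {
  plan <- generate_trial_plan(study_layout("study1"), 1, seed = 15)
  p <- params_s1()
  b <- simulate_agent(p, plan, seed = 3)
  det <- log_likelihood(p, b, details = TRUE)
  # the simulated choices must have been drawn from the replayed
  # probabilities: resimulating with the same seed and the replayed
  # probabilities reproduces the identical choice sequence
  b2 <- simulate_agent(p, plan, seed = 3)
  expect_identical(b$a1, b2$a1)
  expect_identical(b$reward, b2$reward)
  expect_false(any(is.na(det$p_chosen)))
})

test_that("single-strategy limits reproduce dedicated learners", {
  plan <- generate_trial_plan(study_layout("study1"), 1, seed = 77)
  w0 <- c(stable.low = 0, stable.high = 0, variable.low = 0,
          variable.high = 0)
  w1 <- c(stable.low = 1, stable.high = 1, variable.low = 1,
          variable.high = 1)
  p_mf <- params_s1(omega = w0)
  p_mb <- params_s1(omega = w1)
  b_mf <- simulate_agent(p_mf, plan, seed = 1)
  b_mb <- simulate_agent(p_mb, plan, seed = 2)
  o_mf <- oracle_replay(params_as_list(p_mf), behavior_with_cells(b_mf))
  o_mb <- oracle_replay(params_as_list(p_mb), behavior_with_cells(b_mb))
  expect_equal(log_likelihood(p_mf, b_mf), o_mf$loglik, tolerance = 1e-10)
  expect_equal(log_likelihood(p_mb, b_mb), o_mb$loglik, tolerance = 1e-10)
})

test_that("value and transition tables stay inside their ranges", {
  plan <- generate_trial_plan(study_layout("study1"), 1, seed = 30)
  set.seed(123)
  for (i in 1:5) {
    p <- params_s1(alpha = runif(1), lam = runif(1), eta = runif(1),
                   eta_cf = runif(1), beta = runif(1, 0, 3))
    b <- simulate_agent(p, plan, seed = i, missing_rate = 0.02)
    det <- log_likelihood(p, b, details = TRUE)
    expect_true(all(det$q1 >= 0 & det$q1 <= 9))
    expect_true(all(det$q2 >= 0 & det$q2 <= 9))
    expect_true(all(det$trans >= 0 & det$trans <= 1))
  }
})

test_that("a flat-softmax agent chooses uniformly and has closed-form likelihood", {
  plan <- generate_trial_plan(study_layout("study1"), 1, seed = 8)
  p <- params_s1(beta = 0)
  freq <- mean(unlist(lapply(1:32, function(s) {
    simulate_agent(p, plan, seed = s)$a1 == 1L
  })))
  expect_lt(abs(freq - 0.5), 0.02) # ~10^4 trials in total
  b <- simulate_agent(p, plan, seed = 1, missing_rate = 0.05)
  n_valid <- sum(b$missing_stage1 == 0L)
  expect_equal(log_likelihood(p, b), n_valid * log(0.5), tolerance = 1e-12)
})

test_that("a planning agent on a stable map earns above baseline", {
  plan <- generate_trial_plan(study_layout("study2"), 1, seed = 4)
  p <- params_s2(omega = c(low = 1, high = 1), beta = 5)
  b <- simulate_agent(p, plan, seed = 2)
  perf <- task_performance(b)
  expect_true(all(perf$mean_performance > 0))
})

test_that("the likelihood is maximized near the generating parameters", {
  plan <- generate_trial_plan(study_layout("study2"), 1, seed = 44)
  p <- params_s2(beta = 2)
  p_pert <- params_s2(beta = 4)
  diffs <- vapply(1:40, function(s) {
    b <- simulate_agent(p, plan, seed = s)
    log_likelihood(p, b) - log_likelihood(p_pert, b)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("likelihood rejects degenerate inputs", {
  plan <- generate_trial_plan(study_layout("study2"), 1, seed = 1)
  p <- params_s2()
  b <- simulate_agent(p, plan, seed = 1)
  expect_error(log_likelihood(p, b[0, ]), "empty")
  p_bad <- p
  p_bad$beta <- NaN
  expect_error(log_likelihood(p_bad, b), "NA|NaN")
  expect_error(simulate_agent(params_s1(), plan, seed = 1), "layout")
})
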