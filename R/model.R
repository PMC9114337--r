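#' Parameter vector of the hybrid reinforcement-learning model
#'
#' One participant's parameters for the hybrid model-free/model-based learner:
#' reward learning rate `alpha`, eligibility-trace decay `lam`, transition
#' learning rate `eta` and counterfactual transition learning rate `eta_cf`
#' (all in `[0, 1]`), condition-specific model-based weights `omega` (one per
#' condition cell of the layout, each in `[0, 1]`), inverse softmax
#' temperature `beta` (non-negative), and the unbounded choice stickiness
#' `pi` (same stimulus as the previous trial) and response stickiness `rho`
#' (same key as the previous trial).
#'
#' @param alpha Reward learning rate in `[0, 1]`.
#' @param omega Named numeric vector of model-based weights; names must be
#'   exactly the layout's condition cells (see [study_layout()]).
#' @param beta Inverse softmax temperature, `>= 0`.
#' @param lam Eligibility-trace decay in `[0, 1]` (default 0).
#' @param eta Transition learning rate in `[0, 1]` (default 1); applies in
#'   variable-transitions blocks, while stable blocks always use rate 1.
#' @param eta_cf Counterfactual transition learning rate in `[0, 1]`
#'   (default 1).
#' @param pi Choice stickiness (default 0).
#' @param rho Response stickiness (default 0).
#' @return An object of class `model_params`.
#' @export
#' @examples
#' model_params(alpha = 0.4, omega = c(low = 0.3, high = 0.7), beta = 1)
model_params <- function(alpha, omega, beta, lam = 0, eta = 1, eta_cf = 1,
                         pi = 0, rho = 0) {
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
      stop("`", nm, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  chk01(alpha, "alpha"); chk01(lam, "lam")
  chk01(eta, "eta"); chk01(eta_cf, "eta_cf"); chk01(omega, "omega")
  if (!is.numeric(beta) || is.na(beta) || beta < 0) {
    stop("`beta` must be >= 0", call. = FALSE)
  }
  if (is.null(names(omega)) || anyDuplicated(names(omega))) {
    stop("`omega` must be a named vector with unique condition-cell names",
         call. = FALSE)
  }
  structure(list(alpha = alpha, lam = lam, eta = eta, eta_cf = eta_cf,
                 omega = omega, beta = beta, pi = pi, rho = rho),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Hybrid RL parameters:\n")
  cat(sprintf("  alpha = %.3f  lam = %.3f  eta = %.3f  eta_cf = %.3f\n",
              x$alpha, x$lam, x$eta, x$eta_cf))
  cat(sprintf("  beta = %.3f  pi = %+.3f  rho = %+.3f\n", x$beta, x$pi, x$rho))
  cat("  omega: ", paste(names(x$omega), "=", round(x$omega, 3),
                         collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Initial beliefs of the hybrid learner
#'
#' Returns the agent's state at the start of a session: all model-free reward
#' expectations at 4.5 (the midpoint of the 0–9 reward range), all transition
#' probabilities at 0.5, all eligibility traces at 0, and no previous
#' stimulus or key.
#'
#' @param layout A [study_layout()] (kept for interface symmetry; the state
#'   dimensions are the same for both layouts).
#' @return An object of class `agent_state`: list with `q1` (2 x 2 matrix of
#'   first-stage expectations, rows = first-stage states, columns = actions),
#'   `q2` (length-2 planet expectations, `red`, `purple`), `trans` (2 x 2
#'   matrix of probabilities that each state-action pair leads to the red
#'   planet), `elig1`, `elig2` (eligibility traces), and `prev_s1`, `prev_a`,
#'   `prev_key` (`NA` at session start).
#' @export
init_agent_state <- function(layout = study_layout("study1")) {
  stopifnot(inherits(layout, "task_layout"))
  structure(list(
    q1 = matrix(4.5, 2, 2, dimnames = list(state = NULL, action = NULL)),
    q2 = c(red = 4.5, purple = 4.5),
    trans = matrix(0.5, 2, 2),
    elig1 = matrix(0, 2, 2),
    elig2 = c(red = 0, purple = 0),
    prev_s1 = NA_integer_, prev_a = NA_integer_, prev_key = NA_integer_
  ), class = "agent_state")
}

#' Temporal-difference update of the model-free values
#'
#' Applies one model-free learning step for an observed stage transition:
#' the eligibility trace of the just-taken state-action pair is set to 1, the
#' reward prediction error `delta = r + next_value - Q_MF(s, a)` is computed,
#' every state-action pair is updated by `alpha * elig * delta`, and all
#' eligibility traces are then decayed by `lam`.  After a first-stage choice
#' `r = 0` and `next_value` is the model-free value of the planet reached;
#' after a second-stage event `next_value = 0` (planets are terminal) and `r`
#' is the obtained reward.
#'
#' @param state An [init_agent_state()] object.
#' @param step List describing the transition: `stage` (1 or 2), `s` (the
#'   state acted in: first-stage state for stage 1, planet for stage 2), `a`
#'   (action, stage 1 only), `r` (immediate reward), `next_value`.
#' @param alpha,lam Learning rate and trace decay, both in `[0, 1]`.
#' @return The updated `agent_state`.
#' @export
mf_update <- function(state, step, alpha, lam) {
  stopifnot(inherits(state, "agent_state"),
            alpha >= 0, alpha <= 1, lam >= 0, lam <= 1)
  if (step$stage == 1L) {
    state$elig1[step$s, step$a] <- 1
    delta <- step$r + step$next_value - state$q1[step$s, step$a]
  } else {
    state$elig2[step$s] <- 1
    delta <- step$r + step$next_value - state$q2[step$s]
  }
  state$q1 <- state$q1 + alpha * state$elig1 * delta
  state$q2 <- state$q2 + alpha * state$elig2 * delta
  state$elig1 <- state$elig1 * lam
  state$elig2 <- state$elig2 * lam
  state
}

#' State-prediction-error update of the transition beliefs
#'
#' Moves the transition probability of the taken first-stage action toward
#' the observed planet by `eta * (1 - T)` (the state prediction error) and
#' rescales the complementary planet's probability by `1 - eta` so the pair
#' still sums to 1.  Because the two actions of a first-stage state always
#' lead to different planets, the not-chosen action is updated identically
#' toward the other planet with the counterfactual rate `eta_cf`.
#'
#' @param state An `agent_state`.
#' @param s1 First-stage state (1 or 2).
#' @param a1 Chosen action (1 or 2).
#' @param observed_planet Planet reached (1 = red, 2 = purple).
#' @param eta,eta_cf Factual and counterfactual transition learning rates in
#'   `[0, 1]`.
#' @return The updated `agent_state`.
#' @export
transition_update <- function(state, s1, a1, observed_planet, eta, eta_cf) {
  stopifnot(inherits(state, "agent_state"),
            eta >= 0, eta <= 1, eta_cf >= 0, eta_cf <= 1)
  # trans holds P(red | s1, a); P(purple) is its complement
  if (observed_planet == 1L) {
    state$trans[s1, a1] <- state$trans[s1, a1] +
      eta * (1 - state$trans[s1, a1])
  } else {
    state$trans[s1, a1] <- state$trans[s1, a1] * (1 - eta)
  }
  ao <- 3L - a1 # counterfactual action leads to the other planet
  if (observed_planet == 1L) {
    state$trans[s1, ao] <- state$trans[s1, ao] * (1 - eta_cf)
  } else {
    state$trans[s1, ao] <- state$trans[s1, ao] +
      eta_cf * (1 - state$trans[s1, ao])
  }
  state
}

#' Model-based first-stage values
#'
#' Plans by expectation: the model-based value of each first-stage action is
#' the transition-probability-weighted average of the two planets' current
#' model-free reward expectations (which double as the model-based values at
#' the second stage).
#'
#' @param state An `agent_state`.
#' @return A 2 x 2 matrix (rows = first-stage states, columns = actions).
#' @export
mb_first_stage_values <- function(state) {
  stopifnot(inherits(state, "agent_state"))
  state$trans * state$q2["red"] + (1 - state$trans) * state$q2["purple"]
}

#' First-stage choice probabilities of the hybrid learner
#'
#' Mixes model-free and model-based values with the condition cell's
#' model-based weight, adds the stickiness bonuses (`pi` for repeating the
#' previously chosen stimulus, `rho` for repeating the previously pressed
#' key), and maps the result through a softmax with inverse temperature
#' `beta`.
#'
#' @param state An `agent_state`.
#' @param s1 Current first-stage state (1 or 2).
#' @param cell Condition-cell name; must be a name of `params$omega`.
#' @param params A [model_params()] object.
#' @param a_left Which action is displayed on the left this trial (1 or 2);
#'   determines which key each action requires.
#' @return Named numeric vector `c(a1 = , a2 = )` of choice probabilities
#'   summing to 1.
#' @export
choice_probabilities <- function(state, s1, cell, params, a_left = 1L) {
  stopifnot(inherits(state, "agent_state"), inherits(params, "model_params"))
  if (!cell %in% names(params$omega)) {
    stop("unknown condition cell `", cell, "`", call. = FALSE)
  }
  w <- params$omega[[cell]]
  q_mb <- mb_first_stage_values(state)[s1, ]
  q <- (1 - w) * state$q1[s1, ] + w * q_mb
  rep_ind <- as.numeric(!is.na(state$prev_a) & !is.na(state$prev_s1) &
                          state$prev_s1 == s1 & state$prev_a == 1:2)
  key_of <- ifelse(1:2 == a_left, 1L, 2L)
  resp_ind <- as.numeric(!is.na(state$prev_key) & key_of == state$prev_key)
  v <- params$beta * (q + params$pi * rep_ind + params$rho * resp_ind)
  p <- exp(v - max(v))
  p <- p / sum(p)
  names(p) <- c("a1", "a2")
  p
}
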