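params_for_engine <- function(params) {
  list(alpha = params$alpha, lam = params$lam, eta = params$eta,
       eta_cf = params$eta_cf, beta = params$beta, pi = params$pi,
       rho = params$rho, omega = unname(params$omega))
}

# cell indices (1-based, in the order of layout$omega_cells) for a plan or
# behavior table
cell_index <- function(x, layout) {
  match(condition_cells(x, layout), layout$omega_cells)
}

#' Simulate a session of the hybrid learner
#'
#' Plays the task trial by trial: the first-stage action is sampled from
#' [choice_probabilities()], the transition is resolved from the plan's
#' current spaceship-to-planet map, the displayed reward is collected and
#' converted to points by the trial's stakes multiplier, and the transition
#' and model-free updates are applied.  Which stimulus appears on the left
#' (and therefore which key selects it) is randomized per trial.  Optionally,
#' missing responses are injected independently at each stage with the given
#' rate.  For the study-2 layout the agent knows the true (fixed) transition
#' map and performs no transition updates.
#'
#' @param params A [model_params()] whose `omega` names match the plan's
#'   layout cells.
#' @param plan A [generate_trial_plan()] object.
#' @param seed Integer seed; the same `(params, plan, seed)` reproduce the
#'   session exactly.
#' @param missing_rate Probability of a missing response at each stage
#'   (default 0).
#' @return A `behavior_table`: data frame with one row per trial and columns
#'   `trial`, `block`, `transition_condition`, `stakes`, `s1`, `a1`, `key1`
#'   (1 = left, 2 = right), `s2` (1 = red, 2 = purple), `reward`, `points`,
#'   `missing_stage1`, `missing_stage2`, plus the plan columns `map1`,
#'   `map2`, `reward_red`, `reward_purple` needed for replay and performance
#'   scoring.  The layout is attached as an attribute.
#' @export
#' @examples
#' plan <- generate_trial_plan(study_layout("study2"), 1, seed = 7)
#' p <- model_params(alpha = 0.5, omega = c(low = 0.3, high = 0.8), beta = 2)
#' b <- simulate_agent(p, plan, seed = 1)
#' head(b)
simulate_agent <- function(params, plan, seed, missing_rate = 0) {
  stopifnot(inherits(params, "model_params"), inherits(plan, "trial_plan"))
  layout <- attr(plan, "layout")
  if (!identical(sort(names(params$omega)), sort(layout$omega_cells))) {
    stop("`params$omega` cells do not match the plan's layout", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must be in [0, 1)", call. = FALSE)
  }
  # align omega order with the layout cells
  params$omega <- params$omega[layout$omega_cells]
  n <- nrow(plan)
  draws <- with_seed(seed, list(
    u_choice = stats::runif(n),
    u_miss1 = stats::runif(n),
    u_miss2 = stats::runif(n),
    a_left = sample(1:2, n, replace = TRUE)
  ))
  known <- layout$study_id == "study2"
  sim <- cpp_simulate(params_for_engine(params),
                      plan$s1, cell_index(plan, layout),
                      as.integer(plan$transition_condition == "stable"),
                      plan$map1, plan$map2,
                      plan$reward_red, plan$reward_purple,
                      draws$u_choice, draws$u_miss1, draws$u_miss2,
                      draws$a_left, missing_rate, known)
  mult <- layout$stakes_multipliers[plan$stakes]
  points <- ifelse(is.na(sim$reward), 0L, as.integer(sim$reward * mult))
  out <- data.frame(
    trial = plan$trial, block = plan$block,
    transition_condition = plan$transition_condition,
    stakes = plan$stakes, s1 = plan$s1,
    a1 = sim$a1, key1 = sim$key1, s2 = sim$s2,
    reward = sim$reward, points = points,
    missing_stage1 = sim$missing_stage1,
    missing_stage2 = sim$missing_stage2,
    map1 = plan$map1, map2 = plan$map2,
    reward_red = plan$reward_red, reward_purple = plan$reward_purple,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("behavior_table", "data.frame"),
            layout = layout, seed = seed,
            counterbalance_id = attr(plan, "counterbalance_id"))
}

#' Log-likelihood of a recorded session under the hybrid model
#'
#' Replays the learning updates along the recorded choices exactly as in
#' [simulate_agent()] and sums the log softmax probabilities of the observed
#' first-stage choices.  Trials with a missing first-stage response
#' contribute no likelihood term and no update (and reset the stickiness
#' indicators); trials with a missing second-stage response contribute the
#' first-stage term and the transition update but no reward update.
#'
#' @param params A [model_params()] matching the data's layout.
#' @param data A `behavior_table` (from [simulate_agent()] or read from CSV
#'   with [read_behavior()]).
#' @param details If `TRUE`, also return per-trial choice probabilities and
#'   the internal state trajectories.
#' @return The log-likelihood (a scalar), or a list when `details = TRUE`.
#' @export
log_likelihood <- function(params, data, details = FALSE) {
  stopifnot(inherits(params, "model_params"))
  if (nrow(data) == 0L) stop("`data` is empty", call. = FALSE)
  layout <- attr(data, "layout")
  if (is.null(layout)) stop("`data` has no layout attribute", call. = FALSE)
  core <- c(params$alpha, params$lam, params$eta, params$eta_cf,
            params$beta, params$pi, params$rho, params$omega)
  if (anyNA(core)) stop("parameters contain NA/NaN", call. = FALSE)
  if (!identical(sort(names(params$omega)), sort(layout$omega_cells))) {
    stop("`params$omega` cells do not match the data's layout", call. = FALSE)
  }
  params$omega <- params$omega[layout$omega_cells]
  known <- layout$study_id == "study2"
  enc <- function(x) {
    x <- as.integer(x)
    x[is.na(x)] <- 0L
    x
  }
  rew <- data$reward
  rew[is.na(rew)] <- -1
  res <- cpp_replay(params_for_engine(params),
                    data$s1, enc(data$a1), enc(data$key1), enc(data$s2),
                    as.numeric(rew), cell_index(data, layout),
                    as.integer(data$transition_condition == "stable"),
                    as.integer(data$missing_stage1),
                    as.integer(data$missing_stage2),
                    data$map1, data$map2, known, details)
  if (details) res else res$loglik
}

#' Write / read a behavior table as CSV
#'
#' @param data A `behavior_table`.
#' @param path File path.
#' @param layout Layout to attach when reading (defaults to study 1 when the
#'   file has 4 condition cells, study 2 otherwise).
#' @return `write_behavior` returns `path` invisibly; `read_behavior` a
#'   `behavior_table`.
#' @export
write_behavior <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path, layout = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(layout)) {
    layout <- if (any(df$transition_condition == "variable"))
      study_layout("study1") else study_layout("study2")
  }
  structure(df, class = c("behavior_table", "data.frame"), layout = layout)
}
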