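#' Task layout for the two-stage decision task
#'
#' Describes the session structure of the sequential decision-making task in
#' one of its two variants.  The `"study1"` layout has 320 trials in four
#' blocks of 80 with the transition condition (stable vs. variable spaceship
#' destinations) alternating across blocks; the `"study2"` layout has 280
#' trials with stable transitions throughout.  Rewards earned on a trial are
#' multiplied by 1 (low stakes) or 5 (high stakes) points per reward unit.
#'
#' @param study `"study1"` or `"study2"`.
#' @return An object of class `task_layout`: a list with fields `study_id`,
#'   `n_trials`, `block_length`, `n_blocks`, `transition_condition_per_block`
#'   (the reference ordering; counterbalancing may flip it),
#'   `stakes_multipliers`, and `omega_cells` (the condition cells that index
#'   the model-based weights).
#' @export
#' @examples
#' study_layout("study1")
study_layout <- function(study = c("study1", "study2")) {
  study <- match.arg(study)
  if (study == "study1") {
    structure(list(
      study_id = "study1",
      n_trials = 320L,
      block_length = 80L,
      n_blocks = 4L,
      transition_condition_per_block = c("stable", "variable",
                                         "stable", "variable"),
      stakes_multipliers = c(low = 1L, high = 5L),
      omega_cells = c("stable.low", "stable.high",
                      "variable.low", "variable.high"),
      n_counterbalance = 4L
    ), class = "task_layout")
  } else {
    structure(list(
      study_id = "study2",
      n_trials = 280L,
      block_length = 280L,
      n_blocks = 1L,
      transition_condition_per_block = "stable",
      stakes_multipliers = c(low = 1L, high = 5L),
      omega_cells = c("low", "high"),
      n_counterbalance = 2L
    ), class = "task_layout")
  }
}

#' @export
print.task_layout <- function(x, ...) {
  cat("Two-stage task layout <", x$study_id, ">: ", x$n_trials,
      " trials, ", x$n_blocks, " block(s) [",
      paste(x$transition_condition_per_block, collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

reflect_into <- function(v, lower, upper) {
  # fold excursions back into [lower, upper]; iterate for large jumps
  while (any(v < lower | v > upper)) {
    v <- ifelse(v > upper, 2 * upper - v, v)
    v <- ifelse(v < lower, 2 * lower - v, v)
  }
  v
}

#' Gaussian random reward walks with reflecting boundaries
#'
#' Generates the latent reward trajectories for the two planets: independent
#' Gaussian random walks (increment mean 0, standard deviation `sd`) with
#' reflecting boundaries at `lower` and `upper`.  The reward displayed (and
#' paid) on each trial is the latent value rounded to the nearest integer;
#' reflection acts on the continuous latent value.  Walk starting values are
#' drawn uniformly on `[lower, upper]` unless supplied.
#'
#' @param seed Integer seed; the same seed reproduces the walk bit for bit.
#' @param n_trials Number of trials (walk length), at least 1.
#' @param sd Standard deviation of the Gaussian increments (default 2).
#'   `sd = 0` gives a constant walk; negative values are an error.
#' @param lower,upper Reflecting boundaries (defaults 0 and 9).
#' @param start Optional starting latent value(s); length 1 (recycled) or 2.
#' @return An object of class `reward_walk`: list with `latent` and
#'   `displayed` (`n_trials` x 2 matrices with columns `red`, `purple`) and
#'   the `seed`.
#' @export
#' @examples
#' w <- generate_reward_walk(seed = 1, n_trials = 10)
#' w$displayed
generate_reward_walk <- function(seed, n_trials, sd = 2, lower = 0,
                                 upper = 9, start = NULL) {
  if (!is.numeric(n_trials) || n_trials < 1) {
    stop("`n_trials` must be at least 1", call. = FALSE)
  }
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0) {
    stop("`sd` must be a single non-negative number", call. = FALSE)
  }
  if (lower >= upper) stop("`lower` must be below `upper`", call. = FALSE)
  n_trials <- as.integer(n_trials)
  latent <- with_seed(seed, {
    x0 <- if (is.null(start)) stats::runif(2, lower, upper) else rep(start, length.out = 2)
    steps <- matrix(if (sd > 0) stats::rnorm(2L * (n_trials - 1L), 0, sd) else 0,
                    nrow = max(n_trials - 1L, 0L), ncol = 2L)
    out <- matrix(NA_real_, n_trials, 2L)
    out[1L, ] <- reflect_into(x0, lower, upper)
    if (n_trials > 1L) {
      for (t in 2:n_trials) {
        out[t, ] <- reflect_into(out[t - 1L, ] + steps[t - 1L, ], lower, upper)
      }
    }
    out
  })
  colnames(latent) <- c("red", "purple")
  displayed <- round(latent)
  storage.mode(displayed) <- "integer"
  structure(list(latent = latent, displayed = displayed, seed = seed),
            class = "reward_walk")
}

# Balanced vector of labels (half each), permuted under the current RNG.
balanced_labels <- function(n, labels) {
  stopifnot(n %% 2L == 0L)
  sample(rep(labels, each = n %/% 2L))
}

#' Generate a complete trial plan for a session
#'
#' Builds the experimenter-side schedule of a session: the reward walks and
#' first-stage-state sequence (shared across participants, i.e. they depend
#' only on `seed`), the stakes assignment and block-condition order (which
#' depend on `counterbalance_id`), the spaceship-to-planet transition map per
#' trial, and — in variable-transitions blocks — the swap schedule with
#' inter-swap gaps drawn uniformly from 6 to 14 trials and a uniformly chosen
#' spaceship pair per swap.
#'
#' Counterbalancing cells: for the `"study1"` layout, ids 1–4 encode
#' (block-condition order: stable-first / variable-first) x (stakes labels as
#' drawn / complemented); for `"study2"`, ids 1–2 encode the stakes flip only.
#'
#' @param layout A [study_layout()].
#' @param counterbalance_id Counterbalancing cell (see Details above).
#' @param seed Integer seed for the shared randomness.
#' @return An object of class `trial_plan`: a data frame with one row per
#'   trial and columns `trial`, `block`, `transition_condition`, `stakes`,
#'   `s1` (first-stage state, 1 or 2), `map1`, `map2` (planet that action 1
#'   leads to in states 1 and 2; 1 = red, 2 = purple; action 2 leads to the
#'   other planet), `reward_red`, `reward_purple` (displayed rewards).
#'   Attributes: `layout`, `counterbalance_id`, `seed`, `swap_trials` (data
#'   frame with `trial` and `pair`), `walk` (the [generate_reward_walk()]
#'   object).
#' @export
#' @examples
#' plan <- generate_trial_plan(study_layout("study2"), 1, seed = 42)
#' head(plan)
generate_trial_plan <- function(layout, counterbalance_id = 1L, seed = 1L) {
  stopifnot(inherits(layout, "task_layout"))
  n_cb <- layout$n_counterbalance
  if (!is.numeric(counterbalance_id) || length(counterbalance_id) != 1L ||
      !(counterbalance_id %in% seq_len(n_cb))) {
    stop("`counterbalance_id` must be one of 1..", n_cb, call. = FALSE)
  }
  counterbalance_id <- as.integer(counterbalance_id)
  n <- layout$n_trials
  bl <- layout$block_length

  walk <- generate_reward_walk(seed, n)
  shared <- with_seed(child_seed(seed, 1L), {
    s1 <- balanced_labels(n, c(1L, 2L))
    # stakes: balanced within every block, one draw shared across cells
    stakes <- unlist(lapply(seq_len(layout$n_blocks), function(b) {
      balanced_labels(bl, c("low", "high"))
    }))
    init_map <- sample(1:2, 2L, replace = TRUE)
    # swap-gap / pair reservoirs for up to n_blocks variable blocks
    gap_pool <- matrix(sample(6:14, layout$n_blocks * bl, replace = TRUE),
                       ncol = layout$n_blocks)
    pair_pool <- matrix(sample(1:2, layout$n_blocks * bl, replace = TRUE),
                        ncol = layout$n_blocks)
    list(s1 = s1, stakes = stakes, init_map = init_map,
         gap_pool = gap_pool, pair_pool = pair_pool)
  })

  # counterbalance: bit 1 flips the block-condition order (study1 only),
  # bit 2 complements the stakes labels
  flip_blocks <- layout$study_id == "study1" && counterbalance_id > 2L
  flip_stakes <- counterbalance_id %% 2L == 0L
  conds <- layout$transition_condition_per_block
  if (flip_blocks) conds <- rev(conds)
  stakes <- shared$stakes
  if (flip_stakes) stakes <- ifelse(stakes == "low", "high", "low")

  block <- rep(seq_len(layout$n_blocks), each = bl)
  cond_trial <- conds[block]

  # swap schedule: gaps counted within each variable block; a pending swap is
  # cancelled at the block boundary
  swap_trial <- integer(0)
  swap_pair <- integer(0)
  var_blocks <- which(conds == "variable")
  for (j in seq_along(var_blocks)) {
    b <- var_blocks[j]
    first <- (b - 1L) * bl + 1L
    pos <- first - 1L
    k <- 1L
    repeat {
      pos <- pos + shared$gap_pool[k, j]
      if (pos > b * bl) break
      swap_trial <- c(swap_trial, pos)
      swap_pair <- c(swap_pair, shared$pair_pool[k, j])
      k <- k + 1L
    }
  }

  map <- matrix(NA_integer_, n, 2L)
  cur <- shared$init_map
  for (t in seq_len(n)) {
    hit <- which(swap_trial == t)
    for (h in hit) {
      p <- swap_pair[h]
      cur[p] <- 3L - cur[p]
    }
    map[t, ] <- cur
  }

  plan <- data.frame(
    trial = seq_len(n),
    block = block,
    transition_condition = cond_trial,
    stakes = stakes,
    s1 = shared$s1,
    map1 = map[, 1L],
    map2 = map[, 2L],
    reward_red = walk$displayed[, "red"],
    reward_purple = walk$displayed[, "purple"],
    stringsAsFactors = FALSE
  )
  structure(plan,
            class = c("trial_plan", "data.frame"),
            layout = layout,
            counterbalance_id = counterbalance_id,
            seed = seed,
            swap_trials = data.frame(trial = swap_trial, pair = swap_pair),
            walk = walk)
}

#' Condition cell of each trial
#'
#' Maps each trial of a plan (or behavior table) to the condition cell that
#' indexes the model-based weight: `stable.low` / `stable.high` /
#' `variable.low` / `variable.high` for the study-1 layout, `low` / `high`
#' for study 2.
#'
#' @param x A `trial_plan` or `behavior_table` (any data frame with
#'   `transition_condition` and `stakes` columns).
#' @param layout The [study_layout()] the rows belong to.
#' @return Character vector of cell names, one per row.
#' @export
condition_cells <- function(x, layout = attr(x, "layout")) {
  stopifnot(inherits(layout, "task_layout"))
  if (layout$study_id == "study1") {
    paste(x$transition_condition, x$stakes, sep = ".")
  } else {
    x$stakes
  }
}

#' Write / read a trial plan as CSV
#'
#' The CSV has one row per trial with columns `trial`, `block`,
#' `transition_condition`, `stakes`, `first_stage_state`, `action0_dest`,
#' `action1_dest` (destination planets of the two actions available in the
#' trial's first-stage state), `reward_planet_red`, `reward_planet_purple`,
#' plus `map_state1` / `map_state2` so the full transition map round-trips.
#'
#' @param plan A `trial_plan`.
#' @param path File path.
#' @return `write_trial_plan` returns `path` invisibly; `read_trial_plan`
#'   returns a data frame (without the generator attributes).
#' @export
write_trial_plan <- function(plan, path) {
  stopifnot(inherits(plan, "trial_plan"))
  planet <- c("red", "purple")
  cur_map <- ifelse(plan$s1 == 1L, plan$map1, plan$map2)
  out <- data.frame(
    trial = plan$trial,
    block = plan$block,
    transition_condition = plan$transition_condition,
    stakes = plan$stakes,
    first_stage_state = plan$s1,
    action0_dest = planet[cur_map],
    action1_dest = planet[3L - cur_map],
    reward_planet_red = plan$reward_red,
    reward_planet_purple = plan$reward_purple,
    map_state1 = plan$map1,
    map_state2 = plan$map2
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_plan
#' @export
read_trial_plan <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
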