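#' Baseline-corrected task performance
#'
#' Scores each completed trial as the reward obtained (before any stakes
#' multiplication) minus the average of the rewards available at the two
#' planets on that trial — the excess reward over a uniformly random policy —
#' and averages within each condition cell.  Trials with a missing response
#' at either stage are excluded (no reward was obtained on those trials).
#'
#' @param data A `behavior_table`.
#' @param plan Optional [generate_trial_plan()] aligned with `data` by trial
#'   index; if omitted, the planet-reward columns carried in `data` are used.
#' @return An object of class `performance_summary`: data frame with one row
#'   per condition cell and columns `cell`, `mean_performance`, `n_trials`.
#' @export
#' @examples
#' plan <- generate_trial_plan(study_layout("study2"), 1, seed = 3)
#' p <- model_params(alpha = 0.5, omega = c(low = 1, high = 1), beta = 5)
#' task_performance(simulate_agent(p, plan, seed = 1))
task_performance <- function(data, plan = NULL) {
  layout <- attr(data, "layout")
  if (!is.null(plan)) {
    if (nrow(plan) != nrow(data)) {
      stop("`data` and `plan` have different numbers of trials",
           call. = FALSE)
    }
    rr <- plan$reward_red
    rp <- plan$reward_purple
  } else {
    if (is.null(data$reward_red)) {
      stop("`data` carries no planet rewards; supply `plan`", call. = FALSE)
    }
    rr <- data$reward_red
    rp <- data$reward_purple
  }
  valid <- data$missing_stage1 == 0L & data$missing_stage2 == 0L
  perf <- data$reward - (rr + rp) / 2
  cells <- condition_cells(data, layout)
  out <- do.call(rbind, lapply(layout$omega_cells, function(cl) {
    idx <- valid & cells == cl
    data.frame(cell = cl,
               mean_performance = mean(perf[idx]),
               n_trials = sum(idx),
               stringsAsFactors = FALSE)
  }))
  structure(out, class = c("performance_summary", "data.frame"))
}

#' Metacontrol index
#'
#' The metacontrol of decision making: the difference between the
#' model-based weight for high-stakes trials and the model-based weight for
#' low-stakes trials, computed per transition condition.  Positive values
#' mean the participant upregulated model-based control when more reward was
#' at stake.
#'
#' @param fit A `fit_result`, a [model_params()], or a named `omega` vector
#'   with one entry per condition cell.
#' @return Named numeric vector: `stable` and `variable` for the study-1
#'   cells, `overall` for study 2.  Values lie in `[-1, 1]`.
#' @export
#' @examples
#' metacontrol_index(c(stable.low = 0.3, stable.high = 0.7,
#'                     variable.low = 0.2, variable.high = 0.4))
metacontrol_index <- function(fit) {
  omega <- if (inherits(fit, "fit_result")) fit$params$omega
           else if (inherits(fit, "model_params")) fit$omega
           else fit
  nm <- names(omega)
  if (setequal(nm, c("low", "high"))) {
    return(c(overall = unname(omega[["high"]] - omega[["low"]])))
  }
  need <- c("stable.low", "stable.high", "variable.low", "variable.high")
  if (!all(need %in% nm)) {
    stop("`omega` is missing condition cells: ",
         paste(setdiff(need, nm), collapse = ", "), call. = FALSE)
  }
  c(stable = unname(omega[["stable.high"]] - omega[["stable.low"]]),
    variable = unname(omega[["variable.high"]] - omega[["variable.low"]]))
}
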