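nfc_scales <- list(
  german16 = list(range = c(-48, 48), mean = 14.63, sd = 13.48),
  english18 = list(range = c(18, 90), mean = 64.81, sd = 9.68)
)

#' Specification of a synthetic cohort
#'
#' Describes a cohort of simulated participants: the task layout, the
#' population distributions of the generating model parameters, the
#' distribution of the stakes effect on the model-based weight (the
#' generating metacontrol), the Need-for-Cognition (NFC) scale, and the
#' target population correlation between NFC and the generating metacontrol
#' index.
#'
#' The default parameter population: `alpha ~ Beta(3, 3)`,
#' `beta ~ Gamma(shape 4, scale 0.25)`, `pi, rho ~ Normal(0, 0.3)`,
#' `omega` in low-stakes cells `~ Beta(2, 3)`, and the high-stakes weight is
#' the low-stakes weight plus an effect `~ Normal(0.15, 0.15)`, clipped into
#' `[0, 1]`.  For the study-1 layout `lam ~ Beta(2, 2)` and
#' `eta = eta_cf = 1`; for study 2 `lam = 0` (the variants selected for each
#' study).  NFC totals are generated directly on the chosen scale
#' (`german16`: 16 items at -3..+3, totals in `[-48, 48]`; `english18`: 18
#' items at 1..5, totals in `[18, 90]`), matched to the observed means and
#' spreads of the respective student samples.
#'
#' @param n_participants Number of simulated participants.
#' @param layout A [study_layout()] (default study 2).
#' @param rho_nfc_metacontrol Target population correlation between NFC and
#'   the generating metacontrol index (default 0).
#' @param nfc_scale `"german16"` or `"english18"`; defaults to the scale
#'   used with the chosen layout.
#' @param effect_mean,effect_sd Mean and SD of the stakes effect on the
#'   model-based weight.
#' @param missing_rate Per-stage missing-response probability; defaults to
#'   the observed rates (0.01 for study 1, 0.03 for study 2).
#' @param param_pop Optional list of replacement sampler functions, each
#'   `function(n)` returning `n` draws, for any of `alpha`, `beta`, `lam`,
#'   `pi`, `rho`, `omega_low`, `effect`.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants, layout = study_layout("study2"),
                        rho_nfc_metacontrol = 0, nfc_scale = NULL,
                        effect_mean = 0.15, effect_sd = 0.15,
                        missing_rate = NULL, param_pop = list(),
                        seed = 1L) {
  stopifnot(inherits(layout, "task_layout"))
  if (n_participants < 1L) stop("need at least one participant",
                                call. = FALSE)
  if (abs(rho_nfc_metacontrol) >= 1) {
    stop("`rho_nfc_metacontrol` must be strictly inside (-1, 1)",
         call. = FALSE)
  }
  if (is.null(nfc_scale)) {
    nfc_scale <- if (layout$study_id == "study1") "german16" else "english18"
  }
  nfc_scale <- match.arg(nfc_scale, names(nfc_scales))
  if (is.null(missing_rate)) {
    missing_rate <- if (layout$study_id == "study1") 0.01 else 0.03
  }
  structure(list(
    n_participants = as.integer(n_participants), layout = layout,
    rho_nfc_metacontrol = rho_nfc_metacontrol, nfc_scale = nfc_scale,
    effect_mean = effect_mean, effect_sd = effect_sd,
    missing_rate = missing_rate, param_pop = param_pop, seed = seed
  ), class = "cohort_spec")
}

default_samplers <- function(spec) {
  pop <- list(
    alpha = function(n) stats::rbeta(n, 3, 3),
    beta = function(n) stats::rgamma(n, shape = 4, scale = 0.25),
    lam = if (spec$layout$study_id == "study1") {
      function(n) stats::rbeta(n, 2, 2)
    } else {
      function(n) rep(0, n)
    },
    pi = function(n) stats::rnorm(n, 0, 0.3),
    rho = function(n) stats::rnorm(n, 0, 0.3),
    omega_low = function(n) stats::rbeta(n, 2, 3),
    effect = function(n) stats::rnorm(n, spec$effect_mean, spec$effect_sd)
  )
  utils::modifyList(pop, spec$param_pop)
}

# continuous scores with exact sample correlation `rho` to the anchor vector
correlated_scores <- function(anchor, rho) {
  if (stats::sd(anchor) == 0 && rho != 0) {
    stop("anchor variable has zero variance; a nonzero target correlation ",
         "is infeasible", call. = FALSE)
  }
  g <- stats::rnorm(length(anchor))
  ac <- anchor - mean(anchor)
  gc <- g - mean(g)
  if (stats::sd(anchor) == 0) return(gc / stats::sd(gc))
  e <- gc - ac * sum(ac * gc) / sum(ac * ac)
  z <- rho * ac / stats::sd(ac) + sqrt(1 - rho^2) * e / stats::sd(e)
  z / stats::sd(z)
}

#' Generate a synthetic cohort
#'
#' Draws per-participant generating parameters from the population described
#' by the spec, builds NFC scores whose sample correlation with the
#' generating metacontrol index equals `rho_nfc_metacontrol` exactly (on the
#' continuous scale; integer totals are the rounded, range-clipped version),
#' and simulates each participant's session on a counterbalanced trial plan.
#' Everything is reproducible from the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: list with `spec`,
#'   `participants` (each with `id`, `counterbalance_id`, `params`,
#'   `behavior`, `nfc_score`, `nfc_total`), and the generating vectors
#'   `metacontrol_true` (mean index per participant) and `nfc_score`.
#' @export
#' @examples
#' spec <- cohort_spec(5, study_layout("study2"), seed = 11)
#' cohort <- generate_cohort(spec)
#' length(cohort$participants)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  layout <- spec$layout
  n <- spec$n_participants
  pop <- default_samplers(spec)
  sc <- nfc_scales[[spec$nfc_scale]]

  drawn <- with_seed(child_seed(spec$seed, 1L), {
    n_low <- if (layout$study_id == "study1") 2L else 1L
    params <- lapply(seq_len(n), function(i) {
      w_low <- pop$omega_low(n_low)
      eff <- pop$effect(n_low)
      w_high <- pmin(pmax(w_low + eff, 0), 1)
      omega <- if (layout$study_id == "study1") {
        c(stable.low = w_low[1L], stable.high = w_high[1L],
          variable.low = w_low[2L], variable.high = w_high[2L])
      } else {
        c(low = w_low, high = w_high)
      }
      model_params(alpha = pop$alpha(1L), omega = omega,
                   beta = pop$beta(1L), lam = pop$lam(1L),
                   eta = 1, eta_cf = 1,
                   pi = pop$pi(1L), rho = pop$rho(1L))
    })
    mc <- vapply(params, function(p) mean(metacontrol_index(p)), numeric(1))
    z <- correlated_scores(mc, spec$rho_nfc_metacontrol)
    list(params = params, mc = mc, z = z)
  })

  nfc_score <- sc$mean + sc$sd * drawn$z
  nfc_total <- as.integer(pmin(pmax(round(nfc_score), sc$range[1L]),
                               sc$range[2L]))

  participants <- lapply(seq_len(n), function(i) {
    cb <- ((i - 1L) %% layout$n_counterbalance) + 1L
    plan <- generate_trial_plan(layout, cb, spec$seed)
    beh <- simulate_agent(drawn$params[[i]], plan,
                          seed = child_seed(spec$seed, 100L + i),
                          missing_rate = spec$missing_rate)
    list(id = i, counterbalance_id = cb, params = drawn$params[[i]],
         behavior = beh, nfc_score = nfc_score[i], nfc_total = nfc_total[i])
  })

  structure(list(spec = spec, participants = participants,
                 metacontrol_true = drawn$mc, nfc_score = nfc_score,
                 nfc_total = nfc_total),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", length(x$participants), " participants, layout ",
      x$spec$layout$study_id, ", NFC scale ", x$spec$nfc_scale,
      ", target rho(NFC, metacontrol) = ", x$spec$rho_nfc_metacontrol,
      "\n", sep = "")
  invisible(x)
}

#' Participant exclusion rules
#'
#' Applies the preregistration-style exclusion rules to a cohort: removes
#' participants with missing responses (at either stage) in strictly more
#' than `max_missing_fraction` of trials, and optionally those repeating the
#' same response key in strictly more than `max_key_repeat_fraction` of
#' consecutive completed trials.
#'
#' @param cohort A [generate_cohort()] object.
#' @param max_missing_fraction Missing-trial threshold (default 0.20).
#' @param max_key_repeat_fraction Optional key-repetition threshold (e.g.
#'   0.95); `NULL` disables the check.
#' @return List with `retained` (a `synthetic_cohort`) and `log` (data frame
#'   with per-participant fractions, the `excluded` flag and the reason).
#' @export
exclusion_filter <- function(cohort, max_missing_fraction = 0.20,
                             max_key_repeat_fraction = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (length(cohort$participants) == 0L) {
    stop("`cohort` is empty", call. = FALSE)
  }
  log <- do.call(rbind, lapply(cohort$participants, function(pp) {
    b <- pp$behavior
    miss <- mean(b$missing_stage1 == 1L | b$missing_stage2 == 1L)
    keys <- b$key1[b$missing_stage1 == 0L]
    rep_frac <- if (length(keys) > 1L) {
      mean(keys[-1L] == keys[-length(keys)])
    } else 0
    reason <- character(0)
    if (miss > max_missing_fraction) reason <- c(reason, "missing_responses")
    if (!is.null(max_key_repeat_fraction) &&
        rep_frac > max_key_repeat_fraction) {
      reason <- c(reason, "key_repetitions")
    }
    data.frame(id = pp$id, missing_fraction = miss,
               key_repeat_fraction = rep_frac,
               excluded = length(reason) > 0L,
               reason = paste(reason, collapse = "+"),
               stringsAsFactors = FALSE)
  }))
  keep <- !log$excluded
  retained <- cohort
  retained$participants <- cohort$participants[keep]
  retained$metacontrol_true <- cohort$metacontrol_true[keep]
  retained$nfc_score <- cohort$nfc_score[keep]
  retained$nfc_total <- cohort$nfc_total[keep]
  list(retained = retained, log = log)
}
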