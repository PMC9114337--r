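#' Prior specification for MAP estimation
#'
#' The default priors used for maximum a posteriori fitting: `Beta(2, 2)` on
#' every `[0, 1]`-bounded parameter (`alpha`, `lam`, `eta`, `eta_cf` and each
#' model-based weight `omega`), standard normal priors on the stickiness
#' parameters `pi` and `rho`, and a `Gamma(shape = 3, scale = 0.2)` prior
#' (mode 0.4) on the inverse temperature `beta`.
#'
#' @return An object of class `prior_spec` with functions `log_density(name,
#'   value)` and `sample(name)`; `name` is one of `alpha`, `lam`, `eta`,
#'   `eta_cf`, `omega`, `pi`, `rho`, `beta`.
#' @export
#' @examples
#' pr <- prior_spec()
#' pr$log_density("omega", 0.5) # log(1.5), the Beta(2,2) mode density
prior_spec <- function() {
  fam <- function(name) {
    if (name %in% c("alpha", "lam", "eta", "eta_cf", "omega")) "beta22"
    else if (name %in% c("pi", "rho")) "norm01"
    else if (name == "beta") "gamma"
    else stop("unknown parameter `", name, "`", call. = FALSE)
  }
  structure(list(
    log_density = function(name, value) {
      switch(fam(name),
        beta22 = stats::dbeta(value, 2, 2, log = TRUE),
        norm01 = stats::dnorm(value, 0, 1, log = TRUE),
        gamma  = stats::dgamma(value, shape = 3, scale = 0.2, log = TRUE))
    },
    sample = function(name, n = 1L) {
      switch(fam(name),
        beta22 = stats::rbeta(n, 2, 2),
        norm01 = stats::rnorm(n, 0, 1),
        gamma  = stats::rgamma(n, shape = 3, scale = 0.2))
    }
  ), class = "prior_spec")
}

#' Model variants for fitting
#'
#' A model variant fixes some of `lam`, `eta`, `eta_cf`, `pi`, `rho` and
#' frees the rest; `alpha`, `beta` and all condition-cell model-based weights
#' are always free.  `variant_study1()` is the variant selected by AIC for
#' the study-1 layout (free `lam`, `pi`, `rho`; `eta = eta_cf = 1`, which in
#' any case only act in variable-transitions blocks since stable blocks
#' always use rate 1).  `variant_study2()` is the study-2 selection (free
#' `pi`, `rho`; `lam = 0`), with the transition map known and not updated.
#'
#' @param layout A [study_layout()].
#' @param free Character vector, subset of
#'   `c("lam", "eta", "eta_cf", "pi", "rho")`.
#' @param fixed Named numeric vector of values for the complement.
#' @param name Variant label used in AIC tables.
#' @return An object of class `model_variant`.
#' @export
#' @examples
#' variant_study2()
model_variant <- function(layout, free, fixed = numeric(0),
                          name = paste(free, collapse = "+")) {
  stopifnot(inherits(layout, "task_layout"))
  core <- c("lam", "eta", "eta_cf", "pi", "rho")
  if (!all(free %in% core)) stop("unknown free parameter", call. = FALSE)
  known <- layout$study_id == "study2"
  if (known) {
    # no transition learning in the study-2 model
    free <- setdiff(free, c("eta", "eta_cf"))
    fixed <- fixed[setdiff(names(fixed), c("eta", "eta_cf"))]
    fixed <- c(fixed, eta = 1, eta_cf = 1)
  }
  need_fixed <- setdiff(core, c(free, names(fixed)))
  defaults <- c(lam = 0, eta = 1, eta_cf = 1, pi = 0, rho = 0)
  fixed <- c(fixed, defaults[need_fixed])
  structure(list(
    name = name,
    layout = layout,
    free_core = free,
    fixed_values = fixed[setdiff(core, free)],
    known_transitions = known,
    omega_cells = layout$omega_cells
  ), class = "model_variant")
}

#' @rdname model_variant
#' @export
variant_study1 <- function() {
  model_variant(study_layout("study1"), free = c("lam", "pi", "rho"),
                fixed = c(eta = 1, eta_cf = 1), name = "lam+pi+rho")
}

#' @rdname model_variant
#' @export
variant_study2 <- function() {
  model_variant(study_layout("study2"), free = c("pi", "rho"),
                fixed = c(lam = 0), name = "pi+rho")
}

n_free_params <- function(variant) {
  2L + length(variant$omega_cells) + length(variant$free_core)
}

free_param_names <- function(variant) {
  c("alpha", "beta", paste0("omega.", variant$omega_cells),
    variant$free_core)
}

# base name of a (possibly omega.<cell>) free-parameter label
base_name <- function(nm) ifelse(startsWith(nm, "omega."), "omega", nm)

# ---- transform between the natural scale and the unconstrained scale ----

is_unit <- function(nm) base_name(nm) %in% c("alpha", "lam", "eta", "eta_cf",
                                             "omega")

to_unconstrained <- function(x, nm) {
  b <- base_name(nm)
  if (is_unit(nm)) stats::qlogis(pmin(pmax(x, 1e-12), 1 - 1e-12))
  else if (b == "beta") log(pmax(x, 1e-12))
  else x
}

from_unconstrained <- function(z, nm) {
  b <- base_name(nm)
  if (is_unit(nm)) stats::plogis(z)
  else if (b == "beta") exp(z)
  else z
}

params_from_free <- function(theta_nat, variant) {
  fx <- variant$fixed_values
  getf <- function(nm) if (nm %in% names(theta_nat)) theta_nat[[nm]] else fx[[nm]]
  omega <- theta_nat[paste0("omega.", variant$omega_cells)]
  names(omega) <- variant$omega_cells
  model_params(alpha = theta_nat[["alpha"]], omega = omega,
               beta = theta_nat[["beta"]],
               lam = getf("lam"), eta = getf("eta"), eta_cf = getf("eta_cf"),
               pi = getf("pi"), rho = getf("rho"))
}

free_from_params <- function(params, variant) {
  nm <- free_param_names(variant)
  vals <- vapply(nm, function(x) {
    if (startsWith(x, "omega.")) params$omega[[sub("^omega\\.", "", x)]]
    else params[[x]]
  }, numeric(1))
  names(vals) <- nm
  vals
}

#' Log posterior of the hybrid model
#'
#' Sum of the session [log_likelihood()] and the log prior densities of the
#' variant's free parameters (priors evaluated on the natural scale).
#' Parameters outside their support yield `-Inf` with a warning.
#'
#' @param params A [model_params()] respecting the variant's fixed values.
#' @param data A `behavior_table`.
#' @param priors A [prior_spec()].
#' @param variant A [model_variant()].
#' @return The log posterior (a scalar).
#' @export
log_posterior <- function(params, data, priors = prior_spec(),
                          variant) {
  stopifnot(inherits(variant, "model_variant"))
  free <- free_from_params(params, variant)
  lp <- sum(vapply(names(free), function(nm) {
    priors$log_density(base_name(nm), free[[nm]])
  }, numeric(1)))
  if (!is.finite(lp)) {
    warning("parameters outside the prior support; log posterior is -Inf",
            call. = FALSE)
    return(-Inf)
  }
  lp + log_likelihood(params, data)
}

draw_start <- function(priors, variant) {
  nm <- free_param_names(variant)
  vals <- vapply(nm, function(x) priors$sample(base_name(x)), numeric(1))
  names(vals) <- nm
  vals
}

# Pre-encode a behavior table into the integer vectors the C++ engine takes,
# so the optimizer's objective avoids per-call conversion overhead.
encode_behavior <- function(data, layout) {
  enc <- function(x) {
    x <- as.integer(x)
    x[is.na(x)] <- 0L
    x
  }
  rew <- data$reward
  rew[is.na(rew)] <- -1
  list(s1 = data$s1, a1 = enc(data$a1), key1 = enc(data$key1),
       s2 = enc(data$s2), reward = as.numeric(rew),
       cell = cell_index(data, layout),
       stable = as.integer(data$transition_condition == "stable"),
       miss1 = as.integer(data$missing_stage1),
       miss2 = as.integer(data$missing_stage2),
       map1 = data$map1, map2 = data$map2,
       known = layout$study_id == "study2")
}

loglik_encoded <- function(par, enc) {
  cpp_replay(par, enc$s1, enc$a1, enc$key1, enc$s2, enc$reward, enc$cell,
             enc$stable, enc$miss1, enc$miss2, enc$map1, enc$map2,
             enc$known, FALSE)$loglik
}

#' Maximum a posteriori fit of one session
#'
#' Optimizes the [log_posterior()] over the variant's free parameters from
#' `n_starts` starting points drawn from the priors, and returns the best
#' converged run.  Bounded parameters are optimized on logit (and `beta` on
#' log) scales so the estimates stay strictly inside their bounds; priors are
#' evaluated on the natural scale, so the result is the MAP in natural
#' coordinates.  Exact posterior ties between starts are broken by the
#' lexicographically smallest free-parameter vector.
#'
#' @param data A `behavior_table` for one participant.
#' @param variant A [model_variant()] (defaults to the layout's selected
#'   variant).
#' @param priors A [prior_spec()].
#' @param n_starts Number of random restarts (default 100).
#' @param seed Integer seed making the whole fit deterministic.
#' @return An object of class `fit_result`: list with `params`
#'   ([model_params()] at the MAP), `log_posterior`, `log_likelihood`,
#'   `n_free_params`, `aic` (`2 k - 2 logLik` at the MAP), `n_starts_converged`
#'   and `best_start_index`.
#' @export
fit_map <- function(data, variant = NULL, priors = prior_spec(),
                    n_starts = 100L, seed = 1L) {
  if (nrow(data) == 0L) stop("`data` is empty", call. = FALSE)
  if (n_starts < 1L) stop("`n_starts` must be >= 1", call. = FALSE)
  layout <- attr(data, "layout")
  if (is.null(variant)) {
    variant <- if (layout$study_id == "study1") variant_study1()
               else variant_study2()
  }
  stopifnot(inherits(variant, "model_variant"))
  nm <- free_param_names(variant)
  enc <- encode_behavior(data, layout)
  k_cells <- length(variant$omega_cells)
  is_u <- vapply(nm, is_unit, logical(1))       # logit-scale parameters
  is_b <- base_name(nm) == "beta"               # log-scale
  fx <- variant$fixed_values
  core_free <- variant$free_core
  get_core <- function(nat, which) {
    if (which %in% core_free) nat[[which]] else fx[[which]]
  }

  engine_par <- function(nat) {
    list(alpha = nat[[1L]], lam = get_core(nat, "lam"),
         eta = get_core(nat, "eta"), eta_cf = get_core(nat, "eta_cf"),
         beta = nat[[2L]], pi = get_core(nat, "pi"),
         rho = get_core(nat, "rho"),
         omega = unname(nat[2L + seq_len(k_cells)]))
  }
  bn <- base_name(nm)
  log_prior_vec <- function(nat) {
    sum(vapply(seq_along(nat), function(j) {
      priors$log_density(bn[j], nat[[j]])
    }, numeric(1)))
  }

  neg_obj <- function(z) {
    nat <- z
    nat[is_u] <- stats::plogis(z[is_u])
    nat[is_b] <- exp(z[is_b])
    lp <- log_prior_vec(nat)
    if (!is.finite(lp)) return(1e10)
    v <- lp + loglik_encoded(engine_par(nat), enc)
    if (!is.finite(v)) 1e10 else -v
  }

  starts <- with_seed(seed, lapply(seq_len(n_starts), function(i) {
    draw_start(priors, variant)
  }))

  best <- NULL
  n_conv <- 0L
  fails <- character(0)
  for (i in seq_len(n_starts)) {
    z0 <- mapply(to_unconstrained, starts[[i]], nm)
    res <- tryCatch(
      stats::optim(z0, neg_obj, method = "BFGS",
                   control = list(maxit = 500L, reltol = 1e-6)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      fails <- c(fails, conditionMessage(res))
      next
    }
    if (res$convergence == 0L) n_conv <- n_conv + 1L
    nat <- mapply(from_unconstrained, res$par, nm)
    names(nat) <- nm
    cand <- list(lp = -res$value, nat = nat, index = i)
    if (is.null(best) || cand$lp > best$lp ||
        (cand$lp == best$lp && lex_less(cand$nat, best$nat))) {
      best <- cand
    }
  }
  if (is.null(best)) {
    stop("all ", n_starts, " optimization starts failed: ",
         paste(unique(fails), collapse = "; "), call. = FALSE)
  }
  params <- params_from_free(best$nat, variant)
  ll <- log_likelihood(params, data)
  k <- n_free_params(variant)
  structure(list(
    params = params,
    log_posterior = best$lp,
    log_likelihood = ll,
    n_free_params = k,
    aic = 2 * k - 2 * ll,
    n_starts_converged = n_conv,
    best_start_index = best$index,
    variant = variant$name
  ), class = "fit_result")
}

lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0L && a[d[1L]] < b[d[1L]]
}

#' @export
print.fit_result <- function(x, ...) {
  cat("MAP fit (variant ", x$variant, "): logLik = ",
      round(x$log_likelihood, 2), ", log posterior = ",
      round(x$log_posterior, 2), ", AIC = ", round(x$aic, 2),
      " (k = ", x$n_free_params, ")\n", sep = "")
  print(x$params)
  invisible(x)
}

#' Group-level AIC model comparison
#'
#' Sums each variant's per-participant AICs and selects the variant with the
#' smallest total.  All variants must have been fitted on the same
#' participants (same number and order of fits).
#'
#' @param fits Named list: one entry per variant, each a list of
#'   `fit_result` objects over the same participants.
#' @return List with `selected` (variant name), and `table` (data frame with
#'   per-variant `n_participants`, `n_free_params` and `total_aic`).
#' @export
compare_models_aic <- function(fits) {
  if (length(fits) < 1L || is.null(names(fits))) {
    stop("`fits` must be a named list of per-variant fit lists",
         call. = FALSE)
  }
  sizes <- vapply(fits, length, integer(1))
  if (length(unique(sizes)) != 1L) {
    stop("variants were fitted on different participant sets", call. = FALSE)
  }
  tab <- data.frame(
    variant = names(fits),
    n_participants = sizes,
    n_free_params = vapply(fits, function(f) f[[1L]]$n_free_params,
                           integer(1)),
    total_aic = vapply(fits, function(f) {
      sum(vapply(f, function(x) x$aic, numeric(1)))
    }, numeric(1)),
    row.names = NULL
  )
  list(selected = tab$variant[which.min(tab$total_aic)], table = tab)
}

#' Parameter-recovery study
#'
#' Simulates a session for every generating parameter vector, fits each
#' session by [fit_map()], and summarizes how well the generating parameters
#' are recovered: per-parameter Pearson and Spearman correlations between
#' generating and recovered values, mean signed bias, and RMSE.  The
#' metacontrol index (difference of model-based weights between high- and
#' low-stakes cells) is summarized alongside the raw parameters.
#'
#' @param generating_cohort List of [model_params()] for the simulated
#'   participants.
#' @param layout A [study_layout()].
#' @param seed Integer seed for plans, simulation and fitting.
#' @param n_starts Restarts per fit (default 20).
#' @param variant Fitting variant (defaults to the layout's selection).
#' @param missing_rate Per-stage missing-response rate for the simulations.
#' @return List with `estimates` (data frame of generating vs. recovered
#'   values per participant and parameter) and `summary` (per-parameter
#'   `pearson`, `spearman`, `bias`, `rmse`).  Fit failures are recorded and
#'   skipped, not fatal.
#' @export
parameter_recovery <- function(generating_cohort, layout, seed = 1L,
                               n_starts = 20L, variant = NULL,
                               missing_rate = 0) {
  if (length(generating_cohort) == 0L) {
    stop("`generating_cohort` is empty", call. = FALSE)
  }
  if (is.null(variant)) {
    variant <- if (layout$study_id == "study1") variant_study1()
               else variant_study2()
  }
  rows <- list()
  failures <- character(0)
  for (i in seq_along(generating_cohort)) {
    p_true <- generating_cohort[[i]]
    cb <- ((i - 1L) %% layout$n_counterbalance) + 1L
    plan <- generate_trial_plan(layout, cb, seed)
    beh <- simulate_agent(p_true, plan, seed = child_seed(seed, i),
                          missing_rate = missing_rate)
    fit <- tryCatch(
      fit_map(beh, variant = variant, n_starts = n_starts,
              seed = child_seed(seed, 10000L + i)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      failures <- c(failures, paste0("participant ", i, ": ",
                                     conditionMessage(fit)))
      next
    }
    tv <- free_from_params(p_true, variant)
    rv <- free_from_params(fit$params, variant)
    mc_t <- metacontrol_index(p_true)
    mc_r <- metacontrol_index(fit$params)
    rows[[length(rows) + 1L]] <- data.frame(
      id = i,
      parameter = c(names(tv), paste0("metacontrol.", names(mc_t))),
      generating = c(unname(tv), unname(mc_t)),
      recovered = c(unname(rv), unname(mc_r)),
      stringsAsFactors = FALSE
    )
  }
  est <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(est, est$parameter), function(d) {
    data.frame(
      parameter = d$parameter[1L],
      pearson = if (stats::sd(d$generating) > 0 && stats::sd(d$recovered) > 0)
        stats::cor(d$generating, d$recovered) else NA_real_,
      spearman = if (stats::sd(d$generating) > 0 && stats::sd(d$recovered) > 0)
        stats::cor(d$generating, d$recovered, method = "spearman")
        else NA_real_,
      bias = mean(d$recovered - d$generating),
      rmse = sqrt(mean((d$recovered - d$generating)^2)),
      stringsAsFactors = FALSE
    )
  }))
  row.names(summ) <- NULL
  list(estimates = est, summary = summ, failures = failures)
}
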