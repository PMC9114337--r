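#' Default pipeline configuration
#'
#' @param n_participants Cohort size.
#' @param layout `"study1"` or `"study2"` (or a [study_layout()]).
#' @param rho_nfc_metacontrol Generating NFC-metacontrol correlation.
#' @param n_starts Optimization restarts per participant fit.
#' @param kappa Stretched-beta prior scale for the correlation Bayes
#'   factors.
#' @param robustness_kappas Grid for the prior-robustness check.
#' @param power Optional list with `reps`, `grid` and `side` to also run the
#'   design analysis; `NULL` skips it.
#' @param seed Global seed; every stage seed is derived from it.
#' @param out_dir Optional output directory for persisted artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_participants = 126L, layout = "study2",
                            rho_nfc_metacontrol = 0, n_starts = 10L,
                            kappa = 1, robustness_kappas = c(0.01, 0.1,
                                                             0.25, 0.5, 1),
                            power = NULL, seed = 1L, out_dir = NULL) {
  if (is.character(layout)) layout <- study_layout(layout)
  cfg <- list(n_participants = n_participants, layout = layout,
              rho_nfc_metacontrol = rho_nfc_metacontrol,
              n_starts = n_starts, kappa = kappa,
              robustness_kappas = robustness_kappas, power = power,
              seed = seed, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

validate_config <- function(config) {
  if (config$n_starts < 1L) {
    stop("`n_starts` must be >= 1", call. = FALSE)
  }
  if (config$n_participants < 4L) {
    stop("need at least 4 participants for correlation tests",
         call. = FALSE)
  }
  if (config$kappa <= 0 || config$kappa > 1) {
    stop("`kappa` must be in (0, 1]", call. = FALSE)
  }
  invisible(config)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes, in order: synthetic-cohort generation, participant exclusion,
#' per-participant MAP fitting, metacontrol and task-performance summaries,
#' the correlation Bayes-factor analyses relating NFC to metacontrol,
#' model-based weights, and the stakes-related performance increase,
#' the prior-robustness check, and (optionally) the Monte-Carlo design
#' analysis.  All randomness derives from `config$seed`, so a rerun with the
#' same configuration reproduces the results exactly.
#'
#' @param config A [pipeline_config()] or the path to a YAML file.
#' @return A results list (also written as `results.json`, `summary.txt` and
#'   `fits.csv` when `config$out_dir` is set): per-analysis `r`, `n`, `bf10`
#'   and evidence label; mean performance per condition cell; fitted
#'   parameter table; exclusion log; optional power thresholds.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  layout <- config$layout

  stage <- "cohort"
  res <- tryCatch({
    spec <- cohort_spec(config$n_participants, layout,
                        rho_nfc_metacontrol = config$rho_nfc_metacontrol,
                        seed = child_seed(config$seed, 1L))
    cohort <- generate_cohort(spec)

    stage <- "exclusion"
    excl <- exclusion_filter(cohort,
                             max_key_repeat_fraction =
                               if (layout$study_id == "study2") 0.95 else NULL)
    kept <- excl$retained

    stage <- "fitting"
    fits <- lapply(seq_along(kept$participants), function(i) {
      fit_map(kept$participants[[i]]$behavior,
              n_starts = config$n_starts,
              seed = child_seed(config$seed, 200L + i))
    })

    stage <- "metrics"
    proto <- metacontrol_index(fits[[1L]])
    mcv <- vapply(fits, metacontrol_index, proto)
    mc <- if (is.null(dim(mcv))) {
      matrix(mcv, ncol = 1L, dimnames = list(NULL, names(proto)))
    } else {
      t(mcv)
    }
    mc_mean <- rowMeans(mc)
    omegas <- t(vapply(fits, function(f) f$params$omega,
                       fits[[1L]]$params$omega))
    perf <- lapply(kept$participants,
                   function(pp) task_performance(pp$behavior))
    perf_wide <- t(vapply(perf, function(p) {
      stats::setNames(p$mean_performance, p$cell)
    }, stats::setNames(numeric(length(layout$omega_cells)),
                       layout$omega_cells)))
    nfc <- kept$nfc_total

    stage <- "bayes"
    n_eff <- length(nfc)
    cfg2 <- bayes_config(kappa = config$kappa)
    cfg_neg <- bayes_config(kappa = config$kappa, side = "negative")
    cor_bf <- function(y, cfgb) {
      r <- stats::cor(nfc, y)
      bf <- bf_correlation(r, n_eff, cfgb)
      list(r = r, n = n_eff, bf10 = bf$bf10, label = bf$evidence_label,
           side = cfgb$side, kappa = cfgb$kappa)
    }
    low_cells <- grep("low$", layout$omega_cells, value = TRUE)
    high_cells <- grep("high$", layout$omega_cells, value = TRUE)
    perf_increase <- rowMeans(perf_wide[, high_cells, drop = FALSE]) -
      rowMeans(perf_wide[, low_cells, drop = FALSE])
    analyses <- list(
      nfc_metacontrol = cor_bf(mc_mean, cfg2),
      nfc_metacontrol_negative = cor_bf(mc_mean, cfg_neg),
      nfc_omega_low = cor_bf(rowMeans(omegas[, low_cells, drop = FALSE]),
                             cfg2),
      nfc_omega_high = cor_bf(rowMeans(omegas[, high_cells, drop = FALSE]),
                              cfg2),
      nfc_performance_increase = cor_bf(perf_increase, cfg2)
    )
    robustness <- bf_robustness(analyses$nfc_metacontrol$r, n_eff,
                                kappa_grid = config$robustness_kappas)

    stage <- "power"
    power <- NULL
    if (!is.null(config$power)) {
      pw <- config$power
      curve <- power_curve(pw$grid %||% seq(0, 0.5, by = 0.01), n = n_eff,
                           reps = pw$reps %||% 1000L,
                           config = bayes_config(kappa = config$kappa,
                                                 side = pw$side %||%
                                                   "two_sided"),
                           seed = child_seed(config$seed, 900L))
      power <- list(
        curve = as.data.frame(curve),
        threshold_alt = threshold_for_power(curve, "alt")$rho,
        threshold_null = threshold_for_power(curve, "null")$rho
      )
    }

    list(
      schema_version = "1.0",
      layout = layout$study_id,
      seed = config$seed,
      n_generated = config$n_participants,
      n_retained = n_eff,
      exclusions = excl$log,
      analyses = analyses,
      robustness = robustness,
      mean_performance = colMeans(perf_wide),
      mean_metacontrol = colMeans(mc),
      fits = data.frame(id = vapply(kept$participants, function(p) p$id,
                                    integer(1)),
                        nfc_total = nfc,
                        metacontrol = mc_mean,
                        omegas,
                        aic = vapply(fits, function(f) f$aic, numeric(1)),
                        log_likelihood = vapply(fits,
                                                function(f) f$log_likelihood,
                                                numeric(1))),
      power = power
    )
  }, error = function(e) {
    stop("pipeline failed at stage `", stage, "`: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      res[setdiff(names(res), "fits")],
      file.path(config$out_dir, "results.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns"
    )
    utils::write.csv(res$fits, file.path(config$out_dir, "fits.csv"),
                     row.names = FALSE)
    writeLines(pipeline_summary_text(res),
               file.path(config$out_dir, "summary.txt"))
  }
  res
}

pipeline_summary_text <- function(res) {
  lines <- c(
    sprintf("Pipeline results (layout %s, seed %d)", res$layout, res$seed),
    sprintf("Participants: %d generated, %d retained", res$n_generated,
            res$n_retained),
    "",
    "Bayes factors (NFC correlations):"
  )
  for (nm in names(res$analyses)) {
    a <- res$analyses[[nm]]
    lines <- c(lines, sprintf("  %-26s r = %+.2f  BF10 = %.2f  [%s]",
                              nm, a$r, a$bf10, a$label))
  }
  lines <- c(lines, "",
             paste0("Mean metacontrol: ",
                    paste(names(res$mean_metacontrol), "=",
                          sprintf("%.3f", res$mean_metacontrol),
                          collapse = ", ")),
             paste0("Mean performance: ",
                    paste(names(res$mean_performance), "=",
                          sprintf("%.3f", res$mean_performance),
                          collapse = ", ")))
  if (!is.null(res$power)) {
    lines <- c(lines, "",
               sprintf("Power thresholds: alt |rho| >= %.2f, null |rho| <= %.2f",
                       res$power$threshold_alt, res$power$threshold_null))
  }
  lines
}
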