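# End-to-end orchestration: simulate (or load) -> quantize + extract ->
# interobserver agreement -> univariate screening -> per-feature ROC ->
# scope-wise stepwise models, with all outputs written to one directory.

#' Configure a pipeline run
#'
#' @param cohort Either a [cohort_spec()] (the cohort is simulated) or a
#'   list `list(manifest = path, labels = path)` naming an on-disk cohort.
#' @param n_levels Gray levels for quantization (default 32; see the
#'   methods vignette for the choice).
#' @param alpha Univariate significance level.
#' @param entry_p,removal_p Stepwise thresholds.
#' @param scopes Model scopes, subset of `c("sagittal", "axial", "combined")`.
#' @param reader_policy `"first-reader"` (reader 1 carries forward after the
#'   agreement stage, the classical choice) or `"mean-of-readers"` (feature
#'   values averaged across readers).
#' @param seed Seed recorded for provenance (the synthetic cohort's own seed
#'   lives in its `cohort_spec`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort,
                       n_levels = 32L,
                       alpha = 0.05,
                       entry_p = 0.05,
                       removal_p = 0.10,
                       scopes = c("sagittal", "axial", "combined"),
                       reader_policy = c("first-reader", "mean-of-readers"),
                       seed = 1L) {
  reader_policy <- match.arg(reader_policy)
  scopes <- match.arg(scopes, several.ok = TRUE)
  if (!(inherits(cohort, "cohort_spec") ||
        (is.list(cohort) && all(c("manifest", "labels") %in% names(cohort))))) {
    rlang::abort("cohort must be a cohort_spec or list(manifest =, labels =)")
  }
  structure(
    list(
      cohort = cohort, n_levels = as.integer(n_levels), alpha = alpha,
      entry_p = entry_p, removal_p = removal_p, scopes = scopes,
      reader_policy = reader_policy, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

config_as_list <- function(config) {
  co <- config$cohort
  cohort_repr <- if (inherits(co, "cohort_spec")) {
    c(list(type = "cohort_spec"), unclass(co))
  } else {
    list(type = "manifest", manifest = co$manifest, labels = co$labels)
  }
  list(
    cohort = cohort_repr, n_levels = config$n_levels, alpha = config$alpha,
    entry_p = config$entry_p, removal_p = config$removal_p,
    scopes = config$scopes, reader_policy = config$reader_policy,
    seed = config$seed
  )
}

#' Read a pipeline configuration from JSON
#'
#' Accepts the JSON written by [run_pipeline()] (`config.json`) or any JSON
#' object with the same keys, so a run can be reproduced from its serialized
#' configuration.
#'
#' @param path JSON file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cohort <- if (identical(j$cohort$type, "manifest")) {
    list(manifest = j$cohort$manifest, labels = j$cohort$labels)
  } else {
    sp <- j$cohort
    cohort_spec(
      n_per_class = sp$n_per_class, image_size = sp$image_size,
      correlation_length_neg = sp$correlation_length_neg,
      correlation_length_pos = sp$correlation_length_pos,
      noise_sd_neg = sp$noise_sd_neg, noise_sd_pos = sp$noise_sd_pos,
      sequence_coupling = sp$sequence_coupling,
      reader_perturb_radius = sp$reader_perturb_radius, seed = sp$seed
    )
  }
  run_config(
    cohort = cohort,
    n_levels = j$n_levels %||% 32L,
    alpha = j$alpha %||% 0.05,
    entry_p = j$entry_p %||% 0.05,
    removal_p = j$removal_p %||% 0.10,
    scopes = j$scopes %||% c("sagittal", "axial", "combined"),
    reader_policy = j$reader_policy %||% "first-reader",
    seed = j$seed %||% 1L
  )
}

#' Run the full texture-staging pipeline
#'
#' Executes, in order: cohort acquisition (simulation or manifest load),
#' feature extraction for both readers, per-feature interobserver ICC,
#' reader-policy resolution, univariate screening with Spearman
#' correlations, per-feature ROC for the significant features, and the
#' scope-wise stepwise logistic models. Every stage's table is written to
#' `out_dir` (`features.csv`, `icc.csv`, `univariate.csv`, `roc.csv`,
#' `model_report.json`, `config.json`, `run.log`). The report JSON contains
#' no timestamps, so identical configurations yield byte-identical reports;
#' wall-clock provenance goes to `run.log` only. On a stage failure a
#' `FAILED` marker naming the stage is left in `out_dir` and the error is
#' re-raised.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return The path of `model_report.json` (invisibly, a list of all output
#'   paths is attached as attribute `outputs`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  warn_collect <- character(0)
  log_msg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    log_msg("stage %s: start", name)
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        writeLines(c(log_lines, paste("FAILED at stage:", name)), log_path)
        writeLines(paste("FAILED at stage:", name), file.path(out_dir, "FAILED"))
        rlang::abort(sprintf("pipeline failed at stage '%s': %s", name, conditionMessage(e)))
      }),
      warning = function(w) {
        warn_collect <<- c(warn_collect, sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    log_msg("stage %s: done", name)
    res
  }

  cohort <- stage("cohort", {
    if (inherits(config$cohort, "cohort_spec")) {
      generate_cohort(config$cohort)
    } else {
      load_manifest(config$cohort$manifest, config$cohort$labels)
    }
  })

  readers <- sort(unique(cohort$reader))
  feats <- stage("extract", {
    lapply(readers, function(rd) {
      extract_cohort_features(cohort, n_levels = config$n_levels, reader = rd)
    })
  })

  icc <- stage("agreement", {
    if (length(readers) >= 2L) {
      agreement_table(feats[[1]], feats[[2]])
    } else {
      tibble::tibble(
        feature_name = character(), icc = numeric(),
        band = character(), trivial = logical()
      )
    }
  })

  features <- stage("reader-policy", {
    if (config$reader_policy == "first-reader" || length(readers) < 2L) {
      feats[[1]]
    } else {
      fc <- setdiff(names(feats[[1]]), c("subject_id", "class_label"))
      merged <- feats[[1]]
      for (col in fc) {
        merged[[col]] <- (feats[[1]][[col]] + feats[[2]][[col]]) / 2
      }
      merged
    }
  })

  univariate <- stage("univariate", {
    univariate_screen(features, alpha = config$alpha)
  })

  roc_tab <- stage("roc", {
    sig <- univariate$feature_name[univariate$significant]
    purrr::map_dfr(sig, function(fc) {
      g <- glance(roc_analysis(features[[fc]], features$class_label))
      dplyr::bind_cols(tibble::tibble(feature_name = fc), g)
    })
  })

  suite <- stage("model", {
    run_model_suite(
      features, univariate, scopes = config$scopes,
      entry_p = config$entry_p, removal_p = config$removal_p
    )
  })

  paths <- stage("write", {
    write_feature_table(features, file.path(out_dir, "features.csv"))
    readr::write_csv(icc, file.path(out_dir, "icc.csv"))
    readr::write_csv(univariate, file.path(out_dir, "univariate.csv"))
    readr::write_csv(roc_tab, file.path(out_dir, "roc.csv"))
    jsonlite::write_json(
      config_as_list(config), file.path(out_dir, "config.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
    caveats <- c(
      "No multiple-testing correction is applied across the univariate screen.",
      "Model ROC metrics are in-sample (fit and evaluation on the same cohort)."
    )
    report <- list(
      config = config_as_list(config),
      n_subjects = length(unique(cohort$subject_id)),
      agreement = icc,
      univariate = univariate,
      feature_roc = roc_tab,
      models = purrr::map(seq_len(nrow(suite)), function(i) {
        list(
          scope = suite$scope[i],
          candidates = suite$candidates[[i]],
          selected = suite$model[[i]]$selected,
          coefficients = tidy(suite$model[[i]]),
          fit = glance(suite$model[[i]]),
          roc = if (is.null(suite$roc[[i]])) NULL else glance(suite$roc[[i]])
        )
      }),
      caveats = caveats,
      warnings = warn_collect,
      versions = list(
        package = tryCatch(
          as.character(utils::packageVersion("texturestager")),
          error = function(e) NA_character_
        ),
        r = paste(R.version$major, R.version$minor, sep = ".")
      )
    )
    report_path <- file.path(out_dir, "model_report.json")
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         null = "null", dataframe = "rows")
    report_path
  })

  writeLines(log_lines, log_path)
  structure(paths, outputs = list(
    report = paths,
    features = file.path(out_dir, "features.csv"),
    icc = file.path(out_dir, "icc.csv"),
    univariate = file.path(out_dir, "univariate.csv"),
    roc = file.path(out_dir, "roc.csv"),
    config = file.path(out_dir, "config.json"),
    log = log_path
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
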