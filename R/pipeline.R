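#' Run configuration for the end-to-end pipeline
#'
#' Builds and validates the configuration consumed by [run_pipeline()].
#' Unknown keys fail fast with the offending name, before any training.
#'
#' @param out_dir Output directory for all artifacts.
#' @param cohort_dir Optional cohort directory (see [read_cohort()]); when
#'   `NULL` a cohort is simulated from `simulate`.
#' @param simulate A [synth_config()] (or argument list for one) used when
#'   `cohort_dir` is `NULL`.
#' @param uncertainty `"edl"` or `"mc"`; also selects the training loss of
#'   both models (evidential sum-of-squares vs cross-entropy).
#' @param gate `"simple"` or `"distance"`.
#' @param threshold Simple-gate threshold.
#' @param cutoff_fractions Candidate fractions for distance-gate
#'   calibration.
#' @param passes Monte-Carlo dropout passes.
#' @param train A [train_config()] or argument list for one (its `loss` is
#'   overridden to match `uncertainty`).
#' @param thresholds Sweep grid.
#' @param ood_levels Masking counts (uni-modal OOD probe); `NULL` skips the
#'   OOD step.
#' @param explain `TRUE` to run the referral explanation step.
#' @param n_per_class,n_perm Referral-explanation parameters.
#' @param seed Master seed.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir,
                       cohort_dir = NULL,
                       simulate = synth_config(),
                       uncertainty = "edl",
                       gate = "simple",
                       threshold = 0.5,
                       cutoff_fractions = c(0.1, 0.2, 0.3, 0.4, 0.5),
                       passes = 100,
                       train = train_config(),
                       thresholds = seq(0.1, 0.9, by = 0.1),
                       ood_levels = NULL,
                       explain = FALSE,
                       n_per_class = 20,
                       n_perm = 20,
                       seed = 1) {
  cfg <- as.list(environment())
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  known <- names(formals(run_config))
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$out_dir)) stop("`out_dir` is required", call. = FALSE)
  if (!cfg$uncertainty %in% c("edl", "mc")) {
    stop("invalid `uncertainty`: ", cfg$uncertainty, call. = FALSE)
  }
  if (!cfg$gate %in% c("simple", "distance")) {
    stop("invalid `gate` mode: ", cfg$gate, call. = FALSE)
  }
  if (is.list(cfg$simulate) && !inherits(cfg$simulate, "synth_config")) {
    cfg$simulate <- do.call(synth_config, cfg$simulate)
  }
  if (is.list(cfg$train) && !inherits(cfg$train, "train_config")) {
    cfg$train <- do.call(train_config, cfg$train)
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys are
#'   [run_config()] arguments.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(run_config, raw)
}

#' Run the full gated-ensemble pipeline
#'
#' Orchestrates the method end to end: obtain a cohort (read or simulate),
#' train the uni-modal and multi-modal models on the training split, apply
#' the configured gate to the test split, sweep the accuracy/cost frontier,
#' optionally probe out-of-distribution uncertainty and explain the
#' referral decisions, and serialize every result (CSV/JSON) together with
#' the resolved configuration and a log into `out_dir`. Deterministic given
#' the configured seeds.
#'
#' @param config A [run_config()], or a path accepted by
#'   [read_run_config()].
#' @return Invisibly, a list with the cohort, models, decisions, curve, and
#'   (when requested) OOD report and attribution, plus `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, as.list(config))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "log.txt")
  logline <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   paste0(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  logline("modalgate pipeline | seed=", config$seed,
          " | uncertainty=", config$uncertainty, " | gate=", config$gate,
          " | R ", getRversion())

  cohort <- if (!is.null(config$cohort_dir)) {
    logline("reading cohort from ", config$cohort_dir)
    read_cohort(config$cohort_dir)
  } else {
    logline("simulating cohort (n=", config$simulate$n_subjects, ")")
    generate_cohort(config$simulate)
  }
  train_rec <- dplyr::filter(cohort, .data$split == "train")
  test_rec <- dplyr::filter(cohort, .data$split == "test")

  tc <- config$train
  tc$loss <- if (config$uncertainty == "edl") "edl_sos" else "cross_entropy"
  tc$seed <- config$seed
  logline("training uni-modal model (", tc$loss, ", ", tc$epochs, " epochs)")
  f <- train_unimodal(train_rec, tc)
  logline("training multi-modal model")
  h <- train_multimodal(train_rec, tc)

  policy <- if (config$gate == "simple") {
    gate_policy("simple", tau = config$threshold,
                uncertainty = config$uncertainty, passes = config$passes)
  } else {
    logline("calibrating distance-gate cutoff")
    fr <- calibrate_cutoff(config$cutoff_fractions, f, h, train_rec, test_rec,
                           uncertainty = config$uncertainty,
                           passes = config$passes, seed = config$seed)
    logline("selected cutoff fraction ", fr)
    probe <- gate_policy("simple", uncertainty = config$uncertainty,
                         passes = config$passes)
    cen <- build_centroids(embed(f, train_rec),
                           as.numeric(gate_uncertainties(f, train_rec, probe,
                                                         seed = config$seed)),
                           as.numeric(fr))
    gate_policy("distance", centroids = cen, uncertainty = config$uncertainty,
                passes = config$passes)
  }

  logline("gating ", nrow(test_rec), " test instances")
  decisions <- ensemble_predict(test_rec, f, h, policy, seed = config$seed)
  utils::write.csv(dplyr::select(decisions, -dplyr::any_of("label")),
                   file.path(config$out_dir, "decisions.csv"), row.names = FALSE)

  logline("sweeping ", length(config$thresholds), " thresholds")
  curve <- sweep_thresholds(test_rec, f, h, thresholds = config$thresholds,
                            uncertainty = config$uncertainty,
                            passes = config$passes, seed = config$seed)
  utils::write.csv(tibble::as_tibble(curve),
                   file.path(config$out_dir, "curve.csv"), row.names = FALSE)

  ood <- NULL
  if (!is.null(config$ood_levels)) {
    logline("OOD probe at levels ", paste(config$ood_levels, collapse = ","))
    ood <- ood_report(f, test_rec, method = config$uncertainty,
                      levels = config$ood_levels, passes = config$passes,
                      seed = config$seed)
    utils::write.csv(dplyr::select(tibble::as_tibble(ood), -"u_ind", -"u_ood"),
                     file.path(config$out_dir, "ood.csv"), row.names = FALSE)
  }

  attribution <- NULL
  if (isTRUE(config$explain)) {
    labelled <- label_referrals(decisions)
    counts <- attr(labelled, "counts")
    logline("explaining referrals (", counts["referral"], " referral / ",
            counts["non_referral"], " non-referral)")
    clf <- train_referral_classifier(test_rec, labelled$referral,
                                     n_per_class = config$n_per_class,
                                     seed = config$seed)
    attribution <- feature_attribution(clf, test_rec, labelled$referral,
                                       n_perm = config$n_perm,
                                       seed = config$seed)
    utils::write.csv(tibble::as_tibble(attribution),
                     file.path(config$out_dir, "attribution.csv"),
                     row.names = FALSE)
  }

  metrics <- list(
    uni_accuracy = attr(curve, "uni_accuracy"),
    multi_accuracy = attr(curve, "multi_accuracy"),
    ensemble_accuracy = mean(decisions$predicted_label == decisions$label),
    cost_reduction = cost_reduction(decisions),
    referral_fraction = 1 - cost_reduction(decisions),
    n_test = nrow(test_rec),
    seed = config$seed
  )
  jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  resolved <- config
  resolved$simulate <- unclass(resolved$simulate)
  resolved$train <- unclass(resolved$train)
  yaml::write_yaml(lapply(unclass(resolved), function(x)
    if (is.null(x)) NULL else x), file.path(config$out_dir, "config.yaml"))
  logline("done: ", config$out_dir)
  invisible(list(cohort = cohort, f = f, h = h, policy = policy,
                 decisions = decisions, curve = curve, ood = ood,
                 attribution = attribution, metrics = metrics,
                 out_dir = config$out_dir))
}
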