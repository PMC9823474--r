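#' Configuration of an end-to-end benchmark experiment
#'
#' Describes a full run: synthetic dataset sizes, which approaches to
#' benchmark (the rule-based detector and/or a learned classifier), feature
#' and classifier settings, and the single master seed from which dataset
#' generation and training seeds are derived. The configuration serializes
#' losslessly to YAML via [write_experiment_config()].
#'
#' @param seed Master integer seed.
#' @param approaches Character subset of `c("es", "ml")`.
#' @param train_scale Fraction by which the published imbalanced train
#'   composition is scaled down (see [paper_profile()]).
#' @param test_per_class Frames per class in the balanced test partition.
#' @param side Square frame side in pixels.
#' @param noise_sigma Sensor-noise level of the generator.
#' @param feature_kind One of `"unrolled"`, `"hog"`, `"lbp"`.
#' @param feature_side Feature input side in pixels.
#' @param classifier Classifier kind, see [classifier_config()].
#' @param out_dir Optional report directory.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1L, approaches = c("es", "ml"),
                              train_scale = 0.1, test_per_class = 100L,
                              side = 520, noise_sigma = 4,
                              feature_kind = "unrolled", feature_side = 32,
                              classifier = "svm", out_dir = NULL) {
  known_clf <- c("svm", "mlp", "random_forest", "decision_tree",
                 "gaussian_nb", "knn", "adaboost", "qda")
  if (!classifier %in% known_clf)
    stop("unknown classifier '", classifier, "' in field 'classifier'")
  if (!all(approaches %in% c("es", "ml")))
    stop("unknown approach in field 'approaches'")
  if (!feature_kind %in% c("unrolled", "hog", "lbp"))
    stop("unknown feature kind '", feature_kind, "' in field 'feature_kind'")
  structure(list(seed = as.integer(seed), approaches = approaches,
                 train_scale = train_scale,
                 test_per_class = as.integer(test_per_class),
                 side = side, noise_sigma = noise_sigma,
                 feature_kind = feature_kind, feature_side = feature_side,
                 classifier = classifier, out_dir = out_dir),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param config An `experiment_config`.
#' @param path YAML file path.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(experiment_config, x)
}

# classify every frame with the rule-based detector, timing each frame
run_es_eval <- function(frames, truth, params, warmup = 10L) {
  preds <- character(0)
  timing <- measure_sfpt(function(f) {
    preds[length(preds) + 1] <<- es_classify_frame(f, params)$label
    invisible(NULL)
  }, frames, warmup = warmup)
  confusion <- table(truth = factor(truth, eye_labels()),
                     prediction = factor(preds, eye_labels()))
  list(accuracy = mean(preds == truth), confusion = confusion,
       timing = timing, predictions = preds)
}

#' Run a complete generation / classification / scoring experiment
#'
#' Generates the synthetic train and test partitions from the master seed,
#' runs each requested approach on the balanced test set, and scores every
#' approach with the latency-aware figure of merit computed from its
#' accuracy and 90th-percentile single-frame prediction time. Accuracy
#' figures and the comparison table are fully reproducible from the
#' configuration; wall-clock timings naturally vary between machines and
#' are reported but never part of any reproducibility contract.
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A list with per-approach evaluation results (`es`, `ml`), the
#'   test `manifest`, and `comparison` — a data.frame with columns
#'   approach, input_size, classifier, accuracy, p90_sfpt_ms, fom. Written
#'   as JSON and a text table under `config$out_dir` when set.
#' @export
run_experiment <- function(config = experiment_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  tau <- calibrate_tau()
  say("generating test partition (", 6 * config$test_per_class, " frames)")
  test_profile <- stats::setNames(rep(config$test_per_class, 6), eye_labels())
  test <- generate_dataset(test_profile, seed = config$seed + 1L,
                           side = config$side,
                           noise_sigma = config$noise_sigma)
  truth <- test$manifest$label
  out <- list(config = config, manifest = test$manifest)
  rows <- list()

  if ("es" %in% config$approaches) {
    say("running rule-based detector on ", length(test$frames), " frames")
    params <- if (config$side == 520) es_params()
              else es_scale_params(es_params(), config$side)
    out$es <- run_es_eval(test$frames, truth, params)
    rows[["es"]] <- data.frame(
      approach = "es", input_size = config$side, classifier = "pre-defined",
      accuracy = out$es$accuracy,
      p90_sfpt_ms = out$es$timing$p90_sfpt * 1000,
      fom = compute_fom(out$es$accuracy, out$es$timing$p90_sfpt, tau))
  }

  if ("ml" %in% config$approaches) {
    say("generating imbalanced train partition")
    train <- generate_dataset(paper_profile(config$train_scale)$train,
                              seed = config$seed + 2L, side = config$side,
                              noise_sigma = config$noise_sigma)
    say("extracting ", config$feature_kind, " features at ",
        config$feature_side, " px")
    ftr <- feature_matrix(train$frames, config$feature_kind,
                          config$feature_side)
    fte <- feature_matrix(test$frames, config$feature_kind,
                          config$feature_side)
    say("training ", config$classifier)
    model <- train_classifier(ftr, train$manifest$label,
                              classifier_config(config$classifier,
                                                seed = config$seed + 3L))
    out$ml <- evaluate_classifier(model, fte, truth, time_per_frame = TRUE)
    out$ml$model <- model
    rows[["ml"]] <- data.frame(
      approach = "ml", input_size = config$feature_side,
      classifier = config$classifier, accuracy = out$ml$accuracy,
      p90_sfpt_ms = out$ml$timing$p90_sfpt * 1000,
      fom = compute_fom(out$ml$accuracy, out$ml$timing$p90_sfpt, tau))
  }

  out$comparison <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(config = unclass(config), comparison = out$comparison,
           es_accuracy = out$es$accuracy, ml_accuracy = out$ml$accuracy),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    utils::write.table(format(out$comparison, digits = 4),
                       file.path(config$out_dir, "comparison.txt"),
                       quote = FALSE, row.names = FALSE, sep = "\t")
  }
  out
}
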