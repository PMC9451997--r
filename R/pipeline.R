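# End-to-end pipeline driver: images -> texture features -> binary
# attribute table -> frequent-itemset mining -> CARs -> coverage-pruned
# classifier -> stratified cross-validation, with per-stage counts logged.

#' Pipeline configuration
#'
#' Validated bundle of every tunable the screening pipeline uses.
#'
#' @param glcm A [glcm_params()].
#' @param thresholds Discretization thresholds (see
#'   [discretize_features()]).
#' @param min_sup,min_conf Mining thresholds (defaults 0.01 and 0.50).
#' @param min_up Minimum interest weight for NCFP-growth.
#' @param weighting `"uniform"` or `"class_lift"` (per-fold
#'   [class_lift_weights()]).
#' @param miner Miner choice (see [generate_cars()]).
#' @param folds,cv_seed Cross-validation folds and seed.
#' @param pd_noise Flip probability of the simulated prediagnosis bit when
#'   the pipeline has to derive PD from the images.
#' @param seed Seed for PD simulation.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(glcm = glcm_params(),
                            thresholds = "median-split",
                            min_sup = 0.01, min_conf = 0.5,
                            min_up = 0, weighting = c("uniform",
                                                      "class_lift"),
                            miner = "ncfp", folds = 10L, cv_seed = 1L,
                            pd_noise = 0.1, seed = 1L) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(glcm, "glcm_params"), folds >= 2L, min_up >= 0,
            pd_noise >= 0, pd_noise < 1)
  mp <- mining_params(min_sup, min_conf) # validates thresholds
  structure(list(glcm = glcm, thresholds = thresholds,
                 min_sup = mp$min_sup, min_conf = mp$min_conf,
                 min_up = min_up, weighting = weighting, miner = miner,
                 folds = as.integer(folds), cv_seed = as.integer(cv_seed),
                 pd_noise = pd_noise, seed = as.integer(seed)),
            class = "pipeline_config")
}

mining_params_for <- function(config, db) {
  if (config$miner != "ncfp") {
    return(mining_params(config$min_sup, config$min_conf))
  }
  weights <- if (config$weighting == "class_lift") {
    class_lift_weights(db)
  } else {
    interest_weights()
  }
  ncfp_params(min_sup = config$min_sup, min_up = config$min_up,
              weights = weights, min_conf = config$min_conf)
}

log_stage <- function(log, stage, key, value) {
  rbind(log, data.frame(stage = stage, key = key, value = value,
                        stringsAsFactors = FALSE))
}

#' Run the full screening pipeline
#'
#' Accepts either raw images plus labels (features are extracted and
#' discretized, and a prediagnosis bit is simulated from the images as in
#' [gen_labeled_dataset()]) or an already-binarized attribute table, then
#' mines CARs with the configured miner, builds the coverage-pruned
#' classifier on the full table, and reports stratified cross-validation
#' accuracy.  Every stage's headline counts are appended to a run log.
#'
#' @param config A [pipeline_config()].
#' @param images List of integer gray-level matrices (with `labels`), or
#'   NULL when `table` is given.
#' @param labels Character or 0/1 labels, one per image ("abnormal"/1 is
#'   the positive class).
#' @param table A ready `binary_table` (alternative entry point).
#' @return List of class `pipeline_result`: `log` (stage/key/value data
#'   frame), `table`, `cars`, `classifier`, `cv`.
#' @export
run_pipeline <- function(config, images = NULL, labels = NULL,
                         table = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- data.frame(stage = character(0), key = character(0),
                    value = numeric(0), stringsAsFactors = FALSE)
  if (is.null(table)) {
    if (is.null(images) || is.null(labels)) {
      stop("run_pipeline: provide either `table` or `images` + `labels`")
    }
    stopifnot(length(images) == length(labels))
    feats <- t(vapply(images, extract_image_features, numeric(6),
                      params = config$glcm))
    records <- as.data.frame(feats)
    records$PN <- seq_len(nrow(records))
    med_contrast <- stats::median(records$contrast)
    pd_raw <- as.integer(records$contrast > med_contrast)
    records$PD <- with_seed(config$seed, {
      flip <- stats::runif(length(pd_raw)) < config$pd_noise
      as.integer(xor(pd_raw == 1L, flip))
    })
    records$Class <- if (is.character(labels)) {
      as.integer(labels == "abnormal")
    } else {
      as.integer(labels)
    }
    log <- log_stage(log, "features", "images", length(images))
    table <- discretize_features(records, thresholds = config$thresholds)
    log <- log_stage(log, "discretize", "records", nrow(table))
  }
  db <- binary_table_to_db(table)
  log <- log_stage(log, "transactions", "alphabet", length(db$alphabet))
  params <- mining_params_for(config, db)
  cars <- rank_cars(generate_cars(db, params, miner = config$miner))
  log <- log_stage(log, "mine", "cars", nrow(cars))
  clf <- build_classifier(cars, db)
  log <- log_stage(log, "classifier", "rules", nrow(clf$rules))
  reweight <- if (config$miner == "ncfp" &&
                  config$weighting == "class_lift") {
    class_lift_weights
  }
  cv <- cross_validate(db, params, miner = config$miner,
                       folds = config$folds, seed = config$cv_seed,
                       reweight = reweight)
  log <- log_stage(log, "cv", "mean_accuracy", cv$mean_accuracy)
  for (f in seq_len(cv$folds)) {
    log <- log_stage(log, "cv", paste0("fold_", f), cv$fold_accuracy[f])
  }
  structure(list(log = log, table = table, cars = cars, classifier = clf,
                 cv = cv),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", nrow(x$cars), "CARs,", nrow(x$classifier$rules),
      "classifier rules, CV mean accuracy",
      sprintf("%.3f", x$cv$mean_accuracy), "\n")
  invisible(x)
}
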