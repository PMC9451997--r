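# CBA-style associative classifier: ranked CARs pruned by database
# coverage, first-match prediction, stratified cross-validation.

record_class <- function(transactions, class_items) {
  vapply(transactions, function(t) {
    cl <- t[t %in% class_items]
    if (length(cl) != 1L) NA_character_ else cl
  }, character(1))
}

#' Build a classifier by database-coverage pruning
#'
#' Walks the ranked CAR list and keeps a rule iff it correctly classifies
#' at least one still-uncovered training record; all uncovered records
#' matched by a kept rule's antecedent are then marked covered.  The
#' default class is the majority class of the records left uncovered
#' (global majority when everything is covered; ties broken canonically).
#'
#' @param cars Ranked CARs ([rank_cars()] output; unranked input is ranked
#'   first).
#' @param db Training [transaction_db()] with one class item per record.
#' @param class_attr Class attribute name.
#' @return Object of class `car_classifier`: `rules` (the retained ordered
#'   CARs), `default_class`, `class_attr`.
#' @export
build_classifier <- function(cars, db, class_attr = "Class") {
  stopifnot(inherits(cars, "association_rules"),
            inherits(db, "transaction_db"))
  cars <- rank_cars(cars)
  class_items <- db$alphabet[item_attribute(db$alphabet) == class_attr]
  classes <- record_class(db$transactions, class_items)
  if (anyNA(classes)) {
    stop("build_classifier: every training record needs exactly one '",
         class_attr, "=' item")
  }
  majority <- function(x) {
    if (length(x) == 0L) return(NA_character_)
    tab <- table(x)
    cand <- names(tab)[tab == max(tab)]
    sort(cand, method = "radix")[1L]
  }
  uncovered <- rep(TRUE, db$n)
  keep <- logical(nrow(cars))
  for (i in seq_len(nrow(cars))) {
    if (!any(uncovered)) break
    ant <- cars$antecedent[[i]]
    matched <- uncovered & vapply(db$transactions,
                                  function(t) all(ant %in% t), logical(1))
    if (!any(matched)) next
    correct <- matched & classes == cars$cons_key[i]
    if (any(correct)) {
      keep[i] <- TRUE
      uncovered[matched] <- FALSE
    }
  }
  default_class <- majority(classes[uncovered])
  if (is.na(default_class)) default_class <- majority(classes)
  rules <- cars[keep, , drop = FALSE]
  rownames(rules) <- NULL
  structure(list(rules = rules, default_class = default_class,
                 class_attr = class_attr),
            class = "car_classifier")
}

#' @export
print.car_classifier <- function(x, ...) {
  cat("car_classifier:", nrow(x$rules), "rules, default",
      x$default_class, "\n")
  invisible(x)
}

#' Predict class labels with a CAR classifier
#'
#' First-match prediction: the consequent of the first (highest-ranked)
#' retained rule whose antecedent is a subset of the record, or the
#' default class when no rule fires.
#'
#' @param object A `car_classifier`.
#' @param newdata A single record (character vector of items), a list of
#'   records, or a [transaction_db()]; records must not carry class items.
#' @param ... Unused.
#' @return Character vector of predicted class items (e.g. `"Class=1"`).
#' @export
predict.car_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "transaction_db")) newdata <- newdata$transactions
  if (is.character(newdata)) newdata <- list(newdata)
  ants <- object$rules$antecedent
  cons <- object$rules$cons_key
  vapply(newdata, function(rec) {
    for (j in seq_along(ants)) {
      if (all(ants[[j]] %in% rec)) return(cons[j])
    }
    object$default_class
  }, character(1))
}

#' Classifier training error of a first-match rule list
#'
#' @param cars Ranked CARs.
#' @param db Training database.
#' @param default_class Class item predicted when no rule matches.
#' @param class_attr Class attribute name.
#' @return Fraction of misclassified records.
#' @keywords internal
first_match_error <- function(cars, db, default_class,
                              class_attr = "Class") {
  clf <- structure(list(rules = cars, default_class = default_class,
                        class_attr = class_attr),
                   class = "car_classifier")
  class_items <- db$alphabet[item_attribute(db$alphabet) == class_attr]
  truth <- record_class(db$transactions, class_items)
  recs <- lapply(db$transactions, function(t) t[!t %in% class_items])
  mean(predict(clf, recs) != truth)
}

#' Stratified k-fold cross-validation of the associative classifier
#'
#' Folds are stratified by class with a seeded shuffle; each fold's
#' training records are mined for CARs with the chosen miner, a classifier
#' is built by coverage pruning, and micro accuracy (correct/total) is
#' measured on the held-out fold.
#'
#' @inheritParams generate_cars
#' @param folds Number of folds (default 10); every class must have at
#'   least `folds` records.
#' @param seed Integer seed driving the fold assignment.
#' @param reweight Optional function `(train_db) -> interest_weights`
#'   recomputing NCFP interest weights on each fold's training records
#'   (e.g. [class_lift_weights()]); avoids using held-out records when
#'   weights are data-derived.
#' @return Object of class `cv_result`: `fold_accuracy` (length `folds`),
#'   `mean_accuracy`, `folds`, `seed`, `fold_of` (per-record assignment).
#' @export
cross_validate <- function(db, params, miner = "ncfp", folds = 10L,
                           seed = 1L, class_attr = "Class",
                           reweight = NULL, ...) {
  stopifnot(inherits(db, "transaction_db"), folds >= 2L)
  class_items <- db$alphabet[item_attribute(db$alphabet) == class_attr]
  classes <- record_class(db$transactions, class_items)
  if (anyNA(classes)) {
    stop("cross_validate: every record needs exactly one '", class_attr,
         "=' item")
  }
  tab <- table(classes)
  if (any(tab < folds)) {
    stop("cross_validate: class ", names(tab)[which.min(tab)], " has ",
         min(tab), " records; stratified ", folds,
         "-fold CV needs at least ", folds, " per class")
  }
  fold_of <- integer(db$n)
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(classes == cl))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    train <- transaction_db(db$transactions[fold_of != f])
    p <- params
    if (!is.null(reweight) && inherits(params, "ncfp_params")) {
      p$weights <- reweight(train)
    }
    cars <- generate_cars(train, p, miner = miner,
                          class_attr = class_attr, ...)
    clf <- build_classifier(cars, train, class_attr = class_attr)
    test_tx <- db$transactions[fold_of == f]
    truth <- classes[fold_of == f]
    recs <- lapply(test_tx, function(t) t[!t %in% class_items])
    acc[f] <- mean(predict(clf, recs) == truth)
  }
  structure(list(fold_accuracy = acc, mean_accuracy = mean(acc),
                 folds = folds, seed = seed, fold_of = fold_of),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV: mean accuracy %.3f (folds %s)\n", x$folds,
              x$mean_accuracy,
              paste(sprintf("%.2f", x$fold_accuracy), collapse = " ")))
  invisible(x)
}

#' Serialize a classifier to JSON
#'
#' Ordered rules (antecedent, consequent, support, confidence) plus the
#' default class.
#'
#' @param classifier A `car_classifier`.
#' @param path Optional output file.
#' @return JSON string (invisibly when `path` is given).
#' @export
classifier_to_json <- function(classifier, path = NULL) {
  stopifnot(inherits(classifier, "car_classifier"))
  r <- classifier$rules
  lst <- list(
    rules = lapply(seq_len(nrow(r)), function(i) {
      list(antecedent = I(r$antecedent[[i]]), consequent = r$cons_key[i],
           support = r$support[i], confidence = r$confidence[i])
    }),
    default_class = classifier$default_class
  )
  js <- as.character(jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA))
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
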