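# Association rules from frequent itemsets, and their class-consequent
# restriction (CARs) feeding the associative classifier.

#' Generate strong association rules from a frequent-itemset set
#'
#' For every frequent itemset T of size >= 2 and every nonempty proper
#' subset S, emits S -> (T - S) whenever sigma(T)/sigma(S) >= `min_conf`.
#' The frequent set must be complete for its support threshold so that
#' every sigma(S) is available by anti-monotonicity (any missing
#' denominator is recounted against the database as a fallback).
#'
#' @param frequent A `supported_itemsets` data frame (complete for its
#'   `min_sup`).
#' @param db The [transaction_db()] the itemsets were mined from.
#' @param min_conf Minimum confidence in (0, 1].
#' @return `association_rules` data frame with columns `ant_key`,
#'   `cons_key`, `count` (union count), `support`, `confidence` and list
#'   columns `antecedent`, `consequent`, in deterministic order.
#' @export
generate_rules <- function(frequent, db, min_conf) {
  stopifnot(inherits(frequent, "supported_itemsets"),
            inherits(db, "transaction_db"),
            min_conf > 0, min_conf <= 1)
  count_of <- stats::setNames(frequent$count, frequent$key)
  n <- attr(frequent, "n")
  ants <- list(); cons <- list()
  cnt <- integer(0); conf <- numeric(0)
  for (i in seq_len(nrow(frequent))) {
    t_items <- frequent$items[[i]]
    k <- length(t_items)
    if (k < 2L) next
    t_count <- frequent$count[i]
    for (s_size in seq_len(k - 1L)) {
      for (idx in utils::combn(k, s_size, simplify = FALSE)) {
        s_items <- t_items[idx]
        s_key <- itemset_key(s_items)
        s_count <- count_of[[s_key]]
        if (is.null(s_count) || is.na(s_count)) {
          s_count <- support_count(db, s_items)
        }
        c_val <- t_count / s_count
        if (c_val >= min_conf - 1e-12) {
          ants[[length(ants) + 1L]] <- s_items
          cons[[length(cons) + 1L]] <- t_items[-idx]
          cnt <- c(cnt, t_count)
          conf <- c(conf, c_val)
        }
      }
    }
  }
  new_rules_df(ants, cons, cnt, cnt / n, conf)
}

#' Generate classification association rules (CARs)
#'
#' Mines the database with the chosen miner and keeps the rules whose
#' consequent is exactly one class item and whose antecedent is
#' class-free.  These are the rules the associative classifier is built
#' from.
#'
#' @param db A [transaction_db()] in attribute-table form (alphabet must
#'   contain `Class=` items).
#' @param params A [mining_params()] (or [ncfp_params()] when
#'   `miner = "ncfp"`); `min_sup` and `min_conf` are both used.
#' @param miner One of `"apriori"`, `"dhp"`, `"partition"`, `"fp"`,
#'   `"ncfp"`, `"brute"`.
#' @param class_attr Class attribute name (default `"Class"`).
#' @param ... Passed to the miner (e.g. `bucket_count`, `segment_count`).
#' @return `association_rules` data frame (one class item per consequent)
#'   with an extra `ant_size` column.
#' @export
generate_cars <- function(db, params, miner = c("ncfp", "fp", "apriori",
                                                "dhp", "partition", "brute"),
                          class_attr = "Class", ...) {
  stopifnot(inherits(db, "transaction_db"), inherits(params, "mining_params"))
  miner <- match.arg(miner)
  class_items <- db$alphabet[item_attribute(db$alphabet) == class_attr]
  if (length(class_items) == 0L) {
    stop("generate_cars: database has no '", class_attr, "=' items")
  }
  frequent <- switch(miner,
    brute = brute_force_mine(db, params),
    apriori = apriori_mine(db, params),
    dhp = dhp_mine(db, params, ...),
    partition = partition_mine(db, params, ...),
    fp = fp_growth_mine(db, params),
    ncfp = {
      if (!inherits(params, "ncfp_params")) {
        params <- ncfp_params(min_sup = params$min_sup,
                              min_conf = params$min_conf)
      }
      ncfp_mine(db, params)
    })
  cars_from_frequent(frequent, db, params$min_conf, class_items)
}

# Direct CAR extraction: for each frequent itemset containing exactly one
# class item, the antecedent is the class-free remainder and the
# denominator is its (frequent, by anti-monotonicity) count.  Equivalent
# to filtering generate_rules() output but linear in the frequent set.
cars_from_frequent <- function(frequent, db, min_conf, class_items) {
  count_of <- stats::setNames(frequent$count, frequent$key)
  n <- attr(frequent, "n")
  ants <- list(); cons <- list()
  cnt <- integer(0); conf <- numeric(0)
  for (i in seq_len(nrow(frequent))) {
    t_items <- frequent$items[[i]]
    is_class <- t_items %in% class_items
    if (sum(is_class) != 1L || length(t_items) < 2L) next
    s_items <- t_items[!is_class]
    s_count <- count_of[[itemset_key(s_items)]]
    if (is.null(s_count) || is.na(s_count)) {
      s_count <- support_count(db, s_items)
    }
    c_val <- frequent$count[i] / s_count
    if (c_val >= min_conf - 1e-12) {
      ants[[length(ants) + 1L]] <- s_items
      cons[[length(cons) + 1L]] <- t_items[is_class]
      cnt <- c(cnt, frequent$count[i])
      conf <- c(conf, c_val)
    }
  }
  out <- new_rules_df(ants, cons, cnt, cnt / n, conf)
  out$ant_size <- lengths(out$antecedent)
  class(out) <- c("car_rules", class(out))
  out
}

#' Rank CARs for classifier construction
#'
#' Total order: confidence descending, support descending, antecedent size
#' ascending (more general rules first among ties), then canonical
#' antecedent key ascending.  Stable and deterministic.
#'
#' @param cars Output of [generate_cars()].
#' @return The same data frame, reordered.
#' @export
rank_cars <- function(cars) {
  stopifnot(inherits(cars, "association_rules"))
  if (is.null(cars$ant_size)) cars$ant_size <- lengths(cars$antecedent)
  ord <- order(-cars$confidence, -cars$support, cars$ant_size,
               cars$ant_key, cars$cons_key, method = "radix")
  out <- cars[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
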