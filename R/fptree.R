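# FP-tree: prefix tree over support-ordered transactions with per-item
# node chains, the substrate of FP-growth and of its weighted NCFP
# extension.  Nodes are environments (mutable, with parent links); the
# header maps each item to the list of its nodes, which is the node chain.

new_fp_node <- function(item, parent) {
  node <- new.env(parent = emptyenv())
  node$item <- item
  node$count <- 0
  node$parent <- parent
  node$children <- list()
  node
}

# item_table: character vector of retained items in insertion (descending
# support) order; transactions already filtered/sorted by the caller get
# inserted with the given weights.
build_tree_core <- function(transactions, weights, item_table) {
  root <- new_fp_node(NA_character_, NULL)
  header <- new.env(parent = emptyenv())
  for (it in item_table) assign(it, list(), envir = header)
  for (i in seq_along(transactions)) {
    items <- transactions[[i]]
    w <- weights[[i]]
    cur <- root
    for (it in items) {
      child <- cur$children[[it]]
      if (is.null(child)) {
        child <- new_fp_node(it, cur)
        cur$children[[it]] <- child
        assign(it, c(get(it, envir = header), list(child)), envir = header)
      }
      child$count <- child$count + w
      cur <- child
    }
  }
  structure(list(root = root, header = header, item_order = item_table),
            class = "fp_tree")
}

# Descending support, ties broken by canonical item order: FP-growth
# fixes no tie-break, but golden-file tests need a deterministic tree.
order_items_by_support <- function(counts) {
  items <- names(counts)
  items[order(-counts, items, method = "radix")]
}

filter_sort_transaction <- function(t, item_table) {
  t <- t[t %in% item_table]
  t[order(match(t, item_table))]
}

#' Build an FP-tree from a transaction database
#'
#' Drops items below the support threshold, sorts each transaction's
#' surviving items in global descending-support order (ties broken
#' canonically) and inserts them into a prefix tree whose node counts equal
#' the number of transactions sharing that prefix.
#'
#' @inheritParams brute_force_mine
#' @return Object of class `fp_tree`: `root` node, `header` environment
#'   mapping each retained item to its node chain, and `item_order`.
#' @export
build_fp_tree <- function(db, params) {
  stopifnot(inherits(db, "transaction_db"), inherits(params, "mining_params"))
  params2 <- ncfp_params(min_sup = params$min_sup, min_up = 0,
                         weights = interest_weights())
  build_ncfp_tree(db, params2)
}

#' Node chain of an item
#'
#' @param tree An `fp_tree`.
#' @param item Item token.
#' @return List of the tree nodes holding `item` (each an environment with
#'   `item`, `count`, `parent`, `children`).
#' @export
fp_node_chain <- function(tree, item) {
  stopifnot(inherits(tree, "fp_tree"))
  if (!exists(item, envir = tree$header, inherits = FALSE)) return(list())
  get(item, envir = tree$header, inherits = FALSE)
}

#' Serialize an FP-tree to a canonical JSON string
#'
#' Children appear in insertion order, which is deterministic given the
#' item table, so equal trees serialize to identical bytes.
#'
#' @param tree An `fp_tree`.
#' @return Length-1 character (JSON).
#' @export
fp_tree_serialize <- function(tree) {
  ser <- function(node) {
    kids <- lapply(node$children, ser)
    names(kids) <- NULL
    list(item = if (is.na(node$item)) "" else node$item,
         count = node$count, children = kids)
  }
  as.character(jsonlite::toJSON(ser(tree$root), auto_unbox = TRUE, digits = NA))
}

fp_tree_node_count <- function(tree) {
  walk <- function(node) 1L + sum(vapply(node$children, walk, integer(1)), 0L)
  walk(tree$root) - 1L # exclude the null root
}

# Recursive pattern growth over a built tree.  Every item in the tree's
# item table already meets min_count (guaranteed by the builders), so each
# suffix extension is emitted directly; its conditional pattern base (the
# prefix paths of its node chain, weighted by node counts) is re-filtered
# at min_count and mined as a conditional tree.
mine_tree <- function(tree, min_count, suffix, n) {
  keys <- character(0); counts <- numeric(0)
  for (item in rev(tree$item_order)) {
    chain <- fp_node_chain(tree, item)
    total <- sum(vapply(chain, function(nd) nd$count, numeric(1)))
    itemset <- canonical_items(c(item, suffix))
    keys <- c(keys, itemset_key(itemset))
    counts <- c(counts, total)
    # conditional pattern base
    paths <- list(); weights <- numeric(0)
    for (nd in chain) {
      p <- character(0)
      cur <- nd$parent
      while (!is.null(cur) && !is.na(cur$item)) {
        p <- c(cur$item, p)
        cur <- cur$parent
      }
      if (length(p) > 0L) {
        paths[[length(paths) + 1L]] <- p
        weights <- c(weights, nd$count)
      }
    }
    if (length(paths) == 0L) next
    cond_counts <- tapply(rep(weights, lengths(paths)),
                          unlist(paths, use.names = FALSE), sum)
    cond_counts <- cond_counts[cond_counts >= min_count]
    if (length(cond_counts) == 0L) next
    cond_order <- order_items_by_support(cond_counts)
    cond_tx <- lapply(paths, filter_sort_transaction, item_table = cond_order)
    keep <- lengths(cond_tx) > 0L
    cond_tree <- build_tree_core(cond_tx[keep], weights[keep], cond_order)
    res <- mine_tree(cond_tree, min_count, c(item, suffix), n)
    keys <- c(keys, res$keys)
    counts <- c(counts, res$counts)
  }
  list(keys = keys, counts = counts)
}

#' FP-growth frequent-itemset miner
#'
#' Compresses the database into an FP-tree and mines it recursively through
#' conditional pattern bases, without a candidate-generation stage.
#'
#' @inheritParams brute_force_mine
#' @return `supported_itemsets` identical to [brute_force_mine()]'s output.
#' @export
fp_growth_mine <- function(db, params) {
  stopifnot(inherits(db, "transaction_db"), inherits(params, "mining_params"))
  params2 <- ncfp_params(min_sup = params$min_sup, min_up = 0,
                         weights = interest_weights())
  ncfp_mine(db, params2)
}

#' Per-item interest weights
#'
#' NCFP-growth attaches an interest-degree weight to every item; items
#' whose weight falls below `min_up` are excluded from the tree and from
#' every mined pattern.  Weights are user-supplied (any non-negative
#' measure of how relevant an item is to the analysis); see
#' [class_lift_weights()] for a classification-oriented convenience.
#'
#' @param weights Named numeric vector (item -> weight), possibly empty.
#' @param default_weight Weight applied to items not listed (default 1).
#' @return Object of class `interest_weights`.
#' @export
interest_weights <- function(weights = numeric(0), default_weight = 1) {
  stopifnot(is.numeric(weights), all(is.finite(weights)), all(weights >= 0),
            is.numeric(default_weight), length(default_weight) == 1L,
            is.finite(default_weight), default_weight >= 0)
  if (length(weights) > 0L) stopifnot(!is.null(names(weights)))
  structure(list(weights = weights, default_weight = default_weight),
            class = "interest_weights")
}

item_weights <- function(items, iw) {
  w <- rep(iw$default_weight, length(items))
  hit <- match(items, names(iw$weights))
  w[!is.na(hit)] <- iw$weights[hit[!is.na(hit)]]
  names(w) <- items
  w
}

#' NCFP-growth parameters
#'
#' The dual-threshold parameterization: `min_sup` is the usual minimum
#' support fraction and `min_up` the minimum interest weight an item must
#' carry to enter the tree.  With `min_up = 0` (or all-1 weights and
#' `min_up <= 1`) NCFP-growth reduces exactly to FP-growth.
#'
#' @param min_sup Minimum support fraction in (0, 1].
#' @param min_up Minimum interest weight (>= 0).
#' @param weights An [interest_weights()].
#' @param min_conf Minimum confidence for downstream rule generation.
#' @return List of class `ncfp_params` (also `mining_params`).
#' @export
ncfp_params <- function(min_sup = 0.01, min_up = 0,
                        weights = interest_weights(), min_conf = 0.5) {
  base <- mining_params(min_sup = min_sup, min_conf = min_conf)
  stopifnot(is.numeric(min_up), length(min_up) == 1L, is.finite(min_up),
            min_up >= 0, inherits(weights, "interest_weights"))
  structure(c(base, list(min_up = min_up, weights = weights)),
            class = c("ncfp_params", "mining_params"))
}

#' Weight- and support-filtered item table (table L)
#'
#' Items that pass both thresholds — support fraction >= `min_sup` and
#' interest weight >= `min_up` — sorted by descending support count with
#' canonical tie-break.  Every item excluded here is excluded from the
#' NCFP-tree and from every mined itemset.
#'
#' @param db A [transaction_db()].
#' @param params An [ncfp_params()].
#' @return Data frame with columns `item`, `count`, `support`, `weight`,
#'   in table-L order.
#' @export
weighted_frequent_items <- function(db, params) {
  stopifnot(inherits(db, "transaction_db"), inherits(params, "ncfp_params"))
  inc <- db_incidence(db)
  counts <- colSums(inc)
  w <- item_weights(db$alphabet, params$weights)
  keep <- counts >= min_support_count(db$n, params$min_sup) &
    w >= params$min_up
  items <- db$alphabet[keep]
  cnt <- counts[keep]
  ord <- order(-cnt, items, method = "radix")
  data.frame(item = items[ord], count = as.integer(cnt[ord]),
             support = cnt[ord] / db$n, weight = unname(w[keep][ord]),
             stringsAsFactors = FALSE)
}

#' Build the NCFP-tree
#'
#' Identical construction to [build_fp_tree()] except that each
#' transaction is first restricted to the dual-threshold item table of
#' [weighted_frequent_items()].  With `min_up = 0` and uniform weights the
#' result is byte-identical to the plain FP-tree.
#'
#' @inheritParams weighted_frequent_items
#' @return An `fp_tree`.
#' @export
build_ncfp_tree <- function(db, params) {
  tab <- weighted_frequent_items(db, params)
  tx <- lapply(db$transactions, filter_sort_transaction,
               item_table = tab$item)
  keep <- lengths(tx) > 0L
  build_tree_core(tx[keep], rep(1, sum(keep)), tab$item)
}

#' NCFP-growth miner
#'
#' FP-growth mining over the NCFP-tree: the output is exactly the
#' brute-force frequent-itemset set restricted to itemsets all of whose
#' items pass the interest-weight filter.  Raising `min_up` can only
#' remove itemsets (and hence downstream rules), never add them.
#'
#' @inheritParams weighted_frequent_items
#' @return `supported_itemsets`.
#' @export
ncfp_mine <- function(db, params) {
  stopifnot(inherits(db, "transaction_db"), inherits(params, "ncfp_params"))
  tree <- build_ncfp_tree(db, params)
  minc <- min_support_count(db$n, params$min_sup)
  res <- mine_tree(tree, minc, character(0), db$n)
  new_supported_itemsets(res$keys, res$counts, db$n)
}

#' Class-lift interest weighting
#'
#' A built-in convenience weighting oriented toward classification: the
#' weight of an item is the maximum over class labels of
#' confidence(item -> class) / fraction(class) — the lift of the item
#' toward its best-associated class.  Items unrelated to any class get
#' weight near 1; strongly class-predictive items get weight > 1, so a
#' `min_up` slightly above 1 suppresses class-irrelevant items.
#'
#' @param db A [transaction_db()] in attribute-table form (must contain
#'   `Class=` items).
#' @param class_attr Name of the class attribute (default "Class").
#' @return An [interest_weights()] covering every item in the alphabet.
#' @export
class_lift_weights <- function(db, class_attr = "Class") {
  stopifnot(inherits(db, "transaction_db"))
  classes <- db$alphabet[item_attribute(db$alphabet) == class_attr]
  if (length(classes) == 0L) {
    stop("class_lift_weights: no '", class_attr, "=' items in the database")
  }
  inc <- db_incidence(db)
  class_frac <- colSums(inc[, classes, drop = FALSE]) / db$n
  w <- vapply(db$alphabet, function(it) {
    sup_i <- sum(inc[, it])
    conf <- vapply(classes, function(cl) {
      sum(inc[, it] & inc[, cl]) / sup_i
    }, numeric(1))
    max(conf / class_frac)
  }, numeric(1))
  interest_weights(weights = w, default_weight = 1)
}

#' Serialize mined itemsets to canonical JSON
#'
#' `[{"items": [...], "count": c, "support": f}, ...]` in canonical
#' (size, key) order; equivalent miners produce identical bytes.
#'
#' @param x A `supported_itemsets` data frame.
#' @param path Optional file path; if given, the JSON is written there.
#' @return The JSON string (invisibly when `path` is given).
#' @export
itemsets_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "supported_itemsets"))
  lst <- lapply(seq_len(nrow(x)), function(i) {
    # I() keeps single-item sets as JSON arrays under auto_unbox
    list(items = I(x$items[[i]]), count = x$count[i],
         support = x$support[i])
  })
  js <- as.character(jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA))
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
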