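#' @keywords internal
"_PACKAGE"

# Items are atomic "attribute=value" tokens (Boolean association rules);
# canonical order is plain lexicographic in the C locale so that itemset
# keys, golden files and miner outputs are byte-stable across platforms.

#' Canonicalize a set of items
#'
#' Deduplicates and sorts item tokens into the package's canonical
#' (locale-independent lexicographic) order.
#'
#' @param items Character vector of item tokens, e.g. `c("PD=1", "H=0")`.
#' @return Sorted character vector without duplicates.
#' @export
canonical_items <- function(items) {
  if (length(items) == 0L) return(character(0))
  stopifnot(is.character(items), !anyNA(items), all(nzchar(items)))
  sort(unique(items), method = "radix")
}

#' Attribute part of an item token
#'
#' @param items Character vector of `attribute=value` tokens.
#' @return Character vector of the attribute names (text before the first
#'   `=`; tokens without `=` are their own attribute).
#' @export
item_attribute <- function(items) {
  sub("=.*$", "", items)
}

itemset_key <- function(items) paste(items, collapse = ",")

key_to_items <- function(key) {
  if (!nzchar(key)) character(0) else strsplit(key, ",", fixed = TRUE)[[1L]]
}

#' Construct a transaction database
#'
#' A transaction database is an ordered bag of itemsets over a finite item
#' alphabet; it is the common substrate of all the miners.
#'
#' @param transactions List of character vectors; each vector is one
#'   transaction's items (duplicates within a transaction are dropped).
#' @return Object of class `transaction_db` with elements `transactions`
#'   (canonicalized itemsets), `alphabet` (sorted union of all items) and
#'   `n` (number of transactions).
#' @examples
#' db <- transaction_db(list(c("A", "B"), c("A", "C"), c("A", "B"), "B"))
#' db$n
#' db$alphabet
#' @export
transaction_db <- function(transactions) {
  stopifnot(is.list(transactions), length(transactions) >= 1L)
  tx <- lapply(transactions, canonical_items)
  alphabet <- sort(unique(unlist(tx, use.names = FALSE)), method = "radix")
  structure(
    list(transactions = tx, alphabet = alphabet, n = length(tx)),
    class = "transaction_db"
  )
}

#' @export
print.transaction_db <- function(x, ...) {
  cat("transaction_db:", x$n, "transactions,",
      length(x$alphabet), "items\n")
  invisible(x)
}

# n x |alphabet| logical incidence matrix; the workhorse behind all
# vectorized support counting.
db_incidence <- function(db) {
  m <- length(db$alphabet)
  inc <- matrix(FALSE, nrow = db$n, ncol = m,
                dimnames = list(NULL, db$alphabet))
  for (i in seq_len(db$n)) {
    inc[i, db$transactions[[i]]] <- TRUE
  }
  inc
}

# Support threshold comparison.  min_sup arrives as a double fraction, so
# "count/n >= min_sup" is evaluated in the count domain with a tiny epsilon
# absorbing only float representation error (< 1e-9 of a transaction),
# never a whole count.
min_support_count <- function(n, min_sup) {
  min_sup * n - 1e-9
}

#' Support count of an itemset
#'
#' Number of transactions containing `itemset` as a subset.  The empty
#' itemset is a subset of every transaction, so its support count is `n`.
#' Items absent from the database's alphabet are allowed (support 0).
#'
#' @param db A [transaction_db()].
#' @param itemset Character vector of items (possibly empty).
#' @return Integer count in `[0, n]`.
#' @export
support_count <- function(db, itemset) {
  stopifnot(inherits(db, "transaction_db"))
  itemset <- canonical_items(itemset)
  if (length(itemset) == 0L) return(db$n)
  if (!all(itemset %in% db$alphabet)) return(0L)
  sum(vapply(db$transactions,
             function(t) all(itemset %in% t), logical(1)))
}

#' Support and confidence of a candidate association rule
#'
#' For the rule S -> T-S with antecedent S and consequent T-S, support is
#' the fraction of transactions containing the union S u T and confidence
#' is sigma(S u T) / sigma(S).  Both are computed from integer counts.
#'
#' @param db A [transaction_db()].
#' @param antecedent Nonempty character vector (S), disjoint from the
#'   consequent.
#' @param consequent Nonempty character vector (T - S).
#' @return A one-row data frame of class `association_rules` with columns
#'   `antecedent`, `consequent` (list columns), `ant_key`, `cons_key`,
#'   `count` (of the union), `support`, `confidence`.
#' @export
rule_metrics <- function(db, antecedent, consequent) {
  antecedent <- canonical_items(antecedent)
  consequent <- canonical_items(consequent)
  if (length(antecedent) == 0L || length(consequent) == 0L) {
    stop("antecedent and consequent must both be nonempty")
  }
  if (length(intersect(antecedent, consequent)) > 0L) {
    stop("antecedent and consequent must be disjoint")
  }
  sigma_s <- support_count(db, antecedent)
  if (sigma_s == 0L) {
    stop("antecedent has zero support: confidence is undefined")
  }
  sigma_t <- support_count(db, union(antecedent, consequent))
  new_rules_df(
    antecedent = list(antecedent), consequent = list(consequent),
    count = sigma_t, support = sigma_t / db$n,
    confidence = sigma_t / sigma_s
  )
}

new_rules_df <- function(antecedent, consequent, count, support, confidence) {
  df <- data.frame(
    ant_key = vapply(antecedent, itemset_key, character(1)),
    cons_key = vapply(consequent, itemset_key, character(1)),
    count = as.integer(count),
    support = support,
    confidence = confidence,
    stringsAsFactors = FALSE
  )
  df$antecedent <- antecedent
  df$consequent <- consequent
  class(df) <- c("association_rules", "data.frame")
  df
}

#' Mining thresholds
#'
#' @param min_sup Minimum support fraction in (0, 1].
#' @param min_conf Minimum confidence fraction in (0, 1].
#' @return List of class `mining_params`.
#' @export
mining_params <- function(min_sup = 0.01, min_conf = 0.5) {
  stopifnot(is.numeric(min_sup), length(min_sup) == 1L,
            min_sup > 0, min_sup <= 1,
            is.numeric(min_conf), length(min_conf) == 1L,
            min_conf > 0, min_conf <= 1)
  structure(list(min_sup = min_sup, min_conf = min_conf),
            class = "mining_params")
}

new_supported_itemsets <- function(keys, counts, n) {
  items <- lapply(keys, key_to_items)
  sizes <- lengths(items)
  ord <- order(sizes, keys, method = "radix")
  df <- data.frame(key = keys[ord], count = as.integer(counts[ord]),
                   support = counts[ord] / n, stringsAsFactors = FALSE)
  df$items <- items[ord]
  attr(df, "n") <- n
  class(df) <- c("supported_itemsets", "data.frame")
  df
}

#' Exhaustive frequent-itemset miner (correctness oracle)
#'
#' Enumerates every nonempty subset of the alphabet and keeps those with
#' support fraction >= `min_sup`.  Exponential in the alphabet, so it
#' refuses alphabets larger than 20 items; it exists as the correctness
#' oracle the level-wise and pattern-growth miners are tested against.
#'
#' @param db A [transaction_db()].
#' @param params A [mining_params()] (only `min_sup` is used).
#' @return Data frame of class `supported_itemsets` with columns `key`,
#'   `count`, `support` and list column `items`, canonically sorted by
#'   (size, key).
#' @export
brute_force_mine <- function(db, params) {
  stopifnot(inherits(db, "transaction_db"), inherits(params, "mining_params"))
  m <- length(db$alphabet)
  if (m > 20L) {
    stop("brute_force_mine: alphabet has ", m,
         " items; refusing exhaustive enumeration beyond 20")
  }
  minc <- min_support_count(db$n, params$min_sup)
  if (m == 0L) return(new_supported_itemsets(character(0), integer(0), db$n))
  # bitmask per transaction over the canonical alphabet
  bit <- 2^(seq_len(m) - 1L)
  tmask <- vapply(db$transactions,
                  function(t) sum(bit[match(t, db$alphabet)]), numeric(1))
  keys <- character(0); counts <- integer(0)
  for (s in seq_len(2^m - 1)) {
    cnt <- sum(bitwAnd(tmask, s) == s)
    if (cnt >= minc) {
      members <- db$alphabet[bitwAnd(s, bit) > 0]
      keys <- c(keys, itemset_key(members))
      counts <- c(counts, cnt)
    }
  }
  new_supported_itemsets(keys, counts, db$n)
}

# Restore the global RNG state after seeded simulation, so generators are
# pure functions of (spec, seed) without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
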