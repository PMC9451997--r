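# Level-wise miners.  All of them share the apriori_gen join/prune step and
# the vectorized candidate counting below, and all are contractually
# equivalent to brute_force_mine (tested); they differ only in how they cut
# down candidate sets or database scans.

count_itemsets <- function(inc, itemsets) {
  # inc: logical incidence matrix with item colnames; itemsets: list of
  # character vectors.  Returns integer support counts.
  vapply(itemsets, function(s) {
    if (length(s) == 1L) sum(inc[, s])
    else sum(rowSums(inc[, s, drop = FALSE]) == length(s))
  }, integer(1))
}

#' Apriori candidate generation (join + prune)
#'
#' Joins pairs of frequent k-itemsets sharing their first k-1 items into
#' (k+1)-candidates, then prunes every candidate having a k-subset that is
#' not frequent (the anti-monotone property).
#'
#' @param frequent_k List of character vectors, all of the same size k >= 1,
#'   each in canonical order.
#' @return List of candidate (k+1)-itemsets in canonical order.
#' @export
apriori_gen <- function(frequent_k) {
  if (length(frequent_k) == 0L) return(list())
  k <- unique(lengths(frequent_k))
  if (length(k) != 1L) stop("apriori_gen: itemsets of mixed sizes")
  freq_keys <- vapply(frequent_k, itemset_key, character(1))
  prefixes <- vapply(frequent_k, function(s) itemset_key(s[-k]), character(1))
  cand <- list()
  for (grp in split(frequent_k, prefixes)) {
    if (length(grp) < 2L) next
    lasts <- sort(vapply(grp, function(s) s[k], character(1)),
                  method = "radix")
    base <- grp[[1L]][-k]
    pairs <- utils::combn(lasts, 2L, simplify = FALSE)
    for (p in pairs) cand[[length(cand) + 1L]] <- c(base, p[1L], p[2L])
  }
  cand <- lapply(cand, canonical_items)
  # prune: every k-subset must be frequent
  keep <- vapply(cand, function(s) {
    subs <- vapply(seq_along(s), function(i) itemset_key(s[-i]), character(1))
    all(subs %in% freq_keys)
  }, logical(1))
  cand[keep]
}

# Shared level-wise engine.  prune_fn(candidates, k) may drop candidates
# before counting (DHP's hash filter); it must never be able to drop a
# truly frequent itemset.  Returns supported_itemsets with an attribute
# "candidate_counts": number of counted candidates at levels 2, 3, ...
levelwise_mine <- function(db, min_count, prune_fn = NULL) {
  inc <- db_incidence(db)
  counts1 <- colSums(inc)
  keep1 <- counts1 >= min_count
  freq <- lapply(db$alphabet[keep1], identity)
  keys <- vapply(freq, itemset_key, character(1))
  counts <- as.integer(counts1[keep1])
  cand_counts <- integer(0)
  level <- freq
  k <- 1L
  while (length(level) > 0L) {
    cand <- apriori_gen(level)
    if (!is.null(prune_fn)) cand <- prune_fn(cand, k + 1L)
    cand_counts <- c(cand_counts, length(cand))
    if (length(cand) == 0L) break
    cnt <- count_itemsets(inc, cand)
    ok <- cnt >= min_count
    level <- cand[ok]
    keys <- c(keys, vapply(level, itemset_key, character(1)))
    counts <- c(counts, as.integer(cnt[ok]))
    k <- k + 1L
  }
  out <- new_supported_itemsets(keys, counts, db$n)
  attr(out, "candidate_counts") <- cand_counts
  out
}

#' Apriori frequent-itemset miner
#'
#' Level-wise search: frequent k-itemsets are joined into (k+1)-candidates
#' ([apriori_gen()]), candidates are counted against the database, and the
#' loop stops when no level survives.
#'
#' @inheritParams brute_force_mine
#' @return `supported_itemsets` identical to [brute_force_mine()]'s output;
#'   attribute `candidate_counts` records the number of candidates counted
#'   at levels 2, 3, ...
#' @export
apriori_mine <- function(db, params) {
  stopifnot(inherits(db, "transaction_db"), inherits(params, "mining_params"))
  levelwise_mine(db, min_support_count(db$n, params$min_sup))
}

# Stable polynomial hash of canonical item indices; DHP fixes no hash
# function, so any deterministic one with the bucket-superset property
# works.
dhp_bucket <- function(itemset, alphabet, bucket_count) {
  idx <- match(itemset, alphabet)
  acc <- 0
  for (i in idx) acc <- (acc * 31 + i) %% bucket_count
  acc + 1L
}

#' DHP (direct hashing and pruning) miner
#'
#' Apriori with a hash filter: while level-k candidates are counted, every
#' (k+1)-subset of each transaction (restricted to frequent 1-items) is
#' hashed into a bucket table; a (k+1)-candidate whose bucket total is
#' below the minimum support count cannot be frequent and is pruned before
#' counting.  Bucket totals over-count true support, so pruning only ever
#' removes infrequent candidates.
#'
#' @inheritParams brute_force_mine
#' @param bucket_count Number of hash buckets (>= 1).
#' @return Same contract as [apriori_mine()], including `candidate_counts`.
#' @export
dhp_mine <- function(db, params, bucket_count = 1024L) {
  stopifnot(inherits(db, "transaction_db"), inherits(params, "mining_params"),
            bucket_count >= 1L)
  minc <- min_support_count(db$n, params$min_sup)
  inc <- db_incidence(db)
  freq1 <- db$alphabet[colSums(inc) >= minc]
  # bucket tables per level, built once from the frequent-1-filtered
  # transactions (every occurrence of a candidate made of frequent items
  # hashes into its bucket, preserving the superset property)
  buckets <- list()
  hash_level <- function(k) {
    if (!is.null(buckets[[as.character(k)]])) return(buckets[[as.character(k)]])
    tab <- numeric(bucket_count)
    for (t in db$transactions) {
      t <- t[t %in% freq1]
      if (length(t) < k) next
      for (s in utils::combn(t, k, simplify = FALSE)) {
        b <- dhp_bucket(s, db$alphabet, bucket_count)
        tab[b] <- tab[b] + 1
      }
    }
    buckets[[as.character(k)]] <<- tab
    tab
  }
  prune <- function(cand, k) {
    if (length(cand) == 0L) return(cand)
    tab <- hash_level(k)
    keep <- vapply(cand, function(s) {
      tab[dhp_bucket(s, db$alphabet, bucket_count)] >= minc
    }, logical(1))
    cand[keep]
  }
  levelwise_mine(db, minc, prune_fn = prune)
}

#' Partition miner (two database scans)
#'
#' Phase 1 splits the transaction list into contiguous segments and mines
#' each segment at the local threshold `ceiling(min_sup * segment_size)`;
#' any itemset frequent over the whole database must be frequent in at
#' least one segment, so the union of local results is a global candidate
#' superset.  Phase 2 recounts that union against the full database.
#'
#' @inheritParams brute_force_mine
#' @param segment_count Number of contiguous segments, in `[1, n]`.
#' @return Same output contract as [brute_force_mine()]; attribute
#'   `phase1_candidates` holds the size of the candidate union.
#' @export
partition_mine <- function(db, params, segment_count = 2L) {
  stopifnot(inherits(db, "transaction_db"), inherits(params, "mining_params"),
            segment_count >= 1L, segment_count <= db$n)
  bounds <- floor(seq(0, db$n, length.out = segment_count + 1L))
  cand_keys <- character(0)
  for (s in seq_len(segment_count)) {
    idx <- (bounds[s] + 1L):bounds[s + 1L]
    seg <- transaction_db(db$transactions[idx])
    local_minc <- ceiling(min_support_count(length(idx), params$min_sup))
    local <- levelwise_mine(seg, max(local_minc, 1))
    cand_keys <- union(cand_keys, local$key)
  }
  inc <- db_incidence(db)
  minc <- min_support_count(db$n, params$min_sup)
  itemsets <- lapply(cand_keys, key_to_items)
  # candidates may reference items absent from some segment but all come
  # from the global alphabet, so direct counting is safe
  cnt <- count_itemsets(inc, itemsets)
  ok <- cnt >= minc
  out <- new_supported_itemsets(cand_keys[ok], cnt[ok], db$n)
  attr(out, "phase1_candidates") <- length(cand_keys)
  attr(out, "phase1_keys") <- cand_keys
  out
}
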