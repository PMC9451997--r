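test_that("apriori_gen joins on shared prefixes and prunes by subsets", {
  ab <- c("A", "B"); ac <- c("A", "C"); bc <- c("B", "C")
  out <- apriori_gen(list(ab, ac, bc))
  expect_equal(out, list(c("A", "B", "C")))
  # no joinable prefix
  expect_equal(apriori_gen(list(c("A", "B"), c("C", "D"))), list())
  # join succeeds but candidate pruned: BC not frequent
  expect_equal(apriori_gen(list(ab, ac)), list())
  expect_error(apriori_gen(list("A", c("A", "B"))), "mixed")
})

test_that("all miners reproduce the brute-force frequent set", {
  for (seed in 1:25) {
    db <- random_db(n_items = sample(4:10, 1), n_trans = sample(8:48, 1),
                    seed = seed)
    params <- with_seed_test(seed, mining_params(runif(1, 0.05, 0.5), 0.5))
    bf <- brute_force_mine(db, params)
    for (out in list(apriori_mine(db, params),
                     dhp_mine(db, params, bucket_count = 64),
                     partition_mine(db, params,
                                    segment_count = sample(2:3, 1)),
                     fp_growth_mine(db, params))) {
      expect_identical(out$key, bf$key)
      expect_identical(out$count, bf$count)
    }
  }
})

test_that("equivalent miners serialize to identical JSON bytes", {
  db <- random_db(n_items = 8, n_trans = 32, seed = 99)
  params <- mining_params(0.15, 0.5)
  js <- vapply(list(brute_force_mine(db, params), apriori_mine(db, params),
                    dhp_mine(db, params), partition_mine(db, params, 2),
                    fp_growth_mine(db, params)),
               itemsets_to_json, character(1))
  expect_length(unique(js), 1)
})

test_that("DHP hash pruning is subtractive and degenerates gracefully", {
  db <- random_db(n_items = 8, n_trans = 40, seed = 5)
  params <- mining_params(0.2, 0.5)
  ap <- apriori_mine(db, params)
  dh <- dhp_mine(db, params, bucket_count = 16)
  cc_ap <- attr(ap, "candidate_counts")
  cc_dh <- attr(dh, "candidate_counts")
  len <- min(length(cc_ap), length(cc_dh))
  expect_true(all(cc_dh[seq_len(len)] <= cc_ap[seq_len(len)]))
  # one bucket: no pruning possible while any itemset can still be frequent
  d1 <- dhp_mine(db, params, bucket_count = 1)
  expect_identical(d1$key, ap$key)
  expect_identical(attr(d1, "candidate_counts")[1], cc_ap[1])
})

test_that("partition phase 1 covers every frequent itemset", {
  for (seed in c(3, 17)) {
    db <- random_db(n_items = 8, n_trans = 36, seed = seed)
    params <- mining_params(0.15, 0.5)
    bf <- brute_force_mine(db, params)
    for (k in c(1, 2, 3)) {
      out <- partition_mine(db, params, segment_count = k)
      expect_identical(out$key, bf$key)
      expect_true(all(bf$key %in% attr(out, "phase1_keys")))
    }
  }
})

test_that("FP-tree prefix structure matches a hand trace", {
  db <- transaction_db(list(c("A", "B"), c("A", "C"), "A"))
  tree <- build_fp_tree(db, mining_params(0.01, 0.5))
  root <- tree$root
  expect_equal(names(root$children), "A")
  a <- root$children[["A"]]
  expect_equal(a$count, 3)
  expect_setequal(names(a$children), c("B", "C"))
  expect_equal(a$children[["B"]]$count, 1)
  expect_equal(a$children[["C"]]$count, 1)
  # single transaction: one path, all counts 1
  t2 <- build_fp_tree(transaction_db(list(c("X", "Y", "Z"))),
                      mining_params(0.5, 0.5))
  node <- t2$root
  while (length(node$children) > 0) {
    expect_length(node$children, 1)
    node <- node$children[[1]]
    expect_equal(node$count, 1)
  }
})

test_that("node-chain counts conserve per-item support", {
  db <- random_db(n_items = 9, n_trans = 40, seed = 21)
  tree <- build_fp_tree(db, mining_params(0.1, 0.5))
  for (item in tree$item_order) {
    chain_total <- sum(vapply(fp_node_chain(tree, item),
                              function(nd) nd$count, numeric(1)))
    expect_equal(chain_total, support_count(db, item))
  }
})

test_that("FP-tree paths reconstruct the filtered sorted transactions", {
  db <- random_db(n_items = 7, n_trans = 24, seed = 8)
  params <- mining_params(0.15, 0.5)
  tree <- build_fp_tree(db, params)
  # collect leaf-to-root paths weighted by count differences
  paths <- list()
  collect <- function(node, prefix) {
    here <- c(prefix, node$item)
    child_total <- sum(vapply(node$children, function(ch) ch$count,
                              numeric(1)), 0)
    expect_gte(node$count, child_total) # child counts sum <= parent count
    rem <- node$count - child_total
    if (rem > 0) {
      paths[[length(paths) + 1L]] <<- list(items = here, w = rem)
    }
    for (ch in node$children) collect(ch, here)
  }
  for (ch in tree$root$children) collect(ch, character(0))
  rebuilt <- unlist(lapply(paths, function(p) {
    rep(paste(p$items, collapse = ","), p$w)
  }))
  expected <- vapply(db$transactions, function(t) {
    paste(sahmine:::filter_sort_transaction(t, tree$item_order),
          collapse = ",")
  }, character(1))
  expected <- expected[nzchar(expected)]
  expect_equal(sort(rebuilt), sort(expected))
})

test_that("all-identical transactions yield the full subset lattice", {
  db <- transaction_db(rep(list(c("A", "B", "C")), 5))
  out <- fp_growth_mine(db, mining_params(0.9, 0.5))
  expect_equal(nrow(out), 7) # 2^3 - 1 subsets, all at count 5
  expect_true(all(out$count == 5))
})

test_that("distinct singletons above threshold mine to nothing", {
  db <- transaction_db(as.list(paste0("S", 1:10)))
  out <- apriori_mine(db, mining_params(0.15, 0.5))
  expect_equal(nrow(out), 0)
})
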