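test_that("rule generation emits exactly the confident subset splits", {
  db <- transaction_db(list(c("A", "B"), c("A", "B"), "A", "B"))
  freq <- brute_force_mine(db, mining_params(0.5, 0.5))
  rules <- generate_rules(freq, db, min_conf = 0.5)
  got <- sort(paste(rules$ant_key, "->", rules$cons_key))
  expect_equal(got, c("A -> B", "B -> A"))
  expect_equal(rules$confidence, c(2 / 3, 2 / 3))
  # min_conf ~ 0 keeps every subset split of every size >= 2 itemset
  all_rules <- generate_rules(freq, db, min_conf = 1e-9)
  expect_equal(nrow(all_rules), 2) # only {A,B} has splits here
  # singleton-only frequent set generates nothing
  singles <- brute_force_mine(transaction_db(list("A", "B")),
                              mining_params(0.5, 0.5))
  expect_equal(nrow(generate_rules(singles, db, 0.5)), 0)
})

test_that("rule generation matches exhaustive enumeration on random dbs", {
  for (seed in c(4, 9, 23)) {
    db <- random_db(n_items = 6, n_trans = 20, seed = seed)
    min_conf <- with_seed_test(seed, runif(1, 0.2, 0.8))
    freq <- brute_force_mine(db, mining_params(0.15, 0.5))
    rules <- generate_rules(freq, db, min_conf)
    expect_equal(rule_strings(rules),
                 rules_by_enumeration(freq, db, min_conf))
    expect_true(all(rules$confidence >= min_conf - 1e-12))
    expect_true(all(rules$support >= 0.15 - 1e-12))
    expect_true(all(rules$confidence >= rules$support))
  }
})

test_that("CAR extraction keeps class consequents and class-free antecedents", {
  db <- binary_table_to_db(table1_fixture())
  cars <- generate_cars(db, mining_params(0.01, 0.5), miner = "apriori")
  key <- paste(cars$ant_key, "->", cars$cons_key)
  hit <- cars[cars$ant_key == "PD=1" & cars$cons_key == "Class=1", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$confidence, 6 / 7)
  expect_true(all(item_attribute(cars$cons_key) == "Class"))
  expect_false(any(vapply(cars$antecedent,
                          function(a) any(item_attribute(a) == "Class"),
                          logical(1))))
  expect_error(generate_cars(random_db(5, 10, 1),
                             mining_params(0.1, 0.5)), "no 'Class='")
})

test_that("CAR fast path equals filtering the full rule set", {
  db <- random_db(n_items = 5, n_trans = 30, seed = 41)
  # attach a class item to each transaction
  tx <- lapply(seq_len(db$n), function(i) {
    c(db$transactions[[i]], paste0("Class=", i %% 2))
  })
  db <- transaction_db(tx)
  params <- mining_params(0.1, 0.4)
  cars <- generate_cars(db, params, miner = "brute")
  freq <- brute_force_mine(db, params)
  full <- generate_rules(freq, db, params$min_conf)
  is_car <- lengths(full$consequent) == 1 &
    item_attribute(full$cons_key) == "Class" &
    !vapply(full$antecedent, function(a) any(item_attribute(a) == "Class"),
            logical(1))
  expect_setequal(paste(cars$ant_key, cars$cons_key),
                  paste(full$ant_key[is_car], full$cons_key[is_car]))
})

test_that("single-class databases only yield that consequent", {
  tx <- with_seed_test(6, lapply(1:12, function(i) {
    c(sample(c("A=1", "B=1"), 1), "Class=1")
  }))
  db <- transaction_db(tx)
  cars <- generate_cars(db, mining_params(0.05, 0.5), miner = "fp")
  expect_true(nrow(cars) >= 1)
  expect_true(all(cars$cons_key == "Class=1"))
})

test_that("NCFP never yields more CARs than FP at identical thresholds", {
  spec <- planted_rule_spec(
    n = 300,
    rules = list(
      list(antecedent = "A=1", class = "Class=1",
           confidence = 0.95, support = 0.4),
      list(antecedent = "B=1", class = "Class=0",
           confidence = 0.95, support = 0.4)),
    n_noise_items = 5, noise_rate = 0.15, seed = 3)
  db <- gen_transactions(spec)
  fp_cars <- generate_cars(db, mining_params(0.01, 0.5), miner = "fp")
  np <- ncfp_params(0.01, min_up = 1.2, weights = class_lift_weights(db))
  ncfp_cars <- generate_cars(db, np, miner = "ncfp")
  expect_lte(nrow(ncfp_cars), nrow(fp_cars))
})

test_that("CAR ranking is total, stable and deterministic", {
  mk <- function(ant, cons, count, sup, conf) {
    r <- sahmine:::new_rules_df(list(ant), list(cons), count, sup, conf)
    r$ant_size <- lengths(r$antecedent)
    class(r) <- c("car_rules", class(r))
    r
  }
  cars <- rbind(mk("A=1", "Class=0", 8, 0.4, 0.8),
                mk("B=1", "Class=1", 9, 0.45, 0.9),
                mk(c("A=1", "C=1"), "Class=1", 6, 0.3, 0.9),
                mk("C=1", "Class=1", 6, 0.3, 0.9),
                mk("D=1", "Class=1", 6, 0.3, 0.9))
  ranked <- rank_cars(cars)
  # confidence first
  expect_equal(ranked$confidence[1], 0.9)
  expect_equal(ranked$ant_key[5], "A=1") # lowest confidence last
  # among conf 0.9: support 0.45 first, then size-1 rules before size-2,
  # canonical key among full ties
  expect_equal(ranked$ant_key[1:4], c("B=1", "C=1", "D=1", "A=1,C=1"))
})
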