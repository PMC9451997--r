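# Shared fixtures: random transaction databases, random normalized GLCMs,
# and independent brute-force oracles for rules and texture features.

random_db <- function(n_items = 8, n_trans = 24, seed = 1) {
  items <- paste0("I", seq_len(n_items), "=1")
  with_seed_test(seed, {
    tx <- lapply(seq_len(n_trans), function(i) {
      sample(items, sample.int(n_items, 1L))
    })
    transaction_db(tx)
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

random_prob_matrix <- function(L, seed) {
  with_seed_test(seed, {
    m <- matrix(stats::rexp(L * L), L, L)
    m / sum(m)
  })
}

# independent double-loop evaluation of the six texture features
features_by_double_loop <- function(p) {
  L <- nrow(p)
  energy <- 0; contrast <- 0; entropy <- 0; ls <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    v <- p[i + 1, j + 1]
    energy <- energy + v^2
    contrast <- contrast + (i - j)^2 * v
    if (v > 0) entropy <- entropy - v * log2(v)
    ls <- ls + v / (1 + (i - j)^2)
    mu_i <- mu_i + i * v
    mu_j <- mu_j + j * v
  }
  var_i <- 0; var_j <- 0; cov_ij <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    v <- p[i + 1, j + 1]
    var_i <- var_i + (i - mu_i)^2 * v
    var_j <- var_j + (j - mu_j)^2 * v
    cov_ij <- cov_ij + (i - mu_i) * (j - mu_j) * v
  }
  corr <- if (var_i * var_j == 0) NA_real_ else cov_ij / sqrt(var_i * var_j)
  c(energy = energy, contrast = contrast, entropy = entropy, mean = mu_i,
    local_stability = ls, correlation = corr)
}

rule_strings <- function(rules) {
  if (nrow(rules) == 0) return(character(0))
  sort(paste(rules$ant_key, "->", rules$cons_key))
}

# exhaustive rule enumeration over frequent itemsets via rule_metrics
rules_by_enumeration <- function(frequent, db, min_conf) {
  out <- character(0)
  for (i in seq_len(nrow(frequent))) {
    t_items <- frequent$items[[i]]
    k <- length(t_items)
    if (k < 2) next
    for (s_size in seq_len(k - 1)) {
      for (idx in utils::combn(k, s_size, simplify = FALSE)) {
        r <- rule_metrics(db, t_items[idx], t_items[-idx])
        if (r$confidence >= min_conf - 1e-12) {
          out <- c(out, paste(r$ant_key, "->", r$cons_key))
        }
      }
    }
  }
  sort(out)
}
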