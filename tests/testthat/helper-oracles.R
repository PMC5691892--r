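# Independent brute-force oracles. These walk the definitions step by step
# with scalar loops and must never share code with the package internals.

# Running-sum enumerator for the weighted KS enrichment score.
oracle_es <- function(metric, hit, weight_p) {
  n <- length(metric)
  n_h <- sum(hit)
  w <- if (weight_p == 0) rep(1, n) else abs(metric)^weight_p
  n_r <- sum(w[hit])
  rs <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- if (hit[i]) cur + w[i] / n_r else cur - 1 / (n - n_h)
    rs[i] <- cur
  }
  best <- 1L
  for (i in seq_len(n)) if (abs(rs[i]) > abs(rs[best]) + 1e-12) best <- i
  list(es = rs[best], peak = best, rs = rs)
}

# Exhaustive single-gene-set permutation null: ES of every size-1 subset.
oracle_null_k1 <- function(metric, weight_p) {
  n <- length(metric)
  vapply(seq_len(n), function(i) {
    hit <- rep(FALSE, n)
    hit[i] <- TRUE
    oracle_es(metric, hit, weight_p)$es
  }, numeric(1))
}

# Exhaustive same-sign tail p for an observed ES against a full null.
oracle_exhaustive_p <- function(es_obs, null_es) {
  if (es_obs > 0) {
    same <- null_es[null_es > 0]
    sum(same >= es_obs) / length(same)
  } else {
    same <- null_es[null_es < 0]
    sum(same <= es_obs) / length(same)
  }
}

# Scalar ssGSEA enumerator: rank one sample's values descending (lexical
# gene-id tie-break), then accumulate the in-set/out-of-set step gap.
oracle_ssgsea <- function(expr, genes, members, alpha) {
  n <- length(expr)
  ord <- order(-expr, genes)
  cum_in <- 0
  cum_out <- 0
  total_w <- 0
  for (j in seq_len(n)) {
    if (genes[ord[j]] %in% members) total_w <- total_w + (n - j + 1)^alpha
  }
  k <- sum(genes %in% members)
  es <- 0
  for (j in seq_len(n)) {
    if (genes[ord[j]] %in% members) {
      cum_in <- cum_in + (n - j + 1)^alpha / total_w
    } else {
      cum_out <- cum_out + 1 / (n - k)
    }
    es <- es + (cum_in - cum_out)
  }
  es
}

# Random ranked list with distinct metric values.
random_ranked <- function(n, seed) {
  set.seed(seed)
  ranked_list(sprintf("g%03d", seq_len(n)),
              sort(rnorm(n), decreasing = TRUE))
}

# Small annotated expression matrix fixture.
random_expr <- function(n_genes, sizes, seed, sd = 0.5) {
  set.seed(seed)
  n <- sum(sizes)
  v <- matrix(rnorm(n_genes * n, mean = 8, sd = sd), n_genes, n,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n))))
  expression_matrix(v, groups = rep(names(sizes), times = sizes))
}
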