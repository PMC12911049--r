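# Independent textbook-formula oracles used across the suite.  These are
# deliberately naive (explicit loops, no shared code with the package) so
# they can arbitrate the vectorized implementations.

# step-up false-discovery-rate adjustment, straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  sapply(seq_len(m), function(i) {
    min(1, min(m * p[p >= p[i] | r >= r[i]] /
                 r[p >= p[i] | r >= r[i]]))
  })
}

# product-limit estimator, one group, evaluated at each distinct time
km_oracle <- function(time, status) {
  ut <- sort(unique(time))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & status == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}

# two-group log-rank statistic from the O/E/V table
logrank_oracle <- function(time, status, g1) {
  O <- E <- V <- 0
  for (u in sort(unique(time[status == 1]))) {
    n <- sum(time >= u)
    n1 <- sum(time >= u & g1)
    d <- sum(time == u & status == 1)
    d1 <- sum(time == u & status == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * n1 * (n - n1) * (n - d) / (n^2 * (n - 1))
  }
  if (V > 0) (O - E)^2 / V else 0
}

# Efron-tie Cox partial log-likelihood for a single covariate, written as
# the per-event-time double sum
efron_loglik_oracle <- function(beta, time, status, x) {
  ll <- 0
  for (u in sort(unique(time[status == 1]))) {
    dead <- which(time == u & status == 1)
    risk <- which(time >= u)
    d <- length(dead)
    ll <- ll + sum(beta * x[dead])
    for (j in seq_len(d)) {
      denom <- sum(exp(beta * x[risk])) -
        (j - 1) / d * sum(exp(beta * x[dead]))
      ll <- ll - log(denom)
    }
  }
  ll
}

# exact upper-tail hypergeometric probability as a pmf sum
hyper_tail_oracle <- function(N, K, n, k) {
  if (k <= 0) return(1)
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (feasible for small groups)
wilcox_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  ws <- apply(combos, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# small random survival dataset with ties and censoring
random_surv_data <- function(n, seed) {
  set.seed(seed)
  list(time = sample(1:6, n, replace = TRUE),
       status = rbinom(n, 1, 0.7),
       group = sample(c("a", "b"), n, replace = TRUE))
}

# tiny deterministic cohort helper for DE tests
small_cohort <- function(seed = 1, n_per_sex = 30, n_genes = 20, ...) {
  cc <- cohort_config(n_male_tumor = n_per_sex, n_female_tumor = n_per_sex,
                      n_male_normal = 2, n_female_normal = 2,
                      n_genes = n_genes, n_mirnas = 5,
                      n_planted_pairs = 0, seed = seed, ...)
  generate_bulk(cc)
}
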