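# Independent brute-force oracles used to validate the package's statistics.
# These deliberately avoid the code paths (and where possible the base
# functions) used by the implementation.

# average ranks by explicit counting: rank_i = #{x_j < x_i} + (ties + 1)/2
oracle_avg_rank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    below <- sum(x < x[i])
    ties <- sum(x == x[i])
    r[i] <- below + (ties + 1) / 2
  }
  r
}

# Pearson on oracle ranks via explicit sum formulas
oracle_spearman_rho <- function(x, y) {
  rx <- oracle_avg_rank(x); ry <- oracle_avg_rank(y)
  n <- length(x)
  sx <- sum(rx); sy <- sum(ry)
  num <- n * sum(rx * ry) - sx * sy
  den <- sqrt(n * sum(rx^2) - sx^2) * sqrt(n * sum(ry^2) - sy^2)
  num / den
}

# BH step-through on the sorted vector, mapped back to input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  running_min <- Inf
  for (i in m:1) {
    running_min <- min(running_min, p[o[i]] * m / i)
    q_sorted[i] <- min(running_min, 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# product-limit estimator by explicit loop
oracle_km <- function(times, events) {
  et <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = numeric(0), survival = numeric(0))
  for (t in et) {
    n_i <- sum(times >= t)
    d_i <- sum(times == t & events == 1)
    s <- s * (1 - d_i / n_i)
    out <- rbind(out, data.frame(time = t, survival = s))
  }
  out
}

# weighted running-sum enrichment score by explicit walk
oracle_es <- function(metric_sorted, geneset, w = 1) {
  genes <- names(metric_sorted)
  N <- length(genes)
  hit <- genes %in% geneset
  denom <- sum(abs(metric_sorted[hit])^w)
  miss_step <- 1 / (N - sum(hit))
  rs <- 0; best <- 0
  for (i in seq_len(N)) {
    rs <- if (hit[i]) rs + abs(metric_sorted[i])^w / denom else rs - miss_step
    if (abs(rs) > abs(best)) best <- rs
  }
  unname(best)
}

# random survival cohort with ties and censoring
random_cohort <- function(n, tie_prob = 0.3) {
  times <- ceiling(rexp(n, 1 / 20))
  if (tie_prob > 0) times <- pmax(1, round(times / sample(1:3, 1)))
  events <- rbinom(n, 1, 0.7)
  list(times = as.numeric(times), events = events)
}

make_gem <- function(values) {
  if (is.null(rownames(values)))
    dimnames(values) <- list(sprintf("g%03d", seq_len(nrow(values))),
                             sprintf("c%03d", seq_len(ncol(values))))
  gene_effect_matrix(values)
}
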