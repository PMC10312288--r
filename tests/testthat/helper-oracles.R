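# Independent brute-force oracles. These deliberately use naive loops and
# explicit tabulation so they share no code path with the package
# implementations they check.

# conMI by explicit 2x2 tabulation over t = 1..T-1
oracle_conmi <- function(x, y) {
  Tn <- length(x) - 1
  counts <- matrix(0, 2, 2) # [i_state+1, jhat_state+1]
  for (t in seq_len(Tn)) {
    jhat <- if (y[t] == 1 || y[t + 1] == 1) 1 else 0
    counts[x[t] + 1, jhat + 1] <- counts[x[t] + 1, jhat + 1] + 1
  }
  total <- 0
  for (a in 1:2) {
    for (b in 1:2) {
      p_ab <- counts[a, b] / Tn
      p_a <- sum(counts[a, ]) / Tn
      p_b <- sum(counts[, b]) / Tn
      if (p_ab > 0) total <- total + p_ab * log2(p_ab / (p_a * p_b))
    }
  }
  total
}

# GAS by naive double loop over all ordered pairs
oracle_gas <- function(m, n) {
  num <- 0
  den <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (i == j) next
      num <- num + min(m[i, j], n[i, j])
      den <- den + m[i, j] + n[i, j]
    }
  }
  2 * num / den
}

# weighted reciprocity by naive double loop
oracle_reciprocity <- function(w) {
  recip <- 0
  total <- 0
  for (i in seq_len(nrow(w))) {
    for (j in seq_len(ncol(w))) {
      if (i == j) next
      recip <- recip + min(w[i, j], w[j, i])
      total <- total + w[i, j]
    }
  }
  recip / total
}

# percentile threshold via an explicit sort-based quantile (R type-7)
oracle_threshold <- function(w, percentile) {
  nz <- sort(w[w > 0 & row(w) != col(w)])
  h <- (length(nz) - 1) * percentile / 100
  lo <- floor(h) + 1
  thr <- nz[lo] + (h - floor(h)) * (nz[min(lo + 1, length(nz))] - nz[lo])
  out <- w
  out[out < thr] <- 0
  diag(out) <- 0
  out
}

# random non-negative weighted directed adjacency with zero diagonal
random_fn_matrix <- function(n, density = 0.6) {
  w <- matrix(runif(n * n), n, n) * (matrix(runif(n * n), n, n) < density)
  diag(w) <- 0
  w
}

# small cohorts are expensive; build each configuration once per test run
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(name, config) {
  if (!exists(name, envir = .cohort_cache))
    assign(name, generate_cohort(config), envir = .cohort_cache)
  get(name, envir = .cohort_cache)
}

# workhorse fixture: injected direction-specific correlations, modest size
fixture_cohort <- function() {
  cached_cohort("fixture", cohort_config(
    n_units = 16L, n_trials_per_direction = 6L, assembly_size = 24L,
    corr_strength = 0.35, seed = 42L))
}

# matched null world: same size, no injected correlation, no tuning
fixture_null_cohort <- function() {
  cached_cohort("null", cohort_config(
    n_units = 16L, n_trials_per_direction = 6L, assembly_size = 24L,
    corr_strength = 0, tuning_depth = 0, seed = 43L))
}

# more trials per direction for trial-pair-hungry timeline statistics
# (the stated world is 30/direction; 20 is the desk-scale compromise)
fixture_big_cohort <- function() {
  cached_cohort("big", cohort_config(
    n_units = 16L, n_trials_per_direction = 20L, assembly_size = 24L,
    corr_strength = 0.35, seed = 44L))
}

# injected transient reciprocity drop. Strictly causal (lag-1) injections:
# same-bin co-spikes elevate conMI in both directions at once, which makes
# a directed "reverse leg" ill-defined; and small direction assemblies so
# their post-Instruction onset does not swamp the background scaffold.
fixture_dip_cohort <- function() {
  cached_cohort("dip", cohort_config(
    n_units = 16L, n_trials_per_direction = 12L, assembly_size = 8L,
    corr_strength = 0.6, corr_lag_bins = 1L, reciprocity_dip = 0.75,
    seed = 45L))
}
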