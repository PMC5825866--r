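# Independent oracles, deliberately naive: these re-derive each quantity from
# first principles so the implementation under test shares no code with them.

# Hypergeometric upper tail by explicit summation of point probabilities.
oracle_fisher_p <- function(a, b, c, d) {
  n_univ <- a + b + c + d
  k_tissue <- a + c
  n_query <- a + b
  js <- seq(a, min(k_tissue, n_query))
  sum(choose(k_tissue, js) * choose(n_univ - k_tissue, n_query - js)) /
    choose(n_univ, n_query)
}

# Benjamini-Hochberg step-up written out literally.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, p[o] * m / seq_len(m))
  for (i in rev(seq_len(m - 1))) {
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Asymmetric binary dissimilarity by explicit a/b/c enumeration.
oracle_binary <- function(x, y) {
  a <- 0; b <- 0; cc <- 0
  for (i in seq_along(x)) {
    if (x[i] == 1 && y[i] == 1) a <- a + 1
    else if (x[i] == 1) b <- b + 1
    else if (y[i] == 1) cc <- cc + 1
  }
  (b + cc) / (a + b + cc)
}

# Pooled two-sample Student's t from the textbook closed form.
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tt, df = nx + ny - 2, p = 2 * pt(-abs(tt), nx + ny - 2))
}

# A tiny noiseless flat-baseline compendium where planted markers are exactly
# the per-tissue top genes; used wherever exact recovery must be decidable.
flat_sim <- function(n_tissues = 10, n_genes = 1000, markers_per_tissue = 50,
                     seed = 1) {
  simulate_compendium(
    n_tissues = n_tissues, n_genes = n_genes,
    markers_per_tissue = markers_per_tissue, marker_elevation = 10,
    baseline_log_sd = 0, noise_sd = 0, seed = seed
  )
}
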