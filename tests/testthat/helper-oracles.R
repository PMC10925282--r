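# Independent brute-force oracles and small fixture builders used across the
# test files. The oracles are deliberately written as literal loop
# transcriptions of the defining formulas, independent of the vectorized
# implementation paths they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_sequence <- function(n, letters = AA20) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Moran autocorrelation straight from its definition, all sums as loops.
oracle_moran <- function(sequence, scale_values, d) {
  chars <- strsplit(sequence, "")[[1]]
  m <- as.numeric(scale_values[chars])
  n <- length(m)
  mbar <- sum(m) / n
  num <- 0
  for (i in seq_len(n - d)) {
    num <- num + (m[i] - mbar) * (m[i + d] - mbar)
  }
  num <- num / (n - d)
  den <- 0
  for (i in seq_len(n)) den <- den + (m[i] - mbar)^2
  den <- den / n
  if (den == 0) return(0)
  num / den
}

# Pseudo amino-acid composition transcribed term by term from the published
# closed form (composition fractions + lambda sequence-order tiers over
# hydrophobicity, hydrophilicity and side-chain mass, weight w).
oracle_paac <- function(sequence, lambda, w) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  norm20 <- function(v) (v - mean(v)) / sqrt(sum((v - mean(v))^2) / 20)
  h1 <- norm20(property_scale("PAACHydrophobicity"))
  h2 <- norm20(property_scale("PAACHydrophilicity"))
  ms <- norm20(property_scale("SideChainMass"))
  theta <- numeric(lambda)
  for (k in seq_len(lambda)) {
    acc <- 0
    for (i in seq_len(n - k)) {
      a <- chars[i]; b <- chars[i + k]
      acc <- acc + ((h1[a] - h1[b])^2 + (h2[a] - h2[b])^2 +
                      (ms[a] - ms[b])^2) / 3
    }
    theta[k] <- acc / (n - k)
  }
  f <- vapply(AA20, function(a) sum(chars == a) / n, numeric(1))
  denom <- 1 + w * sum(theta)
  unname(c(f / denom, w * theta / denom))
}

oracle_apaac <- function(sequence, lambda, w) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  norm20 <- function(v) (v - mean(v)) / sqrt(sum((v - mean(v))^2) / 20)
  h1 <- norm20(property_scale("PAACHydrophobicity"))
  h2 <- norm20(property_scale("PAACHydrophilicity"))
  tau <- numeric(2 * lambda)
  for (k in seq_len(lambda)) {
    a1 <- 0; a2 <- 0
    for (i in seq_len(n - k)) {
      a1 <- a1 + h1[chars[i]] * h1[chars[i + k]]
      a2 <- a2 + h2[chars[i]] * h2[chars[i + k]]
    }
    tau[2 * k - 1] <- a1 / (n - k)
    tau[2 * k] <- a2 / (n - k)
  }
  f <- vapply(AA20, function(a) sum(chars == a) / n, numeric(1))
  denom <- 1 + w * sum(tau)
  unname(c(f / denom, w * tau / denom))
}

# CTD from the class tables, computed per definition with explicit loops.
oracle_ctd_property <- function(sequence, groups) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  cls <- integer(n)
  for (k in 1:3) {
    cls[chars %in% strsplit(groups[k], "")[[1]]] <- k
  }
  comp <- c(sum(cls == 1), sum(cls == 2), sum(cls == 3)) / n
  t12 <- 0; t13 <- 0; t23 <- 0
  for (i in seq_len(n - 1)) {
    pr <- sort(c(cls[i], cls[i + 1]))
    if (pr[1] == 1 && pr[2] == 2) t12 <- t12 + 1
    if (pr[1] == 1 && pr[2] == 3) t13 <- t13 + 1
    if (pr[1] == 2 && pr[2] == 3) t23 <- t23 + 1
  }
  trans <- c(t12, t13, t23) / (n - 1)
  dist <- c()
  for (k in 1:3) {
    pos <- which(cls == k)
    cnt <- length(pos)
    for (q in c(0, 0.25, 0.5, 0.75, 1)) {
      v <- if (cnt == 0) 0 else {
        idx <- if (q == 0) 1 else max(1, floor(q * cnt))
        100 * pos[idx] / n
      }
      dist <- c(dist, v)
    }
  }
  c(comp, trans, dist)
}

# Small planted-signal regression fixture: y depends on one known column.
planted_rows <- function(n = 80, p = 12, signal_col = 7, beta = 2,
                         seed = 42) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    prob <- plogis(beta * x[, signal_col])
    y <- rbinom(n, 1, prob)
    list(x = x, y = y)
  })
}

# A tiny synthetic design matrix built once per test file when needed.
small_sim_design <- function(seed = 7, n_proteins = 120,
                             n_pairs_per_class = 120, effect_size = 6) {
  cfg <- synthetic_config(n_proteins = n_proteins,
                          n_pairs_per_class = n_pairs_per_class,
                          effect_size = effect_size, seed = seed)
  sim <- simulate_ppi_dataset(cfg)
  feats <- suppressMessages(
    compute_descriptors(sim$proteins, descriptor_config(families = "DPC")))
  norm <- fit_normalization(feats)
  design <- suppressMessages(
    build_design_matrix(sim$pairs, apply_normalization(feats, norm)))
  list(sim = sim, design = design)
}
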