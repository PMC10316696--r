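# Shared fixtures, all built in code.

# Small all-continuous dataset with reproducible Gaussian values.
tiny_dataset <- function(n = 20, m = 5, seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(n * m), n, m)
  meta <- lapply(paste0("v", seq_len(m)), variable_meta, kind = "continuous")
  kd_dataset(vals, meta)
}

# Mixed dataset: continuous columns plus one ordinal column derived by
# thresholding a latent Gaussian, so cont/ordinal associations exist.
mixed_dataset <- function(n = 300, seed = 2) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  lat <- x1 + 0.5 * rnorm(n)
  ord <- cut(lat, breaks = c(-Inf, -0.5, 0.5, Inf), labels = FALSE) - 1
  meta <- list(variable_meta("x1"), variable_meta("x2"),
               variable_meta("grade", "ordinal", c("low", "mid", "high")))
  kd_dataset(cbind(x1, x2, ord), meta)
}

# Columns with exactly zero sample correlation and unit sample variance
# (whitened), for closed-form likelihood identities.
whitened_matrix <- function(n = 100, m = 2, seed = 3) {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m)
  x <- sweep(x, 2, colMeans(x))
  x %*% backsolve(chol(crossprod(x) / n), diag(m))
}

# Fast network settings for unit tests.
fast_net <- function(seed = 1, epochs = 40, ...) {
  net_config(epochs = epochs, seed = seed, ...)
}

# Brute-force knockoff threshold: try every candidate t by enumeration.
brute_threshold <- function(S, q, plus) {
  cand <- sort(unique(abs(S[S != 0])))
  off <- if (plus) 1 else 0
  for (t in cand) {
    if ((off + sum(S <= -t)) / max(1, sum(S >= t)) <= q) return(t)
  }
  Inf
}
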