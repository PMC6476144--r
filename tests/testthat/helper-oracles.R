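# Shared oracles and fixtures, all built in code.

# adjusted Rand index between two label vectors (Hubert & Arabie)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# exhaustive global optimum of 2-means inertia over all 2-partitions
brute_force_2means <- function(m) {
  n <- nrow(m)
  stopifnot(n >= 2, n <= 12)
  best <- Inf
  ss <- function(x) {
    if (nrow(x) == 0) return(0)
    mu <- colMeans(x)
    sum(sweep(x, 2, mu)^2)
  }
  for (code in 1:(2^(n - 1) - 1)) {
    in1 <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    v <- ss(m[in1, , drop = FALSE]) + ss(m[!in1, , drop = FALSE])
    if (v < best) best <- v
  }
  best
}

# compact noisy phantom used across tests (kept at the package defaults so
# tests exercise the stated study conditions)
default_phantom <- function(seed = 1, ...) {
  generate_phantom(phantom_spec(seed = seed, ...))
}

truth_roles <- function(truth) {
  ifelse(truth$inner_mask[truth$node_mask], "inner", "outer")
}

node_mask_of <- function(truth) roi_mask(truth$node_mask, "node")
muscle_mask_of <- function(truth) roi_mask(truth$muscle_mask, "muscle")

nde_of <- function(ph) {
  compute_nde(ph$series, node_mask_of(ph$truth), muscle_mask_of(ph$truth))
}
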