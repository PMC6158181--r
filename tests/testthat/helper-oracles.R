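# Fixture builders and independent brute-force oracles.

# Network with m alters and a row-major 0/1/2 pair-code vector.
toy_net <- function(m, ties = NULL, total = m, id = "ego1") {
  ego_network(id, total, alter_table(m), ties)
}

# Row-major pair index (i < j) for m alters.
pairs_of <- function(m) {
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# All binary alter-alter graphs on m alters, as row-major tie vectors.
all_tie_vectors <- function(m) {
  np <- m * (m - 1) / 2
  if (np == 0) return(list(integer(0)))
  lapply(seq_len(2^np) - 1L, function(code) {
    as.integer(intToBits(code)[seq_len(np)])
  })
}

# Burt constraint of vertex 1 by direct triple loop over the definition.
constraint_oracle <- function(w) {
  stopifnot(isSymmetric(w))
  p <- sweep(w, 1, rowSums(w), "/")
  n <- nrow(w)
  total <- 0
  for (j in 2:n) {
    c_ej <- p[1, j]
    for (q in 2:n) {
      if (q != j) c_ej <- c_ej + p[1, q] * p[q, j]
    }
    total <- total + c_ej^2
  }
  total
}

# Burt effective size of vertex 1 (ego) by the full redundancy sum:
# sum_j [1 - sum_q p_eq m_jq], q over alters != j, m_jq = w_jq / max_k w_jk.
effective_size_oracle <- function(w) {
  n <- nrow(w)
  p <- sweep(w, 1, rowSums(w), "/")
  total <- 0
  for (j in 2:n) {
    red <- 0
    for (q in 2:n) {
      if (q == j) next
      mjq <- if (max(w[j, -j]) > 0) w[j, q] / max(w[j, -j]) else 0
      red <- red + p[1, q] * mjq
    }
    total <- total + (1 - red)
  }
  total
}

# full (1+m) binary weight matrix from a row-major pair vector
full_weight_matrix <- function(m, ties) {
  w <- matrix(0, 1 + m, 1 + m)
  w[1, -1] <- w[-1, 1] <- 1
  if (m >= 2 && length(ties)) {
    pr <- pairs_of(m)
    on <- ties > 0
    w[cbind(pr[on, 1] + 1, pr[on, 2] + 1)] <- 1
    w[cbind(pr[on, 2] + 1, pr[on, 1] + 1)] <- 1
  }
  w
}

# small cohort fixture shared across io/cli tests
small_sim <- function(n = 25, seed = 42, preset = "paper-like", ...) {
  generate_cohort(preset_params(preset, n = n, seed = seed, ...))
}
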