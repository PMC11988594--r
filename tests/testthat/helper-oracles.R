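# Independent oracles used across the suite. These deliberately re-derive
# results with naive loops / closed forms, separate from the package's
# vectorized implementations.

# Plain-loop forward pass for a single input vector: cross-correlation with
# valid padding, ReLU, non-overlapping max pools (trailing remainder
# dropped), channel-fastest flatten, dense layers, softmax.
naive_cnn_forward <- function(model, x) {
  cfg <- model$config
  w <- model$weights
  k <- cfg$kernel_len
  f1 <- cfg$conv_filters[1]
  f2 <- cfg$conv_filters[2]
  l1 <- cfg$input_len - k + 1
  a1 <- matrix(0, l1, f1)
  for (f in seq_len(f1)) {
    for (t in seq_len(l1)) {
      acc <- w$b1[f]
      for (kk in seq_len(k)) acc <- acc + x[t + kk - 1] * w$w1[kk, f]
      a1[t, f] <- max(acc, 0)
    }
  }
  p1n <- l1 %/% cfg$pool_len
  p1 <- matrix(0, p1n, f1)
  for (f in seq_len(f1)) {
    for (t in seq_len(p1n)) {
      p1[t, f] <- max(a1[((t - 1) * cfg$pool_len + 1):(t * cfg$pool_len), f])
    }
  }
  l2 <- p1n - k + 1
  a2 <- matrix(0, l2, f2)
  for (g in seq_len(f2)) {
    for (t in seq_len(l2)) {
      acc <- w$b2[g]
      for (kk in seq_len(k)) {
        for (cc in seq_len(f1)) {
          acc <- acc + p1[t + kk - 1, cc] * w$w2[kk, cc, g]
        }
      }
      a2[t, g] <- max(acc, 0)
    }
  }
  p2n <- l2 %/% cfg$pool_len
  p2 <- matrix(0, p2n, f2)
  for (g in seq_len(f2)) {
    for (t in seq_len(p2n)) {
      p2[t, g] <- max(a2[((t - 1) * cfg$pool_len + 1):(t * cfg$pool_len), g])
    }
  }
  flat <- numeric(p2n * f2)
  for (t in seq_len(p2n)) {
    for (g in seq_len(f2)) flat[(t - 1) * f2 + g] <- p2[t, g]
  }
  z3 <- numeric(cfg$dense_units)
  for (u in seq_len(cfg$dense_units)) {
    z3[u] <- max(sum(flat * w$w3[, u]) + w$b3[u], 0)
  }
  z4 <- numeric(cfg$n_classes)
  for (cl in seq_len(cfg$n_classes)) {
    z4[cl] <- sum(z3 * w$w4[, cl]) + w$b4[cl]
  }
  ez <- exp(z4 - max(z4))
  ez / sum(ez)
}

# Studentized-range quantile for k = 2 groups via the exact closed form
# q = sqrt(2) * t_{1 - alpha/2, df} (the two-group range test is a t test).
stud_range_q2 <- function(alpha, df) {
  sqrt(2) * qt(1 - alpha / 2, df)
}

# Mann-Whitney AUC by brute-force pair counting (half credit for ties).
pair_count_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Hand-built toy value models for Shapley tests (matrix in, matrix out).
toy_linear <- function(w, b = 0) {
  function(X) cbind(X %*% w + b)
}
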