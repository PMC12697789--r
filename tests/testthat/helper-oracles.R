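# Independent brute-force oracles shared across test files.

# hand-coded reference: softmax attention + residual layer norms, written
# with explicit loops, independent of the package's graph engine
oracle_mab <- function(p, X, Y, heads) {
  dh <- ncol(X) / heads
  softmax <- function(v) { e <- exp(v - max(v)); e / sum(e) }
  ln <- function(M, eps = 1e-5) {
    t(apply(M, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps)))
  }
  O <- NULL
  for (h in seq_len(heads)) {
    Q <- X %*% p$Wq[[h]]; K <- Y %*% p$Wk[[h]]; V <- Y %*% p$Wv[[h]]
    Oh <- matrix(0, nrow(X), dh)
    for (i in seq_len(nrow(X))) {
      a <- softmax(as.numeric(Q[i, ] %*% t(K)) / sqrt(dh))
      for (j in seq_len(nrow(Y))) Oh[i, ] <- Oh[i, ] + a[j] * V[j, ]
    }
    O <- cbind(O, Oh)
  }
  H <- ln(X + O %*% p$Wo)
  ff <- pmax(sweep(H %*% p$ff$W1, 2, p$ff$b1[1, ], "+"), 0)
  ln(H + sweep(ff %*% p$ff$W2, 2, p$ff$b2[1, ], "+"))
}

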