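# shared fixture builders and independent oracles

tiny_design <- function(n_rep = 2, doses = c(0, 1000), days = c(1, 3)) {
  make_design(n_rep, doses, days)
}

# brute-force Q2 by explicit segment refits, independent of q2_cv's
# internals: refit scaling + PLS without each round-robin segment, predict
# the held-out samples, accumulate PRESS per component count
oracle_q2 <- function(X, Y, ncomp, nseg = 7, mode = "pareto") {
  n <- nrow(X)
  seg <- (seq_len(n) - 1) %% nseg
  press <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    for (k in unique(seg)) {
      tr <- seg != k
      sc <- scale_matrix(X[tr, , drop = FALSE], scaling_spec(mode))
      ym <- mean(Y[tr])
      fit <- fit_pls(sc$X, Y[tr] - ym, a)
      Xte <- sweep(sweep(X[!tr, sc$kept, drop = FALSE], 2, sc$centers),
                   2, sc$scales, "/")
      press[a] <- press[a] + sum((Y[!tr] - (predict(fit, Xte) + ym))^2)
    }
  }
  sc <- scale_matrix(X, scaling_spec(mode))
  fit <- fit_pls(sc$X, Y - mean(Y), ncomp)
  ss0 <- sum((Y - mean(Y))^2)
  ss_prev <- (ss0 * (1 - c(0, fit$r2y_cum)))[seq_len(ncomp)]
  list(q2 = 1 - press / ss_prev, q2_cum = 1 - prod(press / ss_prev))
}

# exhaustive hypergeometric upper tail by enumerating every possible draw
oracle_hyper <- function(N, K, n, k_obs) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # members 1..K form the term
  mean(hits >= k_obs)
}

# naive average-linkage agglomeration on a distance matrix, recording
# merge heights
oracle_average_linkage_heights <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestd <- Inf
    idx <- which(active)
    for (i in idx) for (j in idx) if (i < j) {
      dd <- mean(D[members[[i]], members[[j]], drop = FALSE])
      if (dd < bestd) { bestd <- dd; best <- c(i, j) }
    }
    heights[step] <- bestd
    members[[best[1]]] <- c(members[[best[1]]], members[[best[2]]])
    active[best[2]] <- FALSE
  }
  heights
}

random_xy <- function(n, p, seed, beta_scale = 1, noise = 0.3) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
    beta <- rnorm(p) * beta_scale
    y <- as.numeric(X %*% beta) + rnorm(n, 0, noise)
    list(X = X, y = y)
  })
}
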