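# Independent brute-force oracles used to pin expected values. These
# deliberately avoid the package's own code paths.

# Naive trailing-window mean of |x| at each output frame.
oracle_mav <- function(x, fs, frame_rate, window_ms) {
  w <- round(window_ms * fs / 1000)
  n_frames <- floor(length(x) * frame_rate / fs)
  sapply(seq_len(n_frames), function(k) {
    end <- round(k * fs / frame_rate)
    start <- max(end - w + 1, 1)
    mean(abs(x[start:end]))
  })
}

# Textbook covariance-form Kalman recursion (predict/update).
oracle_kf <- function(A, W, H, Q, Z, x0, P0) {
  x <- x0
  P <- P0
  out <- matrix(0, length(x0), ncol(Z))
  I <- diag(length(x0))
  for (t in seq_len(ncol(Z))) {
    xp <- A %*% x
    Pp <- A %*% P %*% t(A) + W + 1e-9 * I
    S <- H %*% Pp %*% t(H) + Q + 1e-10 * diag(nrow(H))
    K <- Pp %*% t(H) %*% solve(S)
    x <- xp + K %*% (Z[, t] - H %*% xp)
    P <- (I - K %*% H) %*% Pp
    out[, t] <- x
  }
  out
}

# Score used by the forward-selection criterion, restated independently.
oracle_gs_score <- function(r, Y) {
  sum(apply(Y, 1, function(y) {
    if (sd(y) == 0 || sd(r) == 0) 0 else cor(r, y)^2
  }))
}

# Exhaustive search over ordered channel pairs with Gram-Schmidt
# residualization, same criterion.
oracle_gs_best_pair <- function(X, Y) {
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  n <- nrow(X)
  best <- NULL
  best_score <- -Inf
  for (i in seq_len(n)) {
    si <- oracle_gs_score(Xc[i, ], Yc)
    u <- Xc[i, ] / sqrt(sum(Xc[i, ]^2))
    for (j in setdiff(seq_len(n), i)) {
      r <- Xc[j, ] - sum(Xc[j, ] * u) * u
      total <- si + oracle_gs_score(r, Yc)
      if (total > best_score + 1e-12) {
        best_score <- total
        best <- c(i, j)
      }
    }
  }
  best
}

# Closed-form OLS slope/intercept from the normal equations.
oracle_ols <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  c(slope = slope, intercept = (sy - slope * sx) / n)
}

# Kruskal-Wallis H from rank arithmetic (with tie correction).
oracle_kw_H <- function(groups) {
  all_v <- unlist(groups)
  r <- rank(all_v)
  n <- length(all_v)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(all_v)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# First two principal axes via eigendecomposition of the covariance matrix.
oracle_pca_eig <- function(X) {   # X: observations x variables
  C <- cov(X)
  e <- eigen(C, symmetric = TRUE)
  list(vectors = e$vectors[, 1:2],
       var_frac = e$values[1:2] / sum(e$values))
}
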