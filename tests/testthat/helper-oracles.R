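# Brute-force / independent oracles used across the suite. These are kept
# deliberately naive (explicit loops, direct least squares) so they share no
# code path with the package implementations they check.

# exhaustive Otsu: try every candidate bin-edge cut, compute the two groups'
# between-class variance directly from binned pixel values
otsu_brute <- function(image, levels = 256L) {
  v <- as.vector(image)
  rng <- range(v)
  edges <- seq(rng[1], rng[2], length.out = levels + 1L)
  bin <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  centers <- (edges[-1] + edges[-(levels + 1L)]) / 2
  vals <- centers[bin]
  best_t <- NA; best_s <- -Inf
  for (t in 1:(levels - 1L)) {
    lo <- vals[bin <= t]; hi <- vals[bin > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(vals); w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best_s) { best_s <- s; best_t <- t }
  }
  edges[best_t + 1L]
}

# SPA chain recomputed with an explicit orthogonal-projection matrix at every
# step (QR of the selected columns), instead of in-place deflation
spa_chain_brute <- function(X, start_band, max_len) {
  X <- sweep(as.matrix(X), 2, colMeans(X))
  chain <- as.integer(start_band)
  while (length(chain) < max_len) {
    S <- X[, chain, drop = FALSE]
    qrS <- qr(S)
    Q <- qr.Q(qrS)[, seq_len(qrS$rank), drop = FALSE]
    P <- diag(nrow(X)) - Q %*% t(Q)
    norms <- rep(-Inf, ncol(X))
    for (j in seq_len(ncol(X)))
      if (!(j %in% chain)) norms[j] <- sqrt(sum((P %*% X[, j])^2))
    if (max(norms) <= max(abs(X)) * 1e-10) break
    chain <- c(chain, which.max(norms))
  }
  chain
}

# synchronous spectrum via explicit double loop over wavelength pairs
sync_brute <- function(series) {
  m <- nrow(series); B <- ncol(series)
  dyn <- series
  for (j in seq_len(B)) dyn[, j] <- series[, j] - mean(series[, j])
  phi <- matrix(NA_real_, B, B)
  for (a in seq_len(B)) for (b in seq_len(B))
    phi[a, b] <- sum(dyn[, a] * dyn[, b]) / (m - 1)
  phi
}

# naive greedy Kennard-Stone on one class: O(n^2) distance rescan each step
ks_brute <- function(X, n_sel) {
  n <- nrow(X)
  d2 <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- c(1L, 2L); bd <- -Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (d2(i, j) > bd) { bd <- d2(i, j); best <- c(i, j) }
  sel <- best
  while (length(sel) < n_sel) {
    cand <- setdiff(seq_len(n), sel)
    md <- sapply(cand, function(i) min(sapply(sel, function(j) d2(i, j))))
    sel <- c(sel, cand[which.max(md)])
  }
  sort(sel)
}

# direct per-window cubic least-squares fit evaluated at the window centre
# (interior points only; endpoints left as-is)
sg53_window_brute <- function(y) {
  n <- length(y)
  out <- y
  x <- 1:5
  for (i in 3:(n - 2)) {
    w <- y[(i - 2):(i + 2)]
    fit <- lm(w ~ x + I(x^2) + I(x^3))
    out[i] <- unname(fitted(fit)[3])
  }
  out
}

# deterministic stratified folds, re-derived independently for oracle CV
folds_oracle <- function(y, k) {
  f <- integer(length(y))
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    f[idx] <- rep_len(seq_len(k), length(idx))
  }
  f
}
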