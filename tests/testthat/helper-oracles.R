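# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulations so they stay independent of the
# package's FFT/vectorized implementations.

# double-loop normalized cross-correlation, centered convention
naive_cross_correlation <- function(s, a, L) {
  N <- length(s)
  ms <- mean(s); ma <- mean(a)
  ss <- sqrt(mean((s - ms)^2)); sa <- sqrt(mean((a - ma)^2))
  vals <- numeric(2 * L + 1)
  for (i in seq_along(vals)) {
    tau <- i - L - 1L
    acc <- 0
    if (tau >= 0) {
      for (n in 1:(N - tau)) acc <- acc + (s[n + tau] - ms) * (a[n] - ma)
    } else {
      for (n in 1:(N + tau)) acc <- acc + (s[n] - ms) * (a[n - tau] - ma)
    }
    vals[i] <- acc / ((N - abs(tau)) * ss * sa)
  }
  vals
}

# literal uncentred cross-correlation (sum of products over std * std)
naive_raw_cc <- function(s, a, L) {
  N <- length(s)
  ss <- sqrt(mean((s - mean(s))^2)); sa <- sqrt(mean((a - mean(a))^2))
  sapply(-L:L, function(tau) {
    acc <- 0
    if (tau >= 0) for (n in 1:(N - tau)) acc <- acc + s[n + tau] * a[n]
    else for (n in 1:(N + tau)) acc <- acc + s[n] * a[n - tau]
    acc / (ss * sa)
  })
}

# direct weighted-sum centre of mass with explicit noise-floor rectification
naive_com <- function(lag_s, vals, k = 2) {
  scale <- stats::mad(vals)
  w <- ifelse(vals - k * scale > 0, vals - k * scale, 0)
  sum(lag_s * w) / sum(w)
}

# exact Mann-Whitney by full enumeration of group assignments (midranks)
naive_mann_whitney <- function(a, b, alternative = "two.sided") {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  U_obs <- sum(rk[(na + 1):(na + nb)]) - nb * (nb + 1) / 2
  mu <- na * nb / 2
  combs <- utils::combn(na + nb, nb)
  Us <- apply(combs, 2, function(idx) sum(rk[idx]) - nb * (nb + 1) / 2)
  eps <- 1e-9
  p <- switch(alternative,
    two.sided = mean(abs(Us - mu) >= abs(U_obs - mu) - eps),
    greater = mean(Us >= U_obs - eps),
    less = mean(Us <= U_obs + eps)
  )
  list(U = U_obs, p = p, r = 2 * U_obs / (na * nb) - 1)
}

# smoothed random texture with gradients everywhere
make_texture <- function(nr, nc, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(runif(nr * nc), nr, nc)
    k <- matrix(1 / 9, 3, 3)
    # small 3x3 blur by shifting
    out <- m * 0
    for (dr in -1:1) for (dc in -1:1) {
      rs <- pmin(pmax(seq_len(nr) + dr, 1), nr)
      cs <- pmin(pmax(seq_len(nc) + dc, 1), nc)
      out <- out + m[rs, cs] / 9
    }
    out
  })
}

# entrainment profile built directly from a CoM vector (for bout tests)
profile_from_com <- function(com, hop = 1) {
  out <- tibble::tibble(
    window = seq_along(com),
    start_s = (seq_along(com) - 1) * hop,
    center_s = (seq_along(com) - 1) * hop + 10,
    com = com
  )
  attr(out, "window_len") <- 20
  attr(out, "hop") <- hop
  attr(out, "max_lag") <- 5
  attr(out, "fps") <- 25
  class(out) <- c("entrainment_profile", class(out))
  out
}
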