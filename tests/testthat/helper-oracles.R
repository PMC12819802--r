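# Independent oracle implementations used to cross-check the package.
# These deliberately follow textbook definitions, not the package's code path.

# tiny parcel_ts builder
make_ts <- function(x, tr = 2, networks = NULL, id = "s1") {
  x <- as.matrix(x)
  dimnames(x) <- NULL
  p <- ncol(x)
  if (is.null(networks)) {
    networks <- seven_networks()[ceiling(seq_len(p) / (p / 7))]
  }
  parcel_ts(x, tr, data.frame(parcel_id = paste0("p", seq_len(p)),
                              network = networks), id)
}

# adjusted Rand index from the contingency-table definition
ari_index <- function(a, b) {
  tab <- table(a, b)
  sn <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  (sn - sa * sb / n2) / ((sa + sb) / 2 - sa * sb / n2)
}

# dense diffusion-map oracle: explicit matrix products and a dense
# non-symmetric eigensolver on the Markov matrix itself
oracle_diffusion <- function(affinity, alpha = 0.5, n_components = 5) {
  w <- as.matrix(affinity)
  deg <- rowSums(w)
  wprime <- w / outer(deg^alpha, deg^alpha)
  m <- wprime / rowSums(wprime)
  e <- eigen(m)
  ord <- order(Re(e$values), decreasing = TRUE)
  vals <- Re(e$values[ord])
  vecs <- Re(e$vectors[, ord, drop = FALSE])
  list(markov = m, eigenvalues = vals[2:(n_components + 1)],
       components = vecs[, 2:(n_components + 1), drop = FALSE])
}

# maximum absolute difference between two component matrices after unit-norm
# scaling, allowing a per-component sign flip (eigenvectors are defined up to
# sign and scale)
component_diff <- function(a, b) {
  stopifnot(ncol(a) == ncol(b))
  max(vapply(seq_len(ncol(a)), function(j) {
    u <- a[, j] / sqrt(sum(a[, j]^2))
    v <- b[, j] / sqrt(sum(b[, j]^2))
    min(max(abs(u - v)), max(abs(u + v)))
  }, numeric(1)))
}

# brute-force mean silhouette from the definition
oracle_silhouette <- function(x, cluster) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster == cluster[i]
    a <- if (sum(own) > 1) sum(d[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(setdiff(unique(cluster), cluster[i]), function(g) {
      mean(d[i, cluster == g])
    }, numeric(1)))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# brute-force Calinski-Harabasz from the definition
oracle_ch <- function(x, cluster) {
  x <- as.matrix(x)
  n <- nrow(x); k <- length(unique(cluster))
  grand <- colMeans(x)
  ssb <- sum(vapply(unique(cluster), function(g) {
    nrow(x[cluster == g, , drop = FALSE]) *
      sum((colMeans(x[cluster == g, , drop = FALSE]) - grand)^2)
  }, numeric(1)))
  ssw <- sum(vapply(unique(cluster), function(g) {
    xi <- x[cluster == g, , drop = FALSE]
    sum(sweep(xi, 2, colMeans(xi))^2)
  }, numeric(1)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# hand Benjamini-Hochberg step-up: p * m / rank, then backward running min
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# periodogram power at an exact DFT bin frequency
fft_power <- function(x, freq, fs) {
  n <- length(x)
  bin <- round(freq * n / fs) + 1
  Mod(stats::fft(x))[bin]^2
}

# random orthogonal matrix via QR of a Gaussian matrix
random_orthogonal <- function(d) {
  qr.Q(qr(matrix(rnorm(d * d), d)))
}
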