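# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

stop_not <- function(ok, msg, ...) {
  if (!isTRUE(ok)) abort(sprintf(msg, ...))
  invisible(TRUE)
}

# Fisher r-to-z on a correlation matrix; diagonal forced to 0.
fisher_z_matrix <- function(r, clamp = 1 - 1e-7) {
  z <- atanh(pmin(pmax(r, -clamp), clamp))
  diag(z) <- 0
  z
}

# Vectorize the strict upper triangle (column-major, matching upper.tri()).
vec_upper <- function(m) m[upper.tri(m)]

# Inverse of vec_upper for a P x P symmetric matrix with 0 diagonal.
unvec_upper <- function(v, p) {
  m <- matrix(0, p, p)
  m[upper.tri(m)] <- v
  m + t(m)
}

# Edge labels "a--b" for the strict upper triangle of parcel ids.
edge_names <- function(ids) {
  p <- length(ids)
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  paste0(ids[idx[, 1]], "--", ids[idx[, 2]])
}

# Symmetrize and floor eigenvalues so the matrix is numerically PSD.
psd_floor <- function(m, floor = 1e-8) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= floor) return(m)
  v <- pmax(e$values, floor)
  out <- e$vectors %*% (v * t(e$vectors))
  (out + t(out)) / 2
}

is_row_stochastic <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && all(m >= -tol) &&
    all(abs(rowSums(m) - 1) <= tol)
}

# Run lengths of a label vector as a tibble(state, length).
label_runs <- function(labels) {
  r <- rle(as.integer(labels))
  tibble(state = r$values, length = r$lengths)
}
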