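#' Static functional connectivity
#'
#' Pairwise Pearson correlation between parcel time series, optionally
#' Fisher r-to-z transformed (z = atanh(r), diagonal set to 0).
#'
#' @param ts A [parcel_ts()] object.
#' @param fisher Apply the r-to-z transform (default TRUE).
#' @return A `connectivity_matrix`: the P x P matrix with attributes `kind`
#'   (`"pearson_r"` or `"fisher_z"`) and `parcels`.
#' @export
compute_fc <- function(ts, fisher = TRUE) {
  stop_not(inherits(ts, "parcel_ts"), "`ts` must be a parcel_ts")
  stop_not(nrow(ts$data) >= 3, "need at least 3 timepoints")
  const <- apply(ts$data, 2, function(v) sd(v) < 1e-12)
  stop_not(!any(const), "constant parcel(s): %s",
           paste(ts$parcels$parcel_id[const], collapse = ", "))
  r <- cor(ts$data)
  out <- if (fisher) fisher_z_matrix(r) else r
  structure(out, kind = if (fisher) "fisher_z" else "pearson_r",
            parcels = ts$parcels, class = c("connectivity_matrix", "matrix"))
}

#' Within-network connectivity profile matrix
#'
#' Rows are the parcels of one network ("units"); columns are Fisher-z
#' correlations of each unit with every parcel of the cortex. This is the
#' input for per-network gradient embedding: units are embedded by the
#' similarity of their whole-cortex connectivity profiles. The unit's
#' self-correlation column is set to 0 (excluded from similarity).
#'
#' @param ts A [parcel_ts()] object.
#' @param network One of [seven_networks()], or `"all"` for whole-cortex
#'   profiles (units = all parcels).
#' @return Numeric matrix, units x parcels, with unit ids as row names.
#' @export
network_profile_matrix <- function(ts, network = "all") {
  z <- compute_fc(ts, fisher = TRUE)
  if (identical(network, "all")) return(unclass_fc(z))
  stop_not(network %in% .networks7, "unknown network '%s'", network)
  rows <- which(ts$parcels$network == network)
  stop_not(length(rows) >= 5, "network '%s' has %d units; need >= 5",
           network, length(rows))
  m <- unclass_fc(z)[rows, , drop = FALSE]
  # self-columns already 0 via the z diagonal
  m
}

unclass_fc <- function(z) {
  out <- unclass(z)
  attr(out, "kind") <- NULL
  attr(out, "parcels") <- NULL
  out
}

#' Embedding configuration
#'
#' Parameters of the diffusion-map embedding: the anisotropic normalization
#' exponent `alpha` (0.5 balances local and global geometry), the diffusion
#' time `t` (0 leaves components unscaled), the number of components
#' returned, and the row-wise sparsity fraction retained before cosine
#' similarity.
#'
#' @param alpha Anisotropy exponent in \eqn{[0, 1]} (default 0.5).
#' @param t Diffusion time, nonnegative integer (default 0).
#' @param n_components Number of non-trivial components (default 10).
#' @param row_sparsity Fraction of each profile row retained (default 0.10).
#' @return An `embedding_config` list.
#' @export
embedding_config <- function(alpha = 0.5, t = 0, n_components = 10,
                             row_sparsity = 0.10) {
  stop_not(alpha >= 0 && alpha <= 1, "`alpha` must be in [0, 1]")
  stop_not(t >= 0 && t == round(t), "`t` must be a nonnegative integer")
  stop_not(row_sparsity > 0 && row_sparsity <= 1,
           "`row_sparsity` must be in (0, 1]")
  structure(list(alpha = alpha, t = t, n_components = n_components,
                 row_sparsity = row_sparsity), class = "embedding_config")
}

#' Cosine-similarity affinity matrix
#'
#' Sparsifies each profile row to its top `row_sparsity` fraction of entries
#' (the rest set to 0), computes cosine similarity between the sparsified
#' rows, clips negative similarities to 0 (so the affinity admits a Markov
#' normalization), zeroes the diagonal and symmetrizes as (A + t(A)) / 2.
#'
#' @param profiles Units x parcels profile matrix
#'   ([network_profile_matrix()]).
#' @param config An [embedding_config()].
#' @return An `affinity_matrix` (units x units, entries in \eqn{[0, 1]}).
#' @export
cosine_affinity <- function(profiles, config = embedding_config()) {
  m <- as.matrix(profiles)
  keep <- ceiling(ncol(m) * config$row_sparsity)
  sp <- m
  for (i in seq_len(nrow(m))) {
    thr <- sort(m[i, ], decreasing = TRUE)[keep]
    sp[i, m[i, ] < thr] <- 0
  }
  norms <- sqrt(rowSums(sp^2))
  bad <- which(norms < 1e-12)
  stop_not(length(bad) == 0,
           "zero-norm profile row(s) after sparsification: %s",
           paste(bad, collapse = ", "))
  a <- (sp %*% t(sp)) / outer(norms, norms)
  a[a < 0] <- 0
  diag(a) <- 0
  a <- (a + t(a)) / 2
  structure(a, class = c("affinity_matrix", "matrix"))
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Normalized graph-Laplacian diffusion embedding: the affinity W is
#' anisotropically normalized, \eqn{W' = D^{-\alpha} W D^{-\alpha}} with D
#' the degree diagonal, then row-normalized into a Markov transition matrix
#' M. Components are the non-trivial right eigenvectors of M (the constant
#' first eigenvector is dropped), ordered by descending eigenvalue and scaled
#' by \eqn{\lambda^t} (t = 0 leaves them unscaled). The eigenproblem is
#' solved through the symmetric conjugate of M, so eigenvalues are real.
#' Variance explained is \eqn{\lambda_i^2 / \sum_j \lambda_j^2} over the
#' retained components.
#'
#' @param affinity Symmetric nonnegative matrix ([cosine_affinity()]).
#' @param config An [embedding_config()].
#' @return A `gradient_embedding`: list with `components` (units x
#'   n_components), `eigenvalues` (non-increasing), `variance_explained`.
#' @export
diffusion_embedding <- function(affinity, config = embedding_config()) {
  w <- as.matrix(affinity)
  n <- nrow(w)
  stop_not(config$n_components < n, "`n_components` must be < number of units")
  deg <- rowSums(w)
  stop_not(all(deg > 1e-12),
           "disconnected affinity: unit(s) with zero degree: %s",
           paste(which(deg <= 1e-12), collapse = ", "))
  wprime <- w / outer(deg^config$alpha, deg^config$alpha)
  d1 <- rowSums(wprime)
  stop_not(all(d1 > 1e-12), "disconnected affinity after normalization")
  # M = diag(1/d1) %*% wprime; conjugate S = D^1/2 M D^-1/2 is symmetric
  s <- wprime / outer(sqrt(d1), sqrt(d1))
  e <- eigen(s, symmetric = TRUE)
  nc <- config$n_components
  lam <- e$values[2:(nc + 1)]
  psi <- (e$vectors / sqrt(d1))[, 2:(nc + 1), drop = FALSE]
  # fix an overall sign per component for reproducibility
  for (j in seq_len(nc)) {
    if (psi[which.max(abs(psi[, j])), j] < 0) psi[, j] <- -psi[, j]
  }
  comp <- psi
  if (config$t > 0) comp <- sweep(comp, 2, lam^config$t, `*`)
  colnames(comp) <- paste0("g", seq_len(nc))
  rownames(comp) <- rownames(w)
  structure(list(components = comp, eigenvalues = lam,
                 variance_explained = lam^2 / sum(lam^2),
                 markov_degree = d1, config = config),
            class = "gradient_embedding")
}

#' @export
print.gradient_embedding <- function(x, ...) {
  cat(sprintf("<gradient_embedding> %d units x %d components\n",
              nrow(x$components), ncol(x$components)))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * head(x$variance_explained, 5)),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Group-level gradient template
#'
#' Averages the subjects' connectivity (or profile) matrices elementwise and
#' embeds the average: affinity of the mean matrix, then
#' [diffusion_embedding()].
#'
#' @param matrices List of matched units x parcels matrices (one per
#'   subject).
#' @param config An [embedding_config()].
#' @return A `gradient_embedding` of the group-average matrix.
#' @export
build_group_template <- function(matrices, config = embedding_config()) {
  stop_not(length(matrices) >= 1, "need at least one subject matrix")
  dims <- vapply(matrices, dim, integer(2))
  stop_not(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
           "subject matrices have mismatched dimensions")
  avg <- Reduce(`+`, lapply(matrices, as.matrix)) / length(matrices)
  diffusion_embedding(cosine_affinity(avg, config), config)
}

#' Procrustes alignment of an embedding to a template
#'
#' Finds the orthogonal transform (rotation/reflection, no scaling; columns
#' centered first) minimizing the Frobenius distance between the embedding's
#' components and the template's, via the SVD of the cross-product matrix.
#'
#' @param embedding A `gradient_embedding` (or bare component matrix).
#' @param template The reference `gradient_embedding` (or matrix) of matching
#'   dimensions.
#' @return An `aligned_gradients` list: `components` (aligned), `rotation`,
#'   `disparity` (residual Frobenius distance), `template_id`.
#' @export
procrustes_align <- function(embedding, template) {
  x <- if (inherits(embedding, "gradient_embedding")) embedding$components
       else as.matrix(embedding)
  y <- if (inherits(template, "gradient_embedding")) template$components
       else as.matrix(template)
  stop_not(all(dim(x) == dim(y)),
           "embedding (%d x %d) and template (%d x %d) dimensions differ",
           nrow(x), ncol(x), nrow(y), ncol(y))
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)
  sv <- svd(crossprod(xc, yc))
  stop_not(min(sv$d) > 1e-12 * max(sv$d), "rank-deficient input to alignment")
  rot <- sv$u %*% t(sv$v)
  aligned <- xc %*% rot
  dimnames(aligned) <- dimnames(x)
  structure(list(components = aligned, rotation = rot,
                 disparity = sqrt(sum((aligned - yc)^2)),
                 template_id = attr(template, "template_id") %||% "template"),
            class = "aligned_gradients")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standardize gradient components to z-scores
#'
#' Scales each component column to mean 0 and sd 1 across units. Idempotent;
#' a constant component is an error.
#'
#' @param aligned An `aligned_gradients` (or bare matrix).
#' @return The same structure with standardized `components`.
#' @export
standardize_components <- function(aligned) {
  x <- if (inherits(aligned, "aligned_gradients")) aligned$components
       else as.matrix(aligned)
  sds <- apply(x, 2, sd)
  stop_not(all(sds > 1e-12), "constant component(s): %s",
           paste(which(sds <= 1e-12), collapse = ", "))
  z <- scale(x, center = TRUE, scale = TRUE)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  if (inherits(aligned, "aligned_gradients")) {
    aligned$components <- z
    aligned
  } else {
    structure(list(components = z, rotation = NULL, disparity = NA_real_,
                   template_id = "none"), class = "aligned_gradients")
  }
}

#' Orient gradient signs by the somatomotor convention
#'
#' Flips the sign of gradient 1 (and of the template-consistent others, if
#' requested) so the somatomotor-network mean score is negative, making the
#' unimodal end of the principal gradient consistently negative across runs.
#'
#' @param aligned An `aligned_gradients`.
#' @param networks Length-units character vector of network labels.
#' @param components Which components to orient (default 1).
#' @return The oriented `aligned_gradients`.
#' @export
orient_gradients <- function(aligned, networks, components = 1) {
  x <- aligned$components
  smi <- networks == "somatomotor"
  if (!any(smi)) return(aligned)
  for (j in components) {
    if (mean(x[smi, j]) > 0) x[, j] <- -x[, j]
  }
  aligned$components <- x
  aligned
}

#' Network dispersion in gradient space
#'
#' Within-network dispersion is the sum of squared Euclidean distances of a
#' network's units to their centroid in the space of the first
#' `n_components_used` aligned gradients; between-network dispersion is the
#' Euclidean distance between network centroids. Empty networks are excluded
#' with a warning.
#'
#' @param aligned An `aligned_gradients` (or matrix of component scores).
#' @param networks Length-units character vector of network labels.
#' @param n_components_used Number of leading components defining the space
#'   (default 2).
#' @return A list of two tibbles: `within` (network, n_units, dispersion) and
#'   `between` (network_a, network_b, distance).
#' @export
network_dispersion <- function(aligned, networks, n_components_used = 2) {
  x <- if (inherits(aligned, "aligned_gradients")) aligned$components
       else as.matrix(aligned)
  stop_not(length(networks) == nrow(x),
           "`networks` must label every unit")
  x <- x[, seq_len(n_components_used), drop = FALSE]
  present <- intersect(.networks7, unique(networks))
  absent <- setdiff(unique(networks), .networks7)
  stop_not(length(absent) == 0, "unknown network label(s): %s",
           paste(absent, collapse = ", "))
  centroids <- t(vapply(present, function(nw) {
    colMeans(x[networks == nw, , drop = FALSE])
  }, numeric(n_components_used)))
  within <- tibble(
    network = present,
    n_units = unname(vapply(present, function(nw) sum(networks == nw),
                            integer(1))),
    dispersion = unname(vapply(present, function(nw) {
      xi <- x[networks == nw, , drop = FALSE]
      sum(sweep(xi, 2, colMeans(xi))^2)
    }, numeric(1)))
  )
  pairs <- which(upper.tri(diag(length(present))), arr.ind = TRUE)
  between <- tibble(
    network_a = present[pairs[, 1]],
    network_b = present[pairs[, 2]],
    distance = unname(sqrt(rowSums((centroids[pairs[, 1], , drop = FALSE] -
                                    centroids[pairs[, 2], , drop = FALSE])^2)))
  )
  list(within = within, between = between)
}

#' Subject-level gradients for a cohort, aligned to the group template
#'
#' The full gradient pipeline of the package: per-subject Fisher-z
#' connectivity profiles (whole-cortex or one network), a group template from
#' the subject-average matrix, per-subject diffusion embeddings aligned to
#' the template by Procrustes, z-scored, and oriented by the somatomotor sign
#' convention.
#'
#' @param ts_list Named list of [parcel_ts()] objects.
#' @param network `"all"` (default) or one of [seven_networks()].
#' @param config An [embedding_config()].
#' @return A list with `template` (`gradient_embedding`), `aligned` (named
#'   list of `aligned_gradients`), `scores` (long tibble: subject_id,
#'   unit_id, network, component, score), and `networks` (unit labels).
#' @export
fit_gradients <- function(ts_list, network = "all",
                          config = embedding_config()) {
  stop_not(length(ts_list) >= 1, "need at least one subject")
  profiles <- lapply(ts_list, network_profile_matrix, network = network)
  template <- build_group_template(profiles, config)
  p1 <- ts_list[[1]]$parcels
  unit_ids <- if (identical(network, "all")) p1$parcel_id
              else p1$parcel_id[p1$network == network]
  unit_networks <- p1$network[match(unit_ids, p1$parcel_id)]
  aligned <- lapply(profiles, function(pm) {
    emb <- diffusion_embedding(cosine_affinity(pm, config), config)
    al <- standardize_components(procrustes_align(emb, template))
    orient_gradients(al, unit_networks)
  })
  scores <- purrr::imap_dfr(aligned, function(al, id) {
    m <- al$components
    tibble(subject_id = id,
           unit_id = rep(unit_ids, ncol(m)),
           network = rep(unit_networks, ncol(m)),
           component = rep(colnames(m), each = nrow(m)),
           score = as.vector(m))
  })
  list(template = template, aligned = aligned, scores = scores,
       networks = unit_networks)
}
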