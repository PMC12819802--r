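#' Sliding-window specification
#'
#' Window length and step for dynamic functional connectivity (defaults: 50
#' timepoints with step 1, the convention for ~100 s windows at TR = 2 s),
#' and the window taper (rectangular default, Gaussian optional).
#'
#' @param length Window length L in timepoints (>= 10).
#' @param step Step between window starts (>= 1).
#' @param taper `"rectangular"` (default) or `"gaussian"` (sd = L/4).
#' @return A `window_spec` list.
#' @export
window_spec <- function(length = 50, step = 1,
                        taper = c("rectangular", "gaussian")) {
  taper <- match.arg(taper)
  stop_not(length >= 10, "window length must be >= 10")
  stop_not(step >= 1, "step must be >= 1")
  structure(list(length = as.integer(length), step = as.integer(step),
                 taper = taper), class = "window_spec")
}

#' Number of sliding windows
#'
#' `W = floor((T - L) / step) + 1` for a series of `T` timepoints.
#'
#' @param n_timepoints Series length T.
#' @param spec A [window_spec()].
#' @return Integer window count.
#' @export
#' @examples
#' n_windows(230, window_spec(50, 1))  # 181
n_windows <- function(n_timepoints, spec = window_spec()) {
  stop_not(n_timepoints >= spec$length, "series (T = %d) shorter than window (L = %d)",
           n_timepoints, spec$length)
  as.integer(floor((n_timepoints - spec$length) / spec$step) + 1L)
}

weighted_cor <- function(x, w) {
  w <- w / sum(w)
  xc <- sweep(x, 2, colSums(x * w))
  cv <- crossprod(xc * sqrt(w))
  d <- sqrt(diag(cv))
  cv / outer(d, d)
}

#' Sliding-window dynamic connectivity
#'
#' Computes, for each window, the Pearson correlation over the (optionally
#' tapered) segment, applies Fisher's r-to-z, and stores the vectorized
#' strict upper triangle. A parcel that is constant within some window is an
#' error naming the window and parcel.
#'
#' @param ts A [parcel_ts()] object.
#' @param spec A [window_spec()].
#' @return A `dfc_series`: list with `edges` (W x E matrix of z values,
#'   E = P(P-1)/2), `subject_id`, `spec`, `tr_seconds`, `parcels`,
#'   `edge_names`.
#' @export
sliding_window_fc <- function(ts, spec = window_spec()) {
  stop_not(inherits(ts, "parcel_ts"), "`ts` must be a parcel_ts")
  x <- ts$data
  tp <- nrow(x)
  w_n <- n_windows(tp, spec)
  p <- ncol(x)
  ut <- upper.tri(diag(p))
  wts <- if (spec$taper == "gaussian") {
    stats::dnorm(seq_len(spec$length), mean = (spec$length + 1) / 2,
                 sd = spec$length / 4)
  } else {
    rep(1, spec$length)
  }
  edges <- matrix(NA_real_, w_n, sum(ut))
  for (w in seq_len(w_n)) {
    i0 <- (w - 1L) * spec$step + 1L
    seg <- x[i0:(i0 + spec$length - 1L), , drop = FALSE]
    sds <- apply(seg, 2, sd)
    if (any(sds < 1e-12)) {
      abort(sprintf("parcel '%s' constant within window %d",
                    ts$parcels$parcel_id[which(sds < 1e-12)[1]], w))
    }
    r <- if (spec$taper == "rectangular") cor(seg) else weighted_cor(seg, wts)
    clamp <- 1 - 1e-7
    edges[w, ] <- atanh(pmin(pmax(r[ut], -clamp), clamp))
  }
  structure(list(edges = edges, subject_id = ts$subject_id, spec = spec,
                 tr_seconds = ts$tr_seconds, parcels = ts$parcels,
                 edge_names = edge_names(ts$parcels$parcel_id)),
            class = "dfc_series")
}

#' @export
print.dfc_series <- function(x, ...) {
  cat(sprintf("<dfc_series> %s: %d windows x %d edges (L = %d, step = %d)\n",
              x$subject_id, nrow(x$edges), ncol(x$edges), x$spec$length,
              x$spec$step))
  invisible(x)
}

#' Per-edge dynamic connectivity variability
#'
#' Standard deviation of each edge's Fisher-z value across windows
#' (denominator W - 1).
#'
#' @param series A `dfc_series`.
#' @return A tibble (edge, sd).
#' @export
dfc_variability <- function(series) {
  stop_not(inherits(series, "dfc_series"), "`series` must be a dfc_series")
  stop_not(nrow(series$edges) >= 2, "need at least 2 windows")
  tibble(edge = series$edge_names, sd = apply(series$edges, 2, sd))
}

# k-means++ seeding (deterministic given the RNG state)
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  if (k > 1) for (j in 2:k) {
    probs <- d2 / sum(d2)
    i <- sample.int(n, 1, prob = probs)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' Fit connectivity states by k-means
#'
#' Pools windows across subjects and clusters their z-edge vectors with
#' k-means (Lloyd iterations, k-means++ seeding, `n_restarts` independent
#' runs keeping the lowest within-cluster sum of squares). Labels are mapped
#' back per subject. Fully reproducible under `seed`. A restart that
#' converges with an empty cluster is re-seeded.
#'
#' @param series_list List of `dfc_series` (or a single one), or a bare
#'   windows x edges matrix.
#' @param k Number of states (>= 1).
#' @param seed Integer seed.
#' @param n_restarts Independent k-means restarts (default 50).
#' @param iter_max Lloyd iteration cap per restart (default 300).
#' @return A `state_model`: `k`, `centroids` (k x E), `labels` (named list,
#'   per subject), `cluster` (pooled integer vector), `sse` (total
#'   within-cluster SSE), `sizes`, `seed`, `n_restarts`.
#' @export
fit_states <- function(series_list, k, seed = 1L, n_restarts = 50,
                       iter_max = 300) {
  pooled <- pool_windows(series_list)
  x <- pooled$x
  stop_not(k >= 1 && k == round(k), "`k` must be a positive integer")
  stop_not(nrow(x) >= k, "fewer windows (%d) than clusters (%d)", nrow(x), k)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      fit <- NULL
      for (attempt in 1:5) {
        centers <- kmeanspp_centers(x, k)
        fit <- tryCatch(
          suppressWarnings(kmeans(x, centers = centers, iter.max = iter_max,
                                  algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(fit) && length(unique(fit$cluster)) == k) break
        fit <- NULL
      }
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  stop_not(!is.null(best), "k-means failed in every restart")
  labels <- split(best$cluster, pooled$subject)[unique(pooled$subject)]
  structure(list(k = k, centroids = best$centers, labels = labels,
                 cluster = best$cluster, sse = best$tot.withinss,
                 sizes = as.integer(best$size), seed = seed,
                 n_restarts = n_restarts,
                 subject = pooled$subject),
            class = "state_model")
}

pool_windows <- function(series_list) {
  if (is.matrix(series_list)) {
    return(list(x = series_list,
                subject = rep("pooled", nrow(series_list))))
  }
  if (inherits(series_list, "dfc_series")) series_list <- list(series_list)
  stop_not(all(vapply(series_list, inherits, logical(1), "dfc_series")),
           "`series_list` must contain dfc_series objects")
  ids <- vapply(series_list, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  x <- do.call(rbind, lapply(series_list, `[[`, "edges"))
  subject <- rep(ids, vapply(series_list, function(s) nrow(s$edges),
                             integer(1)))
  list(x = x, subject = subject)
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> k = %d over %d windows; SSE = %.1f\n",
              x$k, length(x$cluster), x$sse))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

# Calinski-Harabasz index from its definition.
calinski_harabasz <- function(x, cluster) {
  n <- nrow(x)
  k <- length(unique(cluster))
  grand <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (g in unique(cluster)) {
    xi <- x[cluster == g, , drop = FALSE]
    ci <- colMeans(xi)
    ssb <- ssb + nrow(xi) * sum((ci - grand)^2)
    ssw <- ssw + sum(sweep(xi, 2, ci)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Cluster-number diagnostics and selection
#'
#' Fits [fit_states()] for each k in `k_range` and reports the SSE curve, the
#' mean silhouette coefficient and the Calinski-Harabasz index. The chosen k
#' is the elbow-candidate set (ks with positive second difference of the SSE
#' curve, anchored at the single-cluster SSE) member that maximizes the
#' silhouette; ties are broken by larger Calinski-Harabasz, then smaller k.
#' For large pooled window counts the silhouette is evaluated on a
#' seed-fixed subsample of at most `silhouette_max_n` windows.
#'
#' @param series_list As in [fit_states()].
#' @param k_range Integer ks to scan (default 2:20; clipped with a warning
#'   if it exceeds n - 1).
#' @param seed Integer seed.
#' @param n_restarts Restarts per k (default 10).
#' @param silhouette_max_n Subsample cap for the silhouette (default 1000).
#' @return A `state_quality_scan`: tibble `scan` (k, sse, silhouette,
#'   calinski_harabasz, elbow_candidate) plus `chosen_k` and `sse1`.
#' @export
cluster_quality_scan <- function(series_list, k_range = 2:20, seed = 1L,
                                 n_restarts = 10, silhouette_max_n = 1000) {
  pooled <- pool_windows(series_list)
  x <- pooled$x
  n <- nrow(x)
  if (max(k_range) > n - 1) {
    warn(sprintf("k_range clipped to 2..%d (only %d windows)", n - 1, n))
    k_range <- k_range[k_range <= n - 1]
  }
  k_range <- sort(unique(as.integer(k_range)))
  stop_not(length(k_range) > 0 && min(k_range) >= 2, "empty or invalid k_range")
  sse1 <- sum(sweep(x, 2, colMeans(x))^2)
  sil_idx <- if (n > silhouette_max_n) {
    with_seed(seed, sort(sample.int(n, silhouette_max_n)))
  } else {
    seq_len(n)
  }
  dmat <- stats::dist(x[sil_idx, , drop = FALSE])
  rows <- purrr::map_dfr(k_range, function(k) {
    fit <- fit_states(x, k, seed = seed + k, n_restarts = n_restarts)
    sil <- cluster::silhouette(fit$cluster[sil_idx], dmat)
    tibble(k = k, sse = fit$sse,
           silhouette = mean(sil[, "sil_width"]),
           calinski_harabasz = calinski_harabasz(x, fit$cluster))
  })
  sse_curve <- c(sse1, rows$sse)
  kk <- c(1L, rows$k)
  second_diff <- rep(NA_real_, length(kk))
  for (i in 2:(length(kk) - 1)) {
    second_diff[i] <- sse_curve[i - 1] - 2 * sse_curve[i] + sse_curve[i + 1]
  }
  rows$elbow_candidate <- (second_diff[-1] > 0) & !is.na(second_diff[-1])
  cand <- rows[rows$elbow_candidate, ]
  if (nrow(cand) == 0) cand <- rows
  ord <- order(-cand$silhouette, -cand$calinski_harabasz, cand$k)
  chosen <- cand$k[ord[1]]
  structure(list(scan = rows, chosen_k = chosen, sse1 = sse1, seed = seed),
            class = "state_quality_scan")
}

#' @export
print.state_quality_scan <- function(x, ...) {
  cat(sprintf("<state_quality_scan> k in %d..%d; chosen k = %d\n",
              min(x$scan$k), max(x$scan$k), x$chosen_k))
  print(as.data.frame(x$scan), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Temporal state metrics
#'
#' Fractional occupancy (fraction of windows per state), mean dwell time
#' (mean consecutive-run length per state, in windows and in seconds
#' = windows x step x TR), and number of transitions (label changes between
#' consecutive windows). Unvisited states have FO = 0 and missing MDT.
#'
#' @param labels Integer window-label vector for one subject, or a
#'   `state_model` (metrics per subject).
#' @param k Number of states (inferred from a `state_model`).
#' @param spec The [window_spec()] used (for seconds conversion).
#' @param tr_seconds Repetition time.
#' @param subject_id Identifier used in the output.
#' @return A tibble (subject_id, state, fo, mdt_windows, mdt_seconds, nt).
#'   `nt` is repeated per state for convenience.
#' @export
#' @examples
#' temporal_metrics(c(1, 1, 2, 2, 2, 1), k = 2)
temporal_metrics <- function(labels, k = NULL, spec = window_spec(),
                             tr_seconds = 2, subject_id = "subject") {
  if (inherits(labels, "state_model")) {
    model <- labels
    out <- purrr::imap_dfr(model$labels, function(lab, id) {
      temporal_metrics(lab, k = model$k, spec = spec,
                       tr_seconds = tr_seconds, subject_id = id)
    })
    return(out)
  }
  labels <- as.integer(labels)
  stop_not(length(labels) >= 1, "`labels` is empty")
  if (is.null(k)) k <- max(labels)
  stop_not(all(labels >= 1 & labels <= k), "label outside 1..%d", k)
  w <- length(labels)
  runs <- label_runs(labels)
  fo <- tabulate(labels, nbins = k) / w
  mdt_w <- vapply(seq_len(k), function(s) {
    r <- runs$length[runs$state == s]
    if (length(r) == 0) NA_real_ else mean(r)
  }, numeric(1))
  nt <- sum(diff(labels) != 0)
  tibble(subject_id = subject_id, state = seq_len(k), fo = fo,
         mdt_windows = mdt_w,
         mdt_seconds = mdt_w * spec$step * tr_seconds,
         nt = nt)
}

#' Per-state edge contrasts between groups
#'
#' For one state, averages each subject's z-edge vectors over their windows
#' assigned to that state, then tests every edge for a covariate-adjusted
#' group difference ([adjusted_group_contrast()]) with BH-FDR across edges.
#' Subjects with no window in the state are excluded and counted.
#'
#' @param series_list Named list of `dfc_series` matching the model's
#'   subjects.
#' @param model A `state_model` from [fit_states()].
#' @param state State index to contrast.
#' @param subjects Tibble with `subject_id`, `group`, and any covariates.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return A `state_contrast`: tibble `edges` (edge, t, df, p, q) plus
#'   `n_per_group`, `excluded` (subject ids lacking the state).
#' @export
state_edge_contrast <- function(series_list, model, state, subjects,
                                covariates = character()) {
  stop_not(inherits(model, "state_model"), "`model` must be a state_model")
  stop_not(state >= 1 && state <= model$k, "state %s out of range", state)
  ids <- names(model$labels)
  stop_not(all(ids %in% names(series_list)),
           "series_list must cover every subject in the model")
  means <- lapply(ids, function(id) {
    sel <- model$labels[[id]] == state
    if (!any(sel)) return(NULL)
    colMeans(series_list[[id]]$edges[sel, , drop = FALSE])
  })
  names(means) <- ids
  excluded <- ids[vapply(means, is.null, logical(1))]
  kept <- setdiff(ids, excluded)
  feat <- do.call(rbind, means[kept])
  sub <- subjects[match(kept, subjects$subject_id), , drop = FALSE]
  counts <- table(sub$group)
  stop_not(all(counts >= 3),
           "a group has fewer than 3 subjects with windows in state %d", state)
  colnames(feat) <- series_list[[kept[1]]]$edge_names
  res <- adjusted_group_contrast(feat, sub$group,
                                 covariates = sub[, covariates, drop = FALSE])
  res$q <- fdr_bh(res$p)
  structure(list(edges = res, state = state,
                 n_per_group = as.integer(counts),
                 groups = names(counts), excluded = excluded),
            class = "state_contrast")
}

#' Ground-truth state labels at window resolution
#'
#' Converts a per-timepoint state sequence (as attached by
#' [simulate_subject()]) to one label per sliding window: the modal state
#' within the window span. Used when comparing recovered window labels with
#' the generating chain.
#'
#' @param state_labels Integer per-timepoint state sequence.
#' @param spec The [window_spec()] used for the dynamic connectivity.
#' @return Integer vector of length [n_windows()].
#' @export
true_window_labels <- function(state_labels, spec = window_spec()) {
  lab <- as.integer(state_labels)
  w <- n_windows(length(lab), spec)
  k <- max(lab)
  vapply(seq_len(w), function(i) {
    i0 <- (i - 1L) * spec$step + 1L
    which.max(tabulate(lab[i0:(i0 + spec$length - 1L)], nbins = k))
  }, integer(1))
}

#' Match fitted states to generating states
#'
#' Greedy maximum-agreement matching between cluster labels and ground-truth
#' labels over the same windows: true states are visited in order of
#' decreasing window count and each is assigned the unclaimed cluster with
#' the largest overlap.
#'
#' @param cluster Integer fitted labels.
#' @param truth Integer ground-truth labels over the same windows.
#' @param k Number of states (default `max(truth)`).
#' @return Integer vector `m` of length `k`: `m[s]` is the cluster id
#'   matched to true state `s`.
#' @export
match_states <- function(cluster, truth, k = max(truth)) {
  stop_not(length(cluster) == length(truth),
           "cluster and truth labels must align")
  tab <- table(factor(cluster, levels = sort(unique(cluster))),
               factor(truth, levels = seq_len(k)))
  m <- integer(k)
  taken <- integer(0)
  for (s in order(-colSums(tab))) {
    cand <- as.integer(rownames(tab))[order(-tab[, s])]
    cand <- cand[!(cand %in% taken)]
    m[s] <- cand[1]
    taken <- c(taken, cand[1])
  }
  m
}
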