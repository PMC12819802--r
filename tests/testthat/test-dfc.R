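test_that("window count follows floor((T - L)/step) + 1 across a grid", {
  expect_equal(n_windows(230, window_spec(50, 1)), 181L)
  expect_equal(n_windows(140, window_spec(50, 1)), 91L)
  for (tp in c(60, 100, 231)) {
    for (L in c(10, 30, 50)) {
      for (st in c(1, 2, 5)) {
        if (tp >= L) {
          expect_equal(n_windows(tp, window_spec(L, st)),
                       as.integer(floor((tp - L) / st) + 1))
        }
      }
    }
  }
  expect_error(n_windows(40, window_spec(50, 1)), "shorter")
})

test_that("a single full-length window reproduces the static z-FC", {
  set.seed(20)
  ts <- make_ts(matrix(rnorm(50 * 7), 50, 7))
  ser <- sliding_window_fc(ts, window_spec(50, 1))
  expect_equal(nrow(ser$edges), 1)
  static <- compute_fc(ts, fisher = TRUE)
  expect_equal(as.vector(ser$edges[1, ]),
               unclass(static)[upper.tri(static)], tolerance = 1e-10)
  # constant-in-window parcel named in the error
  x <- matrix(rnorm(80 * 7), 80, 7)
  x[1:55, 3] <- 0
  expect_error(sliding_window_fc(make_ts(x), window_spec(50, 1)), "p3")
})

test_that("edge variability matches the hand sample-sd", {
  # alternating z in {0, 1} over 4 windows: sd with denominator 3
  edges <- cbind(c(0, 1, 0, 1), c(0.3, 0.3, 0.3, 0.3))
  ser <- structure(list(edges = edges, subject_id = "s",
                        spec = window_spec(10, 1), tr_seconds = 2,
                        parcels = NULL, edge_names = c("e1", "e2")),
                   class = "dfc_series")
  v <- dfc_variability(ser)
  expect_equal(v$sd[1], sqrt(1 / 3), tolerance = 1e-10)
  expect_equal(round(v$sd[1], 5), 0.57735)
  expect_equal(v$sd[2], 0)
  # permutation invariance of window order
  ser2 <- ser; ser2$edges <- edges[c(3, 1, 4, 2), ]
  expect_equal(dfc_variability(ser2)$sd, v$sd)
  ser1 <- ser; ser1$edges <- edges[1, , drop = FALSE]
  expect_error(dfc_variability(ser1), "2 windows")
})

test_that("k-means recovers planted clusters and honors determinism", {
  set.seed(21)
  centers <- matrix(rnorm(4 * 30, sd = 4), 4, 30)
  truth <- rep(1:4, each = 50)
  x <- centers[truth, ] + matrix(rnorm(200 * 30, sd = 0.3), 200, 30)
  m <- fit_states(x, k = 4, seed = 3, n_restarts = 10)
  expect_equal(ari_index(m$cluster, truth), 1)
  m2 <- fit_states(x, k = 4, seed = 3, n_restarts = 10)
  expect_identical(m$cluster, m2$cluster)
  expect_identical(m$centroids, m2$centroids)
  # k = 1: SSE equals total deviation from the grand centroid
  m1 <- fit_states(x, k = 1, seed = 1, n_restarts = 2)
  expect_equal(m1$sse, sum(sweep(x, 2, colMeans(x))^2), tolerance = 1e-8)
  expect_true(all(m1$cluster == 1))
})

test_that("quality scan matches brute-force silhouette and CH, and the
           elbow+silhouette rule picks separated blob counts", {
  # hand-checkable 1-D silhouette: {0, 0.1} vs {10, 10.1}
  x4 <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  cl4 <- c(1, 1, 2, 2)
  s0 <- (10.05 - 0.1) / 10.05
  expect_equal(round(s0, 6), 0.990050)
  expect_equal(oracle_silhouette(x4, cl4),
               mean(c(s0, (9.95 - 0.1) / 9.95, (9.95 - 0.1) / 9.95, s0)),
               tolerance = 1e-12)
  set.seed(22)
  centers <- rbind(c(0, 0), c(8, 8))
  truth <- rep(1:2, each = 25)
  x <- centers[truth, ] + matrix(rnorm(100, sd = 0.5), 50, 2)
  scan <- cluster_quality_scan(x, k_range = 2:5, seed = 7, n_restarts = 5)
  expect_equal(scan$chosen_k, 2)
  expect_equal(which.max(scan$scan$silhouette), 1)
  # SSE non-increasing in k
  expect_true(all(diff(scan$scan$sse) <= 1e-8))
  # silhouette and CH match definitional evaluations at each k
  for (i in seq_len(nrow(scan$scan))) {
    k <- scan$scan$k[i]
    fit <- fit_states(x, k, seed = 7 + k, n_restarts = 5)
    expect_equal(scan$scan$silhouette[i], oracle_silhouette(x, fit$cluster),
                 tolerance = 1e-10)
    expect_equal(scan$scan$calinski_harabasz[i], oracle_ch(x, fit$cluster),
                 tolerance = 1e-10)
  }
  # k_range clipped with a warning when it exceeds n - 1
  expect_warning(cluster_quality_scan(x[1:6, ], k_range = 2:10, seed = 1,
                                      n_restarts = 2), "clipped")
})

test_that("temporal metrics reproduce hand run-length accounting", {
  tm <- temporal_metrics(c(1, 1, 2, 2, 2, 1), k = 2)
  expect_equal(tm$fo, c(0.5, 0.5))
  expect_equal(tm$mdt_windows, c(1.5, 3.0))
  expect_equal(unique(tm$nt), 2)
  # seconds conversion: windows x step x TR
  tm2 <- temporal_metrics(c(1, 1, 2, 2, 2, 1), k = 2,
                          spec = window_spec(50, 2), tr_seconds = 2)
  expect_equal(tm2$mdt_seconds, c(1.5, 3.0) * 2 * 2)
  # constant labels: one run, FO 1, NT 0, MDT = W
  tc <- temporal_metrics(rep(2, 8), k = 3)
  expect_equal(tc$fo, c(0, 1, 0))
  expect_equal(tc$mdt_windows[2], 8)
  expect_true(is.na(tc$mdt_windows[1]))
  expect_equal(unique(tc$nt), 0)
  # FO partitions the windows for random label vectors
  set.seed(23)
  for (r in 1:10) {
    lab <- sample(1:4, 60, replace = TRUE)
    tmx <- temporal_metrics(lab, k = 4)
    expect_equal(sum(tmx$fo), 1, tolerance = 1e-12)
    expect_equal(unique(tmx$nt), sum(diff(lab) != 0))
  }
  expect_error(temporal_metrics(c(1, 5), k = 4), "outside")
})

test_that("per-state edge contrasts detect a planted group difference", {
  set.seed(24)
  p <- 8; e_count <- p * (p - 1) / 2
  n_per <- 20
  spec <- window_spec(10, 1)
  mk_series <- function(id, shift) {
    w <- 30
    edges <- matrix(rnorm(w * e_count, sd = 1), w, e_count)
    edges[, 5] <- edges[, 5] + shift
    structure(list(edges = edges, subject_id = id, spec = spec,
                   tr_seconds = 2,
                   parcels = tibble::tibble(parcel_id = paste0("p", 1:p),
                                            network = rep("default", p)),
                   edge_names = paste0("e", 1:e_count)),
              class = "dfc_series")
  }
  ids <- c(paste0("a", 1:n_per), paste0("b", 1:n_per))
  series <- c(lapply(ids[1:n_per], mk_series, shift = 0),
              lapply(ids[-(1:n_per)], mk_series, shift = 1))
  names(series) <- ids
  model <- structure(list(k = 2,
                          labels = setNames(rep(list(rep(1:2, 15)), 2 * n_per),
                                            ids)),
                     class = "state_model")
  subjects <- tibble::tibble(subject_id = ids,
                             group = rep(c("A", "B"), each = n_per))
  res <- state_edge_contrast(series, model, state = 1, subjects)
  hit <- res$edges[res$edges$q < 0.05, ]
  expect_true("e5" %in% hit$feature)
  expect_gt(res$edges$t[res$edges$feature == "e5"], 0)
  # null edges mostly clean
  expect_lte(nrow(hit), 3)
  # a subject lacking the state is excluded and counted
  model$labels[[1]] <- rep(2, 30)
  res2 <- state_edge_contrast(series, model, state = 1, subjects)
  expect_equal(res2$excluded, ids[1])
  expect_equal(sum(res2$n_per_group), 2 * n_per - 1)
})

test_that("window-truth conversion and state matching are consistent", {
  # modal labelling: windows spanning a transition take the majority state
  lab <- rep(c(1L, 2L), each = 30)
  spec <- window_spec(10, 5)
  tw <- true_window_labels(lab, spec)
  expect_length(tw, n_windows(60, spec))
  expect_equal(tw[1], 1L)
  expect_equal(tw[length(tw)], 2L)
  # matching recovers an arbitrary relabelling exactly
  set.seed(25)
  truth <- sample(1:4, 300, replace = TRUE)
  perm <- c(3L, 1L, 4L, 2L)
  clust <- perm[truth]
  m <- match_states(clust, truth, k = 4)
  expect_equal(m, perm)
  expect_error(match_states(clust[-1], truth), "align")
})
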