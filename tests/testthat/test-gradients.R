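test_that("static FC matches correlation identities and the r-to-z form", {
  set.seed(10)
  x <- matrix(rnorm(200 * 6), 200, 6)
  x[, 2] <- x[, 1]                      # duplicated pair
  tt <- seq_len(200)
  x[, 3] <- sin(2 * pi * tt / 50)       # orthogonal sine/cosine over whole
  x[, 4] <- cos(2 * pi * tt / 50)       # periods
  ts <- make_ts(x)
  r <- compute_fc(ts, fisher = FALSE)
  expect_equal(unclass(r)[1, 2], 1, tolerance = 1e-12)
  expect_lt(abs(unclass(r)[3, 4]), 1e-10)
  expect_equal(unclass(r), t(unclass(r)), tolerance = 1e-12)
  expect_equal(diag(unclass(r)), rep(1, 6), ignore_attr = TRUE)
  # Fisher transform: z = atanh(r), checked against the log form at r = 0.5
  y <- cbind(x[, 5], x[, 5] * 0.5 + x[, 6] * sqrt(0.75))
  r2 <- cor(y)[1, 2]
  z <- compute_fc(make_ts(cbind(y, x[, 1:5])), fisher = TRUE)
  expect_equal(unclass(z)[1, 2], 0.5 * log((1 + r2) / (1 - r2)),
               tolerance = 1e-10)
  expect_equal(0.5 * log(1.5 / 0.5), atanh(0.5), tolerance = 1e-12)
  expect_equal(round(atanh(0.5), 6), 0.549306)
  # constant parcel rejected by name
  xc <- x; xc[, 5] <- 1
  expect_error(compute_fc(make_ts(xc)), "p5")
})

test_that("network profiles have unit rows against all parcels", {
  set.seed(11)
  nets <- rep(seven_networks(), times = c(12, 10, 8, 8, 7, 7, 8))
  x <- matrix(rnorm(120 * 60), 120, 60)
  ts <- make_ts(x, networks = nets)
  pm <- network_profile_matrix(ts, "visual")
  expect_equal(dim(pm), c(12, 60))
  # duplicated unit gives identical profile rows
  x2 <- x; x2[, 2] <- x2[, 1]
  pm2 <- network_profile_matrix(make_ts(x2, networks = nets), "visual")
  expect_equal(pm2[1, -(1:2)], pm2[2, -(1:2)], tolerance = 1e-10)
  # too-small network rejected
  nets_small <- c(rep("visual", 2), rep("default", 58))
  expect_error(network_profile_matrix(make_ts(x, networks = nets_small),
                                      "visual"), ">= 5")
  expect_error(network_profile_matrix(ts, "attention"), "unknown")
})

test_that("cosine affinity sparsifies, clips and symmetrizes", {
  # identical rows -> affinity 1; antiparallel rows -> clipped to 0
  base <- matrix(rnorm(5 * 40), 5, 40)
  prof <- rbind(base[1, ], base[1, ], -base[1, ], base[2:3, ])
  a <- cosine_affinity(prof, embedding_config(row_sparsity = 1))
  expect_equal(unclass(a)[1, 2], 1, tolerance = 1e-12)
  expect_equal(unclass(a)[1, 3], 0)
  expect_true(all(a >= 0 & a <= 1 + 1e-12))
  expect_equal(unclass(a), t(unclass(a)), tolerance = 1e-12)
  # top-10% retention keeps ceiling(0.1 * 60) = 6 entries per row
  set.seed(12)
  prof60 <- matrix(rnorm(10 * 60), 10, 60)
  cfg <- embedding_config(row_sparsity = 0.10)
  keep <- ceiling(60 * 0.10)
  expect_equal(keep, 6)
  # reproduce the sparsification and check the affinity agrees with a
  # direct cosine of the thresholded rows
  sp <- prof60
  for (i in 1:10) {
    thr <- sort(prof60[i, ], decreasing = TRUE)[6]
    sp[i, prof60[i, ] < thr] <- 0
  }
  expect_true(all(rowSums(sp != 0) == 6))
  a2 <- cosine_affinity(prof60, cfg)
  i <- 3; j <- 7
  manual <- sum(sp[i, ] * sp[j, ]) /
    sqrt(sum(sp[i, ]^2) * sum(sp[j, ]^2))
  expect_equal(unclass(a2)[i, j], max(manual, 0), tolerance = 1e-12)
})

test_that("diffusion embedding matches a dense eigensolver oracle", {
  set.seed(13)
  # random smooth affinity on 18 units
  g <- seq(-1, 1, length.out = 18)
  a <- 0.5 * exp(-abs(outer(g, g, "-")) / 0.6) +
    matrix(runif(18 * 18, 0, 0.05), 18, 18)
  a <- (a + t(a)) / 2; diag(a) <- 0
  cfg <- embedding_config(n_components = 5)
  emb <- diffusion_embedding(a, cfg)
  # Markov row-stochasticity of the normalized operator
  deg <- rowSums(a)
  wprime <- a / outer(deg^0.5, deg^0.5)
  markov <- wprime / rowSums(wprime)
  expect_equal(rowSums(markov), rep(1, 18), tolerance = 1e-12)
  # dense non-symmetric eigendecomposition oracle
  orc <- oracle_diffusion(a, alpha = 0.5, n_components = 5)
  expect_equal(emb$eigenvalues, orc$eigenvalues, tolerance = 1e-10)
  expect_lt(component_diff(emb$components, orc$components), 1e-8)
  # eigenvalues non-increasing; variance fractions well-formed
  expect_true(all(diff(emb$eigenvalues) <= 1e-12))
  expect_equal(sum(emb$variance_explained), 1, tolerance = 1e-12)
})

test_that("two-block affinity sign-separates blocks on gradient 1", {
  blocks <- matrix(0.05, 20, 20)
  blocks[1:10, 1:10] <- 1
  blocks[11:20, 11:20] <- 1
  diag(blocks) <- 0
  emb <- diffusion_embedding(blocks, embedding_config(n_components = 3))
  g1 <- emb$components[, 1]
  expect_true(all(sign(g1[1:10]) == sign(g1[1])))
  expect_true(all(sign(g1[11:20]) == -sign(g1[1])))
  # disconnected affinity rejected
  disc <- blocks
  disc[1:10, 11:20] <- 0; disc[11:20, 1:10] <- 0; disc[5, ] <- 0; disc[, 5] <- 0
  expect_error(diffusion_embedding(disc, embedding_config(n_components = 3)),
               "disconnected")
})

test_that("group template equals the subject embedding for identical input", {
  set.seed(14)
  x <- matrix(rnorm(150 * 20), 150, 20)
  ts <- make_ts(x)
  prof <- network_profile_matrix(ts, "all")
  cfg <- embedding_config(n_components = 4)
  tmpl1 <- build_group_template(list(prof), cfg)
  tmpl3 <- build_group_template(list(prof, prof, prof), cfg)
  direct <- diffusion_embedding(cosine_affinity(prof, cfg), cfg)
  expect_lt(component_diff(tmpl1$components, direct$components), 1e-10)
  expect_lt(component_diff(tmpl3$components, direct$components), 1e-10)
  expect_error(build_group_template(list(prof, prof[, 1:10]), cfg),
               "mismatch")
})

test_that("Procrustes alignment recovers orthogonal transforms", {
  set.seed(15)
  x <- matrix(rnorm(30 * 4), 30, 4)
  x <- scale(x, scale = FALSE)
  # self-alignment: identity up to sign, zero disparity
  self <- procrustes_align(x, x)
  expect_lt(self$disparity, 1e-10)
  expect_equal(abs(diag(self$rotation)), rep(1, 4), tolerance = 1e-8)
  # random rotation recovered
  q <- random_orthogonal(4)
  al <- procrustes_align(x %*% q, x)
  expect_lt(al$disparity, 1e-8)
  expect_equal(al$components, x, tolerance = 1e-8, ignore_attr = TRUE)
  # reflection (sign flip) corrected
  flip <- diag(c(-1, 1, 1, 1))
  al2 <- procrustes_align(x %*% flip, x)
  expect_lt(al2$disparity, 1e-8)
  # rank-deficient input rejected
  bad <- cbind(x[, 1], x[, 1], x[, 2], x[, 3])
  expect_error(procrustes_align(bad, x), "rank")
})

test_that("standardization yields exact z-scores and is idempotent", {
  set.seed(16)
  x <- matrix(rnorm(40 * 3, mean = 5, sd = 3), 40, 3)
  colnames(x) <- paste0("g", 1:3)
  z1 <- standardize_components(x)
  expect_lt(max(abs(colMeans(z1$components))), 1e-10)
  expect_lt(max(abs(apply(z1$components, 2, sd) - 1)), 1e-10)
  z2 <- standardize_components(z1)
  expect_equal(z2$components, z1$components, tolerance = 1e-12)
  xc <- x; xc[, 2] <- 7
  expect_error(standardize_components(xc), "constant")
})

test_that("network dispersion follows centroid geometry", {
  # all members at one point: zero within-dispersion
  pts <- rbind(c(1, 2), c(1, 2), c(1, 2), c(0, 0), c(3, 4))
  nets <- c("visual", "visual", "visual", "default", "default")
  colnames(pts) <- c("g1", "g2")
  d <- network_dispersion(pts, nets, n_components_used = 2)
  expect_equal(d$within$dispersion[d$within$network == "visual"], 0)
  # members at (0,0) and (2,0): centroid (1,0), dispersion 1 + 1 = 2
  pts2 <- rbind(c(0, 0), c(2, 0), c(0, 0), c(0, 3), c(0, 5))
  nets2 <- c("visual", "visual", "default", "default", "default")
  colnames(pts2) <- c("g1", "g2")
  d2 <- network_dispersion(pts2, nets2, 2)
  expect_equal(d2$within$dispersion[d2$within$network == "visual"], 2)
  # centroids at (0,0) and (3,4): 3-4-5 triangle distance 5
  pts3 <- rbind(c(0, 0), c(0, 0), c(3, 4), c(3, 4))
  nets3 <- c("somatomotor", "somatomotor", "default", "default")
  colnames(pts3) <- c("g1", "g2")
  d3 <- network_dispersion(pts3, nets3, 2)
  expect_equal(d3$between$distance, 5)
})

test_that("pipeline orients gradient 1 with somatomotor negative", {
  cfg <- cohort_config(n_per_group = 2, n_parcels = 28, n_timepoints = 120,
                       seed = 21)
  coh <- simulate_cohort(cfg)
  fit <- fit_gradients(coh$timeseries, config = embedding_config(n_components = 4))
  for (al in fit$aligned) {
    smi <- fit$networks == "somatomotor"
    expect_lte(mean(al$components[smi, 1]), 0)
    # z-scored components
    expect_lt(max(abs(colMeans(al$components))), 1e-8)
    expect_lt(max(abs(apply(al$components, 2, sd) - 1)), 1e-8)
  }
  expect_equal(sort(unique(fit$scores$component)), paste0("g", 1:4))
})

test_that("alignment makes a rotated dataset's scores recoverable", {
  set.seed(17)
  x <- scale(matrix(rnorm(25 * 5), 25, 5), scale = FALSE)
  q <- random_orthogonal(5)
  back <- procrustes_align(x %*% q, x)$components
  expect_lt(max(abs(back - x)), 1e-6)
})
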