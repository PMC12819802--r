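#' Synthetic-cohort configuration
#'
#' Full generative specification of a two-group synthetic resting-state
#' cohort. Each subject's parcel time series follows a hidden-Markov switching
#' multivariate normal model: a latent 1-D connectivity hierarchy `g` (the
#' unimodal-to-transmodal axis, spaced over \eqn{[-1, 1]}) shapes a smooth
#' base covariance whose entries decay with axis distance; each of the K
#' recurring states modulates that kernel with a state-specific coupling
#' strength and a smooth harmonic field on the axis, so that states are well
#' separated as window-level connectivity patterns while every state preserves
#' the planted hierarchy. States switch on an epoch grid (default 10
#' timepoints) following group-specific row-stochastic transition matrices.
#' Group effects re-wire chosen parcels toward the opposite end of the axis;
#' clinical covariates are linear functions of chosen features plus noise.
#'
#' @param n_per_group Subjects per group (two groups, "A" and "B").
#' @param n_parcels Number of parcels P (>= 10).
#' @param n_timepoints Timepoints T per subject (before any volume discard).
#' @param tr_seconds Repetition time in seconds.
#' @param n_states Number K of connectivity states.
#' @param transition_matrix_per_group Named list of K x K row-stochastic
#'   matrices (names "A", "B"); default: sticky chains with uniform stationary
#'   occupancy and self-transition 0.95 for both groups.
#' @param network_labels Length-P character vector of seven-network labels;
#'   default: seven contiguous blocks along the axis.
#' @param latent_axis Length-P numeric in \eqn{[-1, 1]}; default linearly
#'   spaced.
#' @param epoch_length Timepoints per state epoch (default 10): states switch
#'   at epoch boundaries so that dwell structure survives 50-TR windowing.
#' @param base_strength Range of state coupling strengths b_s (peak
#'   correlation scale), default `c(0.25, 0.5)`.
#' @param kernel_length Decay length of the axis kernel exp(-|g_p - g_q|/len),
#'   default 0.8.
#' @param modulation_amplitude Amplitude a of the per-state harmonic field
#'   `1 + a f_s(g_p) f_s(g_q)`, default 1.
#' @param network_boost Additive within-network correlation boost, default 0
#'   (a sizeable boost masks the planted hierarchy).
#' @param effect_spec List of group-B effects, each
#'   `list(parcels = <ids or indices>, magnitude = m in [0,1])`: the target
#'   parcel's couplings are moved fraction `m` toward those of its
#'   axis-mirrored position.
#' @param covariate_spec List of covariates, each
#'   `list(name, feature = <parcel id or index>, slope, noise_sd)`; the
#'   covariate is `slope * planted_feature + noise`, where the planted
#'   per-subject feature is the linked parcel's axis score plus
#'   subject-level variation (stored in the ground truth for recovery
#'   tests).
#' @param ar1_coefficient AR(1) smoothing coefficient in \eqn{[0, 1)}.
#' @param noise_sd Additive white observation noise sd.
#' @param seed Integer seed governing all randomness in [simulate_cohort()].
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 20,
                          n_parcels = 60,
                          n_timepoints = 240,
                          tr_seconds = 2,
                          n_states = 4,
                          transition_matrix_per_group = NULL,
                          network_labels = NULL,
                          latent_axis = NULL,
                          epoch_length = 10,
                          base_strength = c(0.25, 0.5),
                          kernel_length = 0.8,
                          modulation_amplitude = 1,
                          network_boost = 0,
                          effect_spec = list(),
                          covariate_spec = list(),
                          ar1_coefficient = 0.3,
                          noise_sd = 0.1,
                          seed = 1L) {
  stop_not(n_parcels >= 10, "need at least 10 parcels")
  stop_not(n_states >= 1, "need at least one state")
  stop_not(ar1_coefficient >= 0 && ar1_coefficient < 1,
           "`ar1_coefficient` must be in [0, 1)")
  if (is.null(network_labels)) {
    network_labels <- .networks7[ceiling(seq_len(n_parcels) / (n_parcels / 7))]
  }
  stop_not(length(network_labels) == n_parcels,
           "`network_labels` must have length n_parcels")
  bad <- setdiff(unique(network_labels), .networks7)
  stop_not(length(bad) == 0, "unknown network name(s): %s",
           paste(bad, collapse = ", "))
  if (is.null(latent_axis)) {
    latent_axis <- seq(-1, 1, length.out = n_parcels)
  }
  stop_not(length(latent_axis) == n_parcels &&
             all(abs(latent_axis) <= 1 + 1e-12),
           "`latent_axis` must be length n_parcels with values in [-1, 1]")
  if (is.null(transition_matrix_per_group)) {
    tm <- sticky_transition_matrix(rep(1 / n_states, n_states),
                                   self_transition = 0.95)
    transition_matrix_per_group <- list(A = tm, B = tm)
  }
  stop_not(all(c("A", "B") %in% names(transition_matrix_per_group)),
           "`transition_matrix_per_group` needs elements 'A' and 'B'")
  for (gr in c("A", "B")) {
    tm <- transition_matrix_per_group[[gr]]
    stop_not(is_row_stochastic(tm, tol = 1e-12) && nrow(tm) == n_states,
             "group %s transition matrix must be %d x %d row-stochastic",
             gr, n_states, n_states)
  }
  structure(
    list(n_per_group = n_per_group, n_parcels = n_parcels,
         n_timepoints = n_timepoints, tr_seconds = tr_seconds,
         n_states = n_states,
         transition_matrix_per_group = transition_matrix_per_group,
         network_labels = network_labels, latent_axis = latent_axis,
         epoch_length = epoch_length, base_strength = base_strength,
         kernel_length = kernel_length,
         modulation_amplitude = modulation_amplitude,
         network_boost = network_boost,
         effect_spec = effect_spec, covariate_spec = covariate_spec,
         ar1_coefficient = ar1_coefficient, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Sticky transition matrix with a chosen stationary distribution
#'
#' Builds the reversible chain `T_ij = c * pi_j` (i != j),
#' `T_ii = 1 - c * (1 - pi_i)`, whose stationary distribution is exactly
#' `pi`. `c` is set from either `coupling` directly or from the requested
#' mean `self_transition` (averaged over states under `pi`).
#'
#' @param pi Stationary probabilities (must sum to 1).
#' @param self_transition Target mean self-transition probability.
#' @param coupling Directly specify `c` instead (overrides `self_transition`).
#' @return A K x K row-stochastic matrix.
#' @export
#' @examples
#' tm <- sticky_transition_matrix(c(0.35, 0.65), self_transition = 0.9)
#' analytic_expectations(tm)
sticky_transition_matrix <- function(pi, self_transition = 0.95,
                                     coupling = NULL) {
  stop_not(abs(sum(pi) - 1) < 1e-10 && all(pi > 0),
           "`pi` must be positive and sum to 1")
  k <- length(pi)
  if (k == 1) return(matrix(1, 1, 1))
  if (is.null(coupling)) {
    # mean self-transition = 1 - c * sum_i pi_i (1 - pi_i)
    coupling <- (1 - self_transition) / sum(pi * (1 - pi))
  }
  stop_not(coupling > 0 && all(1 - coupling * (1 - pi) >= 0),
           "coupling too large for the requested stationary distribution")
  tm <- coupling * matrix(pi, k, k, byrow = TRUE)
  diag(tm) <- 1 - coupling * (1 - pi)
  tm
}

#' Build the generative covariance model
#'
#' Constructs the latent axis and the K state covariance matrices implied by a
#' [cohort_config()]. The base kernel is
#' \eqn{b_s \exp(-|g_p - g_q| / \ell) (1 + a f_s(g_p) f_s(g_q))} with
#' \eqn{f_s(g) = \cos(\pi s (g + 1) / 2)}, plus an optional within-network
#' boost; the diagonal is 1 and every matrix is floored to be positive
#' semidefinite (eigenvalue floor 1e-8).
#'
#' @param config A [cohort_config()].
#' @return A list with `state_covariances` (list of K P x P matrices),
#'   `latent_axis`, and `network_labels`.
#' @export
build_generative_model <- function(config) {
  stop_not(inherits(config, "cohort_config"), "`config` must be a cohort_config")
  g <- config$latent_axis
  p <- config$n_parcels
  k <- config$n_states
  d <- abs(outer(g, g, "-"))
  same_net <- outer(config$network_labels, config$network_labels, "==")
  b <- seq(config$base_strength[1], config$base_strength[2],
           length.out = max(k, 2))[seq_len(k)]
  covs <- lapply(seq_len(k), function(s) {
    f <- cos(pi * s * (g + 1) / 2)
    r <- b[s] * exp(-d / config$kernel_length) *
      (1 + config$modulation_amplitude * outer(f, f))
    r[same_net] <- r[same_net] + config$network_boost
    r <- pmin(pmax(r, -0.9), 0.9)
    diag(r) <- 1
    out <- psd_floor(r)
    stop_not(min(eigen(out, symmetric = TRUE, only.values = TRUE)$values) >=
               -1e-10, "state %d covariance not PSD after flooring", s)
    out
  })
  list(state_covariances = covs, latent_axis = g,
       network_labels = config$network_labels)
}

#' Simulate a Markov state sequence
#'
#' Simulates `n` steps of the chain defined by a row-stochastic transition
#' matrix, started from its stationary distribution (or a fixed state). The
#' same seed always yields the same sequence.
#'
#' @param transition_matrix K x K row-stochastic matrix.
#' @param n Number of steps.
#' @param seed Integer seed.
#' @param init Optional fixed initial state (1..K); default: drawn from the
#'   stationary distribution.
#' @return Integer vector of length `n` with values in 1..K.
#' @export
#' @examples
#' simulate_state_sequence(matrix(c(0, 1, 1, 0), 2, 2), 6, seed = 1, init = 1)
simulate_state_sequence <- function(transition_matrix, n, seed, init = NULL) {
  stop_not(is_row_stochastic(transition_matrix, tol = 1e-8),
           "`transition_matrix` rows must be nonnegative and sum to 1")
  stop_not(n >= 1, "`n` must be >= 1")
  k <- nrow(transition_matrix)
  with_seed(seed, {
    s <- integer(n)
    s[1] <- if (is.null(init)) {
      pi0 <- stationary_distribution(transition_matrix)
      sample.int(k, 1, prob = pi0)
    } else {
      as.integer(init)
    }
    if (n > 1) {
      for (i in 2:n) {
        row <- transition_matrix[s[i - 1], ]
        s[i] <- if (max(row) >= 1 - 1e-12) which.max(row)
                else sample.int(k, 1, prob = row)
      }
    }
    s
  })
}

stationary_distribution <- function(tm) {
  e <- eigen(t(tm))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Analytic occupancy and dwell-time expectations of a Markov chain
#'
#' Solves \eqn{\pi T = \pi} for the stationary occupancy and applies the
#' closed form \eqn{\mathrm{dwell}_s = 1 / (1 - p_{ss})} for the expected
#' dwell length (in chain steps). Absorbing states (`p_ss = 1`) are flagged
#' as unbounded with `dwell = Inf`.
#'
#' @param transition_matrix K x K row-stochastic matrix.
#' @return A tibble with columns `state`, `occupancy`, `dwell`, `unbounded`.
#' @export
#' @examples
#' analytic_expectations(matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2))
analytic_expectations <- function(transition_matrix) {
  stop_not(is_row_stochastic(transition_matrix, tol = 1e-8),
           "`transition_matrix` rows must be nonnegative and sum to 1")
  pi0 <- stationary_distribution(transition_matrix)
  pss <- diag(transition_matrix)
  unbounded <- pss >= 1 - 1e-12
  dwell <- ifelse(unbounded, Inf, 1 / (1 - pss))
  tibble(state = seq_along(pi0), occupancy = pi0, dwell = dwell,
         unbounded = unbounded)
}

# Apply group-B re-wiring: move target parcels' couplings toward the
# axis-mirrored parcel's couplings by fraction m.
apply_effects <- function(covs, config) {
  if (length(config$effect_spec) == 0) return(covs)
  g <- config$latent_axis
  ids <- paste0("p", seq_len(config$n_parcels))
  for (eff in config$effect_spec) {
    idx <- eff$parcels
    if (is.character(idx)) idx <- match(idx, ids)
    stop_not(all(!is.na(idx)) && all(idx >= 1 & idx <= config$n_parcels),
             "effect parcels outside 1..%d", config$n_parcels)
    m <- eff$magnitude
    stop_not(is.numeric(m) && m >= 0 && m <= 1,
             "effect magnitude must be in [0, 1]")
    for (p0 in idx) {
      mirror <- which.min(abs(g + g[p0]))  # parcel closest to -g[p0]
      covs <- lapply(covs, function(s) {
        row <- (1 - m) * s[p0, ] + m * s[mirror, ]
        row[p0] <- 1
        s[p0, ] <- row
        s[, p0] <- row
        psd_floor(s)
      })
    }
  }
  covs
}

#' Simulate one subject's parcel time series
#'
#' Draws an epoch-level Markov state sequence, samples each timepoint from a
#' zero-mean multivariate normal with the active state's covariance, applies
#' AR(1) temporal smoothing and additive white noise. Reproducible under
#' `seed`; the true per-timepoint state labels are attached as attribute
#' `"state_labels"`.
#'
#' @param config A [cohort_config()].
#' @param group `"A"` or `"B"`; group B receives the configured connectivity
#'   effects.
#' @param seed Integer seed for this subject.
#' @param subject_id Identifier.
#' @param model Optional precomputed [build_generative_model()] output (with
#'   effects already applied), to avoid rebuilding per subject.
#' @return A [parcel_ts()] with attribute `state_labels` (length T).
#' @export
simulate_subject <- function(config, group = "A", seed = config$seed,
                             subject_id = "subject", model = NULL) {
  stop_not(group %in% c("A", "B"), "`group` must be 'A' or 'B'")
  if (is.null(model)) {
    model <- build_generative_model(config)
    if (group == "B") {
      model$state_covariances <- apply_effects(model$state_covariances, config)
    }
  }
  tmat <- config$transition_matrix_per_group[[group]]
  tp <- config$n_timepoints
  n_epochs <- ceiling(tp / config$epoch_length)
  lab_epoch <- simulate_state_sequence(tmat, n_epochs, seed = seed)
  lab <- rep(lab_epoch, each = config$epoch_length)[seq_len(tp)]
  chols <- lapply(seq_along(model$state_covariances), function(s) {
    out <- tryCatch(chol(model$state_covariances[[s]] +
                           diag(1e-10, config$n_parcels)),
                    error = function(e) NULL)
    stop_not(!is.null(out), "covariance sampling failed for state %d", s)
    out
  })
  x <- with_seed(seed + 1L, {
    x <- matrix(rnorm(tp * config$n_parcels), tp, config$n_parcels)
    for (s in unique(lab)) {
      i <- which(lab == s)
      x[i, ] <- x[i, , drop = FALSE] %*% chols[[s]]
    }
    a <- config$ar1_coefficient
    if (a > 0) {
      for (t in 2:tp) x[t, ] <- a * x[t - 1, ] + sqrt(1 - a^2) * x[t, ]
    }
    if (config$noise_sd > 0) {
      x <- x + matrix(rnorm(tp * config$n_parcels, sd = config$noise_sd),
                      tp, config$n_parcels)
    }
    x
  })
  parcels <- tibble(parcel_id = paste0("p", seq_len(config$n_parcels)),
                    network = config$network_labels)
  out <- parcel_ts(x, config$tr_seconds, parcels, subject_id)
  attr(out, "state_labels") <- lab
  out
}

#' Simulate a full two-group cohort
#'
#' Generates `n_per_group` subjects per group with group-specific transition
#' matrices and (for group B) the configured connectivity effects, draws age,
#' sex and the configured clinical covariates, and returns analytic ground
#' truth for parameter-recovery testing.
#'
#' @param config A [cohort_config()].
#' @return A list with
#'   * `timeseries`: named list of [parcel_ts()] objects,
#'   * `subjects`: tibble (subject_id, group, age, sex, covariates...),
#'   * `truth`: list with per-subject epoch state labels, per-group stationary
#'     occupancy/dwell expectations, the planted axis, planted per-parcel
#'     gradient offsets (effect parcels and magnitudes) and covariate links.
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_config(n_per_group = 2, n_parcels = 20,
#'                                         n_timepoints = 120, seed = 7))
#' cohort$subjects
#' }
simulate_cohort <- function(config) {
  stop_not(inherits(config, "cohort_config"), "`config` must be a cohort_config")
  n <- config$n_per_group
  groups <- rep(c("A", "B"), each = n)
  ids <- sprintf("sub-%s%02d", groups, c(seq_len(n), seq_len(n)))
  base_model <- build_generative_model(config)
  model_b <- base_model
  model_b$state_covariances <- apply_effects(base_model$state_covariances, config)
  seeds <- config$seed + 1000L + seq_along(ids)
  ts_list <- vector("list", length(ids))
  state_labels <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    m <- if (groups[i] == "A") base_model else model_b
    ts_list[[i]] <- simulate_subject(config, groups[i], seed = seeds[i],
                                     subject_id = ids[i], model = m)
    state_labels[[i]] <- attr(ts_list[[i]], "state_labels")
  }
  names(ts_list) <- ids
  names(state_labels) <- ids

  covariate_features <- list()
  subjects <- with_seed(config$seed + 5000L, {
    tb <- tibble(
      subject_id = ids, group = groups,
      age = round(rnorm(length(ids), mean = 68, sd = 6), 1),
      sex = sample(c("F", "M"), length(ids), replace = TRUE)
    )
    for (cv in config$covariate_spec) {
      feat_idx <- cv$feature
      if (is.character(feat_idx)) {
        feat_idx <- match(feat_idx, paste0("p", seq_len(config$n_parcels)))
      }
      stop_not(!is.na(feat_idx) && feat_idx >= 1 &&
                 feat_idx <= config$n_parcels,
               "covariate '%s' links to an unknown feature", cv$name)
      # planted per-subject feature value: the linked parcel's axis score
      # plus subject-level variation (individual gradient differences)
      feat <- config$latent_axis[feat_idx] + rnorm(length(ids), sd = 0.5)
      covariate_features[[cv$name]] <- setNames(feat, ids)
      tb[[cv$name]] <- cv$slope * feat + rnorm(length(ids), sd = cv$noise_sd)
    }
    tb
  })

  truth <- list(
    state_labels = state_labels,
    expectations = lapply(config$transition_matrix_per_group,
                          analytic_expectations),
    latent_axis = config$latent_axis,
    effects = config$effect_spec,
    covariate_links = config$covariate_spec,
    covariate_features = covariate_features,
    seeds = setNames(seeds, ids)
  )
  list(timeseries = ts_list, subjects = subjects, truth = truth)
}

#' Write a simulated cohort to plain-text files
#'
#' One TSV per subject (rows = timepoints, columns = parcel ids), a parcel
#' metadata TSV, a subjects TSV and a ground-truth JSON.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$timeseries)) {
    write_parcel_timeseries(cohort$timeseries[[id]],
                            file.path(dir, paste0(id, ".tsv")))
  }
  first <- cohort$timeseries[[1]]
  readr::write_tsv(first$parcels, file.path(dir, "parcels.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$subjects, file.path(dir, "subjects.tsv"),
                   progress = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
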