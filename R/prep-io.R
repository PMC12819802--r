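#' Parcellated BOLD time-series container
#'
#' Bundles one subject's timepoints x parcels signal matrix with its repetition
#' time and parcel metadata. All analysis functions in the package accept this
#' object. The parcel table must label every parcel with one of the seven
#' canonical networks (see [seven_networks()]).
#'
#' @param data Numeric matrix, timepoints x parcels. Column names, if present,
#'   must match `parcels$parcel_id`.
#' @param tr_seconds Repetition time in seconds (> 0).
#' @param parcels Data frame with columns `parcel_id`, `network` and optional
#'   `x`, `y`, `z` coordinates; one row per column of `data`, in column order.
#' @param subject_id Identifier carried through to downstream tables.
#'
#' @return An object of class `parcel_ts`.
#' @export
#' @examples
#' ts <- parcel_ts(matrix(rnorm(40), 10, 4), 2,
#'                 data.frame(parcel_id = paste0("p", 1:4),
#'                            network = seven_networks()[c(1, 1, 2, 7)]))
#' dim(ts$data)
parcel_ts <- function(data, tr_seconds, parcels, subject_id = "subject") {
  stop_not(is.matrix(data) && is.numeric(data), "`data` must be a numeric matrix")
  stop_not(!anyNA(data), "`data` contains missing values; impute or drop upstream")
  stop_not(is.numeric(tr_seconds) && length(tr_seconds) == 1 && tr_seconds > 0,
           "`tr_seconds` must be a single positive number")
  parcels <- as_tibble(parcels)
  stop_not(all(c("parcel_id", "network") %in% names(parcels)),
           "`parcels` needs columns parcel_id and network")
  stop_not(nrow(parcels) == ncol(data),
           "parcel table has %d rows but data has %d columns",
           nrow(parcels), ncol(data))
  bad <- setdiff(unique(parcels$network), .networks7)
  stop_not(length(bad) == 0, "unknown network name(s): %s",
           paste(bad, collapse = ", "))
  parcels$parcel_id <- as.character(parcels$parcel_id)
  stop_not(!anyDuplicated(parcels$parcel_id), "duplicated parcel ids")
  if (!is.null(colnames(data))) {
    stop_not(identical(colnames(data), parcels$parcel_id),
             "data column names disagree with the parcel table order")
  } else {
    colnames(data) <- parcels$parcel_id
  }
  structure(
    list(subject_id = as.character(subject_id), data = data,
         tr_seconds = tr_seconds, parcels = parcels),
    class = "parcel_ts"
  )
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> %s: %d timepoints x %d parcels, TR = %gs\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  nets <- table(x$parcels$network)
  cat("  networks:", paste(sprintf("%s(%d)", names(nets), nets), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read a parcellated time series from TSV
#'
#' The data file is a TSV with a header row of parcel ids and one row per
#' timepoint. The metadata file maps every parcel id to a seven-network label
#' (columns `parcel_id`, `network`, optional `x`, `y`, `z`). Parcels are
#' reordered to the data's column order; a parcel present in the data but
#' absent from the metadata is an error naming the parcel.
#'
#' @param path Path to the time-series TSV.
#' @param parcel_metadata_path Path to the parcel metadata TSV.
#' @param tr_seconds Repetition time in seconds.
#' @param subject_id Subject identifier; defaults to the file stem.
#' @return A [parcel_ts()] object.
#' @export
read_parcel_timeseries <- function(path, parcel_metadata_path, tr_seconds = 2,
                                   subject_id = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  not_num <- names(raw)[!vapply(raw, is.numeric, logical(1))]
  if (length(not_num) > 0) {
    for (cn in not_num) {
      row <- which(is.na(suppressWarnings(as.numeric(raw[[cn]]))))[1]
      abort(sprintf("non-numeric value in column '%s', data row %d", cn, row))
    }
  }
  meta <- readr::read_tsv(parcel_metadata_path, show_col_types = FALSE,
                          progress = FALSE)
  meta$parcel_id <- as.character(meta$parcel_id)
  missing <- setdiff(names(raw), meta$parcel_id)
  stop_not(length(missing) == 0,
           "parcel(s) in data but not in metadata: %s",
           paste(missing, collapse = ", "))
  meta <- meta[match(names(raw), meta$parcel_id), , drop = FALSE]
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  parcel_ts(as.matrix(raw), tr_seconds, meta, subject_id)
}

#' Write a parcellated time series to TSV
#'
#' Inverse of [read_parcel_timeseries()]; writing then reading round-trips the
#' data to near machine precision.
#'
#' @param ts A [parcel_ts()] object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_parcel_timeseries <- function(ts, path) {
  readr::write_tsv(as_tibble(as.data.frame(ts$data)), path, progress = FALSE)
  invisible(path)
}

#' Discard initial volumes
#'
#' Drops the first `n_discard` timepoints (signal-equilibration volumes) from
#' the series; the standard resting-state convention discards 10.
#'
#' @param ts A [parcel_ts()] object.
#' @param n_discard Number of leading timepoints to remove (default 10); must
#'   leave at least one timepoint.
#' @return A [parcel_ts()] with `n_discard` fewer rows.
#' @export
#' @examples
#' ts <- parcel_ts(matrix(rnorm(240 * 3), 240, 3), 2,
#'                 data.frame(parcel_id = c("a", "b", "c"),
#'                            network = rep("default", 3)))
#' nrow(discard_initial_volumes(ts, 10)$data)  # 230
discard_initial_volumes <- function(ts, n_discard = 10) {
  stop_not(inherits(ts, "parcel_ts"), "`ts` must be a parcel_ts")
  stop_not(n_discard >= 0 && n_discard == round(n_discard),
           "`n_discard` must be a nonnegative integer")
  stop_not(n_discard < nrow(ts$data),
           "discarding %d volumes would leave an empty series (T = %d)",
           n_discard, nrow(ts$data))
  if (n_discard == 0) return(ts)
  ts$data <- ts$data[-seq_len(n_discard), , drop = FALSE]
  ts
}

#' Temporal-cleaning configuration
#'
#' Parameters for [clean_timeseries()]: polynomial detrending order, the
#' band-pass edges in Hz, and the number of leading volumes handled by
#' [discard_initial_volumes()]. The default band 0.01-0.08 Hz is the
#' conventional low-frequency BOLD band; it must lie inside (0, Nyquist).
#'
#' @param n_discard Leading volumes to discard (default 10).
#' @param detrend_order Polynomial trend order: 0 (demean only), 1 (linear,
#'   default) or 2 (linear + quadratic).
#' @param band Length-2 numeric, band-pass edges in Hz (default
#'   c(0.01, 0.08)), or `NULL` to skip filtering.
#' @return A `cleaning_config` list.
#' @export
cleaning_config <- function(n_discard = 10, detrend_order = 1,
                            band = c(0.01, 0.08)) {
  stop_not(detrend_order %in% 0:2, "`detrend_order` must be 0, 1 or 2")
  if (!is.null(band)) {
    stop_not(length(band) == 2 && band[1] >= 0 && band[1] < band[2],
             "`band` must satisfy 0 <= low < high")
  }
  structure(list(n_discard = n_discard, detrend_order = detrend_order,
                 band = band), class = "cleaning_config")
}

# Zero-phase Butterworth band-pass, order 4, forward-backward.
butter_bandpass <- function(x, band, fs, order = 4) {
  wn <- band / (fs / 2)
  flt <- signal::butter(order, wn, type = "pass")
  signal::filtfilt(flt, x)
}

#' Clean a parcellated time series
#'
#' Applies, in fixed order and independently per parcel: polynomial
#' detrending by least squares, regression of nuisance confounds, and a
#' zero-phase (forward-backward) order-4 Butterworth band-pass. The cleaned
#' series has (numerically) zero mean per parcel. Volume discard is separate
#' ([discard_initial_volumes()]) so the two steps can be logged individually.
#'
#' @param ts A [parcel_ts()] object.
#' @param config A [cleaning_config()].
#' @param confounds Optional numeric matrix of nuisance regressors
#'   (timepoints x regressors), e.g. CSF signal; regressed out after
#'   detrending.
#' @return A cleaned [parcel_ts()]. Parcels that end up constant are an error.
#' @export
clean_timeseries <- function(ts, config = cleaning_config(), confounds = NULL) {
  stop_not(inherits(ts, "parcel_ts"), "`ts` must be a parcel_ts")
  stop_not(inherits(config, "cleaning_config"), "`config` must be a cleaning_config")
  x <- ts$data
  n <- nrow(x)
  nyq <- 1 / (2 * ts$tr_seconds)
  if (!is.null(config$band)) {
    stop_not(config$band[2] < nyq,
             "band upper edge %.3f Hz is not below Nyquist %.3f Hz",
             config$band[2], nyq)
  }
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    stop_not(nrow(confounds) == n,
             "confounds have %d rows but series has %d timepoints",
             nrow(confounds), n)
  }
  # 1) detrend
  if (config$detrend_order == 0) {
    x <- scale(x, center = TRUE, scale = FALSE)
  } else {
    tt <- poly(seq_len(n), degree = config$detrend_order)
    x <- stats::lm.fit(cbind(1, tt), x)$residuals
  }
  # 2) confound regression
  if (!is.null(confounds)) {
    x <- stats::lm.fit(cbind(1, confounds), x)$residuals
  }
  # 3) zero-phase band-pass
  fs <- 1 / ts$tr_seconds
  if (!is.null(config$band)) {
    x <- apply(x, 2, butter_bandpass, band = config$band, fs = fs)
  }
  x <- scale(x, center = TRUE, scale = FALSE)  # filtering leaves a tiny offset
  attr(x, "scaled:center") <- NULL
  const <- apply(x, 2, function(v) sd(v) < 1e-12)
  stop_not(!any(const), "parcel(s) constant after cleaning: %s",
           paste(ts$parcels$parcel_id[const], collapse = ", "))
  dimnames(x) <- dimnames(ts$data)
  ts$data <- x
  ts
}
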