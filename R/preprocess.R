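# Preprocessing: filtering, mu-law normalization and sliding-window
# segmentation of sEMG trials into fixed-length windows.

# direct-form-II-transposed IIR filter with explicit initial state
iir_filter <- function(b, a, x, zi = NULL) {
  nf <- max(length(a), length(b))
  b <- c(b, numeric(nf - length(b))) / a[1]
  a <- c(a, numeric(nf - length(a))) / a[1]
  n <- length(x)
  z <- if (is.null(zi)) numeric(nf - 1L) else zi
  y <- numeric(n)
  if (nf == 1L) return(b[1] * x)
  for (i in seq_len(n)) {
    yi <- b[1] * x[i] + z[1]
    if (nf > 2L) {
      z[1:(nf - 2L)] <- b[2:(nf - 1L)] * x[i] + z[2:(nf - 1L)] - a[2:(nf - 1L)] * yi
    }
    z[nf - 1L] <- b[nf] * x[i] - a[nf] * yi
    y[i] <- yi
  }
  y
}

# steady-state filter state for a unit-amplitude constant input
iir_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, numeric(nf - length(b))) / a[1]
  a <- c(a, numeric(nf - length(a))) / a[1]
  K <- nf - 1L
  if (K == 0L) return(numeric(0))
  comp <- matrix(0, K, K)
  comp[1, ] <- -a[-1]
  if (K > 1L) comp[cbind(2:K, 1:(K - 1L))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(K) - t(comp), B)
}

# zero-phase filtering with odd-reflection padding and steady-state initial
# conditions, so constants pass exactly and edge transients are suppressed
filtfilt_zp <- function(bf, x) {
  b <- bf$b
  a <- bf$a
  n <- length(x)
  np <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L))
  zi <- iir_zi(b, a)
  ext <- if (np > 0) {
    c(2 * x[1] - x[(np + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - np)])
  } else x
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  if (np > 0) y[(np + 1L):(np + n)] else y
}

#' Zero-phase low-pass Butterworth filter
#'
#' Filters each channel independently, forward and backward (no phase
#' distortion), with odd-reflection padding and steady-state initial
#' conditions so that a constant signal passes exactly unchanged.
#' Coefficients are designed with `signal::butter`.
#'
#' @param trial an `emg_trial`.
#' @param cutoff cutoff frequency in Hz (must be below Nyquist).
#' @param order filter order.
#' @return the filtered `emg_trial` (same shape).
#' @export
lowpass_butterworth <- function(trial, cutoff = 1, order = 1L) {
  stopifnot(inherits(trial, "emg_trial"))
  fs <- trial$sampling_rate
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stop(sprintf("cutoff must lie in (0, %g) Hz (Nyquist = %g Hz)", fs / 2, fs / 2))
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  out <- trial$samples
  for (c in seq_len(ncol(out))) {
    out[, c] <- filtfilt_zp(bf, trial$samples[, c])
  }
  trial$samples <- out
  trial
}

#' Moving root-mean-square envelope
#'
#' Per-channel RMS over a trailing window of `window_ms` milliseconds, with
#' the window shrinking at the start of the trial so the output has the same
#' length as the input. Output is nonnegative.
#'
#' @param trial an `emg_trial`.
#' @param window_ms RMS window length in milliseconds (> 0).
#' @return the smoothed `emg_trial`.
#' @export
rms_smooth <- function(trial, window_ms = 20) {
  stopifnot(inherits(trial, "emg_trial"))
  if (window_ms <= 0) stop("window_ms must be > 0")
  w <- max(1L, round(window_ms * trial$sampling_rate / 1000))
  x <- trial$samples
  n <- nrow(x)
  cs <- apply(x^2, 2L, cumsum)
  cs <- rbind(0, cs)
  i <- seq_len(n)
  lo <- pmax(0L, i - w)
  denom <- i - lo
  out <- sqrt((cs[i + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]) / denom)
  trial$samples <- out
  trial
}

#' Mu-law amplitude companding
#'
#' `T(x) = sign(x) * ln(1 + mu*|x|) / ln(1 + mu)` with `sign(x) = 1` for
#' `x > 0` and `-1` otherwise. Odd-symmetric, strictly increasing, and maps
#' `[-1, 1]` onto `[-1, 1]`; inputs are expected to be pre-scaled to
#' `[-1, 1]`.
#'
#' @param x numeric vector or matrix with values in `[-1, 1]`.
#' @param mu positive companding strength (default 256).
#' @return transformed values, same shape as `x`.
#' @seealso [mu_law_inverse()]
#' @export
mu_law_normalize <- function(x, mu = 256) {
  if (mu <= 0) stop("mu must be > 0")
  sgn <- ifelse(x > 0, 1, -1)
  sgn * log(1 + mu * abs(x)) / log(1 + mu)
}

#' Inverse of the mu-law transform
#'
#' @param y mu-law-transformed values in `[-1, 1]`.
#' @param mu positive companding strength.
#' @return original values.
#' @export
mu_law_inverse <- function(y, mu = 256) {
  if (mu <= 0) stop("mu must be > 0")
  sgn <- ifelse(y > 0, 1, -1)
  sgn * ((1 + mu)^abs(y) - 1) / mu
}

#' Scale a trial to `[-1, 1]` and apply mu-law normalization
#'
#' Divides by the trial's maximum absolute sample value (left untouched when
#' the trial is identically zero) and then applies [mu_law_normalize()].
#'
#' @param trial an `emg_trial`.
#' @param mu companding strength.
#' @return the normalized `emg_trial`.
#' @export
normalize_trial <- function(trial, mu = 256) {
  stopifnot(inherits(trial, "emg_trial"))
  m <- max(abs(trial$samples))
  if (m > 0) trial$samples <- trial$samples / m
  trial$samples <- mu_law_normalize(trial$samples, mu)
  trial
}

#' Apply the standard preprocessing chain to every trial
#'
#' @param trials a `semg_dataset` or list of `emg_trial`.
#' @param filter one of `"rms"` (moving RMS envelope; the default, suited to
#'   raw oscillating recordings such as the synthetic simulator's output),
#'   `"butterworth"` (low-pass, for recordings that are already
#'   envelope-encoded, as in NinaPro DB1) or `"none"`.
#' @param cutoff,order Butterworth parameters.
#' @param rms_ms RMS window in milliseconds.
#' @param mu mu-law companding strength.
#' @return list of preprocessed `emg_trial`.
#' @export
preprocess_trials <- function(trials, filter = c("rms", "butterworth", "none"),
                              cutoff = 1, order = 1L, rms_ms = 100, mu = 256) {
  filter <- match.arg(filter)
  if (inherits(trials, "semg_dataset")) trials <- trials$trials
  lapply(trials, function(tr) {
    tr <- switch(filter,
      butterworth = lowpass_butterworth(tr, cutoff, order),
      rms = rms_smooth(tr, rms_ms),
      none = tr)
    normalize_trial(tr, mu)
  })
}

#' Segment a trial into fixed-length sliding windows
#'
#' Windows are half-open sample intervals `[t, t+W)` starting at 0-based
#' sample indices `0, S, 2S, ...` with `W = round(window_ms * fs / 1000)` and
#' `S = round(stride_ms * fs / 1000)`; a trial shorter than one window yields
#' an empty set. Each window inherits the trial's labels and records its
#' start index as `time_step`. When the trial carries a pose sequence the
#' matching pose frames are segmented alongside (flattened to
#' `W x (4 * joint_count)` per window).
#'
#' @param trial an `emg_trial`.
#' @param window_ms window length in milliseconds.
#' @param stride_ms stride in milliseconds.
#' @return object of class `window_set`: list with `values`
#'   (`W x C x n` array), optional `pose` (`W x 4J x n` array), `meta`
#'   (data.frame with subject_id, gesture_id, trial_index, time_step),
#'   `window_len`, `stride`, `sampling_rate`.
#' @export
segment_windows <- function(trial, window_ms = 200, stride_ms = 100) {
  stopifnot(inherits(trial, "emg_trial"))
  if (window_ms <= 0 || stride_ms <= 0) stop("window_ms and stride_ms must be > 0")
  fs <- trial$sampling_rate
  W <- max(1L, round(window_ms * fs / 1000))
  S <- max(1L, round(stride_ms * fs / 1000))
  L <- nrow(trial$samples)
  C <- ncol(trial$samples)
  n <- if (L >= W) (L - W) %/% S + 1L else 0L
  starts <- if (n > 0) (seq_len(n) - 1L) * S else integer(0)
  values <- array(0, dim = c(W, C, n))
  pose <- NULL
  if (!is.null(trial$pose)) {
    J <- trial$pose$joint_count
    pf <- trial$pose$frames            # (L, J, 4)
    pmat <- matrix(aperm(pf, c(1L, 3L, 2L)), nrow = dim(pf)[1])  # L x (4J), q-comps fastest
    pose <- array(0, dim = c(W, 4L * J, n))
  }
  for (i in seq_len(n)) {
    rows <- starts[i] + seq_len(W)
    values[, , i] <- trial$samples[rows, , drop = FALSE]
    if (!is.null(pose)) pose[, , i] <- pmat[rows, , drop = FALSE]
  }
  structure(list(
    values = values, pose = pose,
    meta = data.frame(subject_id = rep(trial$subject_id, n),
                      gesture_id = rep(trial$gesture_id, n),
                      trial_index = rep(trial$trial_index, n),
                      time_step = starts),
    window_len = W, stride = S, sampling_rate = fs
  ), class = "window_set")
}

#' Concatenate several window sets
#'
#' @param sets list of `window_set` objects with identical window length and
#'   channel count.
#' @return a single combined `window_set`.
#' @export
combine_window_sets <- function(sets) {
  sets <- Filter(function(s) nrow(s$meta) > 0, sets)
  if (length(sets) == 0) stop("no non-empty window sets to combine")
  W <- sets[[1]]$window_len
  C <- dim(sets[[1]]$values)[2]
  stopifnot(all(vapply(sets, function(s) s$window_len == W, logical(1))))
  n <- sum(vapply(sets, function(s) dim(s$values)[3], integer(1)))
  values <- array(0, dim = c(W, C, n))
  pose <- NULL
  if (!is.null(sets[[1]]$pose)) {
    pose <- array(0, dim = c(W, dim(sets[[1]]$pose)[2], n))
  }
  at <- 0L
  for (s in sets) {
    k <- dim(s$values)[3]
    if (k > 0) {
      values[, , at + seq_len(k)] <- s$values
      if (!is.null(pose)) pose[, , at + seq_len(k)] <- s$pose
      at <- at + k
    }
  }
  structure(list(values = values, pose = pose,
                 meta = do.call(rbind, lapply(sets, `[[`, "meta")),
                 window_len = W, stride = sets[[1]]$stride,
                 sampling_rate = sets[[1]]$sampling_rate),
            class = "window_set")
}

n_windows <- function(ws) nrow(ws$meta)

subset_windows <- function(ws, idx) {
  structure(list(values = ws$values[, , idx, drop = FALSE],
                 pose = if (!is.null(ws$pose)) ws$pose[, , idx, drop = FALSE],
                 meta = ws$meta[idx, , drop = FALSE],
                 window_len = ws$window_len, stride = ws$stride,
                 sampling_rate = ws$sampling_rate),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("window_set: %d windows of %d samples x %d channels%s\n",
              n_windows(x), x$window_len, dim(x$values)[2],
              if (!is.null(x$pose)) " (with pose)" else ""))
  invisible(x)
}

#' Preprocess, align and segment a dataset into labelled windows
#'
#' Full preparation pipeline: per-trial filtering and mu-law normalization,
#' alignment of each (subject, gesture) trial group to its minimum length,
#' and sliding-window segmentation.
#'
#' @param dataset a `semg_dataset` or list of `emg_trial`.
#' @param window_ms,stride_ms segmentation parameters.
#' @param filter,cutoff,order,rms_ms,mu see [preprocess_trials()].
#' @param align truncate each (subject, gesture) group to its minimum trial
#'   length before segmentation (required for cross-trial pairing).
#' @return a combined `window_set`.
#' @export
prepare_windows <- function(dataset, window_ms = 200, stride_ms = 100,
                            filter = "rms", cutoff = 1, order = 1L,
                            rms_ms = 100, mu = 256, align = TRUE) {
  trials <- preprocess_trials(dataset, filter, cutoff, order, rms_ms, mu)
  if (align) {
    groups <- split(trials, vapply(trials, function(tr) {
      paste(tr$subject_id, tr$gesture_id)
    }, character(1)))
    trials <- unlist(lapply(groups, function(g) {
      if (length(g) >= 2) align_trials(g) else g
    }), recursive = FALSE)
  }
  combine_window_sets(lapply(trials, segment_windows, window_ms = window_ms,
                             stride_ms = stride_ms))
}
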