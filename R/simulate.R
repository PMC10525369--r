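# Synthetic sEMG trial simulator with aligned hand-pose streams.
#
# Each trial is zero-mean band-limited Gaussian carrier noise, amplitude-
# modulated per channel by a gesture-specific trapezoidal envelope over the
# three movement phases (making, holding, ending the gesture). Cross-trial
# nuisance factors: a per-trial multiplicative LogNormal gain, an optional
# one-position circular electrode shift, and additive sensor noise. Hand
# poses are one unit quaternion per joint per sample, synthesized by
# spherical interpolation from the neutral pose to a per-gesture ending pose.

#' Simulation configuration
#'
#' @param n_subjects,n_gestures,n_trials counts (>= 1); `n_trials` is the
#'   number of repetitions per gesture.
#' @param n_channels electrode count C.
#' @param sampling_rate sampling rate in Hz.
#' @param trial_duration nominal trial length in seconds.
#' @param phase_fractions length-3 positive vector (make, hold, end) summing
#'   to 1.
#' @param trial_gain_sd sd of the log of the per-trial multiplicative gain
#'   (gain ~ LogNormal(0, trial_gain_sd)).
#' @param electrode_shift_prob probability that a trial is recorded with a
#'   one-position circular electrode shift.
#' @param noise_sd sd of additive Gaussian sensor noise, in signal units.
#' @param duration_jitter relative sd of the per-trial length, so trial
#'   lengths slightly vary and alignment by minimum length is meaningful.
#' @param joint_count number of hand joints in the pose stream.
#' @param seed integer RNG seed; identical configs give bitwise-identical
#'   datasets.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 2L, n_gestures = 8L, n_trials = 6L,
                       n_channels = 10L, sampling_rate = 100,
                       trial_duration = 2, phase_fractions = c(0.25, 0.5, 0.25),
                       trial_gain_sd = 0.2, electrode_shift_prob = 0.2,
                       noise_sd = 0.3, duration_jitter = 0.05,
                       joint_count = 15L, seed = 1L) {
  counts <- c(n_subjects, n_gestures, n_trials, n_channels, joint_count)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("counts (subjects, gestures, trials, channels, joints) must be integers >= 1")
  }
  if (sampling_rate <= 0 || trial_duration <= 0) {
    stop("sampling_rate and trial_duration must be positive")
  }
  if (length(phase_fractions) != 3L || any(phase_fractions <= 0) ||
      abs(sum(phase_fractions) - 1) > 1e-9) {
    stop("phase_fractions must be 3 strictly positive values summing to 1")
  }
  if (electrode_shift_prob < 0 || electrode_shift_prob > 1) {
    stop("electrode_shift_prob must be in [0, 1]")
  }
  if (trial_gain_sd < 0 || noise_sd < 0 || duration_jitter < 0) {
    stop("trial_gain_sd, noise_sd and duration_jitter must be >= 0")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_gestures = as.integer(n_gestures),
    n_trials = as.integer(n_trials), n_channels = as.integer(n_channels),
    sampling_rate = sampling_rate, trial_duration = trial_duration,
    phase_fractions = phase_fractions, trial_gain_sd = trial_gain_sd,
    electrode_shift_prob = electrode_shift_prob, noise_sd = noise_sd,
    duration_jitter = duration_jitter, joint_count = as.integer(joint_count),
    seed = as.integer(seed)
  ), class = "sim_config")
}

emg_trial <- function(samples, sampling_rate, subject_id, gesture_id,
                      trial_index, pose = NULL) {
  stopifnot(is.matrix(samples), all(is.finite(samples)), nrow(samples) >= 1)
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 subject_id = as.integer(subject_id),
                 gesture_id = as.integer(gesture_id),
                 trial_index = as.integer(trial_index), pose = pose),
            class = "emg_trial")
}

# ---- quaternion helpers --------------------------------------------------

quat_normalize <- function(q) q / sqrt(sum(q^2))

#' Geodesic distance between two unit quaternions
#'
#' Angle of the rotation taking one orientation to the other, in radians,
#' identifying q and -q.
#'
#' @param q1,q2 length-4 unit quaternions (w, x, y, z).
#' @return nonnegative angle in `[0, pi]`.
#' @export
quat_geodesic <- function(q1, q2) {
  d <- min(1, abs(sum(q1 * q2)))
  2 * acos(d)
}

#' Spherical linear interpolation between unit quaternions
#'
#' @param q0,q1 length-4 unit quaternions.
#' @param t interpolation parameter in `[0, 1]`.
#' @return a unit quaternion on the geodesic from `q0` to `q1`.
#' @export
quat_slerp <- function(q0, q1, t) {
  d <- sum(q0 * q1)
  if (d < 0) {
    q1 <- -q1
    d <- -d
  }
  if (d > 1 - 1e-10) {
    return(quat_normalize(q0 + t * (q1 - q0)))
  }
  th <- acos(min(1, d))
  (sin((1 - t) * th) * q0 + sin(t * th) * q1) / sin(th)
}

# run expr under a private seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Ending hand pose of a gesture
#'
#' Deterministic per-gesture dictionary of per-joint unit quaternions: the
#' orientation each joint reaches when the gesture is fully formed. The
#' dictionary is synthetic (a stand-in for glove-measured ending poses) but
#' fixed: calling twice returns the identical frame, and distinct gestures
#' map to distinct frames.
#'
#' @param gesture_id positive integer gesture identifier.
#' @param joint_count number of joints.
#' @return `joint_count x 4` matrix of unit quaternions (rows `(w,x,y,z)`).
#' @export
gesture_ending_pose <- function(gesture_id, joint_count = 15L) {
  if (length(gesture_id) != 1L || is.na(gesture_id) || gesture_id < 1 ||
      gesture_id != round(gesture_id)) {
    stop("unknown gesture_id: must be a positive integer")
  }
  with_local_seed(200003L + 977L * as.integer(gesture_id), {
    qs <- matrix(0, joint_count, 4L)
    for (j in seq_len(joint_count)) {
      axis <- stats::rnorm(3L)
      axis <- axis / sqrt(sum(axis^2))
      angle <- stats::runif(1L, 0.4, 1.4)
      qs[j, ] <- c(cos(angle / 2), sin(angle / 2) * axis)
    }
    qs
  })
}

phase_lengths <- function(n, fractions) {
  nm <- max(2L, round(fractions[1] * n))
  ne <- max(1L, round(fractions[3] * n))
  if (nm + ne > n) {
    nm <- max(2L, n - 2L)
    ne <- max(1L, n - nm)
  }
  nh <- n - nm - ne
  c(make = nm, hold = nh, end = ne)
}

#' Synthesize a hand-pose sequence for one trial
#'
#' Per joint, frames slerp from the neutral (identity) quaternion to the
#' gesture's ending pose over the make phase, hold the ending pose during the
#' hold phase, and slerp back to neutral over the end phase. The first frame
#' is exactly the identity and the last frame of the make phase is exactly
#' the ending pose.
#'
#' @param gesture_id positive integer gesture identifier.
#' @param n_frames number of frames (>= 2), one per sEMG sample.
#' @param phase_fractions length-3 (make, hold, end) fractions summing to 1.
#' @param joint_count number of joints.
#' @return object of class `pose_sequence`: list with `frames`
#'   (`n_frames x joint_count x 4` array) and `joint_count`.
#' @export
synthesize_pose_sequence <- function(gesture_id, n_frames,
                                     phase_fractions = c(0.25, 0.5, 0.25),
                                     joint_count = 15L) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  ending <- gesture_ending_pose(gesture_id, joint_count)
  neutral <- c(1, 0, 0, 0)
  ph <- phase_lengths(as.integer(n_frames), phase_fractions)
  ts <- c(
    seq(0, 1, length.out = ph["make"]),          # make: neutral -> ending
    rep(1, ph["hold"]),                          # hold
    if (ph["end"] > 0) 1 - seq_len(ph["end"]) / ph["end"] else numeric(0)
  )
  frames <- array(0, dim = c(n_frames, joint_count, 4L))
  for (j in seq_len(joint_count)) {
    for (i in seq_len(n_frames)) {
      frames[i, j, ] <- quat_slerp(neutral, ending[j, ], ts[i])
    }
  }
  structure(list(frames = frames, joint_count = as.integer(joint_count)),
            class = "pose_sequence")
}

trapezoid_envelope <- function(n, fractions) {
  ph <- phase_lengths(n, fractions)
  c(seq(0, 1, length.out = ph["make"]),
    rep(1, ph["hold"]),
    if (ph["end"] > 0) 1 - seq_len(ph["end"]) / ph["end"] else numeric(0))
}

band_limited_noise <- function(n, n_channels) {
  x <- matrix(stats::rnorm(n * n_channels), n, n_channels)
  if (n > 12) {
    bf <- signal::butter(2, 0.8, type = "low")
    for (c in seq_len(n_channels)) {
      x[, c] <- filtfilt_zp(bf, x[, c])
    }
  }
  x
}

#' Generate a synthetic sEMG dataset with aligned pose streams
#'
#' Produces `n_subjects * n_gestures * n_trials` trials. Per-(gesture,
#' channel) peak amplitudes are drawn once per dataset and frozen, so trials
#' of the same gesture share the same underlying envelope pattern up to the
#' configured nuisance factors.
#'
#' @param config a [sim_config()].
#' @return object of class `semg_dataset`: list with `trials` (list of
#'   `emg_trial`, each carrying its `pose_sequence`) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_gestures
  C <- config$n_channels
  fs <- config$sampling_rate
  # per-(gesture, channel) peak amplitudes, frozen for the dataset
  amp <- matrix(stats::runif(G * C, 0.2, 1), G, C)
  n_nominal <- max(20L, round(fs * config$trial_duration))
  trials <- vector("list", config$n_subjects * G * config$n_trials)
  i <- 0L
  for (s in seq_len(config$n_subjects)) {
    for (g in seq_len(G)) {
      for (k in seq_len(config$n_trials)) {
        L <- max(20L, round(n_nominal * (1 + stats::rnorm(1, 0, config$duration_jitter))))
        env <- trapezoid_envelope(L, config$phase_fractions)
        carrier <- band_limited_noise(L, C)
        x <- carrier * (env %o% amp[g, ])
        gain <- exp(stats::rnorm(1, 0, config$trial_gain_sd))
        x <- x * gain
        if (stats::runif(1) < config$electrode_shift_prob) {
          shift <- if (stats::runif(1) < 0.5) 1L else -1L
          ord <- ((seq_len(C) - 1L + shift) %% C) + 1L
          x <- x[, ord, drop = FALSE]
        }
        if (config$noise_sd > 0) {
          x <- x + matrix(stats::rnorm(L * C, 0, config$noise_sd), L, C)
        }
        pose <- synthesize_pose_sequence(g, L, config$phase_fractions,
                                         config$joint_count)
        i <- i + 1L
        trials[[i]] <- emg_trial(x, fs, s, g, k, pose)
      }
    }
  }
  structure(list(trials = trials, config = config), class = "semg_dataset")
}

#' @export
print.semg_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic sEMG dataset: %d trials (%d subjects x %d gestures x %d trials)\n",
    length(x$trials), cfg$n_subjects, cfg$n_gestures, cfg$n_trials))
  cat(sprintf("  %d channels at %g Hz, ~%g s per trial, %d pose joints\n",
              cfg$n_channels, cfg$sampling_rate, cfg$trial_duration,
              cfg$joint_count))
  invisible(x)
}
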