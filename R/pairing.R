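# Cross-trial pairing: align trials of the same subject and gesture, then
# sample anchor/positive window pairs at matched time steps from different
# trials (the stage-1 training unit).

#' Align trials to their common minimum length
#'
#' Trials of the same subject and gesture are truncated from the end to the
#' minimum sample length among them (discarding tail-end information), so
#' that a time step indexes the same movement phase in every trial. Pose
#' sequences are truncated alongside.
#'
#' @param trials list of >= 2 `emg_trial` objects sharing subject, gesture
#'   and channel count.
#' @return list of truncated `emg_trial`, in the input order.
#' @export
align_trials <- function(trials) {
  if (length(trials) < 2) stop("align_trials needs at least 2 trials")
  subj <- unique(vapply(trials, `[[`, integer(1), "subject_id"))
  gest <- unique(vapply(trials, `[[`, integer(1), "gesture_id"))
  if (length(subj) != 1 || length(gest) != 1) {
    stop("all trials must share one subject and one gesture")
  }
  ncs <- unique(vapply(trials, function(tr) ncol(tr$samples), integer(1)))
  if (length(ncs) != 1) stop("all trials must have the same channel count")
  lmin <- min(vapply(trials, function(tr) nrow(tr$samples), integer(1)))
  lapply(trials, function(tr) {
    tr$samples <- tr$samples[seq_len(lmin), , drop = FALSE]
    if (!is.null(tr$pose)) {
      tr$pose$frames <- tr$pose$frames[seq_len(lmin), , , drop = FALSE]
    }
    tr
  })
}

#' Sample cross-trial anchor/positive window pairs
#'
#' For every anchor window of every trial, one positive window is drawn
#' uniformly from the other trials of the same (subject, gesture) group at
#' the identical time step. Groups with a single trial are skipped with a
#' warning. Trials within each group are aligned to their minimum length
#' first.
#'
#' @param trials list of preprocessed `emg_trial` (all groups together).
#' @param window_ms,stride_ms segmentation parameters.
#' @param seed optional integer; when given, seeds the RNG (otherwise the
#'   current RNG stream is used, e.g. inside a training epoch).
#' @return object of class `pair_set`: `anchor` and `positive` (`W x C x n`
#'   arrays) plus `meta` (subject_id, gesture_id, anchor_trial,
#'   positive_trial, time_step).
#' @export
sample_pairs <- function(trials, window_ms = 200, stride_ms = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(trials, "semg_dataset")) trials <- trials$trials
  key <- vapply(trials, function(tr) paste(tr$subject_id, tr$gesture_id),
                character(1))
  groups <- split(trials, key)
  anchors <- list()
  positives <- list()
  metas <- list()
  for (g in groups) {
    if (length(g) < 2) {
      warning(sprintf(
        "skipping group (subject %d, gesture %d): only one trial",
        g[[1]]$subject_id, g[[1]]$gesture_id))
      next
    }
    g <- align_trials(g)
    wsets <- lapply(g, segment_windows, window_ms = window_ms,
                    stride_ms = stride_ms)
    nw <- n_windows(wsets[[1]])
    if (nw == 0) next
    nt <- length(g)
    for (i in seq_len(nt)) {
      # positives drawn uniformly from the other trials, per anchor window
      others <- setdiff(seq_len(nt), i)
      js <- if (length(others) == 1) rep(others, nw) else
        others[sample.int(length(others), nw, replace = TRUE)]
      pos <- array(0, dim = dim(wsets[[i]]$values))
      for (w in seq_len(nw)) pos[, , w] <- wsets[[js[w]]]$values[, , w]
      anchors[[length(anchors) + 1L]] <- wsets[[i]]$values
      positives[[length(positives) + 1L]] <- pos
      metas[[length(metas) + 1L]] <- data.frame(
        subject_id = g[[i]]$subject_id, gesture_id = g[[i]]$gesture_id,
        anchor_trial = g[[i]]$trial_index,
        positive_trial = vapply(js, function(j) g[[j]]$trial_index, integer(1)),
        time_step = wsets[[i]]$meta$time_step)
    }
  }
  if (length(anchors) == 0) stop("no pairable (subject, gesture) group with >= 2 trials")
  W <- dim(anchors[[1]])[1]
  C <- dim(anchors[[1]])[2]
  n <- sum(vapply(anchors, function(a) dim(a)[3], integer(1)))
  a3 <- array(0, dim = c(W, C, n))
  p3 <- array(0, dim = c(W, C, n))
  at <- 0L
  for (k in seq_along(anchors)) {
    m <- dim(anchors[[k]])[3]
    a3[, , at + seq_len(m)] <- anchors[[k]]
    p3[, , at + seq_len(m)] <- positives[[k]]
    at <- at + m
  }
  structure(list(anchor = a3, positive = p3, meta = do.call(rbind, metas),
                 window_len = W),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("pair_set: %d cross-trial anchor/positive window pairs\n",
              nrow(x$meta)))
  invisible(x)
}
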