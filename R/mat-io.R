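# Minimal MAT-file (level 5, uncompressed) reader/writer for numeric
# arrays, plus NinaPro-style import/export of sEMG recordings.
#
# Supported subset: little-endian files, miMATRIX elements of numeric
# classes, real data, 2-D dimensions, normal and small-data-element tags.
# The v7.3 (HDF5) dialect is not supported.

MI_TYPES <- list(
  miINT8 = 1L, miUINT8 = 2L, miINT16 = 3L, miUINT16 = 4L, miINT32 = 5L,
  miUINT32 = 6L, miSINGLE = 7L, miDOUBLE = 9L, miINT64 = 12L, miUINT64 = 13L,
  miMATRIX = 14L, miCOMPRESSED = 15L, miUTF8 = 16L
)

pad8 <- function(n) (8L - n %% 8L) %% 8L

#' Write numeric matrices to a MAT (level 5) file
#'
#' @param vars named list of numeric vectors/matrices (stored as doubles).
#' @param path output file path.
#' @export
write_mat <- function(vars, path) {
  stopifnot(is.list(vars), !is.null(names(vars)), all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  # 128-byte header: 116 text, 8 subsys, version 0x0100, endian "IM"
  desc <- sprintf("MATLAB 5.0 MAT-file, written by semgpose")
  txt <- charToRaw(desc)
  header <- raw(116)
  header[seq_along(txt)] <- txt
  header[header == as.raw(0)] <- charToRaw(" ")
  writeBin(header, con)
  writeBin(raw(8L), con)
  writeBin(as.integer(256L), con, size = 2L, endian = "little")
  writeChar("IM", con, nchars = 2L, eos = NULL)
  for (nm in names(vars)) {
    x <- vars[[nm]]
    if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
    storage.mode(x) <- "double"
    name_raw <- charToRaw(nm)
    nlen <- length(name_raw)
    ndata <- length(x) * 8L
    body_bytes <- 16L +                       # array flags
      (8L + 8L) +                             # dims (2 x int32 padded)
      (8L + nlen + pad8(nlen)) +              # name
      (8L + ndata + pad8(ndata))              # real data
    writeBin(c(MI_TYPES$miMATRIX, body_bytes), con, size = 4L, endian = "little")
    # array flags: class mxDOUBLE_CLASS = 6
    writeBin(c(MI_TYPES$miUINT32, 8L), con, size = 4L, endian = "little")
    writeBin(c(6L, 0L), con, size = 4L, endian = "little")
    # dimensions
    writeBin(c(MI_TYPES$miINT32, 8L), con, size = 4L, endian = "little")
    writeBin(as.integer(dim(x)), con, size = 4L, endian = "little")
    # name
    writeBin(c(MI_TYPES$miINT8, nlen), con, size = 4L, endian = "little")
    writeBin(name_raw, con)
    if (pad8(nlen) > 0) writeBin(raw(pad8(nlen)), con)
    # real part
    writeBin(c(MI_TYPES$miDOUBLE, ndata), con, size = 4L, endian = "little")
    writeBin(as.numeric(x), con, size = 8L, endian = "little")
    if (pad8(ndata) > 0) writeBin(raw(pad8(ndata)), con)
  }
  invisible(path)
}

read_mi_numeric <- function(con, type, nbytes) {
  spec <- switch(as.character(type),
    "1" = list(what = integer(), size = 1L, signed = TRUE),
    "2" = list(what = integer(), size = 1L, signed = FALSE),
    "3" = list(what = integer(), size = 2L, signed = TRUE),
    "4" = list(what = integer(), size = 2L, signed = FALSE),
    "5" = list(what = integer(), size = 4L, signed = TRUE),
    "6" = list(what = integer(), size = 4L, signed = TRUE),
    "7" = list(what = numeric(), size = 4L, signed = TRUE),
    "9" = list(what = numeric(), size = 8L, signed = TRUE),
    stop("unsupported MAT data type code: ", type))
  n <- nbytes %/% spec$size
  out <- readBin(con, spec$what, n = n, size = spec$size,
                 signed = spec$signed, endian = "little")
  as.numeric(out)
}

read_tag <- function(con) {
  word <- readBin(con, integer(), n = 1L, size = 4L, endian = "little")
  if (length(word) == 0) return(NULL)
  hi <- bitwAnd(bitwShiftR(word, 16L), 0xFFFFL)
  if (hi != 0L) {
    # small data element: type in low 16 bits, <= 4 data bytes follow
    list(type = bitwAnd(word, 0xFFFFL), nbytes = hi, small = TRUE)
  } else {
    nb <- readBin(con, integer(), n = 1L, size = 4L, endian = "little")
    list(type = word, nbytes = nb, small = FALSE)
  }
}

read_element_data <- function(con, tag) {
  if (tag$small) {
    buf <- readBin(con, raw(), n = 4L)
    rc <- rawConnection(buf[seq_len(tag$nbytes)])
    on.exit(close(rc))
    read_mi_numeric(rc, tag$type, tag$nbytes)
  } else {
    out <- read_mi_numeric(con, tag$type, tag$nbytes)
    if (pad8(tag$nbytes) > 0) readBin(con, raw(), n = pad8(tag$nbytes))
    out
  }
}

read_name <- function(con, tag) {
  if (tag$small) {
    buf <- readBin(con, raw(), n = 4L)
    rawToChar(buf[seq_len(tag$nbytes)])
  } else {
    nm <- rawToChar(readBin(con, raw(), n = tag$nbytes))
    if (pad8(tag$nbytes) > 0) readBin(con, raw(), n = pad8(tag$nbytes))
    nm
  }
}

#' Read numeric variables from a MAT (level 5) file
#'
#' @param path MAT file path.
#' @return named list of numeric matrices.
#' @export
read_mat <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, raw(), n = 128L)
  if (length(header) < 128L) stop("not a MAT-5 file (truncated header): ", path)
  endian <- rawToChar(header[127:128])
  if (endian == "MI") stop("big-endian MAT files are not supported")
  if (endian != "IM") stop("not a MAT-5 file (bad endian indicator): ", path)
  vars <- list()
  repeat {
    tag <- read_tag(con)
    if (is.null(tag)) break
    if (tag$type == MI_TYPES$miCOMPRESSED) {
      stop("compressed MAT elements are not supported; write uncompressed files")
    }
    if (tag$type != MI_TYPES$miMATRIX) {
      # skip unknown top-level element
      nb <- tag$nbytes + pad8(tag$nbytes)
      if (!tag$small) readBin(con, raw(), n = nb) else readBin(con, raw(), n = 4L)
      next
    }
    flags_tag <- read_tag(con)
    flags <- read_element_data(con, flags_tag)
    dims_tag <- read_tag(con)
    dims <- as.integer(read_element_data(con, dims_tag))
    name_tag <- read_tag(con)
    nm <- read_name(con, name_tag)
    data_tag <- read_tag(con)
    x <- read_element_data(con, data_tag)
    if (length(x) != prod(dims)) {
      stop("corrupt MAT variable '", nm, "': dims do not match data length")
    }
    dim(x) <- dims
    vars[[nm]] <- x
  }
  vars
}

# ---- NinaPro-style recordings -------------------------------------------

#' Export trials to a NinaPro-style MAT file
#'
#' Concatenates the trials of one subject into one continuous recording with
#' `rest_gap` zero-signal rest samples (label 0) between trials, and writes
#' the conventional fields: `emg`, `stimulus`/`restimulus` (gesture labels),
#' `repetition`/`rerepetition` (trial indices), and `glove` (flattened
#' quaternion pose frames; identity quaternions during rest) when poses are
#' present.
#'
#' @param trials list of `emg_trial` for one subject.
#' @param path output MAT path.
#' @param rest_gap rest samples inserted between trials.
#' @export
write_ninapro_mat <- function(trials, path, rest_gap = 20L) {
  stopifnot(length(trials) >= 1)
  C <- ncol(trials[[1]]$samples)
  has_pose <- !is.null(trials[[1]]$pose)
  J <- if (has_pose) trials[[1]]$pose$joint_count else 0L
  emg <- list(); stim <- list(); rep_ <- list(); glove <- list()
  rest_pose <- function(n) {
    fr <- matrix(0, n, 4L * J)
    fr[, seq(1L, 4L * J, by = 4L)] <- 1  # identity quaternion per joint
    fr
  }
  gap_emg <- matrix(0, rest_gap, C)
  for (k in seq_along(trials)) {
    tr <- trials[[k]]
    L <- nrow(tr$samples)
    emg[[length(emg) + 1L]] <- tr$samples
    stim[[length(stim) + 1L]] <- rep(tr$gesture_id, L)
    rep_[[length(rep_) + 1L]] <- rep(tr$trial_index, L)
    if (has_pose) {
      pf <- tr$pose$frames
      glove[[length(glove) + 1L]] <-
        matrix(aperm(pf, c(1L, 3L, 2L)), nrow = dim(pf)[1])
    }
    if (k < length(trials) && rest_gap > 0) {
      emg[[length(emg) + 1L]] <- gap_emg
      stim[[length(stim) + 1L]] <- rep(0L, rest_gap)
      rep_[[length(rep_) + 1L]] <- rep(0L, rest_gap)
      if (has_pose) glove[[length(glove) + 1L]] <- rest_pose(rest_gap)
    }
  }
  vars <- list(
    emg = do.call(rbind, emg),
    stimulus = matrix(unlist(stim), ncol = 1L),
    restimulus = matrix(unlist(stim), ncol = 1L),
    repetition = matrix(unlist(rep_), ncol = 1L),
    rerepetition = matrix(unlist(rep_), ncol = 1L)
  )
  if (has_pose) vars$glove <- do.call(rbind, glove)
  write_mat(vars, path)
}

default_glove_map <- function(mat) {
  # columns are flattened quaternions (w,x,y,z per joint)
  if (ncol(mat) %% 4L != 0L) {
    stop("glove matrix has ", ncol(mat),
         " columns; the default map expects a multiple of 4 (quaternions)")
  }
  J <- ncol(mat) %/% 4L
  frames <- array(0, dim = c(nrow(mat), J, 4L))
  for (j in seq_len(J)) {
    q <- mat[, (j - 1L) * 4L + 1:4, drop = FALSE]
    nrm <- sqrt(rowSums(q^2))
    nrm[nrm == 0] <- 1
    frames[, j, ] <- q / nrm
  }
  structure(list(frames = frames, joint_count = J), class = "pose_sequence")
}

#' Read a NinaPro-style MAT recording into trials
#'
#' Segments the continuous recording at gesture-label boundaries, dropping
#' rest segments (label 0). Refined labels (`restimulus`/`rerepetition`)
#' are preferred over `stimulus`/`repetition` when present. Glove columns,
#' when present, are converted to a pose sequence per trial through
#' `glove_map` (default: columns are flattened unit quaternions).
#'
#' @param path MAT file path.
#' @param subject_id subject identifier to attach to the trials.
#' @param sampling_rate sampling rate in Hz to attach.
#' @param prefer_refined use restimulus/rerepetition when available.
#' @param glove_map function(matrix) -> `pose_sequence`.
#' @return list of `emg_trial`.
#' @export
read_ninapro_mat <- function(path, subject_id = 1L, sampling_rate = 100,
                             prefer_refined = TRUE,
                             glove_map = default_glove_map) {
  vars <- read_mat(path)
  if (is.null(vars$emg)) stop("MAT file is missing the required field 'emg'")
  lab_field <- if (prefer_refined && !is.null(vars$restimulus)) "restimulus"
    else if (!is.null(vars$stimulus)) "stimulus"
    else if (!is.null(vars$restimulus)) "restimulus"
    else stop("MAT file is missing the required field 'stimulus'/'restimulus'")
  rep_field <- if (prefer_refined && !is.null(vars$rerepetition)) "rerepetition"
    else if (!is.null(vars$repetition)) "repetition"
    else if (!is.null(vars$rerepetition)) "rerepetition"
    else stop("MAT file is missing the required field 'repetition'/'rerepetition'")
  emg <- vars$emg
  lab <- as.integer(vars[[lab_field]])
  rep_ <- as.integer(vars[[rep_field]])
  if (length(lab) != nrow(emg) || length(rep_) != nrow(emg)) {
    stop("length mismatch between 'emg' and label arrays")
  }
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  trials <- list()
  for (i in seq_along(runs$values)) {
    if (runs$values[i] == 0L) next
    rows <- starts[i]:ends[i]
    pose <- if (!is.null(vars$glove)) {
      glove_map(vars$glove[rows, , drop = FALSE])
    }
    trials[[length(trials) + 1L]] <- emg_trial(
      emg[rows, , drop = FALSE], sampling_rate, subject_id,
      runs$values[i], rep_[starts[i]], pose)
  }
  if (length(trials) == 0) warning("recording contains only rest (label 0)")
  trials
}

#' Export a synthetic dataset to per-subject NinaPro-style MAT files
#'
#' @param dataset a `semg_dataset`.
#' @param dir output directory (created if needed).
#' @param rest_gap rest samples between trials.
#' @return character vector of written file paths.
#' @export
export_dataset_mat <- function(dataset, dir, rest_gap = 20L) {
  stopifnot(inherits(dataset, "semg_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subs <- sort(unique(vapply(dataset$trials, `[[`, integer(1), "subject_id")))
  paths <- character(0)
  for (s in subs) {
    trs <- Filter(function(tr) tr$subject_id == s, dataset$trials)
    # interleave by trial index so consecutive segments change gesture
    ord <- order(vapply(trs, `[[`, integer(1), "trial_index"),
                 vapply(trs, `[[`, integer(1), "gesture_id"))
    p <- file.path(dir, sprintf("subject%02d.mat", s))
    write_ninapro_mat(trs[ord], p, rest_gap)
    paths <- c(paths, p)
  }
  paths
}
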