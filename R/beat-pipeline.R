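# Raw recording -> normalized average beat. Stages: beat segmentation,
# iterated-IQR outlier rejection, onset-aligned end-padded averaging,
# 90 ms Hanning smoothing, velocity rescale to [0,1], cubic-spline time
# normalization to 100 samples.

# unit-sum Hanning smoothing, odd window of ~dur seconds, reflection edges
.hann_smooth <- function(x, fs, dur = 0.09) {
  n <- round(fs * dur)
  if (n %% 2 == 0) n <- n - 1L
  n <- max(n, 3L)
  if (length(x) < n) return(x)
  w <- signal::hanning(n)
  w <- w / sum(w)
  h <- (n - 1L) %/% 2L
  xp <- c(rev(x[2:(h + 1L)]), x, rev(x[(length(x) - h):(length(x) - 1L)]))
  as.numeric(stats::filter(xp, w, sides = 2))[(h + 1L):(h + length(x))]
}

#' Segment a recording into beats at systolic-upstroke feet
#'
#' Derivative-threshold foot detection: the lightly smoothed first
#' difference is scanned for upstroke runs exceeding half its 98th
#' percentile, a 0.3 s refractory period merges candidates, and each onset
#' is placed at the local minimum immediately preceding the sustained rise.
#'
#' @param rec a `tcd_recording` (or list with `samples` and `fs`).
#' @return list of beats; each beat is the numeric velocity segment from one
#'   onset to the next, with attribute `onset_index` (1-based index into the
#'   recording). A recording with no detectable pulsatility yields an empty
#'   list with attribute `unusable = TRUE`.
#' @export
detect_beats <- function(rec) {
  x <- rec$samples
  fs <- rec$fs
  if (length(x) < 2 * fs) stop("recording must be at least 2 seconds long")
  unusable <- function() structure(list(), unusable = TRUE)
  xs <- .hann_smooth(x, fs)
  d <- diff(xs)
  if (max(d) <= 0 || stats::sd(x) < 1e-12) return(unusable())
  thr <- 0.5 * stats::quantile(d, 0.98, names = FALSE)
  if (thr <= 0) return(unusable())
  cand <- which(d > thr)
  if (length(cand) == 0) return(unusable())
  refractory <- round(0.3 * fs)
  starts <- cand[c(TRUE, diff(cand) > 1)]      # first index of each run
  keep <- starts[1]
  for (s in starts[-1]) {
    if (s - keep[length(keep)] > refractory) keep <- c(keep, s)
  }
  onsets <- vapply(keep, function(s) {
    i <- s
    lim <- max(1L, s - round(0.25 * fs))
    while (i > lim && xs[i - 1L] < xs[i]) i <- i - 1L
    i
  }, integer(1))
  onsets <- sort(unique(onsets))
  bounds <- c(onsets, length(x) + 1L)
  beats <- list()
  min_len <- round(0.3 * fs)
  for (j in seq_along(onsets)) {
    seg <- x[bounds[j]:(bounds[j + 1L] - 1L)]
    if (length(seg) >= min_len) {
      beats[[length(beats) + 1L]] <-
        structure(seg, onset_index = onsets[j])
    }
  }
  if (length(beats) == 0) return(unusable())
  beats
}

# pad each beat with its final value to the longest length -> matrix
.pad_ensemble <- function(beats) {
  maxlen <- max(lengths(beats))
  t(vapply(beats, function(b) {
    c(b, rep(b[length(b)], maxlen - length(b)))
  }, numeric(maxlen)))
}

# max normalized cross-correlation of each row against the ensemble mean,
# over lags up to ~10% of the beat length; NA (zero-variance beat) -> -1
.ensemble_ncc <- function(mat) {
  m <- colMeans(mat)
  maxlag <- max(1L, round(0.1 * ncol(mat)))
  n <- ncol(mat)
  apply(mat, 1, function(b) {
    best <- -1
    for (lag in -maxlag:maxlag) {
      if (lag >= 0) {
        a <- b[(1 + lag):n]; r <- m[1:(n - lag)]
      } else {
        a <- b[1:(n + lag)]; r <- m[(1 - lag):n]
      }
      if (stats::sd(a) < 1e-12 || stats::sd(r) < 1e-12) next
      cc <- stats::cor(a, r)
      if (is.finite(cc) && cc > best) best <- cc
    }
    best
  })
}

.tukey_outlier <- function(v, mult) {
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  eps <- 1e-8 * pmax(1, abs(q))  # guard exact-tie ensembles (IQR = 0)
  v < q[1] - mult * iqr - eps[1] | v > q[2] + mult * iqr + eps[2]
}

#' Iterated interquartile-range beat rejection
#'
#' Repeatedly removes beats whose length or whose maximum normalized
#' cross-correlation against the current ensemble mean falls outside the
#' Tukey fences `[Q1 - mult*IQR, Q3 + mult*IQR]` of the current ensemble,
#' until a fixed point is reached or only 3 beats remain.
#'
#' @param beats list of beats from [detect_beats()].
#' @param iqr_mult Tukey fence multiplier (default 1.5).
#' @return list with `accepted`, `rejected` (both beat lists) and
#'   `n_iterations`. Fewer than 3 input beats rejects everything and sets
#'   attribute `flagged = TRUE`.
#' @export
reject_outliers <- function(beats, iqr_mult = 1.5) {
  if (length(beats) < 3) {
    return(structure(
      list(accepted = list(), rejected = beats, n_iterations = 0L),
      flagged = TRUE
    ))
  }
  accepted <- beats
  rejected <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mat <- .pad_ensemble(accepted)
    len <- lengths(accepted)
    ncc <- .ensemble_ncc(mat)
    out <- .tukey_outlier(len, iqr_mult) | .tukey_outlier(ncc, iqr_mult)
    if (!any(out)) break
    if (length(accepted) - sum(out) < 3) {
      # floor of 3: drop only the worst offenders (lowest correlation)
      n_drop <- length(accepted) - 3L
      if (n_drop <= 0) break
      drop_idx <- order(ncc)[seq_len(n_drop)]
      out <- seq_along(accepted) %in% drop_idx
      rejected <- c(rejected, accepted[out])
      accepted <- accepted[!out]
      break
    }
    rejected <- c(rejected, accepted[out])
    accepted <- accepted[!out]
  }
  list(accepted = accepted, rejected = rejected, n_iterations = iter)
}

#' Average an ensemble of accepted beats
#'
#' Beats (already aligned at the systolic-upstroke onset, since each starts
#' at its onset sample) are individually padded with their final value to
#' the length of the longest beat, and the rectangular ensemble is averaged
#' element-wise.
#'
#' @param accepted non-empty list of beats.
#' @return list with `samples` (length = longest beat) and `n_beats_used`.
#' @export
average_beats <- function(accepted) {
  if (length(accepted) == 0) stop("cannot average an empty beat ensemble")
  mat <- .pad_ensemble(accepted)
  list(samples = colMeans(mat), n_beats_used = length(accepted))
}

#' Standardize an average beat to a normalized 100-sample waveform
#'
#' Order of operations: (1) 400 Hz input is resampled to 125 Hz (ratio
#' 5/16: zero-phase FIR anti-aliasing filter with cutoff at the 62.5 Hz
#' target Nyquist frequency, then interpolation onto the 125 Hz time grid);
#' (2) convolution with a unit-sum 90 ms
#' Hanning window (11 samples at 125 Hz, reflection edges); (3) velocity
#' rescale to `[0, 1]` (subtract minimum, divide by resulting maximum);
#' (4) cubic-spline resampling to exactly 100 samples spanning the beat,
#' with a final exact min/max rescale so the normalization invariant holds
#' to machine precision.
#'
#' @param samples numeric velocity series (an average beat), or the list
#'   returned by [average_beats()].
#' @param fs native sampling rate of `samples` (125 or 400 Hz).
#' @return numeric vector of exactly 100 samples with min 0 and max 1.
#' @export
standardize_beat <- function(samples, fs) {
  if (is.list(samples)) samples <- samples$samples
  if (!fs %in% c(125, 400)) stop("fs must be 125 or 400 Hz")
  x <- as.numeric(samples)
  if (max(x) - min(x) < 1e-12) {
    stop("constant waveform cannot be normalized", call. = FALSE)
  }
  if (fs == 400) {
    # reflect-pad to suppress filter edge transients, then trim
    pad <- min(64L, length(x) - 1L)
    xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(length(x) - pad):(length(x) - 1L)]))
    b <- signal::fir1(64, 62.5 / 200)        # cutoff = target Nyquist
    xf <- signal::filtfilt(b, xp)[(pad + 1L):(pad + length(x))]
    n125 <- round(length(x) * 5 / 16)
    x <- stats::spline(seq_along(xf) - 1L, xf,
                       xout = (seq_len(n125) - 1L) * 16 / 5,
                       method = "fmm")$y
  }
  x <- .hann_smooth(x, 125)
  x <- x - min(x)
  x <- x / max(x)
  grid <- seq(0, length(x) - 1L, length.out = 100)
  x <- stats::spline(seq_along(x) - 1L, x, xout = grid, method = "fmm")$y
  x <- x - min(x)
  x / max(x)
}

#' Process one recording through the full beat pipeline
#'
#' Applies [detect_beats()], [reject_outliers()], the minimum-beat inclusion
#' rule, [average_beats()] and [standardize_beat()], returning `NULL` (with
#' a log message) when the recording fails any inclusion criterion.
#'
#' @param rec a `tcd_recording`.
#' @param min_beats minimum accepted beats for inclusion (default 15).
#' @param iqr_mult Tukey fence multiplier for [reject_outliers()].
#' @param depth_range admissible insonation depth in mm.
#' @return list with `samples` (normalized 100-sample beat) and `info`
#'   (one-row data frame of provenance); an excluded recording instead
#'   returns an object of class `tcd_excluded` whose `log` element states
#'   the reason.
#' @export
process_recording <- function(rec, min_beats = 15, iqr_mult = 1.5,
                              depth_range = c(45, 60)) {
  excl <- function(reason) {
    structure(list(log = sprintf(
      "excluded %s %s %.1f mm: %s",
      rec$subject_id, rec$hemisphere, rec$depth, reason
    )), class = "tcd_excluded")
  }
  if (rec$depth < depth_range[1] || rec$depth > depth_range[2]) {
    return(excl("depth outside admissible range"))
  }
  beats <- detect_beats(rec)
  if (isTRUE(attr(beats, "unusable")) || length(beats) == 0) {
    return(excl("no beats detected"))
  }
  rej <- reject_outliers(beats, iqr_mult = iqr_mult)
  if (length(rej$accepted) < min_beats) {
    return(excl(sprintf(
      "only %d accepted beats (minimum %d)", length(rej$accepted), min_beats
    )))
  }
  avg <- average_beats(rej$accepted)
  w <- tryCatch(standardize_beat(avg$samples, rec$fs),
                error = function(e) NULL)
  if (is.null(w)) return(excl("degenerate (constant) average waveform"))
  info <- data.frame(
    waveform_id = sprintf("%s_%s_%04.1fmm", rec$subject_id, rec$hemisphere,
                          rec$depth),
    subject_id = rec$subject_id, group = rec$group,
    hemisphere = rec$hemisphere, depth_mm = rec$depth,
    n_beats = avg$n_beats_used,
    stringsAsFactors = FALSE
  )
  list(samples = w, info = info)
}

#' Build a normalized-beat set from many recordings
#'
#' @param recordings list of `tcd_recording` objects.
#' @param ... passed to [process_recording()].
#' @return a `tcd_beats` object: list with `waveforms` (N x 100 matrix),
#'   `info` (provenance data frame) and `log` (exclusion messages).
#' @export
preprocess_recordings <- function(recordings, ...) {
  rows <- list()
  infos <- list()
  log <- character(0)
  for (rec in recordings) {
    res <- process_recording(rec, ...)
    if (inherits(res, "tcd_excluded")) {
      log <- c(log, res$log)
    } else {
      rows[[length(rows) + 1L]] <- res$samples
      infos[[length(infos) + 1L]] <- res$info
    }
  }
  waveforms <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, 100)
  info <- if (length(infos)) do.call(rbind, infos) else
    data.frame(waveform_id = character(0), subject_id = character(0),
               group = character(0), hemisphere = character(0),
               depth_mm = numeric(0), n_beats = integer(0))
  tcd_beats(waveforms, info, log)
}

#' Construct a normalized-beat set
#'
#' @param waveforms N x 100 matrix of normalized beats (rows in `[0, 1]`).
#' @param info provenance data frame with columns `waveform_id`,
#'   `subject_id`, `group`, `hemisphere`, `depth_mm`, `n_beats`.
#' @param log character vector of pipeline log messages.
#' @return object of class `tcd_beats`.
#' @export
tcd_beats <- function(waveforms, info, log = character(0)) {
  waveforms <- as.matrix(waveforms)
  if (nrow(waveforms) != nrow(info)) {
    stop("waveforms and info must have the same number of rows")
  }
  if (nrow(waveforms) > 0 && ncol(waveforms) != 100) {
    stop("normalized beats must have exactly 100 samples")
  }
  rownames(waveforms) <- info$waveform_id
  structure(list(waveforms = waveforms, info = info, log = log),
            class = "tcd_beats")
}

#' @export
print.tcd_beats <- function(x, ...) {
  cat(sprintf(
    "<tcd_beats> %d normalized waveform(s), %d excluded recording(s)\n",
    nrow(x$waveforms), length(x$log)
  ))
  if (nrow(x$info) > 0) {
    print(utils::head(x$info, 4))
    if (nrow(x$info) > 4) cat(sprintf("  ... %d more rows\n", nrow(x$info) - 4))
  }
  invisible(x)
}

#' Enforce the bilateral-exam inclusion criterion
#'
#' Retains waveforms from subjects possessing at least one qualifying
#' recording in each hemisphere; a recording qualifies when its depth lies
#' in `depth_range` and it used at least `min_beats` accepted beats.
#' Waveforms of other subjects, and non-qualifying waveforms, are dropped
#' with a log entry.
#'
#' @param beats a `tcd_beats` object.
#' @param min_beats,depth_range qualification thresholds.
#' @return filtered `tcd_beats`.
#' @export
filter_exams <- function(beats, min_beats = 15, depth_range = c(45, 60)) {
  stopifnot(inherits(beats, "tcd_beats"))
  info <- beats$info
  if (nrow(info) == 0) return(beats)
  qual <- info$depth_mm >= depth_range[1] & info$depth_mm <= depth_range[2] &
    info$n_beats >= min_beats
  sides <- tapply(info$hemisphere[qual], info$subject_id[qual],
                  function(h) length(unique(h)))
  bilateral <- names(sides)[sides == 2L]
  keep <- qual & info$subject_id %in% bilateral
  dropped <- unique(info$subject_id[!info$subject_id %in% bilateral])
  log <- beats$log
  if (length(dropped)) {
    log <- c(log, sprintf("excluded subject %s: no bilateral qualifying pair",
                          dropped))
  }
  tcd_beats(beats$waveforms[keep, , drop = FALSE],
            info[keep, , drop = FALSE], log)
}
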