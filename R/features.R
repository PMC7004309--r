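# Three morphological features per normalized beat: onset of maximal
# velocity, systolic canopy length, and a weighted peak/trough count.
# Sample indices are reported 0-based (0..99); internally R's 1-based
# indexing is used and converted at the boundary.

.check_normalized <- function(w) {
  if (length(w) < 3) stop("waveform too short")
  if (abs(min(w)) > 1e-6 || abs(max(w) - 1) > 1e-6) {
    stop("waveform must be normalized to [0, 1] (min 0, max 1)")
  }
  invisible(w)
}

# 1-based indices of the systolic canopy: samples strictly above the first
# sample plus a quarter of the diastolic-systolic range
.canopy_set <- function(w) {
  which(w > w[1] + 0.25 * (max(w) - min(w)))
}

#' Onset of maximal velocity
#'
#' The (0-based) sample index at which the normalized beat attains its
#' maximum; ties are broken by the earliest index.
#'
#' @param w normalized beat (min 0, max 1; typically 100 samples).
#' @return integer index in `0..length(w)-1`.
#' @export
beat_onset <- function(w) {
  .check_normalized(w)
  which.max(w) - 1L
}

#' Systolic canopy length
#'
#' Number of samples whose velocity exceeds the first sample's value plus
#' 25% of the diastolic-systolic range.
#'
#' @inheritParams beat_onset
#' @return integer sample count.
#' @export
beat_canopy <- function(w) {
  .check_normalized(w)
  length(.canopy_set(w))
}

#' True peaks/troughs of a normalized beat
#'
#' Canopy samples where the difference between successive samples changes
#' sign (local maxima and minima both count). A maximal run of exactly-zero
#' successive differences (a plateau, where the discrete derivative
#' vanishes) contributes one true peak at its midpoint sample.
#'
#' @inheritParams beat_onset
#' @return sorted integer vector of 0-based sample indices.
#' @export
beat_true_peaks <- function(w) {
  .check_normalized(w)
  canopy <- .canopy_set(w)
  n <- length(w)
  tp <- integer(0)
  for (i in 2:(n - 1L)) {
    dprev <- w[i] - w[i - 1L]
    dnext <- w[i + 1L] - w[i]
    if (dprev * dnext < 0 && i %in% canopy) tp <- c(tp, i)
  }
  # plateaus: maximal runs of zero differences
  d <- diff(w)
  z <- which(d == 0)
  if (length(z)) {
    runs <- split(z, cumsum(c(1L, diff(z) != 1L)))
    for (r in runs) {
      mid <- r[1] + (r[length(r)] + 1L - r[1]) %/% 2L  # midpoint sample
      if (mid %in% canopy) tp <- c(tp, mid)
    }
  }
  sort(unique(tp)) - 1L
}

#' Pseudo-peaks/troughs and their weights
#'
#' Within the canopy, samples whose successive-sample difference magnitude
#' is below `threshold` (but nonzero) mark near-vanishing derivatives. Each
#' maximal run of adjacent sub-threshold canopy samples that contains no
#' true-peak index contributes one pseudo-peak: the run's sample of smallest
#' difference magnitude, weighted `1 - |diff| / threshold` so the flattest
#' pseudo-peaks weigh most (weights in (0, 1)).
#'
#' @inheritParams beat_onset
#' @param threshold critical difference-magnitude threshold (default 0.01).
#' @return data frame with columns `index` (0-based) and `weight`.
#' @export
beat_pseudo_peaks <- function(w, threshold = 0.01) {
  .check_normalized(w)
  stopifnot(threshold > 0)
  canopy <- .canopy_set(w)
  tp <- beat_true_peaks(w) + 1L  # back to 1-based
  n <- length(w)
  # difference attached to sample i: d_i = w[i] - w[i-1], i = 2..n
  idx <- 2:n
  dmag <- abs(w[idx] - w[idx - 1L])
  elig <- idx[idx %in% canopy & dmag < threshold]
  out <- data.frame(index = integer(0), weight = numeric(0))
  if (length(elig) == 0) return(out)
  runs <- split(elig, cumsum(c(1L, diff(elig) != 1L)))
  for (r in runs) {
    if (any(r %in% tp)) next                       # true-peak run: weight 1 there
    dm <- abs(w[r] - w[r - 1L])
    if (min(dm) == 0) next                         # degenerate, handled as TP
    k <- r[which.min(dm)]
    out <- rbind(out, data.frame(index = k - 1L,
                                 weight = 1 - min(dm) / threshold))
  }
  out
}

#' Weighted peak count
#'
#' Cardinality of the true-peak set plus the sum of pseudo-peak weights.
#' As `threshold` shrinks toward zero the value approaches the discrete
#' count of true peaks.
#'
#' @inheritParams beat_pseudo_peaks
#' @return non-negative numeric weighted count.
#' @export
beat_peaks <- function(w, threshold = 0.01) {
  length(beat_true_peaks(w)) + sum(beat_pseudo_peaks(w, threshold)$weight)
}

#' Assemble the N x 3 morphological feature matrix
#'
#' @param beats a `tcd_beats` object.
#' @param pseudo_threshold threshold passed to [beat_peaks()].
#' @return a `tcd_features` object: provenance data frame plus columns
#'   `onset`, `canopy`, `peaks` (row order preserved).
#' @export
build_feature_matrix <- function(beats, pseudo_threshold = 0.01) {
  stopifnot(inherits(beats, "tcd_beats"))
  if (nrow(beats$waveforms) == 0) stop("no waveforms to featurize")
  W <- beats$waveforms
  feats <- data.frame(
    onset = apply(W, 1, beat_onset),
    canopy = apply(W, 1, beat_canopy),
    peaks = apply(W, 1, beat_peaks, threshold = pseudo_threshold)
  )
  out <- cbind(beats$info, feats)
  rownames(out) <- NULL
  class(out) <- c("tcd_features", "data.frame")
  out
}

#' Extract the numeric feature matrix
#'
#' @param features a `tcd_features` object (or any data frame with columns
#'   `onset`, `canopy`, `peaks`).
#' @return N x 3 numeric matrix with columns `onset`, `canopy`, `peaks`.
#' @export
feature_matrix <- function(features) {
  as.matrix(features[, c("onset", "canopy", "peaks")])
}
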