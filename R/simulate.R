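# Synthetic pulsatile TCD recordings with known ground truth. Ground truth
# (beat onsets, artifact flags, flow-type labels) travels alongside the
# signal and is never consumed by the analysis path.

#' Simulation configuration
#'
#' @param n_subjects_per_group subjects simulated per group (LVO, IHC, OHC).
#' @param group_flowtype_mixture 3x4 matrix of per-group probabilities over
#'   flow types I-IV; rows named LVO/IHC/OHC, rows must sum to 1. The default
#'   mixture makes types I/II dominate control groups and types III/IV
#'   dominate LVO, mirroring the group structure the clustering is meant to
#'   recover.
#' @param heart_rate_mean,heart_rate_sd per-beat heart rate distribution
#'   (bpm); beat durations are i.i.d. `60 / HR` with HR from a normal
#'   truncated to `[40, 180]` bpm.
#' @param sampling_rate acquisition rate in Hz, 125 or 400.
#' @param duration recording length in seconds; must admit at least 15 beats
#'   at the mean heart rate.
#' @param noise_sd additive white noise SD as a fraction of the pulse
#'   (systolic minus diastolic) amplitude.
#' @param artifact_beat_rate probability that any beat is replaced by an
#'   artifact (flatline or 3x amplitude spike, equiprobable).
#' @param rng_seed integer seed used by [generate_recording()] and
#'   [simulate_cohort()]; `NULL` uses the current RNG state.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects_per_group = 10,
                       group_flowtype_mixture = default_flowtype_mixture(),
                       heart_rate_mean = 75, heart_rate_sd = 5,
                       sampling_rate = 125, duration = 30,
                       noise_sd = 0.02, artifact_beat_rate = 0.05,
                       rng_seed = NULL) {
  mix <- as.matrix(group_flowtype_mixture)
  if (!all(dim(mix) == c(3L, 4L))) {
    stop("group_flowtype_mixture must be a 3x4 matrix (groups x flow types)")
  }
  if (is.null(rownames(mix))) rownames(mix) <- c("LVO", "IHC", "OHC")
  if (is.null(colnames(mix))) colnames(mix) <- c("I", "II", "III", "IV")
  if (any(mix < 0) || any(abs(rowSums(mix) - 1) > 1e-8)) {
    stop("each row of group_flowtype_mixture must be a probability vector summing to 1")
  }
  if (!sampling_rate %in% c(125, 400)) {
    stop("sampling_rate must be 125 or 400 Hz")
  }
  if (duration < 15 * (60 / heart_rate_mean)) {
    stop("duration must admit at least 15 beats at the mean heart rate")
  }
  stopifnot(
    n_subjects_per_group >= 1,
    heart_rate_mean > 0, heart_rate_sd >= 0,
    noise_sd >= 0, artifact_beat_rate >= 0, artifact_beat_rate <= 1
  )
  structure(
    list(
      n_subjects_per_group = as.integer(n_subjects_per_group),
      group_flowtype_mixture = mix,
      heart_rate_mean = heart_rate_mean, heart_rate_sd = heart_rate_sd,
      sampling_rate = sampling_rate, duration = duration,
      noise_sd = noise_sd, artifact_beat_rate = artifact_beat_rate,
      rng_seed = rng_seed
    ),
    class = "sim_config"
  )
}

#' Default group-to-flow-type mixture
#'
#' Control groups are dominated by the normal-like and late-onset types
#' (I/II) while the LVO group is dominated by the pathological narrow-spike
#' and blunted types (III/IV).
#'
#' @return 3x4 probability matrix, rows LVO/IHC/OHC, columns I-IV.
#' @export
default_flowtype_mixture <- function() {
  mix <- rbind(
    LVO = c(0.10, 0.10, 0.22, 0.58),
    IHC = c(0.47, 0.39, 0.01, 0.13),
    OHC = c(0.61, 0.25, 0.02, 0.12)
  )
  colnames(mix) <- c("I", "II", "III", "IV")
  mix
}

# truncated-normal draw by inverse-CDF (deterministic in the RNG stream)
.rtnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# gamma-shaped unit bump: 0 at u=0, max 1 at u=c, width set by alpha
.gamma_bump <- function(u, c, alpha) {
  out <- numeric(length(u))
  pos <- u > 0
  r <- u[pos] / c
  out[pos] <- exp(alpha * (log(r) - r + 1))
  out
}

# noise-free beat shape on phase grid u in [0,1), scaled to [0,1]
.beat_shape <- function(spec, u) {
  s <- numeric(length(u))
  for (j in seq_along(spec$peak_positions)) {
    s <- s + spec$peak_amplitudes[j] *
      .gamma_bump(u, spec$peak_positions[j], spec$peak_widths[j])
  }
  s / max(s)
}

#' Generate one synthetic beat waveform
#'
#' The beat starts at the systolic foot (the minimum sits at sample 1 for
#' the noise-free shape), rises to maximal velocity at a beat phase equal to
#' `spec$onset_delay`, and decays toward end diastole.
#'
#' @param spec a [flow_type_spec()].
#' @param beat_duration beat length in seconds, in `[0.4, 2]`.
#' @param fs sampling rate in Hz (125 or 400).
#' @param noise_sd additive Gaussian noise SD as a fraction of the pulse
#'   amplitude (systolic minus diastolic velocity).
#' @param v_sys systolic (peak) velocity in cm/s.
#'
#' @return numeric velocity series (cm/s), length `round(beat_duration*fs)`.
#' @export
generate_beat <- function(spec, beat_duration, fs, noise_sd = 0,
                          v_sys = 90) {
  stopifnot(inherits(spec, "flow_type_spec"))
  if (!fs %in% c(125, 400)) stop("fs must be 125 or 400 Hz")
  if (!is.finite(beat_duration) || beat_duration < 0.4 || beat_duration > 2) {
    stop("beat_duration must lie in [0.4, 2] seconds")
  }
  n <- round(beat_duration * fs)
  u <- (seq_len(n) - 1) / n
  v_dia <- spec$diastolic_level * v_sys
  v <- v_dia + (v_sys - v_dia) * .beat_shape(spec, u)
  if (noise_sd > 0) {
    v <- v + stats::rnorm(n, 0, noise_sd * (v_sys - v_dia))
  }
  pmax(v, 0)
}

#' Generate one synthetic 30-second style recording
#'
#' Concatenates beats with durations drawn from the heart-rate distribution,
#' optionally replacing beats with artifacts, and attaches acquisition
#' metadata plus ground truth (onset indices, artifact flags, flow type).
#'
#' @param cfg a [sim_config()].
#' @param spec the [flow_type_spec()] generating every beat of the recording.
#' @param subject_id,group,hemisphere metadata attached to the recording.
#' @param depth insonation depth in mm; default drawn uniformly in 45-60.
#' @param v_sys systolic velocity scale in cm/s.
#'
#' @return an object of class `tcd_recording`: list with `samples` (cm/s),
#'   `fs`, `subject_id`, `group`, `hemisphere`, `depth`, and `ground_truth`
#'   (`onsets` 1-based sample indices, `artifact` logical per beat,
#'   `flow_type`).
#' @export
generate_recording <- function(cfg, spec, subject_id = "S01",
                               group = c("LVO", "IHC", "OHC"),
                               hemisphere = c("left", "right"),
                               depth = NULL, v_sys = 90) {
  stopifnot(inherits(cfg, "sim_config"), inherits(spec, "flow_type_spec"))
  group <- match.arg(group)
  hemisphere <- match.arg(hemisphere)
  run <- function() {
    fs <- cfg$sampling_rate
    n_total <- round(cfg$duration * fs)
    if (is.null(depth)) depth <- stats::runif(1, 45, 60)
    samples <- numeric(0)
    onsets <- integer(0)
    artifact <- logical(0)
    while (length(samples) < n_total) {
      hr <- .rtnorm(1, cfg$heart_rate_mean, cfg$heart_rate_sd, 40, 180)
      dur <- min(max(60 / hr, 0.4), 1.5)
      is_art <- stats::runif(1) < cfg$artifact_beat_rate
      beat <- generate_beat(spec, dur, fs, cfg$noise_sd, v_sys)
      if (is_art) {
        if (stats::runif(1) < 0.5) {
          beat <- rep(spec$diastolic_level * v_sys, length(beat))  # flatline
        } else {
          beat <- beat * 3                                          # spike
        }
      }
      onsets <- c(onsets, length(samples) + 1L)
      artifact <- c(artifact, is_art)
      samples <- c(samples, beat)
    }
    keep <- onsets <= n_total
    structure(
      list(
        samples = samples[seq_len(n_total)], fs = fs,
        subject_id = subject_id, group = group, hemisphere = hemisphere,
        depth = depth,
        ground_truth = list(
          onsets = onsets[keep], artifact = artifact[keep],
          flow_type = spec$type_id
        )
      ),
      class = "tcd_recording"
    )
  }
  if (!is.null(cfg$rng_seed)) withr::with_seed(cfg$rng_seed, run()) else run()
}

#' @export
print.tcd_recording <- function(x, ...) {
  cat(sprintf(
    "<tcd_recording> %s %s %s %.1f mm, %.1f s @ %g Hz (%d ground-truth beats)\n",
    x$subject_id, x$group, x$hemisphere, x$depth,
    length(x$samples) / x$fs, x$fs, length(x$ground_truth$onsets)
  ))
  invisible(x)
}

#' Generate a labeled synthetic feature-space point cloud
#'
#' Produces `k` isotropic unit-variance Gaussian groups in 3-D whose
#' centroids are at least `separation` apart (centroids are placed on a
#' cubic lattice of spacing `separation`), as a test harness for the
#' gap-statistic cluster-number selection.
#'
#' @param k number of planted groups (1 to 27).
#' @param n_per_cluster points per group (>= 1).
#' @param separation minimum pairwise centroid distance, in z-units.
#' @param seed optional integer seed.
#'
#' @return list with `features` (an `k*n_per_cluster` x 3 matrix) and
#'   `labels` (integer ground-truth group per row).
#' @export
generate_feature_cloud <- function(k, n_per_cluster, separation, seed = NULL) {
  stopifnot(k >= 1, k <= 27, separation > 0)
  if (n_per_cluster < 1) stop("n_per_cluster must be >= 1")
  run <- function() {
    # tetrahedral cube corners first so structure spans all 3 dimensions,
    # then the remaining corners and the wider 3-level lattice
    corners <- rbind(
      c(0, 0, 0), c(1, 1, 0), c(1, 0, 1), c(0, 1, 1),
      c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1)
    )
    lattice <- as.matrix(expand.grid(0:2, 0:2, 0:2))
    extra <- lattice[rowSums(lattice == 2) > 0, , drop = FALSE]
    grid <- rbind(corners, unname(extra)) * separation
    centroids <- grid[seq_len(k), , drop = FALSE]
    labels <- rep(seq_len(k), each = n_per_cluster)
    pts <- centroids[labels, , drop = FALSE] +
      matrix(stats::rnorm(3 * length(labels)), ncol = 3)
    colnames(pts) <- c("f1", "f2", "f3")
    list(features = pts, labels = labels)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Simulate a full multi-group cohort of recordings
#'
#' For each group, simulates `cfg$n_subjects_per_group` subjects, each
#' scanned in both hemispheres at 2-4 depths per hemisphere. The flow type
#' of each recording is drawn from the group's mixture row; the systolic
#' velocity scale varies across recordings.
#'
#' @param cfg a [sim_config()]; `cfg$rng_seed` (if set) seeds the whole
#'   cohort draw.
#' @return list of `tcd_recording` objects.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  types <- flow_type_library()
  run <- function() {
    cfg_inner <- cfg
    cfg_inner$rng_seed <- NULL  # one stream for the whole cohort
    recs <- list()
    for (g in rownames(cfg$group_flowtype_mixture)) {
      probs <- cfg$group_flowtype_mixture[g, ]
      for (s in seq_len(cfg$n_subjects_per_group)) {
        sid <- sprintf("%s%02d", g, s)
        for (h in c("left", "right")) {
          n_depths <- sample(2:4, 1)
          depths <- sort(stats::runif(n_depths, 45, 60))
          for (d in depths) {
            ft <- sample(names(probs), 1, prob = probs)
            vs <- .rtnorm(1, 90, 14, 50, 140)
            recs[[length(recs) + 1L]] <- generate_recording(
              cfg_inner, types[[ft]], subject_id = sid, group = g,
              hemisphere = h, depth = d, v_sys = vs
            )
          }
        }
      }
    }
    recs
  }
  if (!is.null(cfg$rng_seed)) withr::with_seed(cfg$rng_seed, run()) else run()
}
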