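# Independent brute-force oracles (naive loops) and small fixtures used
# across the suite. These deliberately avoid the package's vectorized code
# paths.

norm01 <- function(x) (x - min(x)) / (max(x) - min(x))

# random normalized 100-sample waveform
random_waveform <- function(n = 100) {
  norm01(cumsum(stats::rnorm(n)))
}

brute_canopy_set <- function(w) {
  thr <- w[1] + 0.25 * (max(w) - min(w))
  out <- integer(0)
  for (i in seq_along(w)) if (w[i] > thr) out <- c(out, i)
  out
}

brute_onset <- function(w) {
  best <- 1L
  for (i in seq_along(w)) if (w[i] > w[best]) best <- i
  best - 1L
}

brute_canopy <- function(w) length(brute_canopy_set(w))

brute_true_peaks <- function(w) {
  canopy <- brute_canopy_set(w)
  n <- length(w)
  tp <- integer(0)
  for (i in 2:(n - 1)) {
    dprev <- w[i] - w[i - 1]
    dnext <- w[i + 1] - w[i]
    if (dprev * dnext < 0 && i %in% canopy) tp <- c(tp, i)
  }
  # plateau runs of exactly-zero differences -> midpoint sample
  i <- 2
  while (i <= n) {
    if (w[i] == w[i - 1]) {
      j <- i
      while (j < n && w[j + 1] == w[j]) j <- j + 1
      mid <- (i - 1) + (j - (i - 1)) %/% 2
      if (mid %in% canopy) tp <- c(tp, mid)
      i <- j + 1
    } else i <- i + 1
  }
  sort(unique(tp)) - 1L
}

brute_pseudo_peaks <- function(w, threshold = 0.01) {
  canopy <- brute_canopy_set(w)
  tp <- brute_true_peaks(w) + 1L
  n <- length(w)
  eligible <- logical(n)
  for (i in 2:n) {
    eligible[i] <- (i %in% canopy) && abs(w[i] - w[i - 1]) < threshold
  }
  out <- data.frame(index = integer(0), weight = numeric(0))
  i <- 2
  while (i <= n) {
    if (eligible[i]) {
      j <- i
      while (j < n && eligible[j + 1]) j <- j + 1
      run <- i:j
      if (!any(run %in% tp)) {
        dm <- abs(w[run] - w[run - 1])
        if (min(dm) > 0) {
          k <- run[which.min(dm)]
          out <- rbind(out, data.frame(index = k - 1L,
                                       weight = 1 - min(dm) / threshold))
        }
      }
      i <- j + 1
    } else i <- i + 1
  }
  out
}

brute_peaks <- function(w, threshold = 0.01) {
  length(brute_true_peaks(w)) + sum(brute_pseudo_peaks(w, threshold)$weight)
}

# adjusted Rand index (Hubert & Arabie), straightforward contingency form
adj_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxim <- (sum_a + sum_b) / 2
  if (maxim == expected) return(1)
  (sum_ij - expected) / (maxim - expected)
}

# noise-free cohort of recordings for end-to-end checks: `per_type`
# recordings of each flow type, heart rate varied across recordings but
# regular within each recording
noise_free_cohort <- function(per_type, hr_range = c(55, 95)) {
  lib <- flow_type_library()
  recs <- list()
  truth <- character(0)
  for (t in names(lib)) {
    for (r in seq_len(per_type)) {
      hr <- stats::runif(1, hr_range[1], hr_range[2])
      cfg <- sim_config(heart_rate_mean = hr, heart_rate_sd = 0,
                        noise_sd = 0, artifact_beat_rate = 0)
      recs[[length(recs) + 1L]] <- generate_recording(
        cfg, lib[[t]], subject_id = sprintf("%s%02d", t, r),
        hemisphere = if (r %% 2 == 0) "left" else "right"
      )
      truth <- c(truth, t)
    }
  }
  list(recordings = recs, flow_type = truth)
}

# waveform containing exactly one pseudo-peak run whose minimal successive
# difference magnitude is `min_diff`, plus one true peak at the maximum
pseudo_run_waveform <- function(min_diff = 0.001) {
  w <- c(
    seq(0, 0.4, by = 0.1),              # steep ascent (diffs 0.1)
    0.409, 0.410, 0.419,                # sub-threshold run, min diff = min_diff
    seq(0.5, 1, by = 0.1),              # steep ascent resumes
    seq(0.9, 0, by = -0.1)              # steep descent through a true peak
  )
  w[7] <- w[6] + min_diff               # run's minimal difference
  c(w, rep(0, 100 - length(w)))
}
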