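# Feature-space partitioning: z-score standardization, spectral clustering
# (RBF affinity, symmetric normalized spectral embedding, k-means on the
# row-normalized eigenvector basis), and gap-statistic selection of the
# cluster count against an SVD-range uniform reference distribution.

#' Z-score a feature matrix across observations
#'
#' Each column is centered by its mean and scaled by its sample standard
#' deviation (denominator N-1); the stored center/scale allow an exact
#' inverse transform.
#'
#' @param features a `tcd_features` object or numeric matrix.
#' @return a `tcd_zfeatures` object: list with `values` (N x p matrix),
#'   `center`, `scale`, and (when available) the provenance `info`.
#' @export
zscore_features <- function(features) {
  info <- NULL
  if (inherits(features, "tcd_features")) {
    info <- features[, setdiff(names(features), c("onset", "canopy", "peaks"))]
    X <- feature_matrix(features)
  } else {
    X <- as.matrix(features)
  }
  if (nrow(X) < 2) stop("need at least 2 observations to z-score")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  zero <- scl < .Machine$double.eps
  if (any(zero)) {
    stop(sprintf("zero-variance feature column(s): %s",
                 paste(colnames(X)[zero], collapse = ", ")))
  }
  structure(
    list(values = scale(X, center = ctr, scale = scl)[, , drop = FALSE],
         center = ctr, scale = scl, info = info),
    class = "tcd_zfeatures"
  )
}

#' Invert a z-score transform
#'
#' @param z a `tcd_zfeatures` object.
#' @return the original-scale feature matrix.
#' @export
unzscore_features <- function(z) {
  stopifnot(inherits(z, "tcd_zfeatures"))
  sweep(sweep(z$values, 2, z$scale, `*`), 2, z$center, `+`)
}

.as_values <- function(Z) {
  if (inherits(Z, "tcd_zfeatures")) Z$values else as.matrix(Z)
}

# RBF affinity exp(-gamma * d^2) with unit diagonal
.rbf_affinity <- function(X, gamma) {
  D2 <- as.matrix(stats::dist(X))^2
  exp(-gamma * D2)
}

# top-kmax eigenvectors of the symmetric normalized affinity D^-1/2 A D^-1/2
.spectral_embedding <- function(X, kmax, gamma) {
  A <- .rbf_affinity(X, gamma)
  dg <- rowSums(A)
  M <- A / sqrt(outer(dg, dg))
  eigen(M, symmetric = TRUE)$vectors[, seq_len(kmax), drop = FALSE]
}

# k-means on the row-normalized first k eigenvectors
.embedding_labels <- function(E, k, nstart = 10) {
  if (k == nrow(E)) return(seq_len(k))  # every point its own cluster
  Y <- E[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(Y^2))
  rn[rn < .Machine$double.eps] <- 1
  Y <- Y / rn
  stats::kmeans(Y, centers = k, nstart = nstart, iter.max = 100)$cluster
}

#' Spectral clustering with radial-basis affinity
#'
#' Partitions z-scored features into `k` clusters: affinity
#' `exp(-affinity_scale * d^2)`, symmetric normalized spectral embedding,
#' row normalization, k-means on the leading `k` eigenvectors.
#'
#' @param Z a `tcd_zfeatures` object or numeric matrix.
#' @param k number of clusters, `2 <= k <= N`.
#' @param affinity_scale RBF scale gamma (default 1 on z-scored features).
#' @param seed optional integer seed making the k-means step deterministic.
#' @param nstart k-means restarts.
#' @return integer vector of cluster labels in `1..k` (every label used).
#' @export
spectral_cluster <- function(Z, k, affinity_scale = 1, seed = NULL,
                             nstart = 10) {
  X <- .as_values(Z)
  n <- nrow(X)
  if (k < 2 || k > n) stop("k must satisfy 2 <= k <= N")
  run <- function() {
    E <- .spectral_embedding(X, k, affinity_scale)
    .embedding_labels(E, k, nstart)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Pooled within-cluster dispersion
#'
#' Sum over clusters of the ordered-pair squared Euclidean distances among
#' members divided by twice the cluster size (equivalently, the within-
#' cluster sum of squared distances to the centroid).
#'
#' @param Z a `tcd_zfeatures` object or numeric matrix.
#' @param labels cluster assignment per row.
#' @param k optional declared number of clusters; if given, any empty
#'   cluster raises an error.
#' @return non-negative scalar dispersion `W`.
#' @export
pooled_dispersion <- function(Z, labels, k = NULL) {
  X <- .as_values(Z)
  stopifnot(length(labels) == nrow(X))
  if (!is.null(k) && length(unique(labels)) < k) {
    stop("empty cluster: fewer occupied labels than declared k")
  }
  W <- 0
  for (lab in unique(labels)) {
    Xr <- X[labels == lab, , drop = FALSE]
    nr <- nrow(Xr)
    if (nr > 1) {
      W <- W + sum(stats::dist(Xr)^2) / nr  # unordered pairs / n_r
    }
  }
  W
}

#' Draw one SVD-range uniform reference sample
#'
#' The observed matrix is rotated by its right singular vectors, a sample is
#' drawn uniformly over the per-column range of the rotated data, and the
#' sample is rotated back to feature space. Uses the current RNG state;
#' seed upstream for reproducibility.
#'
#' @param Z a `tcd_zfeatures` object or numeric matrix.
#' @return numeric matrix of the same dimensions.
#' @export
reference_sample <- function(Z) {
  X <- .as_values(Z)
  if (nrow(X) < 2) stop("need at least 2 observations")
  V <- svd(X)$v
  Xp <- X %*% V
  lo <- apply(Xp, 2, min)
  hi <- apply(Xp, 2, max)
  U <- vapply(seq_len(ncol(Xp)),
              function(j) stats::runif(nrow(Xp), lo[j], hi[j]),
              numeric(nrow(Xp)))
  U %*% t(V)
}

#' Gap-statistic profile over a range of cluster counts
#'
#' For each `k` in `k_range`, clusters the observed data and `B` reference
#' samples with the same spectral algorithm and computes the gap
#' `G[k] = mean_b log W_ref[b,k] - log W_obs[k]` together with the
#' simulation-corrected bootstrap standard deviation
#' `S[k] = sd_b(log W_ref[,k]) * sqrt(1 + 1/B)`. For each dataset the
#' spectral embedding is computed once and shared across all `k`.
#'
#' @param Z a `tcd_zfeatures` object or numeric matrix.
#' @param k_range consecutive integer cluster counts (default `2:7`).
#' @param B number of reference bootstrap samples (default 1000).
#' @param affinity_scale RBF scale gamma.
#' @param seed optional integer seed covering the whole profile.
#' @param nstart k-means restarts per clustering.
#' @return a `tcd_gap` object: data frame with columns `k`, `logW`, `ElogW`,
#'   `G`, `S`, plus attributes `B`, `seed`, and `labels_by_k` (observed
#'   labels at each k, reusable downstream).
#' @export
gap_profile <- function(Z, k_range = 2:7, B = 1000, affinity_scale = 1,
                        seed = NULL, nstart = 10) {
  X <- .as_values(Z)
  k_range <- as.integer(k_range)
  stopifnot(length(k_range) >= 1, all(diff(k_range) == 1L),
            min(k_range) >= 2, nrow(X) >= max(k_range), B >= 1)
  kmax <- max(k_range)
  logW_of <- function(M) {
    E <- .spectral_embedding(M, kmax, affinity_scale)
    vapply(k_range, function(k) {
      lab <- .embedding_labels(E, k, nstart)
      log(max(pooled_dispersion(M, lab, k = k), .Machine$double.xmin))
    }, numeric(1))
  }
  labels_of <- function(M) {
    E <- .spectral_embedding(M, kmax, affinity_scale)
    lapply(k_range, function(k) .embedding_labels(E, k, nstart))
  }
  run <- function() {
    obs_labels <- labels_of(X)
    logW <- vapply(seq_along(k_range), function(i) {
      log(max(pooled_dispersion(X, obs_labels[[i]], k = k_range[i]),
              .Machine$double.xmin))
    }, numeric(1))
    logW_ref <- matrix(NA_real_, B, length(k_range))
    for (b in seq_len(B)) {
      logW_ref[b, ] <- logW_of(reference_sample(X))
    }
    ElogW <- colMeans(logW_ref)
    S <- apply(logW_ref, 2, stats::sd) * sqrt(1 + 1 / B)
    if (B == 1) S[] <- 0
    out <- data.frame(k = k_range, logW = logW, ElogW = ElogW,
                      G = ElogW - logW, S = S)
    attr(out, "B") <- B
    attr(out, "seed") <- seed
    attr(out, "labels_by_k") <- stats::setNames(obs_labels,
                                                paste0("k", k_range))
    class(out) <- c("tcd_gap", "data.frame")
    out
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Select the cluster count from a gap profile
#'
#' Returns the smallest `k` such that `G[k] > G[k+1] - S[k+1]`. When no `k`
#' in the profile satisfies the rule, the largest `k` is returned with
#' `no_elbow = TRUE`.
#'
#' @param profile a `tcd_gap` object (consecutive `k`).
#' @return list with `k` (integer) and `no_elbow` (logical).
#' @export
select_k <- function(profile) {
  stopifnot(inherits(profile, "tcd_gap"))
  G <- profile$G
  S <- profile$S
  ks <- profile$k
  if (length(ks) > 1) {
    for (i in seq_len(length(ks) - 1L)) {
      if (G[i] > G[i + 1L] - S[i + 1L]) {
        return(list(k = ks[i], no_elbow = FALSE))
      }
    }
  }
  list(k = ks[length(ks)], no_elbow = TRUE)
}
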