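# Cluster description: members ranked by mean intra-cluster squared
# distance over the normalized 100-sample waveforms (not the 3 features),
# yielding the exemplar (rank 1), the archetype (mean of the 5 best-ranked
# members), and the subject-group composition of each cluster.

# mean squared Euclidean distance of each row to the other rows (self
# excluded, denominator n-1; singleton -> 0)
.mean_intra_dist <- function(W) {
  n <- nrow(W)
  if (n == 1) return(0)
  D2 <- as.matrix(stats::dist(W))^2
  rowSums(D2) / (n - 1)
}

#' Rank cluster members by mean intra-cluster distance
#'
#' @param waveforms n x 100 matrix of the cluster's normalized waveforms.
#' @param ids member identifiers (default row names or indices); ties in
#'   mean distance are broken by id order.
#' @return `ids` reordered by ascending mean squared distance to the other
#'   members.
#' @export
rank_members <- function(waveforms, ids = NULL) {
  W <- as.matrix(waveforms)
  if (nrow(W) == 0) stop("cluster is empty")
  if (is.null(ids)) {
    ids <- if (!is.null(rownames(W))) rownames(W) else seq_len(nrow(W))
  }
  stopifnot(length(ids) == nrow(W))
  d <- .mean_intra_dist(W)
  ids[order(d, ids)]
}

#' Most representative cluster member
#'
#' The member with smallest mean intra-cluster squared distance (the first
#' element of [rank_members()]).
#'
#' @inheritParams rank_members
#' @return single id.
#' @export
cluster_exemplar <- function(waveforms, ids = NULL) {
  rank_members(waveforms, ids)[1]
}

#' Cluster archetype waveform
#'
#' Element-wise mean of the `min(5, n)` members with smallest mean
#' intra-cluster distance.
#'
#' @inheritParams rank_members
#' @return numeric waveform of the same length as the inputs.
#' @export
cluster_archetype <- function(waveforms, ids = NULL) {
  W <- as.matrix(waveforms)
  if (nrow(W) == 0) stop("cluster is empty")
  if (is.null(ids)) {
    ids <- if (!is.null(rownames(W))) rownames(W) else seq_len(nrow(W))
  }
  top <- rank_members(W, ids)[seq_len(min(5L, nrow(W)))]
  colMeans(W[match(top, ids), , drop = FALSE])
}

#' Subject-group composition of each cluster
#'
#' @param labels cluster assignment per waveform.
#' @param groups subject-group label per waveform (`LVO`/`IHC`/`OHC`).
#' @return data frame with one row per cluster: `cluster`, `size`, integer
#'   percentages `pct_<group>` (rounded as reported) and raw fractions
#'   `frac_<group>`.
#' @export
cluster_composition <- function(labels, groups) {
  stopifnot(length(labels) == length(groups))
  if (any(is.na(groups))) stop("missing group label")
  lev <- c("LVO", "IHC", "OHC")
  lev <- c(lev[lev %in% groups], setdiff(unique(groups), lev))
  out <- lapply(sort(unique(labels)), function(cl) {
    g <- groups[labels == cl]
    frac <- vapply(lev, function(l) mean(g == l), numeric(1))
    row <- data.frame(cluster = cl, size = length(g))
    for (l in lev) {
      row[[paste0("pct_", l)]] <- round(100 * frac[[l]])
      row[[paste0("frac_", l)]] <- frac[[l]]
    }
    row
  })
  do.call(rbind, out)
}

#' Full per-cluster report
#'
#' Combines cluster sizes, exemplars, archetypes and group composition.
#'
#' @param beats a `tcd_beats` object (rows aligned with `labels`).
#' @param labels cluster assignment per waveform.
#' @return a `tcd_report` object: list with `composition` (data frame),
#'   `exemplars` (named id vector), `archetypes` (k x 100 matrix, one row
#'   per cluster), and `labels`.
#' @export
cluster_report <- function(beats, labels) {
  stopifnot(inherits(beats, "tcd_beats"),
            length(labels) == nrow(beats$waveforms))
  comp <- cluster_composition(labels, beats$info$group)
  cls <- sort(unique(labels))
  ex <- character(length(cls))
  arch <- matrix(NA_real_, length(cls), ncol(beats$waveforms))
  for (i in seq_along(cls)) {
    sel <- labels == cls[i]
    W <- beats$waveforms[sel, , drop = FALSE]
    ids <- beats$info$waveform_id[sel]
    ex[i] <- as.character(cluster_exemplar(W, ids))
    arch[i, ] <- cluster_archetype(W, ids)
  }
  names(ex) <- paste0("cluster_", cls)
  rownames(arch) <- paste0("cluster_", cls)
  structure(
    list(composition = comp, exemplars = ex, archetypes = arch,
         labels = labels),
    class = "tcd_report"
  )
}

#' @export
print.tcd_report <- function(x, ...) {
  cat(sprintf("<tcd_report> %d cluster(s), %d waveform(s)\n",
              nrow(x$composition), length(x$labels)))
  print(x$composition[, !grepl("^frac_", names(x$composition))])
  cat("exemplars:", paste(sprintf("%s=%s", names(x$exemplars), x$exemplars),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Plot cluster archetype waveforms
#'
#' One panel per cluster showing the archetype on the normalized time axis.
#'
#' @param x a `tcd_report` object.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.tcd_report <- function(x, ...) {
  k <- nrow(x$archetypes)
  op <- graphics::par(mfrow = c(ceiling(k / 2), min(k, 2)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(k)) {
    graphics::plot(seq_len(ncol(x$archetypes)) - 1, x$archetypes[i, ],
                   type = "l", lwd = 2, ylim = c(0, 1),
                   xlab = "normalized time (samples)",
                   ylab = "normalized velocity",
                   main = rownames(x$archetypes)[i], ...)
  }
  invisible(x)
}
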