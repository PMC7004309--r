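# Plain-text interchange formats: recording CSV with `# key=value` header
# lines and one velocity per line, normalized-beat CSV (provenance columns
# + s001..s100), feature CSV, and JSON for cluster results and reports.

#' Write a recording to CSV
#'
#' Header lines `# subject_id=... group=... hemisphere=... depth_mm=...
#' fs_hz=...` followed by one velocity value (cm/s) per line. Ground truth,
#' when present, is written to a sibling `<path>.truth.json`.
#'
#' @param rec a `tcd_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  hdr <- sprintf("# subject_id=%s group=%s hemisphere=%s depth_mm=%.2f fs_hz=%g",
                 rec$subject_id, rec$group, rec$hemisphere, rec$depth, rec$fs)
  writeLines(c(hdr, format(rec$samples, trim = TRUE, digits = 10)), path)
  if (!is.null(rec$ground_truth)) {
    jsonlite::write_json(rec$ground_truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a recording from CSV
#'
#' @param path file written by [write_recording_csv()] (or any file in the
#'   same dialect). A sibling `<path>.truth.json`, if present, is loaded as
#'   ground truth.
#' @return a `tcd_recording`.
#' @export
read_recording_csv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (length(hdr) == 0) stop("missing `# key=value` header line")
  kv <- regmatches(hdr[1], gregexpr("[A-Za-z_]+=[^ ]+", hdr[1]))[[1]]
  meta <- stats::setNames(
    sub("^[A-Za-z_]+=", "", kv),
    sub("=.*$", "", kv)
  )
  truth_path <- paste0(path, ".truth.json")
  gt <- NULL
  if (file.exists(truth_path)) {
    gt <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  }
  structure(
    list(
      samples = as.numeric(lines[!startsWith(lines, "#")]),
      fs = as.numeric(meta[["fs_hz"]]),
      subject_id = meta[["subject_id"]],
      group = meta[["group"]],
      hemisphere = meta[["hemisphere"]],
      depth = as.numeric(meta[["depth_mm"]]),
      ground_truth = gt
    ),
    class = "tcd_recording"
  )
}

#' Write a normalized-beat set to CSV
#'
#' @param beats a `tcd_beats` object.
#' @param path output CSV path (provenance columns followed by `s001..s100`).
#' @return `path`, invisibly.
#' @export
write_beats_csv <- function(beats, path) {
  stopifnot(inherits(beats, "tcd_beats"))
  W <- beats$waveforms
  colnames(W) <- sprintf("s%03d", seq_len(ncol(W)))
  utils::write.csv(cbind(beats$info, as.data.frame(W)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a normalized-beat set from CSV
#'
#' @param path file written by [write_beats_csv()].
#' @return a `tcd_beats` object.
#' @export
read_beats_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sample_cols <- grep("^s[0-9]{3}$", names(df))
  tcd_beats(as.matrix(df[, sample_cols]), df[, -sample_cols, drop = FALSE])
}

#' Write the feature table to CSV
#'
#' @param features a `tcd_features` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path file written by [write_features_csv()].
#' @return a `tcd_features` object.
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("tcd_features", "data.frame")
  df
}

#' Write clustering results to JSON
#'
#' @param gap a `tcd_gap` profile.
#' @param selection result of [select_k()].
#' @param labels final labels at the selected k.
#' @param waveform_ids ids aligned with `labels`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_clusters_json <- function(gap, selection, labels, waveform_ids, path) {
  obj <- list(
    k_selected = selection$k,
    no_elbow = selection$no_elbow,
    B = attr(gap, "B"),
    seed = attr(gap, "seed"),
    profile = as.data.frame(gap),
    labels = stats::setNames(as.list(labels), waveform_ids)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a cluster report to disk
#'
#' Writes `report.json` (composition, exemplars) and `archetypes.csv`
#' (one row per cluster) into `dir`.
#'
#' @param report a `tcd_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(composition = report$composition,
         exemplars = as.list(report$exemplars)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA
  )
  arch <- as.data.frame(report$archetypes)
  colnames(arch) <- sprintf("s%03d", seq_len(ncol(arch)))
  utils::write.csv(cbind(cluster = rownames(report$archetypes), arch),
                   file.path(dir, "archetypes.csv"), row.names = FALSE)
  invisible(dir)
}
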