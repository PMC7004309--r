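#' Flow-type morphology specifications
#'
#' A `flow_type_spec` parameterizes the shape of one beat morphology class as
#' a sum of positive gamma-shaped velocity bumps above a diastolic floor. Each
#' bump `j` contributes `a_j * (u/c_j)^alpha_j * exp(-alpha_j*(u/c_j - 1))`
#' at beat phase `u` in `[0, 1)`: the bump is exactly zero at the systolic
#' foot (`u = 0`), attains its maximum 1 at `u = c_j`, and decays toward end
#' diastole. `alpha_j` controls sharpness (larger = narrower).
#'
#' @param type_id one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param peak_positions fractional beat-phase locations of the velocity
#'   bumps (P1/P2/P3 components), strictly increasing, in (0, 1).
#' @param peak_amplitudes relative bump heights (dimensionless, positive).
#' @param peak_widths sharpness parameter per bump (dimensionless, > 1).
#' @param onset_delay fraction of the beat elapsed at maximal velocity.
#' @param canopy_width approximate fraction of the beat above quarter range
#'   (descriptive; used for documentation and sanity checks, not generation).
#' @param diastolic_level end-diastolic velocity as a fraction of systolic.
#'
#' @return an object of class `flow_type_spec`.
#' @seealso [flow_type_library()] for the four bundled archetype specs.
#' @export
flow_type_spec <- function(type_id, peak_positions, peak_amplitudes,
                           peak_widths, onset_delay, canopy_width,
                           diastolic_level) {
  type_id <- match.arg(type_id, c("I", "II", "III", "IV"))
  stopifnot(
    length(peak_positions) >= 1L,
    length(peak_amplitudes) == length(peak_positions),
    length(peak_widths) == length(peak_positions),
    all(peak_positions > 0), all(peak_positions < 1),
    all(diff(peak_positions) > 0),
    all(peak_amplitudes > 0),
    all(peak_widths > 1),
    onset_delay > 0, onset_delay < 1,
    canopy_width > 0, canopy_width <= 1,
    diastolic_level > 0, diastolic_level < 1
  )
  structure(
    list(
      type_id = type_id,
      peak_positions = as.numeric(peak_positions),
      peak_amplitudes = as.numeric(peak_amplitudes),
      peak_widths = as.numeric(peak_widths),
      onset_delay = onset_delay,
      canopy_width = canopy_width,
      diastolic_level = diastolic_level
    ),
    class = "flow_type_spec"
  )
}

#' Bundled flow-type library
#'
#' Fixed, versioned morphology parameters for the four flow types the
#' clustering analysis targets:
#'
#' * **I** (normal-like): early maximal velocity at P1, wide systolic canopy,
#'   three resolvable peaks (P1 > P2 > P3) with clear troughs.
#' * **II** (late-onset): maximal velocity shifted to P2, otherwise wide
#'   canopy and strong peak structure.
#' * **III** (narrow-spike): a single sharp early systolic spike, narrow
#'   canopy, no secondary structure, low diastolic flow.
#' * **IV** (blunted): one broad, delayed velocity mound; late onset, no
#'   resolvable secondary peaks, high relative diastolic flow.
#'
#' @return named list of [flow_type_spec()] objects (`I`, `II`, `III`, `IV`).
#' @export
flow_type_library <- function() {
  list(
    I = flow_type_spec(
      "I",
      peak_positions = c(0.16, 0.35, 0.56),
      peak_amplitudes = c(1.00, 0.72, 0.52),
      peak_widths = c(4, 14, 26),
      onset_delay = 0.176, canopy_width = 0.65, diastolic_level = 0.30
    ),
    II = flow_type_spec(
      "II",
      peak_positions = c(0.16, 0.40, 0.62),
      peak_amplitudes = c(0.78, 1.00, 0.55),
      peak_widths = c(5, 15, 28),
      onset_delay = 0.408, canopy_width = 0.70, diastolic_level = 0.30
    ),
    III = flow_type_spec(
      "III",
      peak_positions = c(0.16, 0.34),
      peak_amplitudes = c(1.00, 0.20),
      peak_widths = c(4, 8),
      onset_delay = 0.168, canopy_width = 0.35, diastolic_level = 0.12
    ),
    IV = flow_type_spec(
      "IV",
      peak_positions = 0.48,
      peak_amplitudes = 1,
      peak_widths = 9,
      onset_delay = 0.48, canopy_width = 0.55, diastolic_level = 0.45
    )
  )
}

#' @export
print.flow_type_spec <- function(x, ...) {
  cat(sprintf(
    "<flow_type_spec %s> %d bump(s) at phase [%s], onset_delay=%.2f, diastolic=%.2f\n",
    x$type_id, length(x$peak_positions),
    paste(format(x$peak_positions), collapse = ", "),
    x$onset_delay, x$diastolic_level
  ))
  invisible(x)
}
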