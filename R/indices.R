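# brute-force geometric primitives shared by the phantom truth and the
# index computations
max_pairwise_distance <- function(xy) {
  xy <- xy[stats::complete.cases(xy), , drop = FALSE]
  if (nrow(xy) < 2L) return(0)
  max(stats::dist(xy))
}

path_length <- function(xy) {
  xy <- xy[stats::complete.cases(xy), , drop = FALSE]
  if (nrow(xy) < 2L) return(0)
  sum(sqrt(rowSums(diff(xy)^2)))
}

traj_positions <- function(trajectory, annulus) {
  tr <- trajectory[trajectory$annulus == annulus, ]
  tr <- tr[order(tr$frame), ]
  as.matrix(tr[, c("row", "col")])
}

index_spacing <- function(trajectory, pixel_spacing) {
  if (is.null(pixel_spacing)) {
    pixel_spacing <- attr(trajectory, "pixel_spacing") %||% NA_real_
  }
  if (is.na(pixel_spacing)) list(spacing = 1, unit = "px")
  else list(spacing = pixel_spacing, unit = "cm")
}

#' Linear tricuspid annular displacement (LTAD)
#'
#' The maximum displacement between two positions of the annulus: the maximum
#' over all frame pairs of the Euclidean distance between tracked positions,
#' converted to cm with the pixel spacing. The pairwise maximum is used (not a
#' fixed reference frame) so the index does not depend on cycle-phase
#' labelling.
#'
#' @param trajectory An `annulus_trajectory`.
#' @param annulus Which annulus (`"lateral"` or `"septal"`).
#' @param pixel_spacing cm/px; defaults to the trajectory's. Without
#'   calibration the value is in px (see [displacement_indices()] for the
#'   unit tag).
#' @return The index (scalar).
#' @export
ltad <- function(trajectory, annulus = "lateral", pixel_spacing = NULL) {
  xy <- traj_positions(trajectory, annulus)
  if (sum(stats::complete.cases(xy)) < 2L) {
    abort("LTAD undefined: fewer than 2 tracked frames")
  }
  sp <- index_spacing(trajectory, pixel_spacing)
  max_pairwise_distance(xy) * sp$spacing
}

#' Circumferential tricuspid annular displacement (CTAD)
#'
#' The total bidirectional distance traversed by the annulus: the sum of
#' Euclidean step lengths between consecutive tracked frames (missing frames
#' are skipped), converted to cm with the pixel spacing. Always at least as
#' large as [ltad()].
#'
#' @inheritParams ltad
#' @return The index (scalar).
#' @export
ctad <- function(trajectory, annulus = "lateral", pixel_spacing = NULL) {
  xy <- traj_positions(trajectory, annulus)
  if (sum(stats::complete.cases(xy)) < 2L) {
    abort("CTAD undefined: fewer than 2 tracked frames")
  }
  sp <- index_spacing(trajectory, pixel_spacing)
  path_length(xy) * sp$spacing
}

#' Displacement indices for every tracked annulus
#'
#' Computes LTAD and CTAD per annulus from a (smoothed) trajectory, together
#' with per-annulus quality information: the number of frames used, the
#' fraction of missing frames, and a validity flag that is cleared when the
#' longest run of missing frames exceeds `max_gap` (by default the median
#' window used for smoothing), since bridging a long gap would understate the
#' traversed path.
#'
#' @param trajectory An `annulus_trajectory`.
#' @param pixel_spacing cm/px; defaults to the trajectory's own. When
#'   uncalibrated, indices are reported in px and `unit` says so — never
#'   silently as cm.
#' @param max_gap Longest tolerated run of missing frames.
#' @return A tibble with columns `annulus`, `ltad`, `ctad`, `unit`,
#'   `frames_used`, `frac_missing`, `valid`.
#' @export
displacement_indices <- function(trajectory, pixel_spacing = NULL,
                                 max_gap = 3L) {
  sp <- index_spacing(trajectory, pixel_spacing)
  dplyr::bind_rows(lapply(unique(trajectory$annulus), function(a) {
    xy <- traj_positions(trajectory, a)
    present <- stats::complete.cases(xy)
    if (sum(present) < 2L) {
      abort(sprintf("indices undefined for %s annulus: fewer than 2 tracked frames", a))
    }
    gaps <- rle(!present)
    longest_gap <- if (any(gaps$values)) max(gaps$lengths[gaps$values]) else 0L
    tibble(annulus = a,
           ltad = max_pairwise_distance(xy) * sp$spacing,
           ctad = path_length(xy) * sp$spacing,
           unit = sp$unit,
           frames_used = sum(present),
           frac_missing = mean(!present),
           valid = longest_gap <= max_gap)
  }))
}
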