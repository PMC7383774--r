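#' Center of mass of a label class
#'
#' The annulus position for one frame is the unweighted mean of the `(row,
#' col)` coordinates (0-based) of all pixels carrying the class label. All
#' labelled pixels contribute — no connected-component filtering — matching
#' the definition used for annular tracking.
#'
#' @param mask Integer matrix (one frame of a label map).
#' @param class_id Label value to locate.
#' @return Numeric `c(row, col)`, or `c(NA, NA)` when no pixel carries the
#'   label (an empty frame is a value, not an error).
#' @export
mask_centroid <- function(mask, class_id) {
  idx <- which(mask == class_id, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(c(row = NA_real_, col = NA_real_))
  c(row = mean(idx[, 1L]) - 1, col = mean(idx[, 2L]) - 1)
}

#' Track annulus positions across a label-map sequence
#'
#' Applies [mask_centroid()] per frame and per annulus class.
#'
#' @param labels A [label_map_sequence] (or plain integer `H x W x T` array).
#' @param classes Named integer vector of annulus classes to track.
#' @param pixel_spacing Overrides the sequence's spacing if given.
#' @return An `annulus_trajectory`: a tibble with columns `frame`, `annulus`,
#'   `row`, `col` (`NA` for frames where the class is absent) and a
#'   `pixel_spacing` attribute.
#' @export
track_sequence <- function(labels, classes = annulus_classes,
                           pixel_spacing = NULL) {
  arr <- label_array(labels)
  if (is.null(pixel_spacing)) {
    pixel_spacing <- if (inherits(labels, "label_map_sequence"))
      labels$pixel_spacing else NA_real_
  }
  nT <- dim(arr)[3L]
  out <- dplyr::bind_rows(lapply(names(classes), function(a) {
    pos <- t(vapply(seq_len(nT),
                    function(t) mask_centroid(arr[, , t], classes[[a]]),
                    numeric(2L)))
    tibble(frame = seq_len(nT), annulus = a, row = pos[, 1L], col = pos[, 2L])
  }))
  new_trajectory(out, pixel_spacing)
}

new_trajectory <- function(tbl, pixel_spacing) {
  structure(tbl, pixel_spacing = as.numeric(pixel_spacing),
            class = c("annulus_trajectory", class(tibble())))
}

#' Median-smooth an annulus trajectory
#'
#' Per-coordinate running median over frames, applied independently per
#' annulus. At the sequence edges the window shrinks to the available frames;
#' frames with a missing position are excluded from each window (and remain
#' missing — no interpolation, since interpolating would invent motion).
#'
#' @param trajectory An `annulus_trajectory` from [track_sequence()].
#' @param window Odd window length in frames (1 = identity).
#' @return The smoothed trajectory (same shape).
#' @export
smooth_trajectory <- function(trajectory, window = 3L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) abort("window must be odd and >= 1")
  if (all(is.na(trajectory$row))) {
    abort("tracking failed: every frame is missing for this case")
  }
  h <- (window - 1L) %/% 2L
  smooth_vec <- function(v) {
    n <- length(v)
    out <- v
    for (i in seq_len(n)) {
      w <- v[max(1L, i - h):min(n, i + h)]
      w <- w[!is.na(w)]
      if (is.na(v[i]) || length(w) == 0L) next
      out[i] <- median(w)
    }
    out
  }
  out <- trajectory |>
    dplyr::group_by(.data$annulus) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(row = smooth_vec(.data$row), col = smooth_vec(.data$col)) |>
    dplyr::ungroup()
  new_trajectory(out, attr(trajectory, "pixel_spacing"))
}

# map a trajectory from standardized geometry back to original frame coords
transform_trajectory <- function(trajectory, transform) {
  out <- trajectory |>
    dplyr::mutate(row = (.data$row - transform$pad[1L]) / transform$scale,
                  col = (.data$col - transform$pad[2L]) / transform$scale)
  new_trajectory(out, attr(trajectory, "pixel_spacing"))
}

#' @export
autoplot.annulus_trajectory <- function(object, ...) {
  ggplot2::ggplot(object[!is.na(object$row), ],
                  ggplot2::aes(x = .data$col, y = .data$row,
                               colour = .data$annulus)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (px)", y = "row (px)",
                  title = "Tracked annulus trajectories")
}
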