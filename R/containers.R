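#' Annulus class coding
#'
#' Label maps use 0 = background (non-annular), 1 = lateral tricuspid
#' annulus, 2 = septal tricuspid annulus. Coordinates throughout the package
#' are 0-based `(row, col)` with the row increasing downward.
#'
#' @export
annulus_classes <- c(lateral = 1L, septal = 2L)

#' Cine image sequence
#'
#' A time-ordered stack of grayscale frames with physical pixel spacing.
#'
#' @param frames Numeric array `H x W x T` with intensities (any range; the
#'   pipeline rescales per frame).
#' @param pixel_spacing Pixel spacing in cm/px, or `NA` when uncalibrated
#'   (indices are then reported in px).
#' @param frame_times Optional numeric vector of frame times in seconds.
#' @return An object of class `cine_sequence`.
#' @export
cine_sequence <- function(frames, pixel_spacing = NA_real_,
                          frame_times = NULL) {
  if (length(dim(frames)) == 2L) dim(frames) <- c(dim(frames), 1L)
  if (length(dim(frames)) != 3L) abort("frames must be an H x W x T array")
  if (!is.null(frame_times) && length(frame_times) != dim(frames)[3L]) {
    abort("frame_times length must equal the frame count")
  }
  structure(list(frames = frames,
                 pixel_spacing = as.numeric(pixel_spacing),
                 frame_times = frame_times),
            class = "cine_sequence")
}

#' @export
print.cine_sequence <- function(x, ...) {
  d <- dim(x$frames)
  sp <- if (is.na(x$pixel_spacing)) "uncalibrated (px)" else
    sprintf("%.4g cm/px", x$pixel_spacing)
  cat(sprintf("<cine_sequence> %d frames of %dx%d, %s\n", d[3L], d[1L], d[2L],
              sp))
  invisible(x)
}

#' @export
dim.cine_sequence <- function(x) dim(x$frames)

#' Label-map sequence
#'
#' Integer segmentation masks per frame: 0 background, 1 lateral annulus,
#' 2 septal annulus.
#'
#' @param labels Integer array `H x W x T`.
#' @param pixel_spacing Pixel spacing in cm/px (`NA` if unknown).
#' @param allowed Permitted label values.
#' @return An object of class `label_map_sequence`.
#' @export
label_map_sequence <- function(labels, pixel_spacing = NA_real_,
                               allowed = c(0L, annulus_classes)) {
  if (length(dim(labels)) == 2L) dim(labels) <- c(dim(labels), 1L)
  if (length(dim(labels)) != 3L) abort("labels must be an H x W x T array")
  bad <- setdiff(unique(as.integer(labels)), as.integer(allowed))
  if (length(bad)) {
    abort(paste0("unknown label values: ", paste(sort(bad), collapse = ", ")))
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, pixel_spacing = as.numeric(pixel_spacing)),
            class = "label_map_sequence")
}

#' @export
print.label_map_sequence <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_map_sequence> %d frames of %dx%d, labels {%s}\n",
              d[3L], d[1L], d[2L],
              paste(sort(unique(as.integer(x$labels))), collapse = ",")))
  invisible(x)
}

#' @export
dim.label_map_sequence <- function(x) dim(x$labels)

label_array <- function(x) {
  if (inherits(x, "label_map_sequence")) x$labels else x
}
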