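# Readers/writers for cine loops and label volumes. Coordinates in all
# outputs are 0-based (row, col) with the row increasing downward.

nifti_spacing <- function(img) {
  pd <- attr(img, "pixdim")
  if (is.null(pd) || length(pd) < 2L || any(pd[1:2] <= 0)) return(NA_real_)
  if (abs(pd[1L] - pd[2L]) > 1e-9) {
    warn("anisotropic pixel spacing; using the first axis")
  }
  pd[1L]
}

#' Read a cine sequence
#'
#' Supported containers: a NIfTI volume (frames along the third axis, pixel
#' spacing from `pixdim` in cm/px) or a directory holding a PNG frame stack
#' (`frame_0001.png`, ...) with a JSON sidecar (`sidecar.json`) carrying
#' `pixel_spacing`. A missing pixel spacing is not an error: the sequence
#' loads with spacing `NA` and downstream indices are reported in px.
#'
#' @param path File (`.nii`/`.nii.gz`) or PNG-stack directory.
#' @return A [cine_sequence].
#' @export
read_cine <- function(path) {
  if (dir.exists(path)) {
    side <- file.path(path, "sidecar.json")
    meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
    files <- sort(list.files(path, pattern = "^frame_\\d+\\.png$",
                             full.names = TRUE))
    if (!length(files)) abort(sprintf("no frame_*.png files in %s", path))
    frames <- simplify2array(lapply(files, png::readPNG))
    return(cine_sequence(frames,
                         pixel_spacing = meta$pixel_spacing %||% NA_real_))
  }
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  cine_sequence(arr, pixel_spacing = nifti_spacing(img))
}

#' Read a label-map sequence
#'
#' Same containers as [read_cine()]. Label values are validated against
#' `{0, 1, 2}` (background, lateral annulus, septal annulus); unknown values
#' raise an error naming the offending labels.
#'
#' @param path File or PNG-stack directory.
#' @return A [label_map_sequence].
#' @export
read_labels <- function(path) {
  if (dir.exists(path)) {
    side <- file.path(path, "sidecar.json")
    meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
    files <- sort(list.files(path, pattern = "^frame_\\d+\\.png$",
                             full.names = TRUE))
    if (!length(files)) abort(sprintf("no frame_*.png files in %s", path))
    arr <- simplify2array(lapply(files, function(f)
      round(png::readPNG(f) * 255)))
    return(label_map_sequence(arr,
                              pixel_spacing = meta$pixel_spacing %||% NA_real_))
  }
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(round(as.numeric(img))), dim = dim(img))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  label_map_sequence(arr, pixel_spacing = nifti_spacing(img))
}

write_nifti_stack <- function(arr, path, spacing) {
  img <- RNifti::asNifti(arr)
  if (!is.na(spacing)) {
    RNifti::pixdim(img) <- c(spacing, spacing, 1)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

write_png_stack <- function(arr, dir, spacing, scale = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_len(dim(arr)[3L])) {
    png::writePNG(arr[, , t] / scale,
                  file.path(dir, sprintf("frame_%04d.png", t)))
  }
  jsonlite::write_json(list(pixel_spacing = spacing,
                            n_frames = dim(arr)[3L]),
                       file.path(dir, "sidecar.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Write a phantom case to disk
#'
#' Writes the cine loop and ground-truth masks plus a JSON sidecar with the
#' pixel spacing, truth trajectories, truth indices, and the dysfunction
#' label. NIfTI format stores cine and masks as multi-frame volumes;
#' PNG format writes per-frame 8-bit images (labels stored as raw values).
#'
#' @param case A `phantom_case`.
#' @param dir Output directory (created if needed).
#' @param format `"nifti"` or `"png"`.
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir, format = c("nifti", "png")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- case$cine$pixel_spacing
  if (format == "nifti") {
    write_nifti_stack(case$cine$frames, file.path(dir, "cine.nii.gz"), sp)
    write_nifti_stack(label_array(case$masks), file.path(dir, "masks.nii.gz"),
                      sp)
  } else {
    write_png_stack(case$cine$frames, file.path(dir, "cine"), sp)
    write_png_stack(label_array(case$masks) * 1, file.path(dir, "masks"), sp,
                    scale = 255)
  }
  jsonlite::write_json(list(
    schema_version = 1L,
    case_id = case$case_id,
    pixel_spacing = sp,
    n_frames = dim(case$cine)[3L],
    coordinate_convention = "0-based (row, col), row increases downward",
    dysfunction = case$dysfunction,
    truth_tracks = case$truth_tracks,
    truth_indices = case$truth_indices
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
  dataframe = "columns")
  invisible(dir)
}

#' Read a phantom case written by [write_case()]
#'
#' @param dir Case directory.
#' @return A list with `cine`, `masks`, and the sidecar metadata (`case_id`,
#'   `dysfunction`, `truth_tracks`, `truth_indices`).
#' @export
read_case <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  cine_path <- if (file.exists(file.path(dir, "cine.nii.gz")))
    file.path(dir, "cine.nii.gz") else file.path(dir, "cine")
  mask_path <- if (file.exists(file.path(dir, "masks.nii.gz")))
    file.path(dir, "masks.nii.gz") else file.path(dir, "masks")
  list(cine = read_cine(cine_path),
       masks = read_labels(mask_path),
       case_id = meta$case_id,
       dysfunction = meta$dysfunction,
       truth_tracks = tibble::as_tibble(meta$truth_tracks),
       truth_indices = tibble::as_tibble(meta$truth_indices))
}

#' Write a report table as CSV and JSON
#'
#' @param x A data frame (e.g. from [evaluate_diagnostics()]) or a tidy-able
#'   report object.
#' @param stem Output path without extension; writes `<stem>.csv` and
#'   `<stem>.json`.
#' @return `stem`, invisibly.
#' @export
write_report <- function(x, stem) {
  df <- if (is.data.frame(x)) x else tidy(x)
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(df, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(stem)
}
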