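#' Phantom configuration
#'
#' Settings for the synthetic echo phantom: a sector-shaped speckle image
#' containing two small bright landmarks (lateral and septal tricuspid
#' annulus) that move sinusoidally along fixed directions with a known peak
#' excursion, plus circular ground-truth masks of uniform radius centred on
#' the landmark positions. The configured amplitude is the ground-truth
#' linear displacement (the analogue of systolic annular excursion), so every
#' downstream stage can be validated against it.
#'
#' @param image_size Square image size in px.
#' @param pixel_spacing Pixel spacing in cm/px.
#' @param n_frames Frames per cine loop.
#' @param lateral_amplitude,septal_amplitude Peak annular excursion in cm.
#' @param lateral_direction,septal_direction Motion direction as a 2-vector
#'   `(row, col)`; normalised internally. Defaults point toward the apex
#'   (upward) with a slight outward/inward tilt.
#' @param period_frames Frames per motion period (default: one full cycle per
#'   loop).
#' @param speckle_snr Mean-to-perturbation ratio of the multiplicative
#'   speckle; larger is cleaner.
#' @param sector_angle Full opening angle of the imaging sector, degrees.
#' @param label_radius Radius in px of the circular ground-truth labels.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 256L, pixel_spacing = 0.05,
                           n_frames = 30L,
                           lateral_amplitude = 1.8, septal_amplitude = 1.0,
                           lateral_direction = c(-0.940, -0.342),
                           septal_direction = c(-0.940, 0.342),
                           period_frames = n_frames, speckle_snr = 5,
                           sector_angle = 90, label_radius = 4L, seed = 1L) {
  if (lateral_amplitude < 0 || septal_amplitude < 0) {
    abort("amplitudes must be nonnegative")
  }
  if (n_frames < 2L) abort("n_frames must be at least 2")
  if (label_radius < 1L) abort("label_radius must be at least 1 px")
  if (pixel_spacing <= 0) abort("pixel_spacing must be positive")
  norm2 <- function(v) v / sqrt(sum(v^2))
  structure(list(
    image_size = as.integer(image_size), pixel_spacing = pixel_spacing,
    n_frames = as.integer(n_frames),
    lateral_amplitude = lateral_amplitude,
    septal_amplitude = septal_amplitude,
    lateral_direction = norm2(lateral_direction),
    septal_direction = norm2(septal_direction),
    period_frames = as.integer(period_frames),
    speckle_snr = speckle_snr, sector_angle = sector_angle,
    label_radius = as.integer(label_radius), seed = as.integer(seed)
  ), class = "phantom_config")
}

# sector geometry: vertex near the top centre, opening downward
sector_params <- function(cfg) {
  s <- cfg$image_size
  list(vertex = c(0.03 * s, 0.5 * s),
       half_angle = cfg$sector_angle / 2 * pi / 180,
       radius = 0.92 * s)
}

sector_mask <- function(cfg) {
  s <- cfg$image_size
  sp <- sector_params(cfg)
  r <- matrix(seq_len(s) - 1, s, s) - sp$vertex[1L]
  c_ <- matrix(seq_len(s) - 1, s, s, byrow = TRUE) - sp$vertex[2L]
  dist <- sqrt(r^2 + c_^2)
  ang <- atan2(abs(c_), r)   # angle from the downward axis
  r >= 0 & dist <= sp$radius & ang <= sp$half_angle
}

# sub-pixel landmark trajectory: base + amplitude * (1 - cos)/2 along dir
phantom_track <- function(cfg, annulus) {
  s <- cfg$image_size
  base <- if (annulus == "lateral") c(0.66, 0.30) else c(0.66, 0.56)
  base <- base * s
  amp_px <- switch(annulus, lateral = cfg$lateral_amplitude,
                   septal = cfg$septal_amplitude) / cfg$pixel_spacing
  dir <- switch(annulus, lateral = cfg$lateral_direction,
                septal = cfg$septal_direction)
  t <- seq_len(cfg$n_frames) - 1L
  disp <- amp_px * (1 - cos(2 * pi * t / cfg$period_frames)) / 2
  cbind(row = base[1L] + disp * dir[1L], col = base[2L] + disp * dir[2L])
}

disk_pixels <- function(center, radius, size) {
  c0 <- round(center)
  rr <- max(1L, floor(c0[1L] - radius)):min(size, ceiling(c0[1L] + radius) + 1L)
  cc <- max(1L, floor(c0[2L] - radius)):min(size, ceiling(c0[2L] + radius) + 1L)
  g <- expand.grid(r = rr, c = cc)
  keep <- (g$r - 1 - c0[1L])^2 + (g$c - 1 - c0[2L])^2 <= radius^2
  g[keep, , drop = FALSE]
}

#' Generate one phantom case
#'
#' Renders a cine loop in which each annulus landmark moves sinusoidally with
#' the configured amplitude over a multiplicative-speckle sector background,
#' along with ground-truth disk masks, sub-pixel truth trajectories, and the
#' ground-truth displacement indices computed from those trajectories.
#'
#' @param config A [phantom_config()].
#' @param dysfunction Logical reference label attached to the case.
#' @param case_id Identifier stored with the case.
#' @return A list of class `phantom_case` with elements `cine`
#'   ([cine_sequence]), `masks` ([label_map_sequence]), `truth_tracks`
#'   (tibble: frame, annulus, row, col), `truth_indices` (tibble: annulus,
#'   ltad, ctad in cm), `dysfunction`, `case_id`, and `config`.
#' @export
generate_case <- function(config = phantom_config(), dysfunction = FALSE,
                          case_id = "case01") {
  stopifnot(inherits(config, "phantom_config"))
  s <- config$image_size
  set.seed(config$seed)
  sec <- sector_mask(config)
  sp <- sector_params(config)

  tracks <- list(lateral = phantom_track(config, "lateral"),
                 septal = phantom_track(config, "septal"))
  # sizing check: every label disk must stay inside the sector
  for (annulus in names(tracks)) {
    tr <- tracks[[annulus]]
    pad <- config$label_radius + 1
    inside <- tr[, 1L] > pad & tr[, 1L] < s - 1 - pad &
      tr[, 2L] > pad & tr[, 2L] < s - 1 - pad
    if (!all(inside)) {
      abort(sprintf(
        "%s amplitude %.2f cm (%.0f px) moves the landmark outside the image",
        annulus,
        switch(annulus, lateral = config$lateral_amplitude,
               septal = config$septal_amplitude),
        switch(annulus, lateral = config$lateral_amplitude,
               septal = config$septal_amplitude) / config$pixel_spacing))
    }
    for (t in seq_len(config$n_frames)) {
      dp <- disk_pixels(tr[t, ], config$label_radius, s)
      if (!all(sec[cbind(dp$r, dp$c)])) {
        abort(sprintf("%s label disk leaves the imaging sector at frame %d",
                      annulus, t))
      }
    }
  }

  # static background: radial intensity falloff from the transducer
  r <- matrix(seq_len(s) - 1, s, s) - sp$vertex[1L]
  c_ <- matrix(seq_len(s) - 1, s, s, byrow = TRUE) - sp$vertex[2L]
  depth <- sqrt(r^2 + c_^2)
  background <- 0.45 * exp(-depth / (1.1 * sp$radius))

  rayleigh_sigma <- sqrt(2 / pi)   # unit-mean Rayleigh
  frames <- array(0, c(s, s, config$n_frames))
  masks <- array(0L, c(s, s, config$n_frames))
  blob_sigma <- 0.8 * config$label_radius
  for (t in seq_len(config$n_frames)) {
    speckle <- matrix(rayleigh_sigma * sqrt(-2 * log(runif(s * s))), s, s)
    img <- background * (1 + (speckle - 1) / config$speckle_snr)
    for (annulus in names(tracks)) {
      p <- tracks[[annulus]][t, ]
      win <- 4 * config$label_radius
      rr <- max(1L, floor(p[1L] - win)):min(s, ceiling(p[1L] + win) + 1L)
      cc <- max(1L, floor(p[2L] - win)):min(s, ceiling(p[2L] + win) + 1L)
      dr <- (rr - 1) - p[1L]
      dc <- (cc - 1) - p[2L]
      blob <- 0.55 * exp(-(outer(dr^2, dc^2, "+")) / (2 * blob_sigma^2))
      img[rr, cc] <- img[rr, cc] + blob
      dp <- disk_pixels(p, config$label_radius, s)
      masks[cbind(dp$r, dp$c, t)] <- annulus_classes[[annulus]]
    }
    img[!sec] <- 0
    img[img > 1] <- 1
    img[img < 0] <- 0
    frames[, , t] <- img
  }

  truth_tracks <- dplyr::bind_rows(lapply(names(tracks), function(a) {
    tibble(frame = seq_len(config$n_frames), annulus = a,
           row = tracks[[a]][, 1L], col = tracks[[a]][, 2L])
  }))
  truth_indices <- dplyr::bind_rows(lapply(names(tracks), function(a) {
    xy <- tracks[[a]]
    tibble(annulus = a,
           ltad = max_pairwise_distance(xy) * config$pixel_spacing,
           ctad = path_length(xy) * config$pixel_spacing)
  }))

  structure(list(
    cine = cine_sequence(frames, pixel_spacing = config$pixel_spacing),
    masks = label_map_sequence(masks, pixel_spacing = config$pixel_spacing),
    truth_tracks = truth_tracks,
    truth_indices = truth_indices,
    dysfunction = isTRUE(dysfunction),
    case_id = case_id,
    config = config
  ), class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s: %d frames, lateral LTAD %.2f cm, dysfunction %s\n",
              x$case_id, x$config$n_frames,
              x$truth_indices$ltad[x$truth_indices$annulus == "lateral"],
              x$dysfunction))
  invisible(x)
}

#' Generate a phantom cohort with a known dysfunction prevalence
#'
#' Draws `floor(n_cases * dysfunction_fraction)` dysfunctional cases (assigned
#' deterministically to the lowest case indices) with lateral amplitudes from
#' `dysfunction_range` and the remainder from `normal_range`; septal amplitude
#' is a fixed fraction (0.55) of lateral, mirroring the roughly halved septal
#' excursion seen clinically. Overlapping ranges are permitted (classification
#' is then imperfect by design) and flagged with a warning.
#'
#' @param n_cases Number of cases.
#' @param dysfunction_fraction Proportion of dysfunctional cases in `[0, 1]`.
#' @param config Base [phantom_config()]; amplitudes and seed are overridden
#'   per case.
#' @param normal_range,dysfunction_range Lateral-amplitude ranges in cm for
#'   normal and dysfunctional cases.
#' @param seed Integer seed for the amplitude draws and per-case seeds.
#' @return A list of class `phantom_cohort`: `cases` (list of
#'   [generate_case()] results) and `truth` (tibble: case_id, dysfunction,
#'   amplitude, truth ltad/ctad per annulus).
#' @export
generate_cohort <- function(n_cases, dysfunction_fraction = 0.3,
                            config = phantom_config(),
                            normal_range = c(1.6, 2.4),
                            dysfunction_range = c(0.8, 1.4),
                            seed = 1L) {
  if (dysfunction_fraction < 0 || dysfunction_fraction > 1) {
    abort("dysfunction_fraction must be in [0, 1]")
  }
  if (max(dysfunction_range) > min(normal_range)) {
    warn("dysfunction and normal amplitude ranges overlap; downstream classification will be imperfect by design")
  }
  n_dys <- floor(n_cases * dysfunction_fraction)
  dys <- seq_len(n_cases) <= n_dys
  set.seed(seed)
  amp <- ifelse(dys,
                runif(n_cases, dysfunction_range[1L], dysfunction_range[2L]),
                runif(n_cases, normal_range[1L], normal_range[2L]))
  cases <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    cfg <- config
    cfg$lateral_amplitude <- amp[i]
    cfg$septal_amplitude <- 0.55 * amp[i]
    cfg$seed <- (seed * 1000L + i) %% .Machine$integer.max
    cases[[i]] <- generate_case(cfg, dysfunction = dys[i],
                                case_id = sprintf("case%02d", i))
  }
  truth <- dplyr::bind_rows(lapply(cases, function(cs) {
    ti <- cs$truth_indices
    tibble(case_id = cs$case_id, dysfunction = cs$dysfunction,
           lateral_amplitude = cs$config$lateral_amplitude,
           truth_ltad_lateral = ti$ltad[ti$annulus == "lateral"],
           truth_ctad_lateral = ti$ctad[ti$annulus == "lateral"],
           truth_ltad_septal = ti$ltad[ti$annulus == "septal"],
           truth_ctad_septal = ti$ctad[ti$annulus == "septal"])
  }))
  structure(list(cases = cases, truth = truth), class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d cases, %d dysfunctional\n",
              length(x$cases), sum(x$truth$dysfunction)))
  invisible(x)
}
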