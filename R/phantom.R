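# Synthetic pelvic phantom generator.
#
# Each case consists of a CT volume (HU), ten binary structure masks and a
# VMAT-like dose grid: prescription dose inside a spherical PTV, exponential
# falloff with distance to the PTV surface inside an elliptical body, a
# low-dose bath towards the body contour, and exactly zero outside the body.
# Volumes are stored as (rows, cols, slices) arrays; voxel centers sit at
# origin + index * spacing (0-based indices), spacing given as (z, y, x) mm.

#' Canonical structure channel order
#'
#' The fixed ten-name ordering used for the mask channels of the
#' superimposed feature maps: PTV first, then the organs at risk, body last.
#'
#' @return Character vector of ten structure names.
#' @export
prt_channel_order <- function() {
  c("PTV", "bladder", "femoral_head_left", "femoral_head_right",
    "kidney_left", "kidney_right", "marrow", "rectum", "spinal_cord", "body")
}

default_oar_specs <- function() {
  # (z, y, x) center offsets in mm from the body center, and radii in mm
  list(
    bladder            = list(offset = c(0, -38, 0),   radius = 15),
    femoral_head_left  = list(offset = c(0, 5, -52),   radius = 12),
    femoral_head_right = list(offset = c(0, 5, 52),    radius = 12),
    kidney_left        = list(offset = c(0, -12, -35), radius = 9),
    kidney_right       = list(offset = c(0, -12, 35),  radius = 9),
    marrow             = list(offset = c(0, 20, 28),   radius = 9),
    rectum             = list(offset = c(0, 38, 0),    radius = 12),
    spinal_cord        = list(offset = c(0, 55, 0),    radius = 6)
  )
}

#' Phantom configuration
#'
#' Parameters of one synthetic pelvic case. Defaults follow the clinical
#' conditions the generator emulates: 45 Gy prescription in 25 fractions and
#' a 2.5 x 2.5 x 5.0 mm voxel grid.
#'
#' @param grid_shape Integer (slices, rows, cols); at least (3, 32, 32).
#' @param spacing_mm Numeric (z, y, x) voxel spacing in mm.
#' @param prescription_Gy Prescription dose in Gy.
#' @param body_axes_mm In-plane ellipse semi-axes (y, x) of the body in mm.
#' @param ptv_radius_mm Radius of the spherical PTV in mm.
#' @param oar_specs Named list of organ specs, each `list(offset, radius)` in
#'   mm; see `default_oar_specs` for the eight defaults.
#' @param falloff_mm Exponential dose falloff scale: dose(d) =
#'   prescription * exp(-d / falloff_mm) at distance d from the PTV surface.
#' @param noise_sd_Gy Standard deviation of additive Gaussian dose noise
#'   inside the body (0 disables noise).
#' @param seed Integer seed making the case reproducible.
#' @param cohort_jitter Relative/absolute randomisation bounds used by
#'   [generate_cohort()]: body and falloff are scaled by U(1 +/- body/falloff),
#'   the PTV radius by U(1 +/- ptv), and OAR centers shifted by
#'   U(-oar_shift_mm, oar_shift_mm) in-plane.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(3L, 64L, 64L),
                           spacing_mm = c(5.0, 2.5, 2.5),
                           prescription_Gy = 45,
                           body_axes_mm = c(70, 75),
                           ptv_radius_mm = 25,
                           oar_specs = default_oar_specs(),
                           falloff_mm = 20,
                           noise_sd_Gy = 1,
                           seed = 1L,
                           cohort_jitter = list(body = 0.1, ptv = 0.2,
                                                falloff = 0.1, oar_shift_mm = 5)) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= c(3L, 32L, 32L)),
            all(spacing_mm > 0), prescription_Gy > 0, ptv_radius_mm > 0,
            falloff_mm > 0, noise_sd_Gy >= 0, all(body_axes_mm > 0))
  structure(list(grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
                 prescription_Gy = prescription_Gy, body_axes_mm = body_axes_mm,
                 ptv_radius_mm = ptv_radius_mm, oar_specs = oar_specs,
                 falloff_mm = falloff_mm, noise_sd_Gy = noise_sd_Gy,
                 seed = as.integer(seed), cohort_jitter = cohort_jitter),
            class = "phantom_config")
}

# voxel-center coordinate vectors (mm) along y (rows), x (cols), z (slices)
grid_coords <- function(config) {
  S <- config$grid_shape[1]; H <- config$grid_shape[2]; W <- config$grid_shape[3]
  sz <- config$spacing_mm[1]; sy <- config$spacing_mm[2]; sx <- config$spacing_mm[3]
  list(y = (seq_len(H) - 1) * sy, x = (seq_len(W) - 1) * sx,
       z = (seq_len(S) - 1) * sz)
}

sphere_mask <- function(co, center, radius) {
  H <- length(co$y); W <- length(co$x); S <- length(co$z)
  dy2 <- (co$y - center[2])^2
  dx2 <- (co$x - center[3])^2
  dz2 <- (co$z - center[1])^2
  arr <- outer(outer(dy2, dx2, "+"), dz2, "+")
  array(arr <= radius^2, dim = c(H, W, S)) * 1L
}

#' Generate one synthetic case
#'
#' @param config A [phantom_config()].
#' @return A `phantom_case` list with elements `ct` (a `ct_volume`),
#'   `structures` (a `structure_set`), `dose` (a `dose_grid`) and the echoed
#'   `config`.
#' @export
generate_case <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$ptv_radius_mm >= min(config$body_axes_mm)) {
    stop("degenerate geometry: PTV radius must be smaller than the body semi-axes")
  }
  set.seed(config$seed)
  S <- config$grid_shape[1]; H <- config$grid_shape[2]; W <- config$grid_shape[3]
  co <- grid_coords(config)
  center <- c(mean(range(co$z)), mean(range(co$y)), mean(range(co$x)))

  # elliptical cylindrical body
  ell <- outer((co$y - center[2])^2 / config$body_axes_mm[1]^2,
               (co$x - center[3])^2 / config$body_axes_mm[2]^2, "+")
  body <- array(rep(ell <= 1, S), dim = c(H, W, S)) * 1L

  masks <- list(PTV = sphere_mask(co, center, config$ptv_radius_mm) * body)
  for (nm in setdiff(prt_channel_order(), c("PTV", "body"))) {
    sp <- config$oar_specs[[nm]]
    if (is.null(sp)) stop("missing OAR definition for structure: ", nm)
    masks[[nm]] <- sphere_mask(co, center + sp$offset, sp$radius) * body
  }
  masks$body <- body
  masks <- masks[prt_channel_order()]

  # CT: air outside body, soft tissue inside, bone in the femoral heads
  ct <- array(-1000, dim = c(H, W, S))
  inside <- body == 1L
  ct[inside] <- stats::rnorm(sum(inside), 0, 30)
  bone <- (masks$femoral_head_left | masks$femoral_head_right) & inside
  ct[bone] <- stats::rnorm(sum(bone), 300, 30)

  # dose: exponential falloff of distance to the PTV sphere surface
  dy2 <- (co$y - center[2])^2
  dx2 <- (co$x - center[3])^2
  dz2 <- (co$z - center[1])^2
  r <- sqrt(outer(outer(dy2, dx2, "+"), dz2, "+"))
  d <- pmax(r - config$ptv_radius_mm, 0)
  dose <- config$prescription_Gy * exp(-d / config$falloff_mm)
  if (config$noise_sd_Gy > 0) {
    dose <- dose + array(stats::rnorm(length(dose), 0, config$noise_sd_Gy), dim(dose))
  }
  dose <- pmax(dose, 0) * body

  list_case <- list(
    ct = ct_volume(ct, spacing_mm = config$spacing_mm),
    structures = structure_set(masks),
    dose = dose_grid(dose, spacing_mm = config$spacing_mm),
    config = config
  )
  class(list_case) <- "phantom_case"
  list_case
}

#' Generate a cohort of randomised cases
#'
#' Geometry parameters (body axes, PTV radius, falloff scale, OAR centers)
#' are drawn within the bounds of `base_config$cohort_jitter`; each case
#' receives its own derived seed, so the cohort is reproducible from `seed`.
#'
#' @param n Number of cases (>= 1).
#' @param base_config A [phantom_config()] providing the central geometry.
#' @param seed Integer master seed.
#' @return List of `phantom_case` objects.
#' @export
generate_cohort <- function(n, base_config = phantom_config(), seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  jit <- base_config$cohort_jitter
  lapply(seq_len(n), function(i) {
    cfg <- base_config
    cfg$body_axes_mm <- cfg$body_axes_mm * stats::runif(2, 1 - jit$body, 1 + jit$body)
    cfg$ptv_radius_mm <- cfg$ptv_radius_mm * stats::runif(1, 1 - jit$ptv, 1 + jit$ptv)
    cfg$falloff_mm <- cfg$falloff_mm * stats::runif(1, 1 - jit$falloff, 1 + jit$falloff)
    cfg$oar_specs <- lapply(cfg$oar_specs, function(sp) {
      sp$offset <- sp$offset + c(0, stats::runif(2, -jit$oar_shift_mm, jit$oar_shift_mm))
      sp
    })
    cfg$seed <- sample.int(2^31 - 1, 1)
    generate_case(cfg)
  })
}
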