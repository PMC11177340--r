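# Preprocessing: HU windowing, dose resampling, zero padding, and assembly
# of the 33-channel triplet inputs (three consecutive slices, each as an
# 11-channel superimposed map of windowed CT plus ten structure masks).

#' Window CT values to the soft-tissue range
#'
#' Clips HU values to [-1000, +400] and rescales them linearly to [0, 1].
#' A volume that has already been windowed is returned unchanged (the
#' operation is idempotent; the `windowed` flag records application).
#'
#' @param ct A [ct_volume()].
#' @return A `ct_volume` with values in [0, 1] and `windowed = TRUE`.
#' @export
window_hu <- function(ct) {
  stopifnot(inherits(ct, "ct_volume"))
  if (isTRUE(ct$windowed)) return(ct)
  v <- pmin(pmax(ct$values, -1000), 400)
  v <- (v + 1000) / 1400
  out <- ct_volume(v, spacing_mm = ct$spacing_mm, origin_mm = ct$origin_mm)
  out$windowed <- TRUE
  out
}

# trilinear sampling of `values` (3D array, rows/cols/slices) at fractional
# 0-based indices (fy, fx, fz), edge-clamped; all index vectors same length
trilinear_sample <- function(values, fy, fx, fz) {
  d <- dim(values)
  cl <- function(f, n) pmin(pmax(f, 0), n - 1)
  fy <- cl(fy, d[1]); fx <- cl(fx, d[2]); fz <- cl(fz, d[3])
  y0 <- floor(fy); x0 <- floor(fx); z0 <- floor(fz)
  y1 <- pmin(y0 + 1, d[1] - 1); x1 <- pmin(x0 + 1, d[2] - 1); z1 <- pmin(z0 + 1, d[3] - 1)
  wy <- fy - y0; wx <- fx - x0; wz <- fz - z0
  g <- function(iy, ix, iz) values[cbind(iy + 1, ix + 1, iz + 1)]
  (1 - wz) * ((1 - wy) * ((1 - wx) * g(y0, x0, z0) + wx * g(y0, x1, z0)) +
              wy * ((1 - wx) * g(y1, x0, z0) + wx * g(y1, x1, z0))) +
  wz * ((1 - wy) * ((1 - wx) * g(y0, x0, z1) + wx * g(y0, x1, z1)) +
        wy * ((1 - wx) * g(y1, x0, z1) + wx * g(y1, x1, z1)))
}

#' Resample a dose grid by trilinear interpolation
#'
#' Interpolates the dose onto a lattice with the requested spacing covering
#' the same physical extent; voxel centers sit at index * spacing from the
#' shared origin.
#'
#' @param dose A [dose_grid()].
#' @param target_spacing Numeric (z, y, x) spacing in mm, strictly positive.
#' @return A `dose_grid` with the target spacing.
#' @export
resample_dose <- function(dose, target_spacing = c(5.0, 2.5, 2.5)) {
  stopifnot(inherits(dose, "dose_grid"))
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  d <- dim(dose$values)
  src <- dose$spacing_mm   # (z, y, x)
  ext <- (c(d[3], d[1], d[2]) - 1) * src            # physical extent (z, y, x)
  nd <- pmax(floor(ext / target_spacing + 1e-9) + 1, 1)  # (z, y, x) counts
  fy <- (seq_len(nd[2]) - 1) * target_spacing[2] / src[2]
  fx <- (seq_len(nd[3]) - 1) * target_spacing[3] / src[3]
  fz <- (seq_len(nd[1]) - 1) * target_spacing[1] / src[1]
  H <- nd[2]; W <- nd[3]; S <- nd[1]
  FY <- rep(fy, times = W * S)
  FX <- rep(rep(fx, each = H), times = S)
  FZ <- rep(fz, each = H * W)
  out <- array(trilinear_sample(dose$values, FY, FX, FZ), dim = c(H, W, S))
  dose_grid(pmax(out, 0), spacing_mm = target_spacing)
}

#' Pad a 2D plane into a centred square grid of zeros
#'
#' @param plane 2D numeric matrix, no larger than `size` in either axis.
#' @param size Target side length (default 512).
#' @return `size` x `size` matrix with `plane` centred.
#' @export
pad_to_grid <- function(plane, size = 512L) {
  h <- nrow(plane); w <- ncol(plane)
  if (h > size || w > size) stop("plane larger than the target grid")
  if (h == size && w == size) return(plane)
  out <- matrix(0, size, size)
  oy <- (size - h) %/% 2L
  ox <- (size - w) %/% 2L
  out[oy + seq_len(h), ox + seq_len(w)] <- plane
  out
}

# inverse of pad_to_grid for a centred plane
unpad_from_grid <- function(plane, h, w) {
  oy <- (nrow(plane) - h) %/% 2L
  ox <- (ncol(plane) - w) %/% 2L
  plane[oy + seq_len(h), ox + seq_len(w), drop = FALSE]
}

#' Build the 11-channel superimposed map for one slice
#'
#' Channel 1 is the windowed CT slice; channels 2-11 are the binary masks in
#' the fixed [prt_channel_order()].
#'
#' @param ct A [ct_volume()] (windowed automatically if not yet).
#' @param structures A [structure_set()].
#' @param k Slice index (1-based).
#' @return Array of shape (11, H, W).
#' @export
build_superimposed_map <- function(ct, structures, k) {
  stopifnot(inherits(ct, "ct_volume"), inherits(structures, "structure_set"))
  ct <- window_hu(ct)
  d <- dim(ct$values)
  if (k < 1L || k > d[3]) stop("slice index out of range")
  out <- array(0, dim = c(11L, d[1], d[2]))
  out[1L, , ] <- ct$values[, , k]
  for (i in seq_along(structures$channel_order)) {
    out[i + 1L, , ] <- structures$masks[[structures$channel_order[i]]][, , k]
  }
  out
}

#' Build per-slice triplet samples for a case
#'
#' One sample per slice k concatenates the 11-channel maps of slices k-1, k
#' and k+1 (boundary slices replicated) into a 33-channel input; the target
#' is the dose of the center slice, optionally normalised by the
#' prescription so training operates on order-one values.
#'
#' @param case A `phantom_case` (or any list with `ct`, `structures`,
#'   `dose`, `config$prescription_Gy`).
#' @param pad_size Optional square grid side; every channel, target and mask
#'   is zero-pad centred to this size (e.g. 512 at clinical scale).
#' @param normalize_dose Divide the target by the prescription (recorded in
#'   the samples' `dose_scale` attribute). Default TRUE.
#' @return List of `triplet_sample` objects, each with `input` (33, H, W),
#'   `target` (H, W), `body_mask`, `ptv_mask`, `slice`, and `dose_scale`.
#' @export
build_triplets <- function(case, pad_size = NULL, normalize_dose = TRUE) {
  d <- dim(case$ct$values)
  S <- d[3]
  stopifnot(S >= 1L)
  rx <- case$config$prescription_Gy %||% 1
  scale <- if (normalize_dose) rx else 1
  ct <- window_hu(case$ct)
  maps <- lapply(seq_len(S), function(k) build_superimposed_map(ct, case$structures, k))
  padc <- function(m) if (is.null(pad_size)) m else pad_to_grid(m, pad_size)
  lapply(seq_len(S), function(k) {
    ks <- c(max(k - 1L, 1L), k, min(k + 1L, S))
    Hp <- if (is.null(pad_size)) d[1] else pad_size
    Wp <- if (is.null(pad_size)) d[2] else pad_size
    input <- array(0, dim = c(33L, Hp, Wp))
    for (t in 1:3) for (c in 1:11) {
      input[(t - 1L) * 11L + c, , ] <- padc(maps[[ks[t]]][c, , ])
    }
    structure(list(
      input = input,
      target = padc(case$dose$values[, , k]) / scale,
      body_mask = padc(case$structures$masks$body[, , k]),
      ptv_mask = padc(case$structures$masks$PTV[, , k]),
      slice = k,
      orig_shape = d[1:2],
      dose_scale = scale
    ), class = "triplet_sample")
  })
}
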