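# Lightweight S3 containers for volumetric data.

#' CT volume
#'
#' @param values 3D numeric array (rows, cols, slices) of HU values (or of
#'   normalised intensities after windowing).
#' @param spacing_mm Numeric (z, y, x) voxel spacing, strictly positive.
#' @param origin_mm Numeric (z, y, x) position of voxel (0,0,0)'s center.
#' @return A `ct_volume`.
#' @export
ct_volume <- function(values, spacing_mm = c(5.0, 2.5, 2.5),
                      origin_mm = c(0, 0, 0)) {
  stopifnot(length(dim(values)) == 3L, all(spacing_mm > 0), all(dim(values) >= 1L))
  structure(list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm,
                 windowed = isTRUE(attr(values, "windowed"))),
            class = "ct_volume")
}

#' Structure set
#'
#' Ordered collection of binary masks on the CT lattice. The channel order
#' is fixed to [prt_channel_order()].
#'
#' @param masks Named list of 3D binary arrays, one per structure; must
#'   contain every name in [prt_channel_order()] and all shapes must agree.
#' @return A `structure_set`.
#' @export
structure_set <- function(masks) {
  ord <- prt_channel_order()
  missing <- setdiff(ord, names(masks))
  if (length(missing)) stop("missing structure(s): ", paste(missing, collapse = ", "))
  masks <- masks[ord]
  d <- dim(masks[[1]])
  for (nm in ord) {
    stopifnot(identical(dim(masks[[nm]]), d))
    if (!all(masks[[nm]] %in% c(0, 1))) stop("mask not binary: ", nm)
  }
  structure(list(masks = masks, channel_order = ord), class = "structure_set")
}

#' Dose grid
#'
#' @param values 3D numeric array (rows, cols, slices) of dose in Gy;
#'   finite and nonnegative.
#' @param spacing_mm Numeric (z, y, x) voxel spacing.
#' @return A `dose_grid`.
#' @export
dose_grid <- function(values, spacing_mm = c(5.0, 2.5, 2.5)) {
  stopifnot(length(dim(values)) == 3L, all(is.finite(values)), all(values >= 0),
            all(spacing_mm > 0))
  structure(list(values = values, spacing_mm = spacing_mm), class = "dose_grid")
}
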