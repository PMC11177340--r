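# Isodose-volume overlap and surface-distance metrics.

mask_coords_mm <- function(mask, sp_axes) {
  w <- which(mask, arr.ind = TRUE)
  sweep((w - 1), 2L, sp_axes, "*")
}

# face-connected surface voxels of a binary array (voxels beyond the grid
# count as background, so volume-edge voxels are surface)
surface_mask <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  interior <- array(TRUE, d)
  for (ax in seq_len(nd)) {
    for (s in c(-1L, 1L)) {
      sh <- integer(nd); sh[ax] <- s
      nb <- shift_int(mask * 1, sh)
      nb[is.na(nb)] <- 0
      interior <- interior & (nb > 0)
    }
  }
  mask & !interior
}

# directed nearest-surface distances from each point of A to the set B (mm)
directed_distances <- function(A, B, chunk = 512L) {
  nA <- nrow(A)
  out <- numeric(nA)
  for (i0 in seq(1L, nA, by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, nA)
    d2 <- outer(rowSums(A[ii, , drop = FALSE]^2), rowSums(B^2), "+") -
      2 * A[ii, , drop = FALSE] %*% t(B)
    out[ii] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

#' Isodose overlap report
#'
#' Thresholds both dose distributions at `level_Gy` (voxels with dose >=
#' level are members) and reports the Dice similarity coefficient
#' `DSC = 2|A & B| / (|A| + |B|)`, the Jaccard coefficient, and the
#' symmetric Hausdorff distance and its 95th percentile (HD95) over the
#' pooled directed surface-to-surface voxel-center distances in mm.
#'
#' @param pred,truth Dose arrays (2D or 3D) or [dose_grid()]s on one grid.
#' @param level_Gy Isodose level in Gy.
#' @param spacing_mm Voxel spacing, (y, x) for 2D or (z, y, x) for 3D.
#' @return An `isodose_report` list with `level_Gy`, `dsc`, `jaccard`,
#'   `hausdorff_mm`, `hd95_mm`, and `distances_defined` (FALSE when either
#'   isodose volume is empty, in which case the distances are NA).
#' @export
isodose_overlap <- function(pred, truth, level_Gy, spacing_mm = c(2.5, 2.5)) {
  if (inherits(pred, "dose_grid")) {
    spacing_mm <- pred$spacing_mm
    pred <- pred$values
  }
  if (inherits(truth, "dose_grid")) truth <- truth$values
  stopifnot(identical(dim(pred), dim(truth)))
  nd <- length(dim(pred))
  sp_axes <- if (nd == 2L) spacing_mm else c(spacing_mm[2], spacing_mm[3], spacing_mm[1])
  A <- truth >= level_Gy
  B <- pred >= level_Gy
  nA <- sum(A); nB <- sum(B); nI <- sum(A & B)
  dsc <- if (nA + nB == 0L) NA_real_ else 2 * nI / (nA + nB)
  jac <- if (nA + nB == 0L) NA_real_ else nI / (nA + nB - nI)
  defined <- nA > 0L && nB > 0L
  hd <- hd95 <- NA_real_
  if (defined) {
    sa <- mask_coords_mm(surface_mask(A), sp_axes)
    sb <- mask_coords_mm(surface_mask(B), sp_axes)
    dab <- directed_distances(sa, sb)
    dba <- directed_distances(sb, sa)
    pooled <- c(dab, dba)
    hd <- max(pooled)
    hd95 <- as.numeric(stats::quantile(pooled, 0.95, type = 7))
  }
  structure(list(level_Gy = level_Gy, dsc = dsc, jaccard = jac,
                 hausdorff_mm = hd, hd95_mm = hd95,
                 distances_defined = defined),
            class = "isodose_report")
}
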