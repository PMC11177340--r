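# Gamma-index dose comparison (dose-difference / distance-to-agreement).
#
# For each evaluated truth voxel r,
#   gamma(r) = min over positions r' within the search radius of
#              sqrt( ||r - r'||^2 / dta^2  +  (D_pred(r') - D_truth(r))^2 / dD^2 )
# with dD = dose_tolerance_pct% of max(truth) (global normalisation).
# The search shifts the prediction by every sub-voxel offset on a regular
# step grid (linear interpolation, edge positions excluded) and keeps the
# per-voxel minimum; offsets are visited by increasing distance so the scan
# stops once the pure distance term exceeds the worst current gamma.

#' Gamma evaluation parameters
#'
#' @param dose_tolerance_pct Dose-difference criterion as % of the maximum
#'   truth dose (default 3).
#' @param dta_mm Distance-to-agreement criterion in mm (default 2).
#' @param low_dose_threshold_pct_of_max Truth voxels below this % of the
#'   maximum truth dose are excluded (default 10).
#' @param search_radius_mm Radius of the spatial search (default 3 * dta).
#' @param interp_step_mm Step of the interpolated search grid (default
#'   dta / 10).
#' @return A `gamma_params` list.
#' @export
gamma_params <- function(dose_tolerance_pct = 3, dta_mm = 2,
                         low_dose_threshold_pct_of_max = 10,
                         search_radius_mm = 3 * dta_mm,
                         interp_step_mm = dta_mm / 10) {
  stopifnot(dose_tolerance_pct > 0, dta_mm > 0, search_radius_mm >= dta_mm,
            interp_step_mm > 0, low_dose_threshold_pct_of_max >= 0)
  structure(list(dose_tolerance_pct = dose_tolerance_pct, dta_mm = dta_mm,
                 low_dose_threshold_pct_of_max = low_dose_threshold_pct_of_max,
                 normalization = "global",
                 search_radius_mm = search_radius_mm,
                 interp_step_mm = interp_step_mm),
            class = "gamma_params")
}

# integer-voxel shift of a 2D/3D array with NA fill outside the grid
shift_int <- function(a, sh) {
  d <- dim(a)
  out <- array(NA_real_, d)
  idx_src <- vector("list", length(d))
  idx_dst <- vector("list", length(d))
  for (ax in seq_along(d)) {
    s <- sh[ax]
    src <- seq_len(d[ax]) + s
    ok <- src >= 1L & src <= d[ax]
    idx_src[[ax]] <- src[ok]
    idx_dst[[ax]] <- seq_len(d[ax])[ok]
    if (!any(ok)) return(out)
  }
  if (length(d) == 2L) {
    out[idx_dst[[1]], idx_dst[[2]]] <- a[idx_src[[1]], idx_src[[2]]]
  } else {
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  }
  out
}

# prediction sampled at r + offset for every voxel r: separable linear
# interpolation from integer-shifted copies; NA where r + offset leaves the grid
shift_frac <- function(a, frac) {
  d <- dim(a)
  lo <- floor(frac)
  w <- frac - lo
  out <- NULL
  corners <- expand.grid(rep(list(0:1), length(d)))
  for (r in seq_len(nrow(corners))) {
    cc <- as.integer(corners[r, ])
    wt <- prod(ifelse(cc == 1, w, 1 - w))
    if (wt == 0) next
    term <- wt * shift_int(a, lo + cc)
    out <- if (is.null(out)) term else out + term
  }
  out
}

#' Gamma index map and pass rate
#'
#' @param pred,truth Dose arrays (2D slice or 3D volume) on the same grid,
#'   or [dose_grid()]s.
#' @param params A [gamma_params()].
#' @param body_mask Optional binary mask; voxels outside are excluded.
#' @param spacing_mm Voxel spacing: (y, x) for 2D, (z, y, x) for 3D
#'   (taken from the `dose_grid` if one is supplied).
#' @param z_integer_offsets For 3D grids, restrict the search along z to
#'   whole-slice offsets (default TRUE; in-plane search remains sub-voxel).
#' @return List with `gamma` (array, NA at non-evaluated voxels),
#'   `pass_rate_pct`, and `n_evaluated`.
#' @export
gamma_index <- function(pred, truth, params = gamma_params(), body_mask = NULL,
                        spacing_mm = c(2.5, 2.5), z_integer_offsets = TRUE) {
  if (inherits(pred, "dose_grid")) {
    spacing_mm <- pred$spacing_mm
    pred <- pred$values
  }
  if (inherits(truth, "dose_grid")) truth <- truth$values
  stopifnot(identical(dim(pred), dim(truth)))
  nd <- length(dim(pred))
  stopifnot(nd %in% c(2L, 3L), length(spacing_mm) == nd)
  # spacing per array axis: 2D arrays are (y, x); 3D arrays (y, x, z) with
  # spacing supplied as (z, y, x)
  sp_axes <- if (nd == 2L) spacing_mm else c(spacing_mm[2], spacing_mm[3], spacing_mm[1])

  dmax <- max(truth)
  dd <- params$dose_tolerance_pct / 100 * dmax
  eval_mask <- truth >= params$low_dose_threshold_pct_of_max / 100 * dmax
  if (!is.null(body_mask)) eval_mask <- eval_mask & (body_mask > 0)
  n_eval <- sum(eval_mask)
  if (n_eval == 0L) stop("no voxels to evaluate (all below threshold or outside body)")

  ax_offsets <- lapply(seq_len(nd), function(ax) {
    if (nd == 3L && ax == 3L && z_integer_offsets) {
      k <- floor(params$search_radius_mm / sp_axes[3])
      (-k:k) * sp_axes[3]
    } else {
      k <- floor(params$search_radius_mm / params$interp_step_mm)
      (-k:k) * params$interp_step_mm
    }
  })
  grid <- do.call(expand.grid, ax_offsets)
  dist2 <- rowSums(grid^2)
  keep <- dist2 <= params$search_radius_mm^2
  grid <- grid[keep, , drop = FALSE]
  dist2 <- dist2[keep]
  o <- order(dist2)
  grid <- grid[o, , drop = FALSE]
  dist2 <- dist2[o]

  dta2 <- params$dta_mm^2
  g2 <- array(Inf, dim(pred))
  tmask <- truth
  for (k in seq_len(nrow(grid))) {
    dterm <- dist2[k] / dta2
    if (dterm >= max(g2[eval_mask])) break
    frac <- as.numeric(grid[k, ]) / sp_axes
    shifted <- if (all(frac == round(frac))) {
      shift_int(pred, as.integer(round(frac)))
    } else {
      shift_frac(pred, frac)
    }
    cand <- dterm + (shifted - tmask)^2 / dd^2
    upd <- !is.na(cand) & cand < g2
    g2[upd] <- cand[upd]
  }
  gmap <- sqrt(g2)
  gmap[!eval_mask] <- NA_real_
  pass <- 100 * sum(gmap[eval_mask] <= 1 + 1e-12) / n_eval
  list(gamma = gmap, pass_rate_pct = pass, n_evaluated = n_eval)
}
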