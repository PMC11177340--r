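# Dosimetric evaluation: body-masked error metrics, DVH statistics,
# plan-criteria checks and low-dose-band voxel counts.

#' Body-masked error metrics
#'
#' MAE, MSE and RMSE over the voxels inside the mask only; voxels outside
#' the body contour never contribute.
#'
#' @param pred,truth Numeric arrays of equal shape (Gy).
#' @param body_mask Binary array of the same shape; must be nonempty.
#' @return List with `mae`, `mse`, `rmse`.
#' @export
masked_errors <- function(pred, truth, body_mask) {
  stopifnot(length(pred) == length(truth), length(body_mask) == length(pred))
  inb <- body_mask > 0
  if (!any(inb)) stop("empty body mask")
  d <- pred[inb] - truth[inb]
  mse <- mean(d^2)
  list(mae = mean(abs(d)), mse = mse, rmse = sqrt(mse))
}

#' Cumulative dose-volume histogram
#'
#' Percent of structure volume receiving at least each bin dose; starts at
#' 100% at 0 Gy and is non-increasing.
#'
#' @param dose Numeric dose array (Gy).
#' @param mask Binary structure mask of the same shape; nonempty.
#' @param bin_width_Gy Dose bin width (default 0.1 Gy).
#' @return A `dvh_curve` list with `dose_bins_Gy` and `cum_volume_pct`.
#' @export
dvh <- function(dose, mask, bin_width_Gy = 0.1) {
  stopifnot(length(dose) == length(mask))
  dm <- dose[mask > 0]
  if (!length(dm)) stop("empty structure")
  m <- length(dm)
  bins <- seq(0, max(dm) + bin_width_Gy, by = bin_width_Gy)
  ds <- sort(dm)
  vol <- 100 * (m - findInterval(bins - 1e-12, ds)) / m
  structure(list(dose_bins_Gy = bins, cum_volume_pct = vol), class = "dvh_curve")
}

#' Dose at volume (Dq)
#'
#' `Dq` is the dose received by at least q% of the structure, computed as
#' the ascending order statistic at position `floor(m * (1 - q/100))`
#' (clamped to at least 1); for a 100-voxel structure with doses 1..100 Gy,
#' D95 = 5 Gy. When given a [dvh()] curve, the largest bin dose whose
#' cumulative volume still reaches q% is returned.
#'
#' @param x A `dvh_curve`, or a numeric dose array (then `mask` is needed).
#' @param q_pct Volume percentage in (0, 100].
#' @param mask Binary structure mask when `x` is a dose array.
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(x, q_pct, mask = NULL) {
  stopifnot(q_pct > 0, q_pct <= 100)
  if (inherits(x, "dvh_curve")) {
    ok <- x$cum_volume_pct >= q_pct
    if (!any(ok)) return(0)
    return(max(x$dose_bins_Gy[ok]))
  }
  stopifnot(!is.null(mask))
  ds <- sort(x[mask > 0])
  m <- length(ds)
  if (!m) stop("empty structure")
  k <- max(1L, floor(m * (1 - q_pct / 100) + 1e-9))
  ds[k]
}

#' Volume at dose (Vd)
#'
#' Percent of structure voxels receiving at least `d_Gy`.
#'
#' @param dose Numeric dose array (Gy).
#' @param mask Binary structure mask.
#' @param d_Gy Dose threshold in Gy.
#' @return Percentage in [0, 100].
#' @export
volume_at_dose <- function(dose, mask, d_Gy) {
  dm <- dose[mask > 0]
  if (!length(dm)) stop("empty structure")
  100 * mean(dm >= d_Gy)
}

#' Plan-criteria check table
#'
#' Evaluates the clinical plan criteria: PTV D95 >= prescription (boundary
#' inclusive), D2 < 110% and D98 > 95% of prescription; bladder V30 < 50%,
#' V40 < 40%, V45 < 35%; rectum V30 < 60%, V40 < 55%; femoral heads
#' V30 < 15%; spinal cord Dmax < 45 Gy. Missing structures are marked
#' not-evaluable.
#'
#' @param dose A [dose_grid()] or numeric dose array (Gy).
#' @param structures A [structure_set()] (or named list of masks).
#' @param prescription_Gy Prescription dose (default 45).
#' @return data.frame with structure, criterion, value, limit, pass,
#'   evaluable.
#' @export
check_plan_criteria <- function(dose, structures, prescription_Gy = 45) {
  dv <- if (inherits(dose, "dose_grid")) dose$values else dose
  masks <- if (inherits(structures, "structure_set")) structures$masks else structures
  rows <- list()
  addrow <- function(structure, criterion, value, limit, pass, evaluable = TRUE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      structure = structure, criterion = criterion, value = value,
      limit = limit, pass = pass, evaluable = evaluable,
      stringsAsFactors = FALSE)
  }
  eval_metric <- function(name, criterion, limit, fn, cmp) {
    mk <- masks[[name]]
    if (is.null(mk) || !any(mk > 0)) {
      addrow(name, criterion, NA_real_, limit, NA, FALSE)
    } else {
      v <- fn(mk)
      addrow(name, criterion, v, limit, cmp(v, limit))
    }
  }
  eval_metric("PTV", "D95 >= prescription", prescription_Gy,
              function(m) dose_at_volume(dv, 95, m), `>=`)
  eval_metric("PTV", "D2 < 110% prescription", 1.1 * prescription_Gy,
              function(m) dose_at_volume(dv, 2, m), `<`)
  eval_metric("PTV", "D98 > 95% prescription", 0.95 * prescription_Gy,
              function(m) dose_at_volume(dv, 98, m), `>`)
  vd <- function(d) function(m) volume_at_dose(dv, m, d)
  eval_metric("bladder", "V30 < 50%", 50, vd(30), `<`)
  eval_metric("bladder", "V40 < 40%", 40, vd(40), `<`)
  eval_metric("bladder", "V45 < 35%", 35, vd(45), `<`)
  eval_metric("rectum", "V30 < 60%", 60, vd(30), `<`)
  eval_metric("rectum", "V40 < 55%", 55, vd(40), `<`)
  eval_metric("femoral_head_left", "V30 < 15%", 15, vd(30), `<`)
  eval_metric("femoral_head_right", "V30 < 15%", 15, vd(30), `<`)
  eval_metric("spinal_cord", "Dmax < 45 Gy", 45,
              function(m) max(dv[m > 0]), `<`)
  do.call(rbind, rows)
}

#' Voxel counts in low-dose bands
#'
#' Counts body voxels with `lo <= dose < hi` for each band; default bands
#' 4-10, 10-15 and 15-20 Gy.
#'
#' @param dose Numeric dose array (Gy).
#' @param bands List of `c(lo, hi)` pairs, non-overlapping.
#' @param body_mask Optional binary mask restricting the count.
#' @return Named integer vector of counts ("lo-hi" names).
#' @export
low_dose_voxel_counts <- function(dose,
                                  bands = list(c(4, 10), c(10, 15), c(15, 20)),
                                  body_mask = NULL) {
  los <- vapply(bands, `[`, 1.0, 1)
  his <- vapply(bands, `[`, 1.0, 2)
  o <- order(los)
  if (any(los[o][-1] < his[o][-length(his)])) stop("bands overlap")
  d <- if (is.null(body_mask)) as.vector(dose) else dose[body_mask > 0]
  counts <- vapply(bands, function(b) sum(d >= b[1] & d < b[2]), 1L)
  names(counts) <- vapply(bands, function(b) paste0(b[1], "-", b[2]), "")
  counts
}
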