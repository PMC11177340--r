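# Case serialisation: one directory per patient with NIfTI volumes, the
# structure channel order in a JSON sidecar, and the generating config
# echoed to JSON.

nifti_with_spacing <- function(arr, spacing_mm) {
  img <- RNifti::asNifti(arr + 0)   # force numeric copy
  # array axes are (y, x, z); spacing supplied as (z, y, x)
  RNifti::pixdim(img) <- c(spacing_mm[2], spacing_mm[3], spacing_mm[1])
  img
}

#' Write a case directory
#'
#' Layout: `ct.nii.gz`, `dose.nii.gz`, `structures/<name>.nii.gz`, and
#' `case.json` holding the channel order, prescription and the phantom
#' configuration.
#'
#' @param case A `phantom_case`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_case <- function(case, dir) {
  dir.create(file.path(dir, "structures"), recursive = TRUE, showWarnings = FALSE)
  sp <- case$ct$spacing_mm
  RNifti::writeNifti(nifti_with_spacing(case$ct$values, sp),
                     file.path(dir, "ct.nii.gz"))
  RNifti::writeNifti(nifti_with_spacing(case$dose$values, case$dose$spacing_mm),
                     file.path(dir, "dose.nii.gz"))
  for (nm in case$structures$channel_order) {
    RNifti::writeNifti(nifti_with_spacing(case$structures$masks[[nm]], sp),
                       file.path(dir, "structures", paste0(nm, ".nii.gz")))
  }
  cfg <- case$config
  cfg$oar_specs <- lapply(cfg$oar_specs, function(s) {
    list(offset = s$offset, radius = s$radius)
  })
  meta <- list(channel_order = case$structures$channel_order,
               prescription_Gy = case$config$prescription_Gy,
               spacing_mm = sp,
               config = unclass(cfg))
  jsonlite::write_json(meta, file.path(dir, "case.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a case directory written by [write_case()]
#'
#' @param dir Case directory.
#' @return A `phantom_case`-shaped list (`ct`, `structures`, `dose`,
#'   `config`).
#' @export
read_case <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "case.json"), simplifyVector = TRUE)
  sp <- as.numeric(meta$spacing_mm)
  ctv <- array(as.numeric(RNifti::readNifti(file.path(dir, "ct.nii.gz"))),
               dim = dim(RNifti::readNifti(file.path(dir, "ct.nii.gz"))))
  dosev <- RNifti::readNifti(file.path(dir, "dose.nii.gz"))
  masks <- lapply(meta$channel_order, function(nm) {
    m <- RNifti::readNifti(file.path(dir, "structures", paste0(nm, ".nii.gz")))
    array(as.integer(round(m)), dim = dim(m))
  })
  names(masks) <- meta$channel_order
  cfg <- meta$config
  cfg$prescription_Gy <- meta$prescription_Gy
  case <- list(ct = ct_volume(ctv, spacing_mm = sp),
               structures = structure_set(masks),
               dose = dose_grid(array(pmax(as.numeric(dosev), 0), dim = dim(dosev)),
                                spacing_mm = sp),
               config = cfg)
  class(case) <- "phantom_case"
  case
}
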