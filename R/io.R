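#' Write / read a CT phantom as NIfTI
#'
#' @param ct a `ct_volume`.
#' @param path output `.nii` or `.nii.gz` path.
#' @return the path (writers, invisibly) or the object (readers).
#' @export
write_ct_nifti <- function(ct, path) {
  stopifnot(inherits(ct, "ct_volume"))
  img <- RNifti::asNifti(ct$data)
  RNifti::pixdim(img) <- ct$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_ct_nifti
#' @export
read_ct_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  structure(list(data = array(as.numeric(img), dim = dim(img)),
                 spacing = RNifti::pixdim(img)[1:3],
                 affine = structure(RNifti::xform(img), class = NULL),
                 axis_convention = "z-superior"),
            class = "ct_volume")
}

#' Write / read a segmentation mask as NIfTI
#'
#' @param mask a `seg_mask`.
#' @param path output path.
#' @param spacing voxel spacing (writer), mm.
#' @export
write_mask_nifti <- function(mask, path, spacing = c(1, 1, 1)) {
  stopifnot(inherits(mask, "seg_mask"))
  img <- RNifti::asNifti(mask$labels)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @param level_map named integer vector label lookup (reader).
#' @export
read_mask_nifti <- function(path, level_map = c(L1 = 1L)) {
  img <- RNifti::readNifti(path)
  structure(list(labels = array(as.integer(img), dim = dim(img)),
                 level_map = level_map),
            class = "seg_mask")
}

#' Write / read a multi-echo series as NIfTI plus JSON sidecar
#'
#' The complex echo signal is stored as one 5D NIfTI volume
#' (x, y, z, echo, real/imaginary) -- a plain-real representation that
#' every NIfTI reader handles -- and a JSON sidecar records the echo
#' times (ms) and the fat spectrum used for simulation.
#'
#' @param echoes an `echo_series` from [make_cse_echoes()].
#' @param path output `.nii`/`.nii.gz` path; sidecar written next to it
#'   with extension `.json`.
#' @export
write_echoes_nifti <- function(echoes, path) {
  stopifnot(inherits(echoes, "echo_series"))
  sig <- echoes$signal
  arr <- array(c(Re(sig), Im(sig)), dim = c(dim(sig), 2))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(echo_times_ms = echoes$echo_times_ms,
         complex_layout = "last axis: 1 = real, 2 = imaginary",
         fat_spectrum = list(ppm = echoes$spectrum$ppm,
                             amplitude = echoes$spectrum$amplitude,
                             field_T = echoes$spectrum$field_T)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_echoes_nifti
#' @export
read_echoes_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  nd <- length(dim(arr))
  stopifnot(dim(arr)[nd] == 2)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  half <- length(arr) / 2
  sig <- complex(real = arr[seq_len(half)], imaginary = arr[half + seq_len(half)])
  dims <- dim(arr)[-nd]
  spec <- fat_spectrum(ppm = meta$fat_spectrum$ppm,
                       amplitude = meta$fat_spectrum$amplitude,
                       field_T = meta$fat_spectrum$field_T)
  structure(list(signal = array(sig, dim = dims),
                 echo_times_ms = meta$echo_times_ms,
                 spectrum = spec, dim = dims[-length(dims)]),
            class = "echo_series")
}

#' Write / read a cohort table as CSV
#'
#' Column layout: `patient_id,group,level,fractured,pdff_percent,`
#' `failure_displacement_mm,failure_load_N`.
#'
#' @param table a `cohort_table`.
#' @param path CSV path.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "group", "level", "fractured", "pdff_percent",
            "failure_displacement_mm", "failure_load_N")
  if (!all(need %in% names(tab)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  tab$fractured <- as.logical(tab$fractured)
  if (anyDuplicated(tab[c("patient_id", "level")]))
    stop("duplicate (patient_id, level) rows")
  stopifnot(all(tab$pdff_percent >= 0 & tab$pdff_percent <= 100),
            all(tab$failure_displacement_mm > 0),
            all(tab$failure_load_N > 0))
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
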