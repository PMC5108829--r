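# File formats: calibration tables as CSV, kernel parameters as JSON,
# arterial input curves as 2-column CSV, volumes as NIfTI-1 (via RNifti,
# suggested), sinograms as RDS.

#' Read/write a calibration table (CSV: volume_cm3, alpha, beta_cm2)
#' @param path file path.
#' @return a [calibration_table()].
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("volume_cm3", "alpha", "beta_cm2")
  if (!all(need %in% names(df))) {
    stop("calibration CSV needs columns: ", paste(need, collapse = ", "))
  }
  calibration_table(df$volume_cm3, df$alpha, df$beta_cm2)
}

#' @rdname read_calibration_table
#' @param table a [calibration_table()].
#' @export
write_calibration_table <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  utils::write.csv(
    data.frame(
      volume_cm3 = table$volume_cm3, alpha = table$alpha,
      beta_cm2 = table$beta
    ),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' Read/write kernel parameters (JSON: alpha, beta_cm2)
#' @param path file path.
#' @return a [kernel_params()].
#' @export
read_kernel_params <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  kernel_params(j$alpha, j$beta_cm2)
}

#' @rdname read_kernel_params
#' @param params a [kernel_params()].
#' @export
write_kernel_params <- function(params, path) {
  stopifnot(inherits(params, "kernel_params"))
  jsonlite::write_json(
    list(alpha = params$alpha, beta_cm2 = params$beta),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read/write an arterial input curve (CSV: time_s, kbq_ml)
#' @param path file path.
#' @return a [tac()].
#' @export
read_aif_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "kbq_ml") %in% names(df))) {
    stop("AIF CSV needs columns time_s, kbq_ml")
  }
  tac(df$time_s, df$kbq_ml)
}

#' @rdname read_aif_csv
#' @param curve a [tac()].
#' @export
write_aif_csv <- function(curve, path) {
  stopifnot(inherits(curve, "tac"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Read/write sinograms (RDS container with geometry metadata)
#' @param path file path.
#' @return a [sinogram()].
#' @export
read_sinogram <- function(path) {
  s <- readRDS(path)
  if (!inherits(s, "sinogram")) stop("file does not contain a sinogram")
  s
}

#' @rdname read_sinogram
#' @param sino a [sinogram()].
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  saveRDS(sino, path)
  invisible(path)
}

#' Read/write volumes as NIfTI-1 (voxel sizes in the header)
#' @param path file path (`.nii` or `.nii.gz`).
#' @param kind volume kind for [pet_volume()] on read.
#' @return a [pet_volume()].
#' @export
read_volume_nifti <- function(path, kind = c("activity", "mu", "image")) {
  kind <- match.arg(kind)
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required for NIfTI I/O")
  }
  img <- RNifti::readNifti(path)
  pix <- RNifti::pixdim(img)[1:3] / 10 # NIfTI mm -> cm
  pet_volume(array(as.numeric(img), dim(img)[1:3]), pix, kind)
}

#' @rdname read_volume_nifti
#' @param vol a [pet_volume()].
#' @export
write_volume_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "pet_volume"))
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required for NIfTI I/O")
  }
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  RNifti::pixdim(img) <- attr(vol, "voxel_cm") * 10
  RNifti::writeNifti(img, path)
  invisible(path)
}
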