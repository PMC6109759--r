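#' Read a 4D NIfTI file as a VolumeSeries
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param tr repetition time override (s); by default taken from the header's
#'   4th pixdim.
#' @return a [VolumeSeries-class].
#' @export
readVolumeSeries <- function(path, tr = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) stop("'", path, "' is not a 4D image")
  pd <- RNifti::pixdim(img)
  if (is.null(tr)) tr <- pd[4]
  new("VolumeSeries", data = array(as.numeric(img), d),
      voxelSize = as.numeric(pd[1:3]), tr = as.numeric(tr))
}

#' Write a VolumeSeries as a 4D NIfTI file
#'
#' @param series a [VolumeSeries-class].
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeVolumeSeries <- function(series, path) {
  img <- RNifti::asNifti(series@data)
  RNifti::pixdim(img) <- c(series@voxelSize, series@tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write one synthesized subject to disk
#'
#' Emits the BOLD series as 4D NIfTI-1 plus one FSL 3-column event file per
#' condition.
#'
#' @param subject a list with `series` and `schedules` as produced by
#'   [generateCohort()].
#' @param dir output directory (created if missing).
#' @param prefix file name prefix, e.g. "sub-01".
#' @return named character vector of the written paths, invisibly.
#' @export
writeSubject <- function(subject, dir, prefix = "sub-01") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(bold = file.path(dir, paste0(prefix, "_bold.nii.gz")))
  writeVolumeSeries(subject$series, paths[["bold"]])
  for (cond in names(subject$schedules)) {
    p <- file.path(dir, paste0(prefix, "_", cond, ".txt"))
    writeEvents(subject$schedules[[cond]], p)
    paths[[cond]] <- p
  }
  invisible(paths)
}
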