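#' Write a DWIStudy to a directory of NIfTI files
#'
#' One NIfTI per station per b-value (`stationSS_bBBBB.nii.gz`), a JSON
#' sidecar per station recording b-values, spacing and slice positions,
#' and a top-level `study.json`. The layout round-trips through
#' [readStudy()].
#'
#' @param study a [DWIStudy].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  stopifnot(is(study, "DWIStudy"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(study@stations)) {
    st <- study@stations[[i]]
    for (j in seq_along(st@bValues)) {
      arr <- aperm(st@signal[j, , , , drop = TRUE], c(2, 3, 1))
      img <- RNifti::asNifti(arr)
      img <- RNifti::`pixdim<-`(img, c(st@spacing[2], st@spacing[3],
                                       st@spacing[1]))
      RNifti::writeNifti(img, file.path(dir, sprintf("station%02d_b%04d.nii.gz",
                                                     i, st@bValues[j])))
    }
    jsonlite::write_json(
      list(bval = st@bValues, spacing = st@spacing,
           slice_positions = st@slicePositions),
      file.path(dir, sprintf("station%02d.json", i)),
      auto_unbox = FALSE, digits = NA)
  }
  jsonlite::write_json(
    list(patient_id = study@patientId, scan_label = study@scanLabel,
         n_stations = length(study@stations)),
    file.path(dir, "study.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a DWIStudy from a directory written by [writeStudy()]
#'
#' Stations are ordered superior to inferior by their slice positions
#' regardless of file order; missing sidecars or b-value volumes raise
#' an error naming the file.
#'
#' @param dir study directory.
#' @return a [DWIStudy].
#' @export
readStudy <- function(dir) {
  metaFile <- file.path(dir, "study.json")
  if (!file.exists(metaFile)) stop("missing study metadata file: ", metaFile)
  meta <- jsonlite::read_json(metaFile, simplifyVector = TRUE)
  stations <- vector("list", meta$n_stations)
  for (i in seq_len(meta$n_stations)) {
    sidecar <- file.path(dir, sprintf("station%02d.json", i))
    if (!file.exists(sidecar)) stop("missing station sidecar: ", sidecar)
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(sc$bval) || !length(sc$bval))
      stop("no b-values listed in ", sidecar)
    vols <- lapply(sc$bval, function(b) {
      f <- file.path(dir, sprintf("station%02d_b%04d.nii.gz", i, b))
      if (!file.exists(f)) stop("missing b-value volume: ", f)
      arr <- as.array(RNifti::readNifti(f))
      aperm(arr, c(3, 1, 2))            # back to (slice, row, col)
    })
    sig <- array(0, c(length(vols), dim(vols[[1]])))
    for (j in seq_along(vols)) sig[j, , , ] <- vols[[j]]
    stations[[i]] <- StationVolume(sig, sc$bval, sc$spacing,
                                   sc$slice_positions)
  }
  ord <- order(vapply(stations, function(s) min(s@slicePositions), numeric(1)))
  DWIStudy(stations[ord], patientId = meta$patient_id,
           scanLabel = meta$scan_label)
}

#' Write a 3-D map or mask as NIfTI
#'
#' @param vol 3-D array (slice, row, col); masks are written as integers.
#' @param path output file.
#' @param spacing voxel spacing (slice, row, col) in mm.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path, spacing = c(5, 1.6, 1.6)) {
  arr <- aperm(vol, c(2, 3, 1))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(spacing[2], spacing[3], spacing[1]))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3-D NIfTI volume into (slice, row, col) order
#'
#' @param path NIfTI file.
#' @return 3-D array.
#' @export
readVolume <- function(path) {
  aperm(as.array(RNifti::readNifti(path)), c(3, 1, 2))
}

#' Combined cord/CSF label map
#'
#' Encodes a [SubSegmentation] as one integer volume: 0 background,
#' 1 spinal cord, 2 CSF.
#'
#' @param sub a [SubSegmentation].
#' @return integer 3-D array.
#' @export
labelMap <- function(sub) {
  stopifnot(is(sub, "SubSegmentation"))
  sub@cordMask + 2 * sub@csfMask
}
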