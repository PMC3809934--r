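#' Read and write image volumes
#'
#' Volumes are exchanged as NIfTI (`.nii`/`.nii.gz`, via the RNifti
#' package) or multi-page TIFF (via the tiff package); both packages are
#' suggested rather than imported, so these helpers error informatively
#' when the needed reader is absent.
#'
#' @param path file path; the extension selects the format.
#' @return `read_volume()`: a [gray_volume()].
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI requires the RNifti package", call. = FALSE)
    img <- RNifti::readNifti(path)
    arr <- array(as.numeric(img), dim = dim(img))
    gray_volume(arr, spacing = RNifti::pixdim(img)[1:3])
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the tiff package", call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
    for (s in seq_along(pages)) {
      p <- pages[[s]]
      if (length(dim(p)) == 3) p <- p[, , 1]
      arr[, , s] <- p
    }
    gray_volume(arr * 255)
  } else {
    stop("unsupported volume format: ", path, call. = FALSE)
  }
}

#' @rdname read_volume
#' @param volume a [gray_volume()] or 3-D array.
#' @return `write_volume()`: the path, invisibly.
#' @export
write_volume <- function(volume, path) {
  vox <- as_voxel_array(volume)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("writing NIfTI requires the RNifti package", call. = FALSE)
    RNifti::writeNifti(RNifti::asNifti(vox), path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("writing TIFF requires the tiff package", call. = FALSE)
    pages <- lapply(seq_len(dim(vox)[3]),
                    function(s) vox[, , s] / 255)
    tiff::writeTIFF(pages, path)
  } else {
    stop("unsupported volume format: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Write a feature table to CSV
#'
#' @param features a tibble (e.g. from [fractal_feature_table()]).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_features_csv <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}
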