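# NIfTI I/O for BOLD volumes and masks (via RNifti).

#' Write a BOLD volume or VOI mask to NIfTI
#'
#' Volumes are written on their own grid with their affine; masks are
#' byte-valued 0/1. The BOLD TR is stored in `pixdim[4]`.
#'
#' @param x a [bold_volume()], a [voi_mask()], or a bare 3D numeric array
#'   (a statistic map written on the grid given by `affine`).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param affine 4x4 transform for bare-array input.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, affine = diag(c(3, 3, 3, 1))) {
  if (is.array(x) && is.numeric(x) && length(dim(x)) == 3) {
    arr <- x
    attr(arr, "pixdim") <- abs(diag(affine)[1:3])
    attr(arr, "pixunits") <- "mm"
    img <- RNifti::asNifti(arr)
    img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  if (inherits(x, "bold_volume")) {
    arr <- x$data
    attr(arr, "pixdim") <- c(abs(diag(x$affine)[1:3]), x$tr_s)
    attr(arr, "pixunits") <- c("mm", "s")
    img <- RNifti::asNifti(arr)
  } else if (inherits(x, "voi_mask")) {
    arr <- array(as.integer(x$mask), dim(x$mask))
    attr(arr, "pixdim") <- abs(diag(x$affine)[1:3])
    attr(arr, "pixunits") <- "mm"
    img <- RNifti::asNifti(arr, datatype = "uint8")
  } else stop("x must be a bold_volume or voi_mask")
  img <- RNifti::`sform<-`(img, structure(x$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D BOLD NIfTI file
#'
#' @param path NIfTI path.
#' @param tr_s repetition time override; default from the header
#'   (`pixdim[4]`).
#' @param run_id,subject_id identifiers.
#' @return A [bold_volume()].
#' @export
read_bold_nifti <- function(path, tr_s = NULL, run_id = "run1",
                            subject_id = "sub1") {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4)
    stop("expected a 4D BOLD NIfTI, got ", length(dim(img)), "D: ", path)
  if (is.null(tr_s)) tr_s <- RNifti::pixdim(img)[4]
  aff <- .nifti_affine(img)
  bold_volume(array(as.numeric(img), dim(img)), tr_s = tr_s, affine = aff,
              run_id = run_id, subject_id = subject_id)
}

#' Read a 3D NIfTI mask
#'
#' @param path NIfTI path.
#' @param label region label.
#' @return A [voi_mask()]; non-binary values are binarized at 0.5 with a
#'   warning.
#' @export
read_mask_nifti <- function(path, label = "VOI") {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3)
    stop("expected a 3D mask NIfTI, got ", length(dim(img)), "D: ", path)
  v <- as.numeric(img)
  if (!all(v %in% c(0, 1))) {
    warning("mask contains non-binary values; binarizing at > 0.5")
    v <- as.numeric(v > 0.5)
  }
  voi_mask(array(v > 0.5, dim(img)), affine = .nifti_affine(img),
           label = label)
}

.nifti_affine <- function(img) {
  aff <- try(structure(RNifti::xform(img), code = NULL), silent = TRUE)
  if (inherits(aff, "try-error")) diag(4) else unclass(aff)[1:4, 1:4]
}
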