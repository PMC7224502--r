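# Label image I/O: NIfTI (.nii/.nii.gz) via RNifti, ANALYZE (.hdr/.img) via
# oro.nifti. Labels are stored as integers; only axis-aligned geometry
# (spacing + translation) is supported -- ANALYZE carries no full affine,
# and the voxel-center world convention used throughout the package has no
# rotation part.

#' Read / write labeled images
#'
#' `write_label_image()` writes a [labeled_image()] as NIfTI (extension
#' `.nii` or `.nii.gz`) or ANALYZE (`.hdr`/`.img`). `read_label_image()`
#' reads either format back; voxel data must be integer-valued.
#'
#' NIfTI files carry spacing and origin (qform translation); ANALYZE
#' carries spacing only, so the origin is restored as 0.
#'
#' @param image a [labeled_image()].
#' @param path file path; the format is chosen by extension.
#' @return `read_label_image()` returns a [labeled_image()];
#'   `write_label_image()` returns `path` invisibly.
#' @export
write_label_image <- function(image, path) {
  lab <- image$labels
  if (grepl("\\.nii(\\.gz)?$", path)) {
    dt <- if (max(lab) <= 32767L) "int16" else "int32"
    im <- RNifti::asNifti(lab, reference = list(
      pixdim = c(1, image$spacing, 1, 1, 1, 1),
      qform_code = 1L, quatern_b = 0, quatern_c = 0, quatern_d = 0,
      qoffset_x = image$origin[1], qoffset_y = image$origin[2],
      qoffset_z = image$origin[3]), datatype = dt, internal = FALSE)
    RNifti::writeNifti(im, path)
  } else if (grepl("\\.(hdr|img)$", path)) {
    a <- oro.nifti::anlz(lab, datatype = 4L)  # int16
    a@pixdim <- c(4, image$spacing, 1, 0, 0, 0)
    oro.nifti::writeANALYZE(a, sub("\\.(hdr|img)$", "", path))
  } else stop("unknown label image format: ", path)
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    im <- RNifti::readNifti(path)
    x <- RNifti::xform(im)
    rot <- x[1:3, 1:3]
    if (max(abs(rot - diag(diag(rot)))) > 1e-6)
      stop("oblique/rotated NIfTI orientations are not supported")
    dat <- as.array(im)
    spacing <- abs(diag(rot))
    origin <- x[1:3, 4]
    # undo axis flips encoded as negative diagonal entries
    for (ax in 1:3) if (diag(rot)[ax] < 0) {
      dat <- flip_axis(dat, ax)
      origin[ax] <- origin[ax] + diag(rot)[ax] * (dim(dat)[ax] - 1)
    }
  } else if (grepl("\\.(hdr|img)$", path)) {
    a <- oro.nifti::readANALYZE(path)
    dat <- a@.Data
    if (length(dim(dat)) == 4L) dat <- dat[, , , 1]
    spacing <- a@pixdim[2:4]
    origin <- c(0, 0, 0)
  } else stop("unknown label image format: ", path)
  if (max(abs(dat - round(dat))) > 0)
    stop("non-integer voxel data cannot be read as labels")
  storage.mode(dat) <- "integer"
  labeled_image(dat, spacing, origin)
}

flip_axis <- function(a, ax) {
  idx <- lapply(dim(a), seq_len)
  idx[[ax]] <- rev(idx[[ax]])
  do.call(`[`, c(list(a), idx))
}
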