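# NIfTI-1 reading and writing via RNifti. Volumes are scalar 3-D images;
# displacement fields are 4-D with the vector components in the last
# dimension (mm). The grid convention (origin at voxel (1,1,1), world =
# origin + (index-1)*spacing, axes x,y,z) matches the in-memory contract.

nifti_of <- function(values, spacing, origin) {
  nd <- length(dim(values))
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- if (nd == 4L) c(spacing, 1) else spacing
  xf <- diag(4)
  xf[1, 1] <- spacing[1L]; xf[2, 2] <- spacing[2L]; xf[3, 3] <- spacing[3L]
  xf[1:3, 4] <- origin
  RNifti::qform(img) <- structure(xf, code = 1L)
  img
}

#' Read and write volumes as NIfTI
#'
#' `write_volume` accepts any of the package's grid objects (`hu_image`,
#' `density_image`, `lung_mask`, `dose_grid`, `function_image`,
#' `disp_field`) and writes a `.nii`/`.nii.gz`; masks are written as uint8.
#' `read_volume` reads a scalar volume into the requested container,
#' `read_field` a 4-D displacement field.
#'
#' @param x the object to write.
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param as one of `"hu"`, `"density"`, `"mask"`, `"dose"` for
#'   `read_volume`.
#' @return `write_volume` returns `path` invisibly; the readers return the
#'   corresponding object.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "disp_field")) {
    img <- nifti_of(x$u, x$spacing, x$origin)
  } else if (inherits(x, "lung_mask") || inherits(x, "function_contour")) {
    v <- x$values
    storage.mode(v) <- "integer"
    img <- nifti_of(v, x$spacing, x$origin)
  } else {
    img <- nifti_of(x$values, x$spacing, x$origin)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, as = c("hu", "density", "mask", "dose")) {
  as <- match.arg(as)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- if (inherits(xf, "try-error")) c(0, 0, 0) else xf[1:3, 4]
  vals <- array(as.numeric(img), dim(img))
  switch(as,
         hu = hu_image(vals, sp, org),
         density = density_image(vals, sp, org),
         mask = lung_mask(vals > 0.5, sp, org),
         dose = grid_obj(vals, sp, org, "dose_grid"))
}

#' @rdname write_volume
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 4L || dm[4L] != 3L)
    stop_("expected a 4-D NIfTI with last dimension 3")
  sp <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- if (inherits(xf, "try-error")) c(0, 0, 0) else xf[1:3, 4]
  disp_field(array(as.numeric(img), dm), sp, org)
}
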