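#' CT image containers
#'
#' Lightweight S3 containers for volumetric data on a regular grid. All
#' grids follow one convention: voxel indices are 1-based in R, the world
#' coordinate (mm) of voxel \code{(i, j, k)} is
#' \code{origin + (index - 1) * spacing}, and axes are ordered (x, y, z) both
#' in memory and on disk.
#'
#' @param values 3-D numeric array. For `hu_image`, Hounsfield units in
#'   \[-1024, 3071\]; for `density_image`, dimensionless density (water = 1,
#'   air = 0); for `lung_mask`, coerced to logical.
#' @param spacing numeric length-3, per-axis voxel size in mm (> 0).
#' @param origin numeric length-3, world coordinate (mm) of voxel (1, 1, 1).
#' @return An object of class `hu_image`, `density_image` or `lung_mask`.
#' @examples
#' hu <- hu_image(array(-800, c(4, 4, 4)), spacing = c(2, 2, 2))
#' rho <- hu_to_density(hu)
#' range(rho$values)
#' @export
hu_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  grid_obj(values, spacing, origin, "hu_image", validate = function(v) {
    check_finite(v, "HU image")
    if (min(v) < -1024 || max(v) > 3071)
      stop_("HU values outside [-1024, 3071] (range %.1f..%.1f)", min(v), max(v))
  })
}

#' @rdname hu_image
#' @export
density_image <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  grid_obj(values, spacing, origin, "density_image", validate = function(v) {
    check_finite(v, "density image")
    if (min(v) < 0) stop_("density values must be >= 0")
  })
}

#' @rdname hu_image
#' @export
lung_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(values) <- "logical"
  values[is.na(values)] <- FALSE
  obj <- grid_obj(values, spacing, origin, "lung_mask", validate = function(v) {
    if (!any(v)) stop_("lung mask is empty")
  })
  obj
}

#' Displacement field on the exhale grid
#'
#' The field lives on the exhale (reference) grid and points into inhale
#' space: a material point at exhale world coordinate `x` is found at inhale
#' world coordinate `x + u(x)` (pull/backward-warp convention).
#'
#' @param u 4-D numeric array, `dim = c(nx, ny, nz, 3)`, displacements in mm.
#' @inheritParams hu_image
#' @return An object of class `disp_field`.
#' @export
disp_field <- function(u, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(u)) != 4L || dim(u)[4L] != 3L)
    stop_("displacement field must be a 4-D array with last dimension 3")
  if (!all(is.finite(u))) stop_("displacement field contains non-finite values")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) stop_("spacing must be 3 positive values")
  structure(list(u = u, spacing = spacing, origin = origin,
                 dim = dim(u)[1:3]),
            class = "disp_field")
}

#' Voxelwise lung-function image
#'
#' Values are finite on mask voxels and `NA` elsewhere. `kind` records the
#' physical quantity: `"specific-volume-change"` (HU method, dimensionless
#' fractional air-volume change), `"jacobian"` (local inhale/exhale volume
#' ratio, > 0), or `"mass-change-magnitude"` (density units per exhale voxel
#' volume, >= 0).
#'
#' @param values 3-D numeric array, `NA` outside `mask`.
#' @param mask logical 3-D array of defined voxels.
#' @param kind one of `"specific-volume-change"`, `"jacobian"`,
#'   `"mass-change-magnitude"`.
#' @inheritParams hu_image
#' @export
function_image <- function(values, mask, kind, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  kind <- match.arg(kind, c("specific-volume-change", "jacobian", "mass-change-magnitude"))
  mask <- as_mask_array(mask)
  if (!identical(dim(values), dim(mask))) stop_("function image and mask shapes differ")
  v <- values[mask]
  if (any(!is.finite(v))) stop_("function image has non-finite values on mask voxels")
  if (kind == "jacobian" && any(v <= 0)) stop_("jacobian image must be > 0 on mask")
  if (kind == "mass-change-magnitude" && any(v < 0)) stop_("mass-change image must be >= 0 on mask")
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask, kind = kind,
                 spacing = as.numeric(spacing), origin = as.numeric(origin),
                 dim = dim(values)),
            class = "function_image")
}

# shared constructor for scalar-grid objects
grid_obj <- function(values, spacing, origin, class, validate = NULL) {
  if (length(dim(values)) != 3L) stop_("expected a 3-D array for a %s", class)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_("spacing must be 3 positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop_("origin must be 3 finite values")
  if (!is.null(validate)) validate(values)
  structure(list(values = values, spacing = spacing, origin = origin,
                 dim = dim(values)),
            class = class)
}

as_mask_array <- function(mask) {
  if (inherits(mask, "lung_mask")) return(mask$values)
  m <- mask
  storage.mode(m) <- "logical"
  m[is.na(m)] <- FALSE
  m
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$dim, b$dim) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' @exportS3Method base::print
print.hu_image <- function(x, ...) {
  cat(sprintf("<hu_image> %s voxels, spacing %s mm, HU range [%.0f, %.0f]\n",
              paste(x$dim, collapse = "x"), paste(signif(x$spacing, 3), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @exportS3Method base::print
print.function_image <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<function_image> kind=%s, %d defined voxels, range [%.4g, %.4g]\n",
              x$kind, length(v), min(v), max(v)))
  invisible(x)
}

#' @exportS3Method base::print
print.lung_mask <- function(x, ...) {
  cat(sprintf("<lung_mask> %s voxels, %d in mask\n",
              paste(x$dim, collapse = "x"), sum(x$values)))
  invisible(x)
}

#' Convert Hounsfield units to density
#'
#' Assumes each voxel is a linear mix of water-like material (HU 0,
#' density 1) and air-like material (HU -1000, density 0), so
#' `density = (HU + 1000) / 1000`. Values below -1000 HU (scanner noise)
#' clip to density 0; the clipped-voxel count is attached as attribute
#' `"clipped"` on the returned values.
#'
#' @param hu an [hu_image()].
#' @return A `density_image` on the same grid.
#' @examples
#' hu <- hu_image(array(c(-1000, 0, -800, -500), c(4, 1, 1)))
#' as.numeric(hu_to_density(hu)$values)  # 0, 1, 0.2, 0.5
#' @export
hu_to_density <- function(hu) {
  stopifnot(inherits(hu, "hu_image"))
  check_finite(hu$values, "HU image")
  rho <- (hu$values + 1000) / 1000
  n_clip <- sum(rho < 0)
  rho[rho < 0] <- 0
  out <- density_image(rho, hu$spacing, hu$origin)
  attr(out, "clipped") <- n_clip
  out
}

# inverse map, used by the phantom when writing HU volumes
density_to_hu <- function(rho) 1000 * rho - 1000
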