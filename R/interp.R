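# Grid sampling and backward warping.

# Sample a 3-D array at continuous 1-based grid coordinates (gx, gy, gz).
# Out-of-bounds points get `fill`; the logical attribute "oob" marks them.
sample_grid <- function(arr, gx, gy, gz, method = c("trilinear", "nearest"),
                        fill = NA_real_) {
  method <- match.arg(method)
  dm <- dim(arr)
  oob <- !(is.finite(gx) & is.finite(gy) & is.finite(gz)) |
    gx < 1 | gx > dm[1L] | gy < 1 | gy > dm[2L] | gz < 1 | gz > dm[3L]
  out <- rep(fill, length(gx))
  ok <- which(!oob)
  if (length(ok)) {
    x <- gx[ok]; y <- gy[ok]; z <- gz[ok]
    if (method == "nearest") {
      i <- pmin(pmax(round(x), 1), dm[1L])
      j <- pmin(pmax(round(y), 1), dm[2L])
      k <- pmin(pmax(round(z), 1), dm[3L])
      out[ok] <- arr[cbind(i, j, k)]
    } else {
      i0 <- pmin(floor(x), dm[1L] - 1); fx <- x - i0
      j0 <- pmin(floor(y), dm[2L] - 1); fy <- y - j0
      k0 <- pmin(floor(z), dm[3L] - 1); fz <- z - k0
      base <- i0 + (j0 - 1) * dm[1L] + (k0 - 1) * dm[1L] * dm[2L]
      sx <- 1L; sy <- dm[1L]; sz <- dm[1L] * dm[2L]
      out[ok] <-
        arr[base]                * (1 - fx) * (1 - fy) * (1 - fz) +
        arr[base + sx]           * fx       * (1 - fy) * (1 - fz) +
        arr[base + sy]           * (1 - fx) * fy       * (1 - fz) +
        arr[base + sx + sy]      * fx       * fy       * (1 - fz) +
        arr[base + sz]           * (1 - fx) * (1 - fy) * fz       +
        arr[base + sx + sz]      * fx       * (1 - fy) * fz       +
        arr[base + sy + sz]      * (1 - fx) * fy       * fz       +
        arr[base + sx + sy + sz] * fx       * fy       * fz
    }
  }
  attr(out, "oob") <- oob
  out
}

# world points (N x 3, mm) -> continuous 1-based grid coordinates of `img`
world_to_grid <- function(pts, img) {
  cbind((pts[, 1L] - img$origin[1L]) / img$spacing[1L] + 1,
        (pts[, 2L] - img$origin[2L]) / img$spacing[2L] + 1,
        (pts[, 3L] - img$origin[3L]) / img$spacing[3L] + 1)
}

#' Pull a moving image through a displacement field
#'
#' Backward warping: the output voxel at exhale grid point `x` holds the
#' moving-image value interpolated at `x + u(x)`. Points that map outside
#' the moving grid take `fill` and are counted in the `"oob_count"`
#' attribute (with the full logical `"oob"` array alongside).
#'
#' @param field a [disp_field()] on the exhale grid.
#' @param moving the image to sample (an `hu_image` or `density_image`).
#' @param interp `"trilinear"` or `"nearest"`.
#' @param fill value for out-of-bounds points (default `NA`).
#' @return An object of the same class as `moving`, on the exhale grid.
#' @export
pull_values <- function(field, moving, interp = c("trilinear", "nearest"),
                        fill = NA_real_) {
  interp <- match.arg(interp)
  stopifnot(inherits(field, "disp_field"))
  if (!all(is.finite(moving$values))) stop_("moving image contains non-finite values")
  dm <- field$dim
  ijk <- arrayInd(seq_len(prod(dm)), dm)
  w <- world_coords(ijk, field$spacing, field$origin)
  tgt <- w + cbind(as.numeric(field$u[, , , 1L]),
                   as.numeric(field$u[, , , 2L]),
                   as.numeric(field$u[, , , 3L]))
  g <- world_to_grid(tgt, moving)
  vals <- sample_grid(moving$values, g[, 1L], g[, 2L], g[, 3L],
                      method = interp, fill = fill)
  oob <- attr(vals, "oob")
  out_arr <- array(as.numeric(vals), dm)
  cls <- class(moving)
  out <- if (identical(cls, "hu_image") && !anyNA(out_arr)) {
    hu_image(out_arr, field$spacing, field$origin)
  } else {
    # NA fill or non-HU payload: bypass range validation, keep metadata
    structure(list(values = out_arr, spacing = field$spacing,
                   origin = field$origin, dim = dm), class = cls)
  }
  attr(out, "oob") <- array(oob, dm)
  attr(out, "oob_count") <- sum(oob)
  out
}

# Interpolate displacement vectors at world points (N x 3); grid coordinates
# are clamped to the field support so voxel-corner lookups at the volume edge
# extrapolate flatly.
field_at_points <- function(field, pts, clamp = TRUE) {
  g <- cbind((pts[, 1L] - field$origin[1L]) / field$spacing[1L] + 1,
             (pts[, 2L] - field$origin[2L]) / field$spacing[2L] + 1,
             (pts[, 3L] - field$origin[3L]) / field$spacing[3L] + 1)
  dm <- field$dim
  if (clamp) {
    g[, 1L] <- pmin(pmax(g[, 1L], 1), dm[1L])
    g[, 2L] <- pmin(pmax(g[, 2L], 1), dm[2L])
    g[, 3L] <- pmin(pmax(g[, 3L], 1), dm[3L])
  }
  cbind(sample_grid(field$u[, , , 1L], g[, 1L], g[, 2L], g[, 3L]),
        sample_grid(field$u[, , , 2L], g[, 1L], g[, 2L], g[, 3L]),
        sample_grid(field$u[, , , 3L], g[, 1L], g[, 2L], g[, 3L]))
}
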