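#' Partition a lung mask into overlapping cubic subregions
#'
#' Slides a cubic window of `window` voxels per axis across the mask bounding
#' grid in steps of `stride`, clips each window to the mask, and keeps windows
#' holding at least 8 lung voxels. A trailing window flush with each axis end
#' is always included so the sweep reaches the boundary. With
#' `stride == window` the kept regions tile the mask disjointly; with
#' `stride < window` they overlap, which the voxelwise reconstruction needs
#' in order not to be underdetermined inside regions.
#'
#' @param mask a [lung_mask()].
#' @param window voxels per axis of the cubic window (>= 2).
#' @param stride step in voxels, `1 <= stride <= window`.
#' @param tau tolerance parameter (> 0): the relative standard-error bound
#'   carried to subregional estimators such as [hit_or_miss_volume()].
#' @return A `subregion_partition`: list of voxel-index vectors (linear
#'   indices into the mask grid) plus grid metadata.
#' @examples
#' m <- lung_mask(array(TRUE, c(8, 8, 8)))
#' length(build_partition(m, window = 4, stride = 4)$regions)  # 8 tiles
#' length(build_partition(m, window = 4, stride = 2)$regions)  # 27 windows
#' @export
build_partition <- function(mask, window = 8L, stride = 4L, tau = 0.01) {
  stopifnot(inherits(mask, "lung_mask"))
  window <- as.integer(window); stride <- as.integer(stride)
  if (window < 2L) stop_("window must be >= 2 voxels")
  if (stride < 1L || stride > window) stop_("stride must satisfy 1 <= stride <= window")
  if (!is.finite(tau) || tau <= 0) stop_("tau must be > 0")
  dm <- mask$dim
  m <- mask$values
  starts <- lapply(dm, function(n) {
    last <- max(1L, n - window + 1L)
    unique(c(seq.int(1L, last, by = stride), last))
  })
  regions <- list()
  centers <- list()
  covered <- array(FALSE, dm)
  for (sz in starts[[3L]]) for (sy in starts[[2L]]) for (sx in starts[[1L]]) {
    ex <- min(sx + window - 1L, dm[1L])
    ey <- min(sy + window - 1L, dm[2L])
    ez <- min(sz + window - 1L, dm[3L])
    sub <- m[sx:ex, sy:ey, sz:ez, drop = FALSE]
    if (sum(sub) < 8L) next
    loc <- which(sub)
    ijk <- arrayInd(loc, dim(sub))
    ijk[, 1L] <- ijk[, 1L] + sx - 1L
    ijk[, 2L] <- ijk[, 2L] + sy - 1L
    ijk[, 3L] <- ijk[, 3L] + sz - 1L
    lin <- lin_index(ijk, dm)
    regions[[length(regions) + 1L]] <- lin
    centers[[length(centers) + 1L]] <- colMeans(ijk)
    covered[lin] <- TRUE
  }
  uncovered <- sum(m & !covered)
  if (uncovered > 0L)
    stop_("partition does not cover the mask: %d lung voxel(s) fall in no kept window (isolated voxels?)", uncovered)
  if (!length(regions)) stop_("no subregion holds >= 8 lung voxels")
  structure(list(regions = regions,
                 centers = do.call(rbind, centers),
                 window = window, stride = stride, tau = tau,
                 dim = dm, spacing = mask$spacing, origin = mask$origin),
            class = "subregion_partition")
}

#' @exportS3Method base::print
print.subregion_partition <- function(x, ...) {
  sizes <- lengths(x$regions)
  cat(sprintf("<subregion_partition> %d regions (window %d, stride %d, tau %.4g), %d-%d voxels each\n",
              length(x$regions), x$window, x$stride, x$tau, min(sizes), max(sizes)))
  invisible(x)
}
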