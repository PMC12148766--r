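# Tolerance-controlled subregional estimators: deformed volumes (exact and
# hit-or-miss), density-ratio Jacobians, and mean-magnitude mass changes.

# Five-tetrahedron decomposition of the unit cube, corner slots numbered
# 1..8 = (000,100,010,110,001,101,011,111). Adjacent cubes use mirrored
# ("odd parity") tables so shared faces carry matching diagonals; vertex
# orders are fixed so signed volumes are positive for the identity map.
TET5_EVEN <- rbind(c(1, 2, 3, 5), c(4, 3, 2, 8), c(6, 5, 8, 2),
                   c(7, 8, 5, 3), c(2, 3, 5, 8))
TET5_ODD <- rbind(c(2, 1, 6, 4), c(3, 4, 7, 1), c(5, 6, 1, 7),
                  c(8, 7, 4, 6), c(1, 4, 7, 6))
CORNER_BITS <- as.matrix(expand.grid(bx = 0:1, by = 0:1, bz = 0:1))

# Decompose a region's voxel cells into tetrahedra and map their corner
# vertices through the trilinearly interpolated displacement field.
# Returns mapped vertices (V x 3, mm) and tetrahedron index rows (T x 4).
region_tetrahedra <- function(field, region) {
  dm <- field$dim
  sp <- field$spacing; org <- field$origin
  ijk <- arrayInd(region, dm)
  nvox <- nrow(ijk)
  # voxel corners live on the corner grid c in 0..n per axis (corner c sits
  # between voxel centers c and c+1, world = origin + (c - 0.5) * spacing)
  keys <- matrix(0, nvox, 8L)
  for (b in 1:8) {
    cx <- ijk[, 1L] - 1L + CORNER_BITS[b, 1L]
    cy <- ijk[, 2L] - 1L + CORNER_BITS[b, 2L]
    cz <- ijk[, 3L] - 1L + CORNER_BITS[b, 3L]
    keys[, b] <- cx + cy * (dm[1L] + 1) + cz * (dm[1L] + 1) * (dm[2L] + 1)
  }
  uk <- sort(unique(as.vector(keys)))
  vid <- matrix(match(keys, uk), nvox, 8L)
  cz <- uk %/% ((dm[1L] + 1) * (dm[2L] + 1))
  rem <- uk %% ((dm[1L] + 1) * (dm[2L] + 1))
  cy <- rem %/% (dm[1L] + 1)
  cx <- rem %% (dm[1L] + 1)
  world <- cbind(org[1L] + (cx - 0.5) * sp[1L],
                 org[2L] + (cy - 0.5) * sp[2L],
                 org[3L] + (cz - 0.5) * sp[3L])
  u <- field_at_points(field, world, clamp = TRUE)
  verts <- world + u
  parity <- (ijk[, 1L] + ijk[, 2L] + ijk[, 3L]) %% 2L
  tets <- matrix(0L, nvox * 5L, 4L)
  for (tt in 1:5) {
    tab <- rbind(TET5_EVEN[tt, ], TET5_ODD[tt, ])
    sel <- tab[parity + 1L, , drop = FALSE]
    rows <- seq.int(tt, by = 5L, length.out = nvox)
    for (c in 1:4) tets[rows, c] <- vid[cbind(seq_len(nvox), sel[, c])]
  }
  list(verts = verts, tets = tets)
}

tet_signed_volumes <- function(verts, tets) {
  a <- verts[tets[, 2L], , drop = FALSE] - verts[tets[, 1L], , drop = FALSE]
  b <- verts[tets[, 3L], , drop = FALSE] - verts[tets[, 1L], , drop = FALSE]
  cc <- verts[tets[, 4L], , drop = FALSE] - verts[tets[, 1L], , drop = FALSE]
  (a[, 1L] * (b[, 2L] * cc[, 3L] - b[, 3L] * cc[, 2L]) -
     a[, 2L] * (b[, 1L] * cc[, 3L] - b[, 3L] * cc[, 1L]) +
     a[, 3L] * (b[, 1L] * cc[, 2L] - b[, 2L] * cc[, 1L])) / 6
}

#' Exact deformed volume of a subregion
#'
#' Decomposes each voxel cell of the region into 5 tetrahedra, maps the
#' corners through the displacement field, and sums absolute signed
#' tetrahedron volumes. Serves as the brute-force oracle for
#' [hit_or_miss_volume()].
#'
#' @param field a [disp_field()].
#' @param region integer vector of linear voxel indices on the field grid.
#' @return Deformed volume in mm^3, with attribute `"folded"` counting
#'   tetrahedra with non-positive orientation (a warning is raised if any).
#' @export
exact_deformed_volume <- function(field, region) {
  if (!length(region)) stop_("region is empty")
  rt <- region_tetrahedra(field, region)
  sv <- tet_signed_volumes(rt$verts, rt$tets)
  folded <- sum(sv <= 0)
  if (folded > 0L)
    warning(sprintf("%d mapped tetrahedra have non-positive orientation (folding)", folded),
            call. = FALSE)
  structure(sum(abs(sv)), folded = folded)
}

#' Hit-or-miss Monte Carlo deformed-volume estimate
#'
#' Represents the deformed region as the union of mapped tetrahedra, samples
#' `N` points uniformly in the mapped-vertex bounding box, and estimates the
#' volume as (hit fraction) x (box volume). `N` is the smallest sample count
#' for which the worst-case binomial standard error of the estimate is at
#' most `tau` times the box volume, i.e. `N = ceiling(0.25 / tau^2)` (the
#' binomial variance `p(1-p)/N` is maximal at `p = 1/2`). The reported
#' standard error uses the plug-in variance with the hit fraction floored at
#' `1/N` so it is defined even at zero hits.
#'
#' @inheritParams exact_deformed_volume
#' @param tau relative standard-error tolerance (> 0).
#' @param seed optional integer seed; the estimate is a deterministic
#'   function of (inputs, seed).
#' @return A one-row data.frame (class `regional_estimate`): `value` (mm^3),
#'   `se`, `n_samples`.
#' @export
hit_or_miss_volume <- function(field, region, tau = 0.01, seed = NULL) {
  if (!length(region)) stop_("region is empty")
  if (!is.finite(tau) || tau <= 0) stop_("tau must be > 0")
  rt <- region_tetrahedra(field, region)
  lo <- apply(rt$verts, 2L, min)
  hi <- apply(rt$verts, 2L, max)
  if (any(hi - lo <= 0)) stop_("degenerate bounding box for deformed region")
  boxvol <- prod(hi - lo)
  n <- as.integer(ceiling(0.25 / tau^2))
  pts <- with_seed(seed, {
    matrix(runif(3L * n), n, 3L)
  })
  pts <- sweep(sweep(pts, 2L, hi - lo, "*"), 2L, lo, "+")
  hits <- hitmiss_hits(rt$verts, rt$tets, pts)
  phat <- hits / n
  pfl <- max(phat, 1 / n)
  se <- boxvol * sqrt(pfl * (1 - pfl) / n)
  structure(data.frame(value = phat * boxvol, se = se, n_samples = n),
            class = c("regional_estimate", "data.frame"))
}

#' Mass-conserving subregional Jacobian estimate
#'
#' Estimates the mean subregional volume-change factor as the ratio of the
#' mean exhale density over the region (fixed side) to the mean inhale
#' density sampled at the mapped points `x + u(x)` of the region's voxels.
#' Under mass conservation this ratio equals the mean Jacobian of the
#' transform over the region. The standard error is propagated from the two
#' within-region sample variances (delta method, covariance neglected).
#'
#' @param rho_ex,rho_in exhale and inhale [density_image()]s.
#' @param field a [disp_field()] on the exhale grid.
#' @param region integer vector of linear voxel indices.
#' @param density_floor reject regions whose mean mapped density falls at or
#'   below this value (default 0.01).
#' @return A `regional_estimate` row: `value` (dimensionless), `se`,
#'   `n_samples`.
#' @export
mcvc_regional_jacobian <- function(rho_ex, rho_in, field, region,
                                   density_floor = 0.01) {
  if (!length(region)) stop_("region is empty")
  dm <- field$dim
  ijk <- arrayInd(region, dm)
  w <- world_coords(ijk, field$spacing, field$origin)
  u <- field_at_points(field, w)
  g <- world_to_grid(w + u, rho_in)
  samp <- sample_grid(rho_in$values, g[, 1L], g[, 2L], g[, 3L])
  if (anyNA(samp))
    stop_("region maps outside the inhale density grid")
  ex <- rho_ex$values[region]
  m1 <- mean(ex); m2 <- mean(samp)
  if (m2 <= density_floor)
    stop_("mean mapped inhale density %.4g at or below floor %.4g for region (first voxel %d)",
          m2, density_floor, region[1L])
  n <- length(region)
  v1 <- var(ex) / n; v2 <- var(samp) / n
  value <- m1 / m2
  se <- sqrt(v1 / m2^2 + m1^2 * v2 / m2^4)
  structure(data.frame(value = value, se = se, n_samples = n),
            class = c("regional_estimate", "data.frame"))
}

#' Subregional mean-magnitude mass change
#'
#' Computes the per-voxel mass change (per unit exhale voxel volume)
#' `dm(x) = J(x) * rho_in(x + u(x)) - rho_ex(x)` and returns the mean of its
#' magnitude over the region. Under exact mass conservation the value is
#' zero; breathing-induced blood-mass redistribution makes it positive.
#'
#' @inheritParams mcvc_regional_jacobian
#' @param jacobian a [function_image()] of kind `"jacobian"` defined on the
#'   region's voxels.
#' @return A `regional_estimate` row: `value` (density units, >= 0), `se`,
#'   `n_samples`. The signed per-voxel changes are attached as attribute
#'   `"signed"` for diagnostics.
#' @export
perf_regional_masschange <- function(rho_ex, rho_in, field, jacobian, region) {
  if (!length(region)) stop_("region is empty")
  J <- jacobian$values[region]
  if (anyNA(J)) stop_("jacobian undefined on %d region voxel(s)", sum(is.na(J)))
  dm <- field$dim
  ijk <- arrayInd(region, dm)
  w <- world_coords(ijk, field$spacing, field$origin)
  u <- field_at_points(field, w)
  g <- world_to_grid(w + u, rho_in)
  samp <- sample_grid(rho_in$values, g[, 1L], g[, 2L], g[, 3L])
  if (anyNA(samp)) stop_("region maps outside the inhale density grid")
  dmass <- J * samp - rho_ex$values[region]
  n <- length(region)
  out <- structure(data.frame(value = mean(abs(dmass)),
                              se = sd(abs(dmass)) / sqrt(n),
                              n_samples = n),
                   class = c("regional_estimate", "data.frame"))
  attr(out, "signed") <- dmass
  out
}
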