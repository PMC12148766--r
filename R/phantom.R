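#' Analytic transforms for phantom generation
#'
#' Phantom deformations are restricted to families with closed-form spatial
#' gradients so the Jacobian determinant ground truth is exact:
#' `affine_transform` maps `x -> center + A (x - center)`;
#' `poly_transform` applies an independent monotone polynomial per axis,
#' `x_i -> center_i + sum_k c_ik (x_i - center_i)^k`.
#'
#' @param A 3x3 matrix with positive determinant.
#' @param center length-3 world coordinate (mm) the transform is anchored at.
#' @param coefs list of 3 numeric coefficient vectors (degree 1 upward), one
#'   per axis; the first coefficient is the linear term and must keep the
#'   per-axis derivative positive over the grid.
#' @return A transform specification used by [make_phantom()].
#' @export
affine_transform <- function(A, center = c(0, 0, 0)) {
  A <- matrix(as.numeric(A), 3, 3)
  if (det(A) <= 0) stop_("affine transform must have positive determinant")
  structure(list(type = "affine", A = A, center = as.numeric(center)),
            class = "phantom_transform")
}

#' @rdname affine_transform
#' @export
poly_transform <- function(coefs, center = c(0, 0, 0)) {
  stopifnot(is.list(coefs), length(coefs) == 3L)
  structure(list(type = "polynomial", coefs = lapply(coefs, as.numeric),
                 center = as.numeric(center)),
            class = "phantom_transform")
}

# phi(X) for N x 3 world points
transform_phi <- function(tr, X) {
  ctr <- tr$center
  if (tr$type == "affine") {
    sweep(sweep(X, 2, ctr) %*% t(tr$A), 2, ctr, "+")
  } else {
    out <- X
    for (ax in 1:3) {
      t <- X[, ax] - ctr[ax]
      acc <- 0
      for (k in seq_along(tr$coefs[[ax]])) acc <- acc + tr$coefs[[ax]][k] * t^k
      out[, ax] <- ctr[ax] + acc
    }
    out
  }
}

# gradient of u = phi - id, as a list of 9 vectors g[[i]][[j]] = d u_i / d x_j
transform_grad_u <- function(tr, X) {
  n <- nrow(X)
  G <- vector("list", 9L)
  if (tr$type == "affine") {
    AI <- tr$A - diag(3)
    for (i in 1:3) for (j in 1:3) G[[(i - 1) * 3 + j]] <- rep(AI[i, j], n)
  } else {
    zero <- numeric(n)
    for (i in 1:3) for (j in 1:3) G[[(i - 1) * 3 + j]] <- zero
    for (ax in 1:3) {
      t <- X[, ax] - tr$center[ax]
      d <- 0
      for (k in seq_along(tr$coefs[[ax]])) d <- d + k * tr$coefs[[ax]][k] * t^(k - 1)
      G[[(ax - 1) * 3 + ax]] <- d - 1
    }
  }
  G
}

# C1 radial bump with a plateau core: K = 1 for t <= c, smooth quartic ramp
# to 0 at t = 1. The plateau makes the displacement vanish identically in the
# defect core (for strength 1), so the core Jacobian is exactly 1.
BUMP_CORE <- 0.5
bump_k <- function(t, c = BUMP_CORE) {
  s <- pmin(pmax((t - c) / (1 - c), 0), 1)
  (1 - s^2)^2
}
bump_k_prime <- function(t, c = BUMP_CORE) {
  s <- (t - c) / (1 - c)
  ifelse(t > c & t < 1, -4 * s * (1 - s^2) / (1 - c), 0)
}

defect_alpha <- function(defect, X) {
  if (is.null(defect)) return(list(alpha = rep(1, nrow(X)),
                                   grad = matrix(0, nrow(X), 3)))
  d <- sweep(X, 2, defect$center)
  r <- sqrt(rowSums(d^2))
  t <- r / defect$radius
  alpha <- 1 - defect$strength * bump_k(t)
  dadr <- -defect$strength * bump_k_prime(t) / defect$radius
  unit <- d / pmax(r, .Machine$double.eps)
  list(alpha = alpha, grad = unit * dadr)
}

# total displacement u(x) = alpha(x) * (phi(x) - x), analytic at any point
phantom_u <- function(tr, defect, X) {
  u <- transform_phi(tr, X) - X
  defect_alpha(defect, X)$alpha * u
}

# exact Jacobian determinant of x + alpha(x) u(x) via the matrix determinant
# lemma: det(M0 + u grad_alpha^T) = det(M0) + grad_alpha^T adj(M0) u
phantom_jacobian_at <- function(tr, defect, X) {
  u <- transform_phi(tr, X) - X
  G <- transform_grad_u(tr, X)
  da <- defect_alpha(defect, X)
  a <- da$alpha
  m <- function(i, j) (if (i == j) 1 else 0) + a * G[[(i - 1) * 3 + j]]
  m11 <- m(1, 1); m12 <- m(1, 2); m13 <- m(1, 3)
  m21 <- m(2, 1); m22 <- m(2, 2); m23 <- m(2, 3)
  m31 <- m(3, 1); m32 <- m(3, 2); m33 <- m(3, 3)
  adj11 <- m22 * m33 - m23 * m32; adj12 <- m13 * m32 - m12 * m33; adj13 <- m12 * m23 - m13 * m22
  adj21 <- m23 * m31 - m21 * m33; adj22 <- m11 * m33 - m13 * m31; adj23 <- m13 * m21 - m11 * m23
  adj31 <- m21 * m32 - m22 * m31; adj32 <- m12 * m31 - m11 * m32; adj33 <- m11 * m22 - m12 * m21
  det0 <- m11 * adj11 + m12 * adj21 + m13 * adj31
  v <- da$grad
  det0 +
    v[, 1] * (adj11 * u[, 1] + adj12 * u[, 2] + adj13 * u[, 3]) +
    v[, 2] * (adj21 * u[, 1] + adj22 * u[, 2] + adj23 * u[, 3]) +
    v[, 3] * (adj31 * u[, 1] + adj32 * u[, 2] + adj33 * u[, 3])
}

# invert y = x + u(x) by damped fixed-point iteration (u is a contraction for
# the small tidal-breathing deformations the phantom uses)
phantom_inverse <- function(tr, defect, Y, iter = 60L, tol = 1e-12) {
  X <- Y
  for (it in seq_len(iter)) {
    U <- phantom_u(tr, defect, X)
    Xn <- Y - U
    delta <- max(abs(Xn - X))
    X <- Xn
    if (delta < tol) break
  }
  X
}

#' Generate a mass-consistent 4DCT phantom with analytic ground truth
#'
#' Builds an exhale/inhale HU pair related by a known analytic deformation.
#' The scene is an ellipsoidal "lung" of low density (default 0.2, with a
#' smooth cosine texture) embedded in water-like body tissue. The inhale
#' density is constructed to conserve mass under the transform,
#' `rho_in(x + u(x)) = rho_ex(x) / J(x)`, so every voxel's volume change is
#' known exactly. A ventilation defect attenuates the local expansion toward
#' 1 by scaling the displacement inside a sphere (the Jacobian ground truth
#' accounts for the attenuation gradient exactly); a perfusion anomaly
#' implants a known per-voxel mass change. Gaussian HU noise is added last.
#'
#' The returned analysis `mask` is the anatomical lung eroded by
#' `mask_margin_vox` voxels, emulating the clinical exclusion of the lung
#' boundary, airways and vasculature, and keeping interpolation at mapped
#' points inside lung parenchyma.
#'
#' @param shape grid size per axis (each >= 32).
#' @param spacing,origin grid geometry (mm).
#' @param transform a [affine_transform()] or [poly_transform()]; default is
#'   uniform expansion with Jacobian 1.15 (typical tidal volume change)
#'   anchored at the lung center.
#' @param defect `NULL` or `list(center=, radius=, strength=)` (mm, mm,
#'   0..1): ventilation defect attenuating local expansion toward 1. The
#'   attenuation is full inside the plateau core `r < radius/2` (so with
#'   strength 1 the core Jacobian is exactly 1) and ramps smoothly to zero
#'   at `r = radius`; `truth$defect_mask` marks the core.
#' @param perfusion `NULL` or `list(center=, radius=, delta=)`: uniform
#'   implanted mass change (density units per exhale voxel volume).
#' @param noise_sd_hu Gaussian HU noise standard deviation (default 20,
#'   typical 4DCT noise); 0 disables.
#' @param seed integer seed for the noise; same seed gives bit-identical
#'   output.
#' @param lung_semiaxes ellipsoid semi-axes in mm (default 0.33 of extent).
#' @param mask_margin_vox erosion margin of the analysis mask, in voxels.
#' @param rho_base,texture_amp exhale lung density level and relative
#'   texture amplitude.
#' @return A list of class `phantom`: `exhale`, `inhale` ([hu_image()]s),
#'   `field` ([disp_field()]), `mask`, `mask_in` ([lung_mask()]s on the
#'   exhale and inhale grids), and `truth` with arrays `jacobian`,
#'   `defect_mask`, `mass_change`, `density_ex`, `sv_air` (the air-based
#'   specific volume change the two-material model predicts,
#'   `(J - 1) / (1 - rho_ex)`), plus the seed.
#' @export
make_phantom <- function(shape = c(48, 48, 48), spacing = c(2, 2, 2),
                         origin = c(0, 0, 0), transform = NULL,
                         defect = NULL, perfusion = NULL,
                         noise_sd_hu = 20, seed = NULL,
                         lung_semiaxes = NULL, mask_margin_vox = 2,
                         rho_base = 0.2, texture_amp = 0.15) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  if (any(shape < 32L)) stop_("phantom grid must be at least 32 voxels per axis")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  extent <- (shape - 1) * spacing
  lung_center <- origin + extent / 2
  semi <- lung_semiaxes %||% (0.33 * extent)
  if (is.null(transform)) {
    s <- 1.15^(1 / 3)
    transform <- affine_transform(diag(rep(s, 3)), center = lung_center)
  }
  stopifnot(inherits(transform, "phantom_transform"))

  n <- prod(shape)
  ijk <- arrayInd(seq_len(n), shape)
  X <- world_coords(ijk, spacing, origin)

  ellip_t <- function(P, margin_mm = 0) {
    s2 <- pmax(semi - margin_mm, 1e-6)
    rowSums(sweep(sweep(P, 2, lung_center), 2, s2, "/")^2)
  }
  rho_fun <- function(P) {
    inside <- ellip_t(P) < 1
    tex <- rho_base * (1 + texture_amp *
                         cos(2 * pi * (P[, 1] - lung_center[1]) / semi[1]) *
                         cos(2 * pi * (P[, 2] - lung_center[2]) / semi[2]) *
                         cos(2 * pi * (P[, 3] - lung_center[3]) / semi[3]))
    ifelse(inside, tex, 1.0)
  }
  delta_fun <- function(P) {
    if (is.null(perfusion)) return(numeric(nrow(P)))
    r2 <- rowSums(sweep(P, 2, perfusion$center)^2)
    ifelse(r2 < perfusion$radius^2, perfusion$delta, 0)
  }

  margin_mm <- mask_margin_vox * max(spacing)
  mask_arr <- array(ellip_t(X, margin_mm) < 1, shape)
  if (!any(mask_arr)) stop_("phantom lung mask is empty; enlarge the grid or semi-axes")

  # forward quantities on the exhale grid
  U <- phantom_u(transform, defect, X)
  J <- phantom_jacobian_at(transform, defect, X)
  if (min(J[mask_arr]) <= 0)
    stop_("transform is not orientation-preserving: Jacobian <= 0 inside the lung mask")
  rho_ex <- rho_fun(X)

  # mass-consistent inhale scene on its own grid: rho_in(y) = (rho_ex + delta)/J at x = phi^-1(y)
  Xi <- phantom_inverse(transform, defect, X)
  Ji <- phantom_jacobian_at(transform, defect, Xi)
  rho_in <- (rho_fun(Xi) + delta_fun(Xi)) / Ji
  mask_in_arr <- array(ellip_t(Xi, margin_mm) < 1, shape)

  clamp_hu <- function(h) pmin(pmax(h, -1024), 3071)
  hu_ex <- density_to_hu(rho_ex)
  hu_in <- density_to_hu(rho_in)
  if (noise_sd_hu > 0) {
    noise <- with_seed(seed, rnorm(2L * n, sd = noise_sd_hu))
    hu_ex <- hu_ex + noise[seq_len(n)]
    hu_in <- hu_in + noise[n + seq_len(n)]
  }
  hu_ex <- array(clamp_hu(hu_ex), shape)
  hu_in <- array(clamp_hu(hu_in), shape)

  # the defect core: the fully attenuated plateau region (r < radius/2)
  defect_mask <- if (is.null(defect)) array(FALSE, shape) else {
    array(rowSums(sweep(X, 2, defect$center)^2) <
            (BUMP_CORE * defect$radius)^2, shape) & mask_arr
  }
  sv_air <- ifelse(rho_ex < 1, (J - 1) / (1 - rho_ex), NA_real_)

  structure(list(
    exhale = hu_image(hu_ex, spacing, origin),
    inhale = hu_image(hu_in, spacing, origin),
    field = disp_field(array(U, c(shape, 3L)), spacing, origin),
    mask = lung_mask(mask_arr, spacing, origin),
    mask_in = lung_mask(mask_in_arr, spacing, origin),
    truth = list(jacobian = array(J, shape),
                 defect_mask = defect_mask,
                 mass_change = array(delta_fun(X), shape) * ifelse(mask_arr, 1, 0),
                 density_ex = array(rho_ex, shape),
                 density_in = array(rho_in, shape),
                 sv_air = array(sv_air, shape),
                 seed = seed),
    transform = transform, defect = defect, perfusion = perfusion,
    lung_center = lung_center, lung_semiaxes = semi,
    noise_sd_hu = noise_sd_hu),
    class = "phantom")
}

#' @exportS3Method base::print
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s grid, %d lung voxels, J range [%.3f, %.3f], noise %.0f HU\n",
              paste(x$exhale$dim, collapse = "x"), sum(x$mask$values),
              min(x$truth$jacobian[x$mask$values]),
              max(x$truth$jacobian[x$mask$values]), x$noise_sd_hu))
  invisible(x)
}

#' Synthetic conformal dose grid
#'
#' Prescription dose inside a spherical target with deterministic Gaussian
#' radial falloff outside, a simple stand-in for a conformal plan.
#'
#' @param shape,spacing,origin grid geometry.
#' @param target_center world coordinate (mm) of the target; must be inside
#'   the grid.
#' @param target_radius target sphere radius (mm).
#' @param prescription_gy prescription dose (Gy, > 0).
#' @param falloff_mm Gaussian falloff scale outside the target surface;
#'   `Inf` gives a uniform prescription everywhere.
#' @return A `dose_grid` (values in Gy, >= 0).
#' @export
make_dose <- function(shape, spacing = c(2, 2, 2), origin = c(0, 0, 0),
                      target_center, target_radius = 20,
                      prescription_gy = 60, falloff_mm = 15) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  if (prescription_gy <= 0) stop_("prescription must be > 0")
  lo <- origin; hi <- origin + (shape - 1) * spacing
  if (any(target_center < lo) || any(target_center > hi))
    stop_("target center lies outside the dose grid")
  ijk <- arrayInd(seq_len(prod(shape)), shape)
  X <- world_coords(ijk, spacing, origin)
  r <- sqrt(rowSums(sweep(X, 2, target_center)^2))
  d <- pmax(r - target_radius, 0)
  dose <- if (is.infinite(falloff_mm)) rep(prescription_gy, length(r)) else
    prescription_gy * exp(-d^2 / (2 * falloff_mm^2))
  grid_obj(array(dose, shape), spacing, origin, "dose_grid",
           validate = function(v) check_finite(v, "dose grid"))
}

# Right/left lung lobes used for reader-call locations.
LUNG_LOBES <- c("RUL", "RML", "RLL", "LUL", "LLL")

#' Simulate binary radiologist defect calls
#'
#' Each truly-positive case is called positive with probability
#' `sensitivity`; each truly-negative case is called negative with
#' probability `specificity`. Positive calls on true defects carry the true
#' lobe with probability `1 - location_error_rate` and a random other lobe
#' otherwise; false-positive calls get a random lobe. Negative calls have
#' location `"none"`.
#'
#' @param truth logical vector of per-case defect presence.
#' @param sensitivity,specificity,location_error_rate rates in \[0, 1\].
#' @param true_lobes character vector of true defect lobes (from RUL, RML,
#'   RLL, LUL, LLL); sampled uniformly where missing.
#' @param method label stored in the `method` column.
#' @param patients patient identifiers (default `seq_along(truth)`).
#' @param seed integer seed; calls are reproducible given the seed.
#' @return A data.frame with columns `patient`, `method`, `call` (logical),
#'   `location`.
#' @export
simulate_reader <- function(truth, sensitivity = 0.9, specificity = 0.9,
                            location_error_rate = 0.1, true_lobes = NULL,
                            method = "reader", patients = NULL, seed = NULL) {
  truth <- as.logical(truth)
  rates <- c(sensitivity, specificity, location_error_rate)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1))
    stop_("sensitivity, specificity and location_error_rate must lie in [0, 1]")
  n <- length(truth)
  patients <- patients %||% seq_len(n)
  with_seed(seed, {
    if (is.null(true_lobes)) true_lobes <- sample(LUNG_LOBES, n, replace = TRUE)
    call <- ifelse(truth, runif(n) < sensitivity, runif(n) >= specificity)
    loc <- rep("none", n)
    pos <- which(call)
    for (i in pos) {
      if (truth[i] && runif(1) >= location_error_rate) {
        loc[i] <- true_lobes[i]
      } else if (truth[i]) {
        loc[i] <- sample(setdiff(LUNG_LOBES, true_lobes[i]), 1L)
      } else {
        loc[i] <- sample(LUNG_LOBES, 1L)
      }
    }
    data.frame(patient = patients, method = method, call = call,
               location = loc, stringsAsFactors = FALSE)
  })
}
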