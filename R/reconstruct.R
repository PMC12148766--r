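#' Reconstruction configuration
#'
#' Parameters of the voxelwise constrained least-squares recovery.
#'
#' @param lower_bound lower bound on the recovered voxel values (default
#'   0.05, the physical floor on a Jacobian; pass 0 for mass-change images).
#' @param smooth_scale correlation length of the roughness prior in units of
#'   the partition window (default 2). Subregional means alone constrain
#'   nothing at the voxel level (a nontrivial null space), so a
#'   first-difference roughness penalty selects the smooth representative;
#'   its weight is derived per problem as
#'   `lambda = d * (smooth_scale * window / 2)^2`, where `d` is the mean
#'   per-voxel curvature of the weighted data term, which makes the
#'   effective averaging kernel of the recovery a fixed spatial width
#'   (about one window radius per unit of `smooth_scale`) regardless of how
#'   precise the regional estimates are. Constant fields are never biased
#'   (first differences vanish on them).
#' @param lambda optional absolute roughness weight overriding the
#'   `smooth_scale` heuristic (>= 0).
#' @param se_floor regional standard errors are floored at this value before
#'   weighting by `1/SE^2`, preventing infinite weights on noise-free
#'   estimates.
#' @param tol relative residual tolerance of the inner conjugate-gradient
#'   solve.
#' @param max_iter maximum conjugate-gradient iterations per active-set
#'   pass.
#' @return A list of class `reconstruction_config`.
#' @export
reconstruction_config <- function(lower_bound = 0.05, smooth_scale = 2,
                                  lambda = NULL, se_floor = 1e-3,
                                  tol = 1e-9, max_iter = 5000L) {
  if (lower_bound < 0) stop_("lower_bound must be >= 0")
  if (!is.null(lambda) && lambda < 0) stop_("lambda must be >= 0")
  if (smooth_scale < 0) stop_("smooth_scale must be >= 0")
  structure(list(lower_bound = lower_bound, smooth_scale = smooth_scale,
                 lambda = lambda, se_floor = se_floor, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "reconstruction_config")
}

# projection onto { j >= lb } intersected (optionally) with { sum(c*j) = V }.
# c is the constant per-voxel volume, so the equality projection reduces to a
# 1-D monotone root-find in the shift multiplier, solved by bisection.
project_feasible <- function(z, lb, cvol = NULL, V = NULL) {
  if (is.null(V)) return(pmax(z, lb))
  g <- function(theta) sum(cvol * pmax(lb, z - theta * cvol)) - V
  lo <- -1; hi <- 1
  while (g(lo) < 0) lo <- lo * 2
  while (g(hi) > 0) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-15 * max(1, abs(mid))) break
  }
  pmax(lb, z - (lo + hi) / 2 * cvol)
}

# Active-set solver for  min 1/2 x'Hx - b'x  s.t. x >= lb, optionally
# c'x = V, with H available only as an operator. The bound-active set is
# refined outside an inner (equality-)projected conjugate-gradient solve;
# the weighted-data + small-roughness Hessian has a tightly two-clustered
# spectrum, which CG resolves in a few dozen iterations where gradient
# methods crawl.
solve_qp_active_set <- function(hmul, b, lb, cvol = NULL, V = NULL, x0,
                                tol = 1e-9, max_cg = 5000L,
                                max_outer = 40L) {
  p <- length(b)
  pinned <- logical(p)
  x <- project_feasible(x0, lb, cvol, V)
  total_cg <- 0L
  kkt_tol <- tol * max(1, sqrt(sum(b^2) / p)) * 10
  for (outer in seq_len(max_outer)) {
    free <- !pinned
    cF <- if (is.null(V)) NULL else cvol[free]
    projc <- function(y) if (is.null(cF)) y else y - cF * sum(cF * y) / sum(cF * cF)
    # feasible start on the free set
    xF <- x[free]
    if (!is.null(V)) {
      resid_V <- V - sum(cvol[pinned] * lb) - sum(cF * xF)
      xF <- xF + cF * resid_V / sum(cF * cF)
    }
    full <- function(y) { z <- numeric(p); z[pinned] <- lb; z[free] <- y; z }
    fullz <- function(y) { z <- numeric(p); z[free] <- y; z }
    hF <- function(y) hmul(fullz(y))[free]
    rhs <- b[free] - (if (any(pinned)) hmul(full(numeric(sum(free))))[free] else 0)
    r <- projc(rhs - hF(xF))
    d <- r
    rs <- sum(r^2)
    rhs_norm <- max(sqrt(sum(rhs^2)), .Machine$double.eps)
    cg_it <- 0L
    while (sqrt(rs) > tol * rhs_norm && cg_it < max_cg) {
      cg_it <- cg_it + 1L
      Hd <- projc(hF(d))
      dHd <- sum(d * Hd)
      if (dHd <= 0) break  # null-space direction: current iterate is optimal there
      a <- rs / dHd
      xF <- xF + a * d
      r <- r - a * Hd
      rs_new <- sum(r^2)
      d <- r + (rs_new / rs) * d
      rs <- rs_new
      if (cg_it %% 50L == 0L) {  # re-project to fight drift
        r <- projc(rhs - hF(xF)); d <- projc(d); rs <- sum(r^2)
      }
    }
    total_cg <- total_cg + cg_it
    x <- full(xF)
    viol <- free & (x < lb - 1e-12 * max(1, abs(lb)))
    if (any(viol)) {
      pinned <- pinned | viol
      x[viol] <- lb
      next
    }
    g <- hmul(x) - b
    mu <- if (is.null(V)) 0 else {
      fr <- which(free)
      sum(cvol[fr] * g[fr]) / sum(cvol[fr]^2)
    }
    release <- pinned & (g - (if (is.null(V)) 0 else mu * cvol) < -kkt_tol)
    if (!any(release))
      return(list(x = x, iterations = total_cg, outer = outer,
                  converged = sqrt(rs) <= tol * rhs_norm, active = sum(pinned)))
    pinned[release] <- FALSE
  }
  list(x = x, iterations = total_cg, outer = max_outer, converged = FALSE,
       active = sum(pinned))
}

#' Recover a voxelwise image from subregional estimates
#'
#' Solves the convex program
#' \deqn{\min_j \sum_r w_r (\mathrm{mean}_{i \in r} j_i - v_r)^2 +
#'   \lambda \|D j\|^2 \quad \mathrm{s.t.}\ j_i \ge \epsilon,\
#'   \sum_i c_i j_i = V \ (\mathrm{optional}),}
#' where `v_r` are the subregional estimates, `w_r = 1/SE_r^2` (floored),
#' `D` takes first differences between 6-neighbour mask voxels, `c_i` is the
#' voxel volume, and `V` an optional global deformed volume. Solved by an
#' active-set method whose inner equality-constrained solves use projected
#' conjugate gradients; the normal-equations operator is applied through
#' sparse matrices, never formed densely.
#'
#' @param estimates data.frame with one row per subregion: columns `value`,
#'   `se` (rows align with `partition$regions`).
#' @param partition a [build_partition()] result covering the mask.
#' @param mask a [lung_mask()].
#' @param cfg a [reconstruction_config()].
#' @param global_value optional total deformed volume (mm^3) enforced as an
#'   equality constraint.
#' @param kind `kind` of the returned [function_image()].
#' @return A [function_image()]; attribute `"diagnostics"` reports the
#'   weighted residual RMS, iterations, objective, and the equality-
#'   constraint violation.
#' @export
reconstruct_voxelwise <- function(estimates, partition, mask,
                                  cfg = reconstruction_config(),
                                  global_value = NULL, kind = "jacobian") {
  stopifnot(inherits(partition, "subregion_partition"))
  m <- as_mask_array(mask)
  dm <- dim(m)
  mask_lin <- which(m)
  p <- length(mask_lin)
  lookup <- integer(prod(dm))
  lookup[mask_lin] <- seq_len(p)

  nr <- length(partition$regions)
  if (nrow(estimates) != nr)
    stop_("estimates (%d rows) do not align with partition (%d regions)",
          nrow(estimates), nr)
  sizes <- lengths(partition$regions)
  cols <- lookup[unlist(partition$regions)]
  if (any(cols == 0L))
    stop_("partition contains voxels outside the mask")
  A <- Matrix::sparseMatrix(i = rep.int(seq_len(nr), sizes), j = cols,
                            x = rep.int(1 / sizes, sizes), dims = c(nr, p))
  if (any(Matrix::colSums(A) == 0))
    stop_("some mask voxels are covered by no estimate region")
  w <- 1 / pmax(estimates$se, cfg$se_floor)^2
  v <- estimates$value

  # first differences between 6-neighbour pairs inside the mask
  pos <- array(lookup, dm)
  ii <- integer(0); jj <- integer(0)
  for (ax in 1:3) {
    n <- dm[ax]
    idx_a <- switch(ax,
                    pos[-n, , , drop = FALSE],
                    pos[, -n, , drop = FALSE],
                    pos[, , -n, drop = FALSE])
    idx_b <- switch(ax,
                    pos[-1, , , drop = FALSE],
                    pos[, -1, , drop = FALSE],
                    pos[, , -1, drop = FALSE])
    keep <- idx_a > 0L & idx_b > 0L
    ii <- c(ii, idx_a[keep]); jj <- c(jj, idx_b[keep])
  }
  npair <- length(ii)
  D <- Matrix::sparseMatrix(i = rep(seq_len(npair), 2L), j = c(ii, jj),
                            x = rep(c(1, -1), each = npair),
                            dims = c(npair, p))

  vv <- prod(partition$spacing)
  lb <- cfg$lower_bound
  if (!is.null(global_value)) {
    if (global_value < lb * vv * p)
      stop_("infeasible constraints: global volume %.4g below bound %.4g x mask volume",
            global_value, lb)
  }
  lam <- cfg$lambda %||% {
    d_data <- mean(Matrix::colSums(w * A^2))  # diag of A'WA
    d_data * (cfg$smooth_scale * partition$window / 2)^2
  }

  objective <- function(j) {
    r <- as.numeric(A %*% j) - v
    sum(w * r^2) + lam * sum(as.numeric(D %*% j)^2)
  }
  hess_mul <- function(x) {
    g <- 2 * as.numeric(Matrix::crossprod(A, w * as.numeric(A %*% x)))
    if (lam > 0) g <- g + 2 * lam * as.numeric(Matrix::crossprod(D, D %*% x))
    g
  }
  bvec <- 2 * as.numeric(Matrix::crossprod(A, w * v))

  cvol <- if (is.null(global_value)) NULL else rep(vv, p)
  # start from the weighted mean of covering regional values
  num <- as.numeric(Matrix::crossprod(A, w * v))
  den <- as.numeric(Matrix::crossprod(A, w))
  sol <- solve_qp_active_set(hess_mul, bvec, lb, cvol, global_value,
                             x0 = num / den, tol = cfg$tol,
                             max_cg = cfg$max_iter)
  j <- sol$x
  resid <- as.numeric(A %*% j) - v
  if (!sol$converged)
    stop_("reconstruction did not converge (%d CG iterations, %d outer passes; weighted residual RMS %.4g, objective %.6g)",
          sol$iterations, sol$outer,
          sqrt(mean(w * resid^2) / mean(w)), objective(j))

  vals <- array(NA_real_, dm)
  vals[mask_lin] <- j
  out <- function_image(vals, m, kind, partition$spacing, partition$origin)
  attr(out, "diagnostics") <- list(
    iterations = sol$iterations, outer = sol$outer,
    n_active_bound = sol$active,
    objective = objective(j),
    residual_rms = sqrt(mean(resid^2)),
    weighted_residual_rms = sqrt(mean(w * resid^2) / mean(w)),
    constraint_violation = if (is.null(global_value)) 0 else
      abs(sum(vv * j) - global_value) / max(global_value, 1))
  out
}
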