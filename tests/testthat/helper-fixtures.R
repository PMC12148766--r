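# Shared fixtures, built in code. Heavy phantoms are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# the noise-free affine phantom used by the Jacobian-recovery checks
affine_phantom_48 <- function() cached("affine48", {
  ph <- make_phantom(shape = 48, noise_sd_hu = 0)
  list(ph = ph, part = build_partition(ph$mask))
})

# displacement field realizing an affine map phi(x) = A x + b on a grid
affine_field <- function(A, b = c(0, 0, 0), dm = c(12, 12, 12),
                         spacing = c(1, 1, 1)) {
  ijk <- arrayInd(seq_len(prod(dm)), dm)
  X <- sweep((ijk - 1), 2, spacing, "*")
  phi <- sweep(X %*% t(A), 2, b, "+")
  u <- array(0, c(dm, 3))
  for (k in 1:3) u[, , , k] <- array(phi[, k] - X[, k], dm)
  disp_field(u, spacing)
}

# an interior cubic region (voxel indices lo..hi per axis) as linear indices
cube_region <- function(dm, lo, hi) {
  ijk <- arrayInd(seq_len(prod(dm)), dm)
  which(ijk[, 1] %in% lo:hi & ijk[, 2] %in% lo:hi & ijk[, 3] %in% lo:hi)
}

# dense KKT oracle for the reconstruction QP, valid when no lower bound is
# active at the optimum: solve [H c; c' 0] [x; mu] = [b; V] (or H x = b).
dense_qp_oracle <- function(estimates, partition, mask, lambda,
                            global_value = NULL, se_floor = 1e-3) {
  m <- if (inherits(mask, "lung_mask")) mask$values else mask
  dm <- dim(m)
  mask_lin <- which(m)
  p <- length(mask_lin)
  lookup <- integer(prod(dm)); lookup[mask_lin] <- seq_len(p)
  nr <- length(partition$regions)
  A <- matrix(0, nr, p)
  for (r in seq_len(nr)) {
    cols <- lookup[partition$regions[[r]]]
    A[r, cols] <- 1 / length(cols)
  }
  w <- 1 / pmax(estimates$se, se_floor)^2
  pos <- array(lookup, dm)
  Dr <- list()
  for (ax in 1:3) {
    n <- dm[ax]
    idx_a <- switch(ax, pos[-n, , ], pos[, -n, ], pos[, , -n])
    idx_b <- switch(ax, pos[-1, , ], pos[, -1, ], pos[, , -1])
    keep <- idx_a > 0 & idx_b > 0
    Dr[[ax]] <- cbind(idx_a[keep], idx_b[keep])
  }
  pairs <- do.call(rbind, Dr)
  D <- matrix(0, nrow(pairs), p)
  D[cbind(seq_len(nrow(pairs)), pairs[, 1])] <- 1
  D[cbind(seq_len(nrow(pairs)), pairs[, 2])] <- -1
  H <- 2 * (t(A) %*% (w * A) + lambda * crossprod(D))
  b <- 2 * as.numeric(t(A) %*% (w * estimates$value))
  if (is.null(global_value)) {
    x <- solve(H, b)
  } else {
    vv <- prod(partition$spacing)
    cc <- rep(vv, p)
    K <- rbind(cbind(H, cc), c(cc, 0))
    x <- solve(K, c(b, global_value))[seq_len(p)]
  }
  x
}
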