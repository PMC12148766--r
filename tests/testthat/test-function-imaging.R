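test_that("the density-change formula matches hand bookkeeping and sign analysis", {
  dm <- c(6, 6, 6)
  mk <- function(hu) hu_image(array(hu, dm), spacing = c(2, 2, 2))
  f0 <- disp_field(array(0, c(dm, 3)), spacing = c(2, 2, 2))
  m <- lung_mask(array(TRUE, dm), spacing = c(2, 2, 2))
  # equal phases: SV identically zero
  sv0 <- vent_hu(mk(-800), mk(-800), f0, m)
  expect_equal(max(abs(sv0$values[sv0$mask])), 0)
  # -800 exhale, -850 inhale: air bookkeeping gives 1000*(-50)/(-800*150)
  sv <- vent_hu(mk(-800), mk(-850), f0, m)
  expect_equal(sv$values[3, 3, 3], 1000 * (-50) / (-800 * 150),
               tolerance = 1e-12)
  expect_equal(sv$values[3, 3, 3], 0.41667, tolerance = 1e-4)
  # less air at inhale (H_in > H_ex) means negative specific volume change
  svn <- vent_hu(mk(-800), mk(-750), f0, m)
  expect_true(all(svn$values[svn$mask] < 0))
})

test_that("HU guards exclude unstable voxels and flag wholesale mismatch", {
  dm <- c(6, 6, 6)
  f0 <- disp_field(array(0, c(dm, 3)), spacing = c(2, 2, 2))
  m <- lung_mask(array(TRUE, dm), spacing = c(2, 2, 2))
  ex <- array(-800, dm); ex[1, 1, 1] <- -5   # near-waterlike exhale voxel
  inh <- array(-850, dm); inh[2, 1, 1] <- -995  # near-pure-air inhale voxel
  sv <- vent_hu(hu_image(ex, c(2, 2, 2)), hu_image(inh, c(2, 2, 2)), f0, m)
  expect_false(sv$mask[1, 1, 1])
  expect_false(sv$mask[2, 1, 1])
  expect_equal(attr(sv, "excluded"), 2L)
  # mostly water-like: more than 20% excluded is an error
  bad <- array(-5, dm)
  expect_error(vent_hu(hu_image(bad, c(2, 2, 2)), hu_image(inh, c(2, 2, 2)),
                       f0, m), "mismatch")
})

test_that("identity scenes reconstruct to a unit Jacobian", {
  dm <- c(34, 34, 34)
  arr <- array(FALSE, dm); arr[6:29, 6:29, 6:29] <- TRUE
  m <- lung_mask(arr, spacing = c(2, 2, 2))
  hu <- hu_image(array(-800, dm), spacing = c(2, 2, 2))
  f0 <- disp_field(array(0, c(dm, 3)), spacing = c(2, 2, 2))
  part <- build_partition(m)
  mc <- vent_mcvc(hu, hu, f0, m, part)
  expect_lt(max(abs(mc$values[mc$mask] - 1)), 0.02)
  ij <- vent_ijf(hu, hu, f0, m, m, part, tau = 0.01, seed = 2)
  expect_lt(max(abs(ij$values[ij$mask] - 1)), 0.02)
})

test_that("noise-free affine phantoms are recovered within the stated accuracy", {
  fx <- affine_phantom_48()
  ph <- fx$ph
  J <- ph$truth$jacobian
  mc <- vent_mcvc(ph$exhale, ph$inhale, ph$field, ph$mask, fx$part)
  rmse_mc <- sqrt(mean((mc$values[mc$mask] - J[mc$mask])^2)) / mean(J[mc$mask])
  expect_lt(rmse_mc, 0.02)
  expect_true(all(mc$values[mc$mask] >= reconstruction_config()$lower_bound))
  ij <- vent_ijf(ph$exhale, ph$inhale, ph$field, ph$mask, ph$mask_in,
                 fx$part, tau = 0.01, seed = 1)
  rmse_ij <- sqrt(mean((ij$values[ij$mask] - J[ij$mask])^2)) / mean(J[ij$mask])
  expect_lt(rmse_ij, 0.02)
  sv <- vent_hu(ph$exhale, ph$inhale, ph$field, ph$mask)
  svt <- ph$truth$sv_air
  rmse_sv <- sqrt(mean((sv$values[sv$mask] - svt[sv$mask])^2)) /
    mean(abs(svt[sv$mask]))
  expect_lt(rmse_sv, 0.03)
})

test_that("outputs are invariant to subregion relabeling", {
  fx <- affine_phantom_48()
  ph <- fx$ph
  part <- fx$part
  perm <- rev(seq_along(part$regions))
  part2 <- part
  part2$regions <- part$regions[perm]
  part2$centers <- part$centers[perm, ]
  a <- vent_mcvc(ph$exhale, ph$inhale, ph$field, ph$mask, part)
  b <- vent_mcvc(ph$exhale, ph$inhale, ph$field, ph$mask, part2)
  expect_lt(max(abs(a$values[a$mask] - b$values[b$mask])), 1e-6)
})

test_that("HU noise hurts the voxelwise HU method more than the subregional MCVC method", {
  worse <- logical(20)
  for (s in 1:20) {
    ph <- make_phantom(shape = 32, noise_sd_hu = 20, seed = 100 + s)
    J <- ph$truth$jacobian
    svt <- ph$truth$sv_air
    part <- build_partition(ph$mask)
    sv <- vent_hu(ph$exhale, ph$inhale, ph$field, ph$mask)
    mc <- vent_mcvc(ph$exhale, ph$inhale, ph$field, ph$mask, part)
    r_hu <- sqrt(mean((sv$values[sv$mask] - svt[sv$mask])^2)) /
      mean(abs(svt[sv$mask]))
    r_mc <- sqrt(mean((mc$values[mc$mask] - J[mc$mask])^2)) / mean(J[mc$mask])
    worse[s] <- r_hu > r_mc
  }
  expect_true(all(worse))
})

test_that("perfusion image is near zero on conserving scenes and lights up an implant", {
  fx <- affine_phantom_48()
  ph <- fx$ph
  mc <- vent_mcvc(ph$exhale, ph$inhale, ph$field, ph$mask, fx$part)
  pf <- perf_image(ph$exhale, ph$inhale, ph$field, ph$mask, fx$part,
                   jacobian = mc)
  expect_true(all(pf$values[pf$mask] >= 0))
  expect_lt(mean(pf$values[pf$mask]), 0.02)
  php <- make_phantom(shape = 48, noise_sd_hu = 0,
                      perfusion = list(center = c(58, 47, 47), radius = 14,
                                       delta = 0.05))
  partp <- build_partition(php$mask)
  pfp <- perf_image(php$exhale, php$inhale, php$field, php$mask, partp)
  imp <- php$truth$mass_change > 0
  expect_gt(mean(pfp$values[imp & pfp$mask]),
            3 * mean(pfp$values[pfp$mask & !imp]))
})
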