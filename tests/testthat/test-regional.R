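test_that("exact deformed volume: identity, translation, and affine scaling", {
  dm <- c(12, 12, 12)
  f0 <- affine_field(diag(3), dm = dm)
  reg <- cube_region(dm, 4, 7)   # interior 4^3 = 64 voxels of (1 mm)^3
  expect_equal(as.numeric(exact_deformed_volume(f0, reg)), 64)
  ft <- affine_field(diag(3), b = c(2.5, -1.5, 0.5), dm = dm)
  expect_equal(as.numeric(exact_deformed_volume(ft, reg)), 64, tolerance = 1e-12)
  f8 <- affine_field(diag(c(2, 2, 2)), dm = dm)
  expect_equal(as.numeric(exact_deformed_volume(f8, cube_region(dm, 4, 6))),
               8 * 27, tolerance = 1e-12)
  expect_error(exact_deformed_volume(f0, integer(0)), "empty")
})

test_that("folding transforms are flagged", {
  dm <- c(10, 10, 10)
  f <- affine_field(diag(c(-0.5, 1, 1)), b = c(9, 0, 0), dm = dm)
  expect_warning(exact_deformed_volume(f, cube_region(dm, 4, 6)),
                 "non-positive orientation")
})

test_that("hit-or-miss estimate brackets truth and obeys the tau -> N rule", {
  dm <- c(12, 12, 12)
  reg <- cube_region(dm, 4, 7)
  f0 <- affine_field(diag(3), dm = dm)
  hm <- hit_or_miss_volume(f0, reg, tau = 0.005, seed = 11)
  expect_lte(abs(hm$value - 64), 3 * max(hm$se, 1e-12))
  # affine det-8 case against the exact oracle
  f8 <- affine_field(diag(c(2, 2, 2)), dm = dm)
  reg3 <- cube_region(dm, 4, 6)
  ex <- as.numeric(exact_deformed_volume(f8, reg3))
  hm8 <- hit_or_miss_volume(f8, reg3, tau = 0.005, seed = 11)
  expect_lte(abs(hm8$value - ex), 3 * max(hm8$se, 1e-12))
  # halving tau at least quadruples N
  n1 <- hit_or_miss_volume(f0, reg, tau = 0.01, seed = 1)$n_samples
  n2 <- hit_or_miss_volume(f0, reg, tau = 0.005, seed = 1)$n_samples
  expect_gte(n2, 4 * n1)
  expect_error(hit_or_miss_volume(f0, reg, tau = 0), "tau")
})

test_that("hit-or-miss is a deterministic function of inputs and seed", {
  dm <- c(12, 12, 12)
  f <- affine_field(diag(c(1.1, 0.95, 1.05)), dm = dm)
  reg <- cube_region(dm, 4, 7)
  a <- hit_or_miss_volume(f, reg, tau = 0.01, seed = 99)
  b <- hit_or_miss_volume(f, reg, tau = 0.01, seed = 99)
  expect_identical(a$value, b$value)
  expect_identical(a$se, b$se)
})

test_that("MCVC regional ratio recovers the constant Jacobian of a mass-conserving phantom", {
  fx <- affine_phantom_48()
  ph <- fx$ph
  rho_ex <- hu_to_density(ph$exhale)
  rho_in <- hu_to_density(ph$inhale)
  # identity scene: value is exactly 1
  dm <- c(12, 12, 12)
  f0 <- affine_field(diag(3), dm = dm)
  rho <- density_image(array(0.2, dm))
  est0 <- mcvc_regional_jacobian(rho, rho, f0, cube_region(dm, 4, 7))
  expect_equal(est0$value, 1)
  # phantom regions: within 2% of s^3 = 1.15
  for (r in fx$part$regions[c(1, 50, 150)]) {
    est <- mcvc_regional_jacobian(rho_ex, rho_in, ph$field, r)
    expect_lt(abs(est$value - 1.15) / 1.15, 0.02)
  }
  # zero density guard
  zero <- density_image(array(0, dm))
  expect_error(mcvc_regional_jacobian(rho, zero, f0, cube_region(dm, 4, 7)),
               "floor")
})

test_that("MCVC tiling estimates integrate to the deformed lung volume", {
  fx <- affine_phantom_48()
  ph <- fx$ph
  tile <- build_partition(ph$mask, window = 8, stride = 8)
  rho_ex <- hu_to_density(ph$exhale)
  rho_in <- hu_to_density(ph$inhale)
  vv <- prod(ph$exhale$spacing)
  tot <- sum(vapply(tile$regions, function(r) {
    mcvc_regional_jacobian(rho_ex, rho_in, ph$field, r)$value * length(r) * vv
  }, numeric(1)))
  expect_lt(abs(tot - 1.15 * sum(ph$mask$values) * vv) /
              (1.15 * sum(ph$mask$values) * vv), 0.02)
})

test_that("regional mass change vanishes on the conserving scene and tracks an implant", {
  fx <- affine_phantom_48()
  ph <- fx$ph
  rho_ex <- hu_to_density(ph$exhale)
  rho_in <- hu_to_density(ph$inhale)
  jac <- function_image(ph$truth$jacobian, ph$mask$values, "jacobian",
                        ph$exhale$spacing, ph$exhale$origin)
  est <- perf_regional_masschange(rho_ex, rho_in, ph$field, jac,
                                  fx$part$regions[[60]])
  expect_gte(est$value, 0)
  expect_lte(est$value, 0.01)
  # implanted +delta throughout a region is recovered within 5%
  delta <- 0.05
  php <- make_phantom(shape = 48, noise_sd_hu = 0,
                      perfusion = list(center = c(47, 47, 47), radius = 16,
                                       delta = delta))
  rex <- hu_to_density(php$exhale); rin <- hu_to_density(php$inhale)
  jacp <- function_image(php$truth$jacobian, php$mask$values, "jacobian",
                         php$exhale$spacing, php$exhale$origin)
  # a region fully inside the implant, away from its boundary
  dmp <- php$mask$dim
  Xall <- vent4d:::world_coords(arrayInd(seq_len(prod(dmp)), dmp),
                                php$mask$spacing, php$mask$origin)
  r2 <- rowSums(sweep(Xall, 2, c(47, 47, 47))^2)
  core <- which(array(r2 < 8^2, dmp) & php$mask$values)
  estp <- perf_regional_masschange(rex, rin, php$field, jacp, core)
  expect_lt(abs(estp$value - delta) / delta, 0.05)
  # jacobian undefined on a region voxel is an error
  jhole <- jac; jhole$values[fx$part$regions[[60]][1]] <- NA
  expect_error(perf_regional_masschange(rho_ex, rho_in, ph$field, jhole,
                                        fx$part$regions[[60]]), "undefined")
})
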