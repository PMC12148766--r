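test_that("identity transform with zero noise gives identical phases and unit Jacobian", {
  ph <- make_phantom(shape = 32, noise_sd_hu = 0,
                     transform = affine_transform(diag(3), center = c(31, 31, 31)))
  expect_identical(ph$inhale$values, ph$exhale$values)
  expect_true(all(ph$truth$jacobian == 1))
  expect_identical(ph$mask$values, ph$mask_in$values)
})

test_that("diagonal affine scaling yields the exact determinant everywhere", {
  s <- 1.15^(1 / 3)
  ph <- make_phantom(shape = 32, noise_sd_hu = 0)
  expect_equal(max(abs(ph$truth$jacobian - 1.15)), 0, tolerance = 1e-12)
  aniso <- affine_transform(diag(c(1.1, 1.05, 1.2)), center = c(31, 31, 31))
  ph2 <- make_phantom(shape = 32, noise_sd_hu = 0, transform = aniso)
  expect_equal(max(abs(ph2$truth$jacobian - 1.1 * 1.05 * 1.2)), 0,
               tolerance = 1e-12)
})

test_that("the defect-attenuated Jacobian matches direct differentiation of the analytic map", {
  ctr <- c(47, 47, 47)
  tr <- poly_transform(list(c(1.05, 0, 1e-6), c(1.04, 2e-4), c(1.06, 0, -1e-6)),
                       center = ctr)
  def <- list(center = c(58, 47, 47), radius = 18, strength = 0.8)
  set.seed(6)
  X <- cbind(runif(500, 20, 74), runif(500, 20, 74), runif(500, 20, 74))
  phi <- function(P) P + vent4d:::phantom_u(tr, def, P)
  h <- 1e-4
  G <- array(0, c(nrow(X), 3, 3))
  for (j in 1:3) {
    e <- matrix(0, nrow(X), 3); e[, j] <- h
    G[, , j] <- (phi(X + e) - phi(X - e)) / (2 * h)
  }
  detn <- G[, 1, 1] * (G[, 2, 2] * G[, 3, 3] - G[, 2, 3] * G[, 3, 2]) -
    G[, 1, 2] * (G[, 2, 1] * G[, 3, 3] - G[, 2, 3] * G[, 3, 1]) +
    G[, 1, 3] * (G[, 2, 1] * G[, 3, 2] - G[, 2, 2] * G[, 3, 1])
  Ja <- vent4d:::phantom_jacobian_at(tr, def, X)
  expect_lt(max(abs(detn - Ja) / Ja), 1e-6)
})

test_that("analytic Jacobian matches numerical differentiation of the grid field", {
  ctr <- c(47, 47, 47)
  tr <- poly_transform(list(c(1.05, 0, 1e-6), c(1.04, 2e-4), c(1.06, 0, -1e-6)),
                       center = ctr)
  ph <- make_phantom(shape = 48, noise_sd_hu = 0, transform = tr)
  u <- ph$field$u
  dm <- ph$field$dim
  sp <- ph$field$spacing
  # central differences of phi = x + u on interior voxels
  interior <- array(FALSE, dm)
  interior[3:(dm[1] - 2), 3:(dm[2] - 2), 3:(dm[3] - 2)] <- TRUE
  interior <- interior & ph$mask$values
  G <- array(0, c(dm, 3, 3))
  for (k in 1:3) for (ax in 1:3) {
    shp <- function(off) {
      idx <- lapply(seq_len(3), function(a) seq_len(dm[a]))
      idx[[ax]] <- pmin(pmax(idx[[ax]] + off, 1), dm[ax])
      do.call(`[`, c(list(u[, , , k]), idx))
    }
    G[, , , k, ax] <- (shp(1) - shp(-1)) / (2 * sp[ax]) +
      (if (k == ax) 1 else 0)
  }
  detn <- G[, , , 1, 1] * (G[, , , 2, 2] * G[, , , 3, 3] - G[, , , 2, 3] * G[, , , 3, 2]) -
    G[, , , 1, 2] * (G[, , , 2, 1] * G[, , , 3, 3] - G[, , , 2, 3] * G[, , , 3, 1]) +
    G[, , , 1, 3] * (G[, , , 2, 1] * G[, , , 3, 2] - G[, , , 2, 2] * G[, , , 3, 1])
  rel <- abs(detn[interior] - ph$truth$jacobian[interior]) /
    ph$truth$jacobian[interior]
  expect_lt(max(rel), 0.01)
})

test_that("phantom conserves total lung mass up to mask discretization", {
  ph <- make_phantom(shape = 64, noise_sd_hu = 0)
  vv <- prod(ph$exhale$spacing)
  m_ex <- sum(ph$truth$density_ex[ph$mask$values]) * vv
  m_in <- sum(ph$truth$density_in[ph$mask_in$values]) * vv
  expect_lt(abs(m_in - m_ex) / m_ex, 0.005)
})

test_that("same seed gives bit-identical phantoms; transforms with J <= 0 are rejected", {
  a <- make_phantom(shape = 32, seed = 9)
  b <- make_phantom(shape = 32, seed = 9)
  expect_identical(a$exhale$values, b$exhale$values)
  expect_identical(a$inhale$values, b$inhale$values)
  expect_identical(a$field$u, b$field$u)
  folding <- poly_transform(list(c(-1), c(1), c(1)), center = c(31, 31, 31))
  expect_error(make_phantom(shape = 32, transform = folding, noise_sd_hu = 0),
               "Jacobian|orientation")
  expect_error(affine_transform(diag(c(-1, 1, 1))), "positive determinant")
})

test_that("a ventilation defect suppresses the density-change signal in its core", {
  def <- list(center = c(58, 47, 47), radius = 20, strength = 1)
  ph <- make_phantom(shape = 48, noise_sd_hu = 0, defect = def)
  core <- ph$truth$defect_mask
  expect_true(any(core))
  expect_equal(max(abs(ph$truth$jacobian[core] - 1)), 0, tolerance = 1e-12)
  sv <- vent_hu(ph$exhale, ph$inhale, ph$field, ph$mask)
  inside <- mean(sv$values[core & sv$mask])
  outside <- mean(sv$values[sv$mask & !core])
  expect_lt(inside, outside)
})

test_that("synthetic dose is prescription at the target and non-increasing outward", {
  d <- make_dose(c(32, 32, 32), spacing = c(2, 2, 2),
                 target_center = c(31, 31, 31), target_radius = 10,
                 prescription_gy = 60, falloff_mm = 12)
  ci <- round(31 / 2) + 1
  expect_equal(d$values[ci, ci, ci], 60)
  # dose along a ray is non-increasing with distance beyond the surface
  ray <- d$values[ci:32, ci, ci]
  expect_true(all(diff(ray) <= 1e-12))
  expect_true(all(d$values >= 0))
  uni <- make_dose(c(32, 32, 32), spacing = c(2, 2, 2),
                   target_center = c(31, 31, 31), target_radius = 10,
                   prescription_gy = 45, falloff_mm = Inf)
  expect_true(all(uni$values == 45))
  expect_error(make_dose(c(32, 32, 32), target_center = c(500, 0, 0)),
               "outside")
})

test_that("simulated readers hit their operating point", {
  truth <- rep(c(TRUE, FALSE), each = 8)
  perfect <- simulate_reader(truth, 1, 1, 0, seed = 1)
  expect_identical(perfect$call, truth)
  expect_true(all(perfect$location[!truth] == "none"))
  blind <- simulate_reader(rep(TRUE, 10), sensitivity = 0, seed = 1)
  expect_true(all(!blind$call))
  # empirical sensitivity within 3 binomial SE at n = 10000
  big <- simulate_reader(rep(TRUE, 10000), sensitivity = 0.8, seed = 4)
  expect_lt(abs(mean(big$call) - 0.8), 3 * sqrt(0.8 * 0.2 / 10000))
  expect_error(simulate_reader(truth, sensitivity = 1.2), "\\[0, 1\\]")
})
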