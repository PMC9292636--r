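test_that("HU to mu conversion hits the anchor points", {
  m <- hu_to_mu(array(c(0, -1000, -770, 1000, -2000), c(5, 1, 1)))
  expect_equal(m$mu[1, 1, 1], 0.096)
  expect_equal(m$mu[2, 1, 1], 0)
  expect_equal(m$mu[3, 1, 1], 0.096 * 230 / 1000) # 0.02208 by the stated line
  expect_equal(m$mu[4, 1, 1], 0.172)
  expect_equal(m$mu[5, 1, 1], 0) # clamped
  expect_error(attenuation_map(array(-0.1, c(2, 2, 1))), ">= 0")
})

test_that("attenuation factors are exact on a water-equivalent chord", {
  # anti-aliased 20 cm water disk at 1 mm voxels, odd grid: the central LOR
  # integral is 19.2 (0.096/cm x 20 cm), factor exp(-1.92)
  n <- 255L
  co <- sctpet:::slice_coords(n, n, c(1, 1))
  ss <- 4
  acc <- matrix(0, n, n)
  for (ox in ((1:ss) - 0.5) / ss - 0.5) for (oy in ((1:ss) - 0.5) / ss - 0.5) {
    acc <- acc + ((co$x + ox)^2 + (co$y + oy)^2 <= 100^2)
  }
  mu <- attenuation_map(array(0.096 * acc / ss^2, c(n, n, 1)), spacing = c(1, 1, 1))
  geom <- projection_geometry(n_angles = 4L, n_bins = n, bin_spacing = 1)
  af <- attenuation_factors(mu, geom)
  ctr <- (n + 1) / 2
  expect_lt(abs(af[ctr, 1, 1] - exp(-1.92)) / exp(-1.92), 0.001)
  # zero mu -> all factors 1
  mu0 <- attenuation_map(array(0, c(32, 32, 1)), spacing = c(2, 2, 2))
  g0 <- projection_geometry(8L, 48L, 2)
  expect_true(all(attenuation_factors(mu0, g0) == 1))
  # doubling mu doubles the log-factors
  mu2 <- attenuation_map(2 * mu$mu, spacing = c(1, 1, 1))
  af2 <- attenuation_factors(mu2, geom)
  expect_equal(log(af2[ctr, 1, 1]), 2 * log(af[ctr, 1, 1]), tolerance = 1e-9)
})

test_that("forward projection agrees with an independent rotation projector", {
  ph <- fixture_phantom(7)
  mu <- hu_to_mu(ph$ct_hu, spacing = ph$spacing)
  geom <- geometry_for_grid(dim(ph$mr), ph$spacing, 16L)
  sino <- forward_project(ph$activity, mu, geom)
  expect_true(all(sino$counts >= 0))
  # oracle: rotate + row-sum projector with its own attenuation factors
  act_p <- rotate_project_oracle(ph$activity[, , 1], ph$spacing, geom$angles)
  mu_p <- rotate_project_oracle(mu$mu[, , 1], ph$spacing, geom$angles)
  oracle_mass <- sum(act_p * exp(-mu_p / 10))
  expect_lt(abs(sum(sino$counts) - oracle_mass) / oracle_mass, 0.02)
  # zero activity -> zero sinogram
  z <- forward_project(0 * ph$activity, mu, geom)
  expect_true(all(z$counts == 0))
  # fixed seed -> identical Poisson realisation
  a <- forward_project(ph$activity, mu, geom, total_counts = 1e5, seed = 3)
  b <- forward_project(ph$activity, mu, geom, total_counts = 1e5, seed = 3)
  expect_identical(a$counts, b$counts)
  expect_equal(a$noise, "poisson")
})

test_that("OSEM converges on a matched-mu disk and stays non-negative", {
  n <- 64L
  sp <- c(4, 4, 4)
  co <- sctpet:::slice_coords(n, n, sp)
  disk <- (co$x^2 + co$y^2) <= 100^2
  act <- array(disk * 1, c(n, n, 1))
  mu <- attenuation_map(array(disk * 0.096, c(n, n, 1)), spacing = sp)
  geom <- geometry_for_grid(c(n, n, 1), sp, 64L)
  sino <- forward_project(act, mu, geom)
  rec <- osem_reconstruct(sino, mu, iterations = 4, subsets = 8)
  expect_true(all(rec >= 0))
  expect_lt(abs(mean(rec[act > 0]) - 1), 0.02)
  # noiseless self-consistency: reprojection reproduces the sinogram
  sino2 <- forward_project(rec, mu, geom)
  sel <- sino$counts > 1e-3 * max(sino$counts)
  mard <- mean(abs(sino2$counts[sel] - sino$counts[sel]) / sino$counts[sel])
  expect_lt(mard, 0.01)
  # subset count must divide the angles
  expect_error(osem_reconstruct(sino, mu, subsets = 7), "divide")
  # zero-count sinogram collapses to zero after one multiplicative update
  zs <- sino; zs$counts[] <- 0
  expect_true(all(osem_reconstruct(zs, mu, iterations = 1) == 0))
})

test_that("underestimating mu in a region biases its uptake low, monotonically", {
  n <- 64L
  sp <- c(4, 4, 4)
  co <- sctpet:::slice_coords(n, n, sp)
  disk <- (co$x^2 + co$y^2) <= 100^2
  lung <- ((co$x - 40)^2 + co$y^2) <= 40^2
  act <- array(disk * 1, c(n, n, 1))
  mu_true_v <- disk * 0.096
  mu_true_v[lung] <- 0.096
  mu_true <- attenuation_map(array(mu_true_v, c(n, n, 1)), spacing = sp)
  geom <- geometry_for_grid(c(n, n, 1), sp, 64L)
  sino <- forward_project(act, mu_true, geom)
  means <- vapply(c(1, 0.7, 0.4, 0.1), function(s) {
    mv <- mu_true_v
    mv[lung] <- 0.096 * s
    rec <- osem_reconstruct(sino, attenuation_map(array(mv, c(n, n, 1)),
                                                  spacing = sp))
    mean(rec[array(lung, c(n, n, 1))])
  }, 0)
  expect_true(all(diff(means) < 0)) # lower candidate mu -> lower uptake
  expect_lt(means[4], means[1] * 0.9)
})

test_that("SUV normalization uses the reference arm and preserves ratios", {
  ph <- fixture_phantom(7)
  body <- ph$organs$body
  rec_ref <- ph$activity + 0.2
  rec_alt <- 0.9 * rec_ref
  suv_ref <- to_suv(rec_ref, body)
  expect_equal(mean(suv_ref[body]), 1.0)
  suv_alt <- to_suv(rec_alt, body, reference = rec_ref)
  b1 <- voxel_bias_map(suv_alt, suv_ref)
  # a common rescaling of both arms leaves the bias untouched
  b2 <- voxel_bias_map(3.7 * suv_alt, 3.7 * suv_ref)
  expect_equal(b1$bias[b1$valid & b2$valid], b2$bias[b1$valid & b2$valid],
               tolerance = 1e-9)
  expect_error(to_suv(rec_ref, body & FALSE), "empty")
})
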