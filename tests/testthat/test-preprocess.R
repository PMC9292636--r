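test_that("unit-range normalization maps, clips and is idempotent", {
  x <- array(c(0, 5, 10), c(3, 1, 1))
  expect_equal(as.vector(normalize_unit_range(x, c(0, 100))), c(0, 0.5, 1))
  cst <- array(4, c(4, 4, 1))
  expect_true(all(normalize_unit_range(cst) == 0))
  set.seed(1)
  y <- array(runif(4000), c(20, 20, 10))
  n1 <- normalize_unit_range(y)
  expect_equal(normalize_unit_range(n1), n1, tolerance = 1e-12)
  expect_true(all(n1 >= 0 & n1 <= 1))
  # a single extreme outlier does not shift the clipped mapping appreciably
  y2 <- y; y2[1] <- 1e6
  q99 <- quantile(y, 0.99)
  m1 <- normalize_unit_range(y, c(0, 99.5))
  m2 <- normalize_unit_range(y2, c(0, 99.5))
  i <- which(abs(y - q99) == min(abs(y - q99)))[1]
  expect_lt(abs(m1[i] - m2[i]), 0.02)
})

test_that("histogram matching reproduces the reference quantile function", {
  ph <- fixture_phantom(7)
  x <- ph$mr
  expect_equal(match_histogram(x, x), x, tolerance = 1e-6)
  scaled <- x * 2
  m <- match_histogram(scaled, x)
  expect_lt(abs(median(m) - median(x)) / max(median(x), 1e-9), 0.05)
  cst <- array(3, c(8, 8, 1))
  out <- match_histogram(cst, x)
  expect_equal(unique(as.vector(out)), median(x))
})

test_that("bias-field correction removes a known 20% field and spares clean data", {
  cfg <- desk_config()
  cfg$mr_bias_field_amplitude <- 0
  clean <- generate_phantom(cfg, 11)
  mask <- clean$labels != 0
  out <- correct_bias_field(clean$mr, mask)
  rel <- abs(out[mask] - clean$mr[mask]) / pmax(clean$mr[mask], 1e-6)
  expect_lt(median(rel), 0.01)
  # apply a known multiplicative 20% gradient field and correct it
  xs <- matrix((seq_len(64) - 32.5) / 32, 64, 64)
  field <- array(exp(0.18 * xs), c(64, 64, 1))
  biased_mr <- clean$mr * field
  soft <- clean$labels == 3
  corr <- correct_bias_field(biased_mr, mask)
  expect_lt(sd(corr[soft]), sd(biased_mr[soft]))
  # the residual multiplicative field is substantially flatter than the
  # applied one (compare against the clean truth)
  resid <- corr[soft] / clean$mr[soft]
  expect_lt(sd(log(resid)), 0.75 * sd(log(field[soft])))
  expect_error(correct_bias_field(clean$mr, mask & FALSE), "empty")
})

test_that("self-registration is near-identity and translation is recovered", {
  ph <- fixture_phantom(7)
  pp <- fixture_mr_norm(7)
  f <- register_images(pp, pp, "affine", spacing = ph$spacing)
  expect_lt(max(sqrt(f$dx^2 + f$dy^2)), 0.5 * 4) # < 0.5 voxel
  tf <- identity_field(dim(pp), ph$spacing)
  tf$dx[] <- 6
  moved <- resample_volume(pp, tf, "linear", fill = min(pp))
  f2 <- register_images(moved, pp, "affine", spacing = ph$spacing)
  body <- ph$organs$body
  # the recovering field is the inverse shift, within one voxel
  expect_lt(abs(mean(f2$dx[body]) + 6), 4)
  # metric never decreases relative to its initial value
  for (l in f2$log) expect_gte(l$nmi_final, l$nmi_initial)
})

test_that("deformable registration recovers at least half the misalignment", {
  ph <- fixture_phantom(7)
  pp <- fixture_mr_norm(7)
  body <- ph$organs$body
  ratios <- vapply(1:3, function(s) {
    sim <- simulate_session_misalignment(ph, 8, seed = s)
    mrn <- normalize_unit_range(sim$mr_moved)
    f <- register_images(mrn, pp, "bspline", spacing = ph$spacing)
    init <- mean(sqrt(sim$truth_field$dx[body]^2 + sim$truth_field$dy[body]^2))
    resid <- mean(sqrt((f$dx[body] + sim$truth_field$dx[body])^2 +
                         (f$dy[body] + sim$truth_field$dy[body])^2))
    resid / init
  }, 0)
  expect_lt(mean(ratios), 0.5)
})

test_that("non-overlapping grids raise a geometry error", {
  a <- array(runif(64), c(8, 8, 1))
  expect_error(
    register_images(a, a, "affine", spacing = c(2, 2, 2),
                    origin_moving = c(0, 0), origin_fixed = c(1000, 0)),
    "overlap")
})

test_that("resampling through the identity field is exact for nearest", {
  ph <- fixture_phantom(7)
  idf <- identity_field(dim(ph$labels), ph$spacing)
  out <- resample_volume(ph$labels, idf, "nearest")
  expect_equal(out, ph$labels + 0)
  lin <- resample_volume(ph$mr, idf, "linear")
  expect_equal(lin, ph$mr, tolerance = 1e-12)
})

test_that("field composition matches sequential resampling", {
  ph <- fixture_phantom(7)
  f1 <- random_deformation(dim(ph$mr), ph$spacing, 3, seed = 1)
  f2 <- random_deformation(dim(ph$mr), ph$spacing, 2, seed = 2)
  seq_warp <- resample_volume(resample_volume(ph$mr, f1, fill = 0), f2, fill = 0)
  comp <- compose_fields(f1, f2)
  one_warp <- resample_volume(ph$mr, comp, fill = 0)
  body <- ph$organs$body & !sctpet:::dilate_mask(ph$labels == 0, 2)
  expect_lt(mean(abs(seq_warp[body] - one_warp[body])), 0.02)
})
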