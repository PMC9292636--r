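test_that("noise-free limit gives piecewise-constant volumes at the tissue means", {
  cfg <- desk_config()
  cfg$tissue_table$ct_hu_sd[] <- 0
  cfg$tissue_table$mr_sd[] <- 0
  cfg$mr_bias_field_amplitude <- 0
  cfg$subject_hu_jitter <- 0
  ph <- generate_phantom(cfg, 3)
  tt <- cfg$tissue_table
  for (code in sort(unique(as.vector(ph$labels)))) {
    sel <- ph$labels == code
    expect_equal(unique(as.vector(ph$ct_hu[sel])), tt$ct_hu_mean[code + 1])
    expect_equal(unique(as.vector(ph$mr[sel])), tt$mr_mean[code + 1])
    expect_equal(unique(as.vector(ph$activity[sel])), tt$activity_mean[code + 1])
  }
})

test_that("phantom generation is deterministic and seed-sensitive", {
  cfg <- desk_config(nz = 2L)
  a <- generate_phantom(cfg, 7)
  b <- generate_phantom(cfg, 7)
  expect_identical(a$mr, b$mr)
  expect_identical(a$ct_hu, b$ct_hu)
  expect_identical(a$labels, b$labels)
  c3 <- generate_phantom(cfg, 8)
  expect_false(identical(a$labels, c3$labels)) # jittered anatomy differs
})

test_that("lung area fraction matches the analytic ellipse ratio", {
  cfg <- desk_config()
  ph <- generate_phantom(cfg, 7)
  analytic <- 2 * prod(cfg$lung_axes) /
    (prod(cfg$body_axes) + 2 * cfg$arm_radius^2)
  measured <- sum(ph$labels == 1) / sum(ph$labels != 0)
  expect_lt(abs(measured - analytic) / analytic, 0.2)
})

test_that("a grid too small for the body is rejected", {
  expect_error(
    generate_phantom(phantom_config(grid_shape = c(32L, 32L, 1L),
                                    voxel_spacing = c(2, 2, 2)), 1),
    "too small")
})

test_that("config invariants are enforced", {
  tt <- default_tissue_table()
  tt$ct_hu_mean[tt$class == "bone"] <- 100
  expect_error(phantom_config(tissue_table = tt), "bone")
  tt <- default_tissue_table()
  tt$mr_mean[tt$class == "air"] <- 0.9
  expect_error(phantom_config(tissue_table = tt), "darker")
  expect_error(phantom_config(voxel_spacing = c(2, 0, 2)), "spacing")
})

test_that("truncation blanks MR only, with the exact oracle voxel count", {
  ph <- fixture_phantom(7)
  expect_identical(inject_truncation(ph, 0), ph) # boundary no-op
  tr <- inject_truncation(ph, 0.15)
  air_mr <- ph$config$tissue_table$mr_mean[1]
  expect_identical(tr$ct_hu, ph$ct_hu)
  expect_identical(tr$labels, ph$labels)
  expect_identical(tr$activity, ph$activity)
  # body support on MR strictly smaller than on CT
  expect_lt(sum(tr$mr > 0.1), sum(ph$mr > 0.1))
  # brute-force oracle: body voxels whose |x| exceeds the reduced FOV
  xs <- (seq_len(64) - 32.5) * 4
  outside <- abs(xs) > (0.5 - 0.15) * 64 * 4
  oracle <- sum(outer(outside, rep(TRUE, 64)) & ph$labels[, , 1] != 0)
  blanked <- sum(tr$mr == air_mr & ph$labels != 0 & ph$mr != air_mr)
  expect_equal(sum(tr$outliers_applied[[1]]$mask), oracle)
  expect_equal(blanked, oracle)
  expect_error(inject_truncation(ph, 0.6), "lateral_fraction")
  expect_error(inject_truncation(ph, -0.1), "lateral_fraction")
})

test_that("metal injection voids MR, implants CT, and is idempotent", {
  ph <- fixture_phantom(7)
  m <- inject_metal(ph, center = c(55, 25), void_radius = 24, implant_radius = 8)
  # voxelized-disk oracle for the void
  co <- sctpet:::slice_coords(64, 64, c(4, 4))
  oracle <- sum((co$x - 55)^2 + (co$y - 25)^2 <= 24^2)
  expect_equal(sum(m$outliers_applied[[1]]$mask), oracle)
  expect_gte(max(m$ct_hu), 3000)
  expect_identical(m$activity, ph$activity)
  m2 <- inject_metal(m, center = c(55, 25), void_radius = 24, implant_radius = 8)
  expect_identical(m2$mr, m$mr)
  expect_error(inject_metal(ph, center = c(120, 120)), "inside the body")
  expect_error(inject_metal(ph, center = c(55, 25), void_radius = 5,
                            implant_radius = 8), "smaller")
})

test_that("lung removal converts one lung to soft tissue and keeps the other", {
  ph <- fixture_phantom(7)
  r <- remove_lung(ph, "left")
  expect_false(any(r$organs$left_lung))
  expect_identical(r$organs$right_lung, ph$organs$right_lung)
  old <- ph$organs$left_lung
  expect_true(all(r$labels[old] == 3)) # soft code
  expect_equal(unique(as.vector(r$activity[old])), 1.0)
  soft_band <- range(ph$hu_means["soft"] +
                       c(-5.5, 5.5) * ph$config$tissue_table$ct_hu_sd[4])
  expect_true(all(r$ct_hu[old] > soft_band[1] & r$ct_hu[old] < soft_band[2]))
})

test_that("lung nodule volume matches the voxel-count oracle", {
  cfg <- phantom_config(grid_shape = c(128L, 128L, 9L),
                        voxel_spacing = c(2, 2, 2))
  ph <- generate_phantom(cfg, 5)
  idx <- which(ph$organs$right_lung, arr.ind = TRUE)
  ctr <- round(colMeans(idx))
  center <- (ctr - c(64.5, 64.5, 5)) * 2
  n <- add_lung_nodule(ph, center = center, radius_mm = 6.2, uptake_ratio = 1)
  voi <- n$organs$lesion_1
  # 1.0 mL at 2x2x2 mm -> 125 voxels (discretization tolerance)
  expect_lt(abs(sum(voi) - 125), 20)
  # uptake_ratio = 1: lesion activity equals soft-tissue activity
  expect_equal(unique(as.vector(n$activity[voi])), 1.0)
  # center in soft tissue is a precondition error
  expect_error(add_lung_nodule(ph, center = c(0, 0, 0)), "inside a lung")
})

test_that("corruptions are local: voxels outside the stated support unchanged", {
  ph <- fixture_phantom(7)
  checks <- list(
    inject_truncation(ph, 0.12),
    inject_metal(ph, center = c(55, 25), void_radius = 20, implant_radius = 6),
    remove_lung(ph, "left")
  )
  for (cor in checks) {
    mask <- Reduce(`|`, lapply(cor$outliers_applied,
                               function(o) if (is.null(o$support)) o$mask else o$support))
    # the recorded mask for lung removal includes the adjacent band; the
    # modified voxels are always inside the recorded support
    changed <- cor$mr != ph$mr | cor$ct_hu != ph$ct_hu |
      cor$activity != ph$activity | cor$labels != ph$labels
    expect_true(all(mask[changed]))
  }
})

test_that("class HU consistency holds after corruption (implant excepted)", {
  ph <- inject_metal(fixture_phantom(7), center = c(55, 25),
                     void_radius = 20, implant_radius = 6)
  tt <- ph$config$tissue_table
  for (code in setdiff(unique(as.vector(ph$labels)), 7)) {
    sel <- ph$labels == code
    band <- ph$hu_means[code + 1] + c(-5, 5) * max(tt$ct_hu_sd[code + 1], 1)
    expect_true(all(ph$ct_hu[sel] >= band[1] & ph$ct_hu[sel] <= band[2]))
  }
})

test_that("session misalignment is seeded and respects the peak magnitude", {
  ph <- fixture_phantom(7)
  a <- simulate_session_misalignment(ph, 6, seed = 4)
  b <- simulate_session_misalignment(ph, 6, seed = 4)
  expect_identical(a$mr_moved, b$mr_moved)
  peak <- max(sqrt(a$truth_field$dx^2 + a$truth_field$dy^2))
  expect_equal(peak, 6, tolerance = 1e-8)
  expect_false(identical(a$mr_moved, ph$mr))
})
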