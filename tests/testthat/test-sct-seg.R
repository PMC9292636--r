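test_that("body delineation matches phantom truth on clean MR", {
  ph <- fixture_phantom(7)
  body <- delineate_body(fixture_mr_norm(7))
  expect_gte(dice(body, ph$organs$body), 0.98)
  expect_error(delineate_body(array(0, c(16, 16, 1))), "constant")
})

test_that("truncated MR yields a body mask without the truncated arms", {
  ph <- fixture_phantom(7)
  tr <- inject_truncation(ph, 0.15)
  mrn <- normalize_unit_range(correct_bias_field(tr$mr, tr$mr > otsu_vec(tr$mr)))
  body <- delineate_body(mrn)
  cut <- tr$outliers_applied[[1]]$mask
  expect_lt(sum(body & cut) / sum(cut), 0.05)
})

test_that("lung segmentation matches truth and handles single-lung anatomy", {
  # noiseless phantom: segmentation accuracy against truth masks
  cfg0 <- desk_config()
  cfg0$tissue_table$ct_hu_sd[] <- 0
  cfg0$tissue_table$mr_sd[] <- 0
  cfg0$mr_bias_field_amplitude <- 0
  cfg0$subject_hu_jitter <- 0
  ph0 <- generate_phantom(cfg0, 7)
  mrn0 <- normalize_unit_range(ph0$mr)
  lungs0 <- segment_lungs(mrn0, delineate_body(mrn0), spacing = ph0$spacing)
  truth0 <- ph0$organs$right_lung | ph0$organs$left_lung
  expect_gte(dice(lungs0, truth0), 0.95)
  # default (noisy, biased) phantom: still two components, decent accuracy
  ph <- fixture_phantom(7)
  mrn <- fixture_mr_norm(7)
  body <- delineate_body(mrn)
  lungs <- segment_lungs(mrn, body, spacing = ph$spacing)
  truth <- ph$organs$right_lung | ph$organs$left_lung
  expect_gte(dice(lungs, truth), 0.85)
  expect_equal(attr(lungs, "n_components")[1], 2L)
  # removed lung: exactly one lung component found
  single <- remove_lung(ph, "left")
  mrn1 <- normalize_unit_range(correct_bias_field(single$mr,
                                                  single$mr > otsu_vec(single$mr)))
  l1 <- segment_lungs(mrn1, delineate_body(mrn1), spacing = ph$spacing)
  expect_equal(attr(l1, "n_components")[1], 1L)
  expect_gte(dice(l1, single$organs$right_lung), 0.85)
})

test_that("a metal void larger than the size prior is mis-labelled as lung", {
  ph <- fixture_phantom(7)
  m <- inject_metal(ph, center = c(0, -22), void_radius = 17, implant_radius = 6)
  mrn <- normalize_unit_range(correct_bias_field(m$mr, m$mr > otsu_vec(m$mr)))
  body <- delineate_body(mrn)
  lungs <- segment_lungs(mrn, body, spacing = ph$spacing)
  void <- m$outliers_applied[[1]]$mask
  expect_gt(sum(lungs & void) / sum(void & body), 0.5)
  # the mis-labelled void inflates the lung class beyond the true lungs
  truth <- ph$organs$right_lung | ph$organs$left_lung
  expect_gt(sum(lungs), sum(truth))
  expect_gt(sum(lungs & void & !truth), 0)
})

test_that("three-class sCT emits exactly the fixed class values", {
  ph <- fixture_phantom(7)
  seg <- build_seg_sct(fixture_mr_norm(7), spacing = ph$spacing)
  expect_true(all(sort(unique(as.vector(seg$mu_map$mu))) %in% c(0, 0.022, 0.096)))
  expect_true(all(sort(unique(as.vector(seg$sct_hu))) %in% c(-1000, -770, 0)))
  expect_equal(length(unique(as.vector(seg$sct_hu))), 3L)
  # per-class voxel counts equal the segmentation mask counts
  expect_equal(sum(seg$class_map == 1), sum(seg$lungs))
  expect_equal(sum(seg$class_map == 2), sum(seg$body & !seg$lungs))
  expect_equal(sum(seg$sct_hu == -770), sum(seg$lungs))
  # mu map is a deterministic relabelling of the class map
  expect_equal(array(c(0, 0.022, 0.096)[seg$class_map + 1], dim(seg$class_map)),
               seg$mu_map$mu)
})

test_that("an all-air input yields an all-zero attenuation map", {
  seg <- build_seg_sct(array(0, c(16, 16, 1)))
  expect_true(all(seg$mu_map$mu == 0))
  expect_true(all(seg$class_map == 0))
})
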