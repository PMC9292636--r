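test_that("voxel bias map implements the relative bias with a validity floor", {
  a <- array(1, c(4, 4, 1))
  expect_true(all(voxel_bias_map(a, a)$bias == 0))
  b <- voxel_bias_map(1.1 * a, a)
  expect_equal(unique(as.vector(b$bias)), 10)
  # floor: reference voxels {0.04, 0.2} with floor 0.05 -> one valid voxel
  r <- array(c(0.04, 0.2), c(2, 1, 1))
  s <- array(0.1, c(2, 1, 1))
  v <- voxel_bias_map(s, r, floor = 0.05)
  expect_equal(sum(v$valid), 1L)
  expect_true(is.na(v$bias[1, 1, 1]))
  expect_equal(v$bias[2, 1, 1], 100 * (0.1 - 0.2) / 0.2)
  expect_error(voxel_bias_map(array(1, c(2, 2, 1)), array(1, c(3, 3, 1))),
               "grid")
})

test_that("region statistics match a brute-force recomputation", {
  st <- region_stats(array(c(10, -10), c(2, 1, 1)),
                     array(TRUE, c(2, 1, 1)), array(TRUE, c(2, 1, 1)))
  expect_equal(st$mean, 0)
  expect_equal(st$abs_mean, 10)
  # empty intersection is explicit
  e <- region_stats(array(1, c(2, 1, 1)), array(TRUE, c(2, 1, 1)),
                    array(FALSE, c(2, 1, 1)))
  expect_true(e$empty)
  expect_equal(e$n_voxels, 0L)
  expect_true(is.na(e$mean))
  set.seed(4)
  bias <- array(rnorm(100, 5, 20), c(10, 10, 1))
  valid <- array(runif(100) > 0.2, c(10, 10, 1))
  mask <- array(runif(100) > 0.3, c(10, 10, 1))
  st2 <- region_stats(bias, valid, mask)
  sel <- valid & mask
  # two-pass loop oracle
  n <- 0; s <- 0
  for (i in which(sel)) { n <- n + 1; s <- s + bias[i] }
  m <- s / n
  ss <- 0
  for (i in which(sel)) ss <- ss + (bias[i] - m)^2
  expect_equal(st2$mean, m)
  expect_equal(st2$sd, sqrt(ss / (n - 1)))
  expect_equal(st2$n_voxels, n)
  expect_gte(st2$abs_mean, abs(st2$mean))
})

test_that("RMSE matches its definition and the triangle inequality", {
  a <- array(runif(64), c(8, 8, 1))
  expect_equal(rmse_volumes(a, a), 0)
  expect_equal(rmse_volumes(a + 0.37, a), 0.37, tolerance = 1e-12)
  set.seed(5)
  b <- a + array(rnorm(64, 0, 0.1), c(8, 8, 1))
  s <- 0
  for (i in 1:64) s <- s + (a[i] - b[i])^2
  expect_equal(rmse_volumes(a, b), sqrt(s / 64))
  c3 <- a + array(rnorm(64, 0, 0.2), c(8, 8, 1))
  expect_lte(rmse_volumes(a, c3), rmse_volumes(a, b) + rmse_volumes(b, c3))
})

test_that("tissue masks follow the closed HU thresholds", {
  ph <- fixture_phantom(7)
  lungs <- ph$organs$right_lung | ph$organs$left_lung
  tm <- tissue_masks_from_ct(ph$ct_hu, lungs, ph$organs$body)
  truth_bone <- ph$labels == 4
  expect_gte(dice(tm$bone, truth_bone), 0.9)
  expect_false(any(tm$soft & tm$bone))
  expect_true(all(tm$soft[ph$organs$liver_like]))
  # all-air CT: empty soft and bone
  airct <- array(-1000, dim(ph$ct_hu))
  tm0 <- tissue_masks_from_ct(airct, lungs, ph$organs$body)
  expect_false(any(tm0$soft) || any(tm0$bone))
  # closed interval endpoints
  edge <- array(c(-400, 160, -400.5, 160.5), c(4, 1, 1))
  body1 <- array(TRUE, c(4, 1, 1))
  tme <- tissue_masks_from_ct(edge, array(FALSE, c(4, 1, 1)), body1)
  expect_equal(as.vector(tme$soft), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(as.vector(tme$bone), c(FALSE, FALSE, FALSE, TRUE))
})

test_that("lesion VOI table reports volume, bias and the plausibility band", {
  bias <- array(-20, c(10, 10, 5))
  valid <- array(TRUE, c(10, 10, 5))
  les <- list(lesion_1 = array(FALSE, c(10, 10, 5)))
  les$lesion_1[4:6, 4:6, 2:3] <- TRUE # 18 voxels * 8 mm3 = 0.144 mL
  vb <- voi_bias(bias, valid, les, spacing = c(2, 2, 2))
  expect_equal(vb$volume_ml, 18 * 8 / 1000)
  expect_false(vb$in_band)
  expect_equal(vb$mean_bias, -20)
})

test_that("paired t-test conventions handle degenerate inputs", {
  expect_equal(paired_ttest(1:5, 1:5)$p, 1)
  expect_warning(r <- paired_ttest(1:5 + 2, 1:5), "zero-variance")
  expect_equal(r$p, 0)
  expect_true(is.infinite(r$t))
  set.seed(8)
  a <- rnorm(12); b <- rnorm(12)
  r2 <- paired_ttest(a, b)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(r2$p, tt$p.value)
  expect_equal(r2$t, unname(tt$statistic))
})

test_that("report assembly aggregates per-subject rows and runs paired tests", {
  rows <- expand.grid(subject = 1:4, region = c("lung", "body"),
                      arm = c("seg", "dl"), stringsAsFactors = FALSE)
  set.seed(2)
  rows$mean <- rnorm(nrow(rows), ifelse(rows$arm == "seg", -10, -2), 1)
  rows$sd <- 1; rows$abs_mean <- abs(rows$mean); rows$abs_sd <- 1
  rows$n_voxels <- 50L
  rmse <- expand.grid(subject = 1:4, arm = c("seg", "dl"))
  rmse$rmse <- runif(nrow(rmse))
  rep <- build_report(rows, rmse, test_metric = "body")
  expect_s3_class(rep, "bias_report")
  expect_equal(nrow(rep$summary), 4) # 2 regions x 2 arms
  expect_true(all(c("t", "p") %in% names(rep$tests)))
  d <- tempfile()
  paths <- write_report(rep, d)
  expect_true(file.exists(file.path(d, "summary.csv")))
  expect_true(any(grepl("report.md$", paths)))
})
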