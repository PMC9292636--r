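make_entry <- function(mr, ct, spacing = c(1, 1, 1), id = NULL) {
  atlas_entry(mr, ct, spacing = spacing, id = id)
}

test_that("bone voting follows the majority and is monotone in the threshold", {
  dims <- c(8, 8, 1)
  base <- array(-100, dims)
  mk <- function(bone_at) {
    ct <- base
    ct[bone_at] <- 500
    make_entry(array(0.5, dims), ct)
  }
  ds <- atlas_dataset(list(mk(1:10), mk(1:10), mk(30:40)))
  vote <- vote_bone_map(ds, 0.5)
  expect_true(all(vote[1:10]))   # 2 of 3 atlases agree
  expect_false(any(vote[30:40])) # 1 of 3 is below threshold
  # all atlases identical -> vote output equals that mask
  ds2 <- atlas_dataset(list(mk(5:12), mk(5:12)))
  expect_equal(which(vote_bone_map(ds2, 0.5)), 5:12)
  # threshold sweep on random masks: bone count monotone non-increasing
  set.seed(3)
  entries <- lapply(1:5, function(i) {
    ct <- base
    ct[sample(64, 20)] <- 500
    make_entry(array(0.5, dims), ct)
  })
  dsr <- atlas_dataset(entries)
  counts <- vapply(seq(0.1, 1, by = 0.1),
                   function(th) sum(vote_bone_map(dsr, th)), 0)
  expect_true(all(diff(counts) <= 0))
  expect_error(vote_bone_map(atlas_dataset(entries[1]), 0.5), "at least 2")
})

test_that("signed distance matches brute force and handles edge cases", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  d <- signed_distance_map(m, c(1, 1, 1))
  expect_equal(d[5, 5, 1], 0) # single voxel is its own boundary
  expect_equal(d[5, 6, 1], 1)
  expect_equal(d[6, 6, 1], sqrt(2))
  expect_error(signed_distance_map(matrix(FALSE, 4, 4)), "empty")
  # 11x11 square inside a 25x25 grid vs exhaustive nearest-boundary search
  sq <- matrix(FALSE, 25, 25); sq[8:18, 8:18] <- TRUE
  sp <- c(1.5, 2) # anisotropic
  d2 <- signed_distance_map(sq, c(sp, 1))
  bnd <- which(sctpet:::boundary_voxels(sq), arr.ind = TRUE)
  brute <- matrix(0, 25, 25)
  for (i in 1:25) for (j in 1:25) {
    dd <- sqrt(((i - bnd[, 1]) * sp[1])^2 + ((j - bnd[, 2]) * sp[2])^2)
    brute[i, j] <- min(dd)
  }
  sign_m <- ifelse(sq & !sctpet:::boundary_voxels(sq), -1, 1)
  expect_equal(d2[, , 1], brute * sign_m, tolerance = 1e-12)
})

test_that("phase congruency responds to structure, not contrast", {
  cst <- matrix(7, 48, 48)
  expect_lt(max(phase_congruency(cst)), 1e-6)
  step <- matrix(0, 48, 48); step[25:48, ] <- 1
  pc <- phase_congruency(step)[, , 1]
  edge_mean <- mean(pc[24:25, 10:38])
  flat_mean <- mean(pc[c(5:15, 35:44), 10:38])
  expect_gt(edge_mean, 3 * flat_mean)
  expect_gt(edge_mean, 0.3)
  ph <- fixture_phantom(7)
  a <- phase_congruency(ph$mr[, , 1])
  b <- phase_congruency(2 * ph$mr[, , 1] + 10)
  expect_lt(max(abs(a - b)), 1e-8)
  expect_true(all(a >= 0 & a <= 1))
})

test_that("atlas weights follow the stated Gaussian kernel product", {
  dims <- c(3, 1, 1)
  ent <- function(sd_vals, pcm_vals) {
    e <- list(mr = array(0.5, dims), ct_hu = array(0, dims),
              bone_mask = array(FALSE, dims),
              signed_distance = array(sd_vals, dims),
              pcm = array(pcm_vals, dims),
              valid = array(TRUE, dims), spacing = c(1, 1, 1), id = NULL)
    class(e) <- "atlas_entry"
    e
  }
  target <- list(signed_distance = array(c(0, 2, -1), dims),
                 pcm = array(c(0.5, 0.1, 0.9), dims))
  ds <- atlas_dataset(list(ent(c(0, 0, 0), c(0.5, 0.3, 0.4)),
                           ent(c(3, 2, -1), c(0.1, 0.1, 0.9))))
  sigma_d <- 5; sigma_p <- 0.2
  w <- atlas_weights(target, ds, sigma_d, sigma_p, patch_radius = 0)
  # spreadsheet-style manual evaluation of the kernels
  manual_raw <- function(dd, dp) exp(-dd^2 / (2 * sigma_d^2)) * exp(-dp^2 / (2 * sigma_p^2))
  r1 <- manual_raw(c(0, 2, -1) - c(0, 0, 0), c(0.5, 0.1, 0.9) - c(0.5, 0.3, 0.4))
  r2 <- manual_raw(c(0, 2, -1) - c(3, 2, -1), c(0.5, 0.1, 0.9) - c(0.1, 0.1, 0.9))
  expect_equal(as.vector(w[[1]]), r1 / (r1 + r2), tolerance = 1e-12)
  expect_equal(as.vector(w[[2]]), r2 / (r1 + r2), tolerance = 1e-12)
  # two identical atlases: weights 0.5 everywhere
  ds2 <- atlas_dataset(list(ent(c(1, 1, 1), c(0.2, 0.2, 0.2)),
                            ent(c(1, 1, 1), c(0.2, 0.2, 0.2))))
  w2 <- atlas_weights(target, ds2, sigma_d, sigma_p, 0)
  expect_true(all(abs(w2[[1]] - 0.5) < 1e-12))
  # an atlas identical to the target dominates everywhere
  ds3 <- atlas_dataset(list(ent(as.vector(target$signed_distance),
                                as.vector(target$pcm)),
                            ent(c(3, 3, 3), c(0.9, 0.9, 0.1))))
  w3 <- atlas_weights(target, ds3, sigma_d, sigma_p, 0)
  expect_true(all(w3[[1]] >= w3[[2]]))
})

test_that("fusion is a convex combination, permutation-invariant, exact for one atlas", {
  dims <- c(6, 6, 1)
  set.seed(9)
  mk <- function(seed) {
    ct <- array(rnorm(36, 0, 300), dims)
    atlas_entry(array(runif(36), dims), ct, spacing = c(1, 1, 1))
  }
  entries <- lapply(1:4, mk)
  target <- list(signed_distance = entries[[1]]$signed_distance,
                 pcm = entries[[1]]$pcm)
  ds <- atlas_dataset(entries)
  w <- atlas_weights(target, ds, 5, 0.2, 1)
  fused <- fuse_sct(ds, w)
  cts <- sapply(entries, function(e) as.vector(e$ct_hu))
  expect_true(all(fused >= apply(cts, 1, min) - 1e-9))
  expect_true(all(fused <= apply(cts, 1, max) + 1e-9))
  # permutation invariance
  perm <- c(3, 1, 4, 2)
  dsp <- atlas_dataset(entries[perm])
  wp <- atlas_weights(target, dsp, 5, 0.2, 1)
  expect_equal(fuse_sct(dsp, wp), fused, tolerance = 1e-9)
  # single atlas: fused equals that atlas exactly
  ds1 <- atlas_dataset(entries[1])
  w1 <- list(array(1, dims))
  expect_equal(fuse_sct(ds1, w1), entries[[1]]$ct_hu)
})

test_that("atlas mapping registers MR and carries the CT along", {
  ph1 <- fixture_phantom(7)
  ph2 <- fixture_phantom(8)
  pp1 <- fixture_mr_norm(7)
  pp2 <- fixture_mr_norm(8)
  ds <- map_atlases_to_target(list(pp2), list(ph2$ct_hu), pp1,
                              spacing = ph1$spacing)
  expect_equal(length(ds), 1L)
  e <- ds$entries[[1]]
  # mapped CT body should overlap the target body better than chance
  mapped_body <- e$ct_hu > -500 & e$valid
  expect_gt(dice(mapped_body, ph1$organs$body), 0.7)
})
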