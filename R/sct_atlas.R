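# Voxel-wise-weighted multi-atlas sCT. Each atlas MR-CT pair is deformed to
# the target MR (the CT rides along on the MR transform), a bone map is
# voted voxel-wise, and atlases are weighted at every voxel by a product of
# Gaussian kernels on (i) the signed-distance discrepancy to the voted
# target bone map and (ii) the local mean absolute phase-congruency
# difference. The fused sCT is the convex combination of the mapped CTs.

ATLAS_BONE_HU <- 160 # bone definition shared with the evaluation thresholds

#' Construct an atlas entry from a target-aligned MR-CT pair
#'
#' Derives the features used by the fusion weights: bone mask
#' (CT > 160 HU), signed distance to the bone boundary, and the phase
#' congruency map of the MR.
#'
#' @param mr target-aligned, preprocessed MR volume
#' @param ct_hu target-aligned CT volume (HU); NA marks voxels the
#'   registration could not map (out of the atlas domain)
#' @param spacing voxel spacing (mm)
#' @param id optional identifier
#' @return object of class \code{atlas_entry}
#' @export
atlas_entry <- function(mr, ct_hu, spacing = c(2, 2, 2), id = NULL) {
  mr <- as_vol3d(mr); ct_hu <- as_vol3d(ct_hu)
  stopifnot(identical(dim(mr), dim(ct_hu)))
  valid <- !is.na(ct_hu)
  bone <- valid & ct_hu > ATLAS_BONE_HU
  sdist <- if (any(bone)) {
    signed_distance_map(bone, spacing)
  } else {
    array(Inf, dim = dim(mr)) # boneless atlas: infinitely far from bone
  }
  structure(list(mr = mr, ct_hu = ct_hu, bone_mask = bone,
                 signed_distance = sdist, pcm = phase_congruency(mr),
                 valid = valid, spacing = spacing, id = id),
            class = "atlas_entry")
}

#' Bundle atlas entries into a dataset
#' @param entries list of \code{atlas_entry}
#' @param target_id identifier excluded by the leave-one-out scheme
#' @return object of class \code{atlas_dataset}
#' @export
atlas_dataset <- function(entries, target_id = NULL) {
  if (!is.null(target_id)) {
    entries <- Filter(function(e) !identical(e$id, target_id), entries)
  }
  structure(list(entries = entries, target_id = target_id),
            class = "atlas_dataset")
}

#' @export
length.atlas_dataset <- function(x) length(x$entries)

#' Map atlas MR-CT pairs onto a target MR
#'
#' Registers each atlas MR to the target (affine then B-spline, mutual
#' information) and resamples both the MR and its paired CT through the
#' same transform (linear interpolation). CT voxels mapped from outside the
#' atlas domain are NA and receive zero fusion weight.
#'
#' @param atlas_mrs,atlas_cts lists of co-registered atlas volumes
#' @param target_mr target MR volume (preprocessed like the atlas MRs)
#' @param spacing voxel spacing (mm)
#' @param ids optional identifiers per atlas
#' @param target_id identifier excluded from the dataset (LOOCV)
#' @param bspline_control control list for the B-spline stage
#' @return \code{atlas_dataset} of target-aligned entries
#' @export
map_atlases_to_target <- function(atlas_mrs, atlas_cts, target_mr,
                                  spacing = c(2, 2, 2), ids = NULL,
                                  target_id = NULL, bspline_control = list()) {
  stopifnot(length(atlas_mrs) == length(atlas_cts))
  target_mr <- as_vol3d(target_mr)
  entries <- vector("list", length(atlas_mrs))
  for (i in seq_along(atlas_mrs)) {
    id <- if (!is.null(ids)) ids[[i]] else i
    if (!is.null(target_id) && identical(id, target_id)) next
    mr_i <- as_vol3d(atlas_mrs[[i]])
    ct_i <- as_vol3d(atlas_cts[[i]])
    field <- register_pair(mr_i, target_mr, spacing = spacing,
                           bspline_control = bspline_control)
    mr_w <- resample_volume(mr_i, field, "linear",
                            fill = as.numeric(quantile(mr_i, 0.01)))
    ct_w <- resample_volume(ct_i, field, "linear", fill = NA_real_)
    entries[[i]] <- atlas_entry(mr_w, ct_w, spacing, id = id)
  }
  atlas_dataset(Filter(Negate(is.null), entries), target_id = target_id)
}

#' Vote a bone map across aligned atlases
#'
#' A voxel is bone iff the mean of the aligned atlas bone masks (over
#' atlases whose CT covers the voxel) reaches the vote threshold.
#' @param dataset \code{atlas_dataset} with >= 2 entries
#' @param threshold vote threshold in (0, 1]
#' @return logical bone map
#' @export
vote_bone_map <- function(dataset, threshold = 0.5) {
  if (length(dataset) < 2) stop_sctpet("bone voting needs at least 2 atlases")
  dims <- dim(dataset$entries[[1]]$bone_mask)
  votes <- array(0, dim = dims)
  cover <- array(0, dim = dims)
  for (e in dataset$entries) {
    votes <- votes + (e$bone_mask & e$valid)
    cover <- cover + e$valid
  }
  frac <- votes / pmax(cover, 1)
  frac >= threshold & cover > 0
}

#' Voxel-wise atlas fusion weights
#'
#' w_i(v) = exp(-dd_i(v)^2 / (2 sigma_d^2)) * exp(-dp_i(v)^2 / (2 sigma_p^2)),
#' where dd_i is the discrepancy between the atlas signed distance map and
#' the target's (from the voted bone map) and dp_i is the mean absolute
#' phase-congruency difference over a local patch. Weights are normalized
#' to sum to one over atlases at every voxel; atlases without CT coverage
#' get zero weight; if every raw weight underflows at a voxel the weights
#' fall back to uniform over covering atlases (count reported in
#' \code{attr(, "n_fallback")}).
#'
#' @param target list with elements \code{signed_distance} and \code{pcm}
#'   (target features; the signed distance comes from the voted bone map)
#' @param dataset \code{atlas_dataset}
#' @param sigma_d signed-distance kernel width (mm)
#' @param sigma_p phase-congruency kernel width (unitless)
#' @param patch_radius patch radius (voxels) for the PCM comparison
#' @return list of per-atlas weight volumes summing to 1 voxel-wise
#' @export
atlas_weights <- function(target, dataset, sigma_d = 5, sigma_p = 0.2,
                          patch_radius = 2) {
  n <- length(dataset)
  dims <- dim(dataset$entries[[1]]$mr)
  raw <- vector("list", n)
  for (i in seq_len(n)) {
    e <- dataset$entries[[i]]
    dd <- target$signed_distance - e$signed_distance
    dd[!is.finite(dd)] <- ifelse(
      is.finite(target$signed_distance[!is.finite(dd)]), 1e6, 0)
    dp <- array(0, dim = dims)
    for (k in seq_len(dims[3])) {
      dp[, , k] <- box_mean(abs(target$pcm[, , k] - e$pcm[, , k]), patch_radius)
    }
    w <- exp(-dd^2 / (2 * sigma_d^2)) * exp(-dp^2 / (2 * sigma_p^2))
    w[!e$valid] <- 0
    raw[[i]] <- w
  }
  total <- Reduce(`+`, raw)
  cover <- Reduce(`+`, lapply(dataset$entries, function(e) e$valid * 1))
  fallback <- total <= 1e-12 & cover > 0
  out <- vector("list", n)
  for (i in seq_len(n)) {
    w <- raw[[i]] / pmax(total, 1e-12)
    w[fallback] <- (dataset$entries[[i]]$valid[fallback] * 1) /
      pmax(cover[fallback], 1)
    w[total <= 1e-12 & cover == 0] <- 0
    out[[i]] <- w
  }
  attr(out, "n_fallback") <- sum(fallback)
  out
}

#' Fuse a continuous sCT from weighted atlases
#'
#' sct(v) = sum_i w_i(v) ct_i(v): a convex combination, so the fused value
#' lies between the minimum and maximum atlas CT value at every covered
#' voxel. Voxels no atlas covers take the background fill (-1000 HU).
#'
#' @param dataset \code{atlas_dataset}
#' @param weights per-atlas weight volumes from \code{\link{atlas_weights}}
#' @param fill_hu value for voxels with no atlas coverage
#' @return fused sCT volume (HU)
#' @export
fuse_sct <- function(dataset, weights, fill_hu = -1000) {
  n <- length(dataset)
  stopifnot(length(weights) == n)
  dims <- dim(dataset$entries[[1]]$ct_hu)
  acc <- array(0, dim = dims)
  wsum <- array(0, dim = dims)
  for (i in seq_len(n)) {
    ct <- dataset$entries[[i]]$ct_hu
    ct[is.na(ct)] <- 0
    acc <- acc + weights[[i]] * ct
    wsum <- wsum + weights[[i]]
  }
  out <- acc / pmax(wsum, 1e-12)
  out[wsum <= 1e-12] <- fill_hu
  out
}

#' Atlas-based sCT pipeline
#'
#' Maps all atlases to the target, votes the bone map, derives the target
#' signed-distance and phase-congruency features, computes the fusion
#' weights and fuses the continuous sCT.
#'
#' @param target_mr preprocessed target MR volume
#' @param atlas_mrs,atlas_cts lists of co-registered atlas MR/CT volumes
#' @param spacing voxel spacing (mm)
#' @param sigma_d,sigma_p,patch_radius fusion weight parameters
#' @param vote_threshold bone vote threshold
#' @param ids,target_id LOOCV bookkeeping, passed through
#' @param bspline_control registration control list
#' @return list(sct_hu, bone_map, dataset, weights)
#' @export
build_atlas_sct <- function(target_mr, atlas_mrs, atlas_cts,
                            spacing = c(2, 2, 2), sigma_d = 5, sigma_p = 0.2,
                            patch_radius = 2, vote_threshold = 0.5,
                            ids = NULL, target_id = NULL,
                            bspline_control = list()) {
  ds <- map_atlases_to_target(atlas_mrs, atlas_cts, target_mr,
                              spacing = spacing, ids = ids,
                              target_id = target_id,
                              bspline_control = bspline_control)
  bone <- vote_bone_map(ds, vote_threshold)
  tsd <- if (any(bone)) signed_distance_map(bone, spacing) else {
    array(Inf, dim = dim(as_vol3d(target_mr)))
  }
  target_feats <- list(signed_distance = tsd,
                       pcm = phase_congruency(as_vol3d(target_mr)))
  w <- atlas_weights(target_feats, ds, sigma_d, sigma_p, patch_radius)
  list(sct_hu = fuse_sct(ds, w), bone_map = bone, dataset = ds, weights = w)
}
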