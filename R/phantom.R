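# Digital torso phantom: co-registered tissue labels, CT (HU), in-phase-like
# MR (arbitrary units, bone and air dark), and an FDG-like activity map,
# built from geometric primitives on a pseudo-3D stack of independent
# transaxial slices. Each corruption operation is a pure function of its
# inputs and records the voxels it touched.

TISSUE_CLASSES <- c("air", "lung", "fat", "soft", "bone", "marrow", "lesion", "implant")

# in-phase MR signal gained per HU of extra lung density (proton-density
# coupling between CT attenuation and MR intensity in aerated tissue)
HU_TO_MR_SLOPE <- (0.55 - 0.17) / (40 - (-770))

default_tissue_table <- function() {
  data.frame(
    class = TISSUE_CLASSES,
    ct_hu_mean = c(-1000, -770, -90, 40, 700, 120, 45, 3000),
    ct_hu_sd = c(5, 30, 15, 15, 80, 25, 10, 0),
    mr_mean = c(0.03, 0.17, 0.78, 0.55, 0.10, 0.45, 0.55, 0.03),
    mr_sd = c(0.010, 0.020, 0.030, 0.030, 0.020, 0.030, 0.030, 0.010),
    activity_mean = c(0, 0.3, 0.7, 1.0, 0.8, 0.8, 4.0, 0),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the digital torso phantom
#'
#' Defines the grid, the geometric primitives (all in mm, centred physical
#' coordinates) and the per-tissue contrast table. Defaults give a
#' 128 x 128 x 3 stack at 2 mm isotropic spacing, a torso ellipse with two
#' lateral arms, two lungs, a spine with marrow, four ribs and a peripheral
#' fat layer. MR contrast follows in-phase Dixon behaviour: bone and air are
#' both dark, which is exactly the ambiguity the sCT methods must resolve.
#'
#' @param grid_shape integer vector c(nx, ny, nz)
#' @param voxel_spacing numeric vector c(dx, dy, dz) in mm, all > 0
#' @param body_axes semi-axes (mm) of the torso ellipse
#' @param arm_radius radius (mm) of the two lateral arm discs
#' @param arm_offset centre-to-centre distance (mm) from midline to each arm
#' @param lung_axes semi-axes (mm) of each lung ellipse
#' @param lung_centers 2 x 2 matrix of lung centres (mm), rows = right/left
#' @param spine_radius radius (mm) of the vertebral disc
#' @param spine_center centre (mm) of the spine
#' @param marrow_radius radius (mm) of the marrow core inside the spine
#' @param rib_spec data.frame with columns x, y, r (mm): rib cross-sections
#' @param fat_thickness thickness (mm) of the peripheral fat layer
#' @param tissue_table data.frame with columns class, ct_hu_mean, ct_hu_sd,
#'   mr_mean, mr_sd, activity_mean (one row per tissue class)
#' @param mr_bias_field_amplitude peak fractional amplitude of the smooth
#'   multiplicative MR bias field (0.2 = +/-20 percent)
#' @param jitter_sd fractional SD of per-subject anatomical jitter on axes
#' @param lung_scale_range per-lung uniform size-scale range: each lung of
#'   each subject draws its own scale, emulating the wide spread of lung
#'   volumes (atelectasis, effusion, hyperinflation) seen in a clinical
#'   cohort; c(1, 1) disables the extra variation
#' @param subject_hu_jitter scale of the per-subject tissue-density shifts
#'   (1 = defaults below, 0 = off): each subject draws its own mean HU per
#'   class (lung SD 55 HU clamped to +/-140, bone SD 50, fat 10, soft 8,
#'   marrow 20), emulating the inter-patient density variability that a
#'   fixed-coefficient attenuation map cannot follow
#' @param noise_seed integer base seed for the noise realisation
#' @param anatomy_scale global scale factor applied to every geometric
#'   primitive (a convenience for small fast grids)
#' @return object of class \code{phantom_config}
#' @export
phantom_config <- function(grid_shape = c(128L, 128L, 3L),
                           voxel_spacing = c(2, 2, 2),
                           body_axes = c(88, 62),
                           arm_radius = 12,
                           arm_offset = 104,
                           lung_axes = c(26, 36),
                           lung_centers = rbind(right = c(38, 8), left = c(-38, 8)),
                           spine_radius = 11,
                           spine_center = c(0, -40),
                           marrow_radius = 5,
                           rib_spec = data.frame(
                             x = c(74, -74, 64, -64, 40, -40, 58, -58, 0),
                             y = c(-20, -20, 38, 38, -48, -48, -38, -38, 48),
                             r = c(7, 7, 6, 6, 6, 6, 8, 8, 7)
                           ),
                           fat_thickness = 7,
                           tissue_table = default_tissue_table(),
                           mr_bias_field_amplitude = 0.2,
                           jitter_sd = 0.05,
                           lung_scale_range = c(1, 1),
                           subject_hu_jitter = 1,
                           noise_seed = 1L,
                           anatomy_scale = 1) {
  if (anatomy_scale != 1) {
    s <- anatomy_scale
    body_axes <- body_axes * s; arm_radius <- arm_radius * s
    arm_offset <- arm_offset * s; lung_axes <- lung_axes * s
    lung_centers <- lung_centers * s; spine_radius <- spine_radius * s
    spine_center <- spine_center * s; marrow_radius <- marrow_radius * s
    rib_spec <- data.frame(x = rib_spec$x * s, y = rib_spec$y * s,
                           r = rib_spec$r * s)
    fat_thickness <- fat_thickness * s
  }
  cfg <- list(
    grid_shape = as.integer(grid_shape), voxel_spacing = as.numeric(voxel_spacing),
    body_axes = body_axes, arm_radius = arm_radius, arm_offset = arm_offset,
    lung_axes = lung_axes, lung_centers = lung_centers,
    spine_radius = spine_radius, spine_center = spine_center,
    marrow_radius = marrow_radius, rib_spec = rib_spec,
    fat_thickness = fat_thickness, tissue_table = tissue_table,
    mr_bias_field_amplitude = mr_bias_field_amplitude,
    jitter_sd = jitter_sd, lung_scale_range = lung_scale_range,
    subject_hu_jitter = subject_hu_jitter,
    noise_seed = as.integer(noise_seed)
  )
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  tt <- cfg$tissue_table
  row <- function(cl) tt[tt$class == cl, , drop = FALSE]
  if (any(cfg$voxel_spacing <= 0)) stop_sctpet("all voxel spacings must be > 0")
  if (row("air")$ct_hu_mean > -950) stop_sctpet("air CT mean must be <= -950 HU")
  if (row("lung")$ct_hu_mean < -900 || row("lung")$ct_hu_mean > -500)
    stop_sctpet("lung CT mean must lie in [-900, -500] HU")
  if (row("bone")$ct_hu_mean <= 160) stop_sctpet("bone CT mean must be > 160 HU")
  if (row("bone")$mr_mean >= row("soft")$mr_mean ||
      row("air")$mr_mean >= row("soft")$mr_mean)
    stop_sctpet("in-phase MR: bone and air must be darker than soft tissue")
  if (any(tt$activity_mean < 0)) stop_sctpet("activity means must be >= 0")
  invisible(cfg)
}

tissue_value <- function(cfg, class, column) {
  tt <- cfg$tissue_table
  tt[[column]][tt$class == class]
}

label_code <- function(class) match(class, TISSUE_CLASSES) - 1L

in_ellipse <- function(x, y, center, axes) {
  ((x - center[1]) / axes[1])^2 + ((y - center[2]) / axes[2])^2 <= 1
}

# Smooth low-order multiplicative bias field for one slice, peak fractional
# amplitude `amp`: exp of a random quadratic surface scaled to log(1 + amp).
make_bias_field <- function(nx, ny, spacing, amp) {
  if (amp <= 0) return(matrix(1, nx, ny))
  co <- slice_coords(nx, ny, spacing)
  xh <- co$x / max(abs(co$x)); yh <- co$y / max(abs(co$y))
  cf <- rnorm(5)
  p <- cf[1] * xh + cf[2] * yh + cf[3] * xh * yh +
    cf[4] * (xh^2 - 1 / 3) + cf[5] * (yh^2 - 1 / 3)
  p <- p / max(abs(p)) * log1p(amp)
  exp(p)
}

#' Generate a digital torso phantom
#'
#' Builds the co-registered truth bundle for one synthetic subject: tissue
#' labels, CT in HU, in-phase-like MR with multiplicative bias field and
#' additive Gaussian noise, an FDG-like activity map, and named organ masks.
#' Anatomy is jittered per subject (axes, lung centres) and tapers mildly
#' along the slice direction. Deterministic for fixed (config, subject_seed).
#'
#' @param config \code{phantom_config}
#' @param subject_seed integer; drives the anatomical jitter and, combined
#'   with \code{config$noise_seed}, the noise realisation
#' @return object of class \code{torso_phantom}: list with elements
#'   \code{labels} (integer codes, see \code{TISSUE_CLASSES}), \code{ct_hu},
#'   \code{mr}, \code{activity}, \code{bias_field}, \code{organs} (named list
#'   of logical masks), \code{spacing}, \code{config}, \code{seed},
#'   \code{outliers_applied}
#' @export
generate_phantom <- function(config, subject_seed = 1L) {
  validate_phantom_config(config)
  nx <- config$grid_shape[1]; ny <- config$grid_shape[2]
  nz <- if (length(config$grid_shape) >= 3) config$grid_shape[3] else 1L
  sp <- config$voxel_spacing

  # subject-level anatomical jitter
  jit <- with_seed(derive_seed(subject_seed, "anatomy"), list(
    body = 1 + config$jitter_sd * rnorm(2),
    lung = 1 + config$jitter_sd * rnorm(2),
    lung_scale = runif(2, config$lung_scale_range[1], config$lung_scale_range[2]),
    lung_shift = 2.5 * rnorm(2),
    arm = 1 + config$jitter_sd * rnorm(1)
  ))
  body_axes <- config$body_axes * jit$body
  lung_axes <- config$lung_axes * jit$lung
  arm_r <- config$arm_radius * jit$arm

  # sizing check: torso plus arms must fit with a one-voxel margin
  half_fov <- c(nx, ny) / 2 * sp[1:2]
  need_x <- config$arm_offset + arm_r + sp[1]
  need_y <- body_axes[2] + sp[2]
  if (need_x > half_fov[1] || need_y > half_fov[2])
    stop_sctpet("grid too small to contain the configured body (+arms); need half-FOV >= (%.0f, %.0f) mm, have (%.0f, %.0f) mm",
                need_x, need_y, half_fov[1], half_fov[2])

  co <- slice_coords(nx, ny, sp)
  labels <- array(label_code("air"), dim = c(nx, ny, nz))
  organs <- list()
  org_arr <- function() array(FALSE, dim = c(nx, ny, nz))
  organs$body <- org_arr(); organs$right_lung <- org_arr(); organs$left_lung <- org_arr()
  organs$spine <- org_arr(); organs$liver_like <- org_arr()
  organs$arm_right <- org_arr(); organs$arm_left <- org_arr()

  for (k in seq_len(nz)) {
    # mild torso taper along z
    tz <- if (nz > 1) (k - (nz + 1) / 2) / ((nz - 1) / 2) else 0
    sc <- 1 + 0.03 * tz
    ba <- body_axes * sc; la <- lung_axes * sc
    torso <- in_ellipse(co$x, co$y, c(0, 0), ba)
    armR <- in_ellipse(co$x, co$y, c(config$arm_offset, 0), c(arm_r, arm_r))
    armL <- in_ellipse(co$x, co$y, c(-config$arm_offset, 0), c(arm_r, arm_r))
    body <- torso | armR | armL
    inner <- in_ellipse(co$x, co$y, c(0, 0), pmax(ba - config$fat_thickness, 1))
    fat <- torso & !inner
    cR <- config$lung_centers[1, ] + jit$lung_shift
    cL <- config$lung_centers[2, ] * c(1, 1) + jit$lung_shift * c(-1, 1)
    lungR <- in_ellipse(co$x, co$y, cR, la * jit$lung_scale[1]) & inner
    lungL <- in_ellipse(co$x, co$y, cL, la * jit$lung_scale[2]) & inner
    spine <- in_ellipse(co$x, co$y, config$spine_center, rep(config$spine_radius, 2))
    marrow <- in_ellipse(co$x, co$y, config$spine_center, rep(config$marrow_radius, 2))
    ribs <- Reduce(`|`, lapply(seq_len(nrow(config$rib_spec)), function(i) {
      rs <- config$rib_spec[i, ]
      in_ellipse(co$x, co$y, c(rs$x, rs$y) * sc, rep(rs$r, 2))
    }))
    ribs <- ribs & torso & !(lungR | lungL)
    liver <- in_ellipse(co$x, co$y, c(34, -34), c(22, 14)) & inner &
      !(lungR | lungL) & !spine

    sl <- matrix(label_code("air"), nx, ny)
    sl[body] <- label_code("soft")
    sl[fat] <- label_code("fat")
    sl[lungR | lungL] <- label_code("lung")
    sl[ribs] <- label_code("bone")
    sl[spine] <- label_code("bone")
    sl[marrow & spine] <- label_code("marrow")
    labels[, , k] <- sl

    organs$body[, , k] <- body
    organs$right_lung[, , k] <- lungR
    organs$left_lung[, , k] <- lungL
    organs$spine[, , k] <- spine | (marrow & spine)
    organs$liver_like[, , k] <- liver & sl == label_code("soft")
    organs$arm_right[, , k] <- armR
    organs$arm_left[, , k] <- armL
  }

  # voxel values from the tissue table, with per-subject density shifts:
  # real patients differ in lung aeration and bone mineral density, which is
  # what breaks any fixed-coefficient attenuation assignment
  tt <- config$tissue_table
  hu_means <- setNames(tt$ct_hu_mean, tt$class)
  if (config$subject_hu_jitter > 0) {
    sh <- with_seed(derive_seed(subject_seed, "tissue"), {
      s <- config$subject_hu_jitter
      c(lung = max(min(rnorm(1, 0, 55 * s), 140 * s), -140),
        bone = rnorm(1, 0, 50 * s), fat = rnorm(1, 0, 10 * s),
        soft = rnorm(1, 0, 8 * s), marrow = rnorm(1, 0, 20 * s))
    })
    hu_means[names(sh)] <- hu_means[names(sh)] + sh
  }
  tt$ct_hu_mean <- unname(hu_means[tt$class])
  # proton density couples MR signal to tissue density: a denser lung is
  # both more attenuating on CT and brighter on in-phase MR, so image-based
  # methods can in principle track it while a fixed coefficient cannot
  tt$mr_mean[tt$class == "lung"] <- tt$mr_mean[tt$class == "lung"] +
    (hu_means["lung"] - default_tissue_table()$ct_hu_mean[2]) * HU_TO_MR_SLOPE
  idx <- labels + 1L # label codes are 0-based row indices into TISSUE_CLASSES
  ct_mean <- array(tt$ct_hu_mean[idx], dim = dim(labels))
  ct_sd <- array(tt$ct_hu_sd[idx], dim = dim(labels))
  mr_mean <- array(tt$mr_mean[idx], dim = dim(labels))
  mr_sd <- array(tt$mr_sd[idx], dim = dim(labels))
  activity <- array(tt$activity_mean[idx], dim = dim(labels))

  noise_seed <- derive_seed(config$noise_seed, subject_seed, "noise")
  vols <- with_seed(noise_seed, {
    bias <- array(1, dim = dim(labels))
    for (k in seq_len(nz)) {
      bias[, , k] <- make_bias_field(nx, ny, sp, config$mr_bias_field_amplitude)
    }
    ct <- ct_mean + if (any(ct_sd > 0)) rnorm(length(ct_mean), 0, 1) * ct_sd else 0
    mr <- mr_mean * bias + if (any(mr_sd > 0)) rnorm(length(mr_mean), 0, 1) * mr_sd else 0
    list(ct = ct, mr = pmax(mr, 0), bias = bias)
  })

  structure(list(
    labels = labels, ct_hu = vols$ct, mr = vols$mr, activity = activity,
    bias_field = vols$bias, organs = organs, hu_means = hu_means,
    spacing = sp, config = config, seed = as.integer(subject_seed),
    outliers_applied = list()
  ), class = "torso_phantom")
}

#' @export
print.torso_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<torso_phantom> %d x %d x %d @ (%g, %g, %g) mm, seed %d\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$seed))
  if (length(x$outliers_applied)) {
    cat("  corruptions:", paste(vapply(x$outliers_applied, `[[`, "", "type"),
                                collapse = ", "), "\n")
  }
  invisible(x)
}

phantom_body_mask <- function(phantom) phantom$labels != label_code("air")

air_mr_level <- function(phantom) tissue_value(phantom$config, "air", "mr_mean")

record_outlier <- function(phantom, type, params, mask, support = mask) {
  phantom$outliers_applied <- c(
    phantom$outliers_applied,
    list(list(type = type, params = params, mask = mask, support = support)))
  phantom
}

#' Truncate the lateral MR field of view
#'
#' Emulates MR body truncation: everything outside the reduced transaxial
#' field of view is set to air-level MR signal. CT, activity and labels are
#' untouched (the artifact afflicts the MR acquisition only).
#'
#' @param phantom \code{torso_phantom}
#' @param lateral_fraction fraction of the FOV width removed from each side,
#'   in [0, 0.5); 0 is a no-op
#' @return corrupted phantom with the truncated in-body region recorded in
#'   \code{outliers_applied}
#' @export
inject_truncation <- function(phantom, lateral_fraction = 0.15) {
  if (lateral_fraction < 0 || lateral_fraction >= 0.5)
    stop_sctpet("lateral_fraction must lie in [0, 0.5)")
  if (lateral_fraction == 0) return(phantom)
  nx <- dim(phantom$mr)[1]
  w <- nx * phantom$spacing[1]
  xs <- grid_coords_mm(nx, phantom$spacing[1])
  outside <- abs(xs) > (0.5 - lateral_fraction) * w
  cut <- array(rep(outside, times = prod(dim(phantom$mr)[2:3])),
               dim = dim(phantom$mr))
  mask <- cut & phantom_body_mask(phantom)
  phantom$mr[cut] <- air_mr_level(phantom)
  record_outlier(phantom, "truncation",
                 list(lateral_fraction = lateral_fraction), mask,
                 support = cut)
}

sphere_mask <- function(dims, spacing, center, radius) {
  co <- slice_coords(dims[1], dims[2], spacing)
  zs <- grid_coords_mm(dims[3], spacing[3])
  cz <- if (length(center) >= 3) center[3] else 0
  out <- array(FALSE, dim = dims)
  for (k in seq_len(dims[3])) {
    dz2 <- (zs[k] - cz)^2
    if (dz2 <= radius^2) {
      out[, , k] <- (co$x - center[1])^2 + (co$y - center[2])^2 <= radius^2 - dz2
    }
  }
  out
}

#' Inject a metal implant with its MR susceptibility void
#'
#' The implant itself occupies a small sphere of very high CT density
#' (default 3000 HU); the MR susceptibility artifact blanks a much larger
#' surrounding sphere to air-level signal. Activity is unchanged.
#'
#' @param phantom \code{torso_phantom}
#' @param center physical point (mm, length 2 or 3) inside the body
#' @param void_radius radius (mm) of the MR signal void
#' @param implant_radius radius (mm) of the metal object; must be smaller
#'   than \code{void_radius}
#' @param implant_hu CT value of the implant (clipped-CT dialect, 3000 HU)
#' @return corrupted phantom; the void sphere is recorded in
#'   \code{outliers_applied}
#' @export
inject_metal <- function(phantom, center = c(0, -22), void_radius = 17,
                         implant_radius = 6, implant_hu = 3000) {
  if (implant_radius >= void_radius)
    stop_sctpet("implant_radius must be smaller than void_radius")
  dims <- dim(phantom$mr)
  ctr_vox <- round(c(center[1] / phantom$spacing[1] + (dims[1] + 1) / 2,
                     center[2] / phantom$spacing[2] + (dims[2] + 1) / 2))
  zc <- if (length(center) >= 3) {
    round(center[3] / phantom$spacing[3] + (dims[3] + 1) / 2)
  } else (dims[3] + 1) %/% 2
  if (any(ctr_vox < 1) || ctr_vox[1] > dims[1] || ctr_vox[2] > dims[2] ||
      zc < 1 || zc > dims[3] ||
      !phantom_body_mask(phantom)[ctr_vox[1], ctr_vox[2], zc])
    stop_sctpet("implant center must lie inside the body")
  void <- sphere_mask(dims, phantom$spacing, center, void_radius)
  implant <- sphere_mask(dims, phantom$spacing, center, implant_radius)
  phantom$mr[void] <- air_mr_level(phantom)
  phantom$ct_hu[implant] <- implant_hu
  phantom$labels[implant] <- label_code("implant")
  record_outlier(phantom, "metal",
                 list(center = center, void_radius = void_radius,
                      implant_radius = implant_radius), void)
}

#' Remove one lung (post-pneumonectomy anatomy)
#'
#' The chosen lung region is relabelled as soft tissue in labels, CT, MR and
#' activity; the stored bias field is re-applied to the regenerated MR so the
#' phantom stays internally consistent. The other lung is untouched.
#'
#' @param phantom \code{torso_phantom}
#' @param side "left" or "right"
#' @param affected_dilate_vox dilation (voxels) of the recorded affected
#'   region, so downstream bias statistics include the adjacent band
#' @param residual_lung_hu mean density (HU) the REMAINING lung is set to:
#'   after pneumonectomy the contralateral lung is typically consolidated
#'   and far denser than any population-level lung coefficient assumes;
#'   the MR signal rises with density through the proton-density coupling.
#'   NA keeps the subject's own lung density.
#' @return corrupted phantom
#' @export
remove_lung <- function(phantom, side = c("left", "right"),
                        affected_dilate_vox = 3, residual_lung_hu = -550) {
  side <- match.arg(side)
  organ <- paste0(side, "_lung")
  region <- phantom$organs[[organ]]
  if (!any(region)) stop_sctpet("phantom has no %s lung to remove", side)
  cfg <- phantom$config
  phantom$labels[region] <- label_code("soft")
  n <- sum(region)
  soft_mean <- unname(phantom$hu_means["soft"])
  vals <- with_seed(derive_seed(phantom$seed, "remove_lung", side), list(
    ct = soft_mean + rnorm(n, 0, tissue_value(cfg, "soft", "ct_hu_sd")),
    mr = tissue_value(cfg, "soft", "mr_mean") * phantom$bias_field[region] +
      rnorm(n, 0, tissue_value(cfg, "soft", "mr_sd"))
  ))
  phantom$ct_hu[region] <- vals$ct
  phantom$mr[region] <- pmax(vals$mr, 0)
  phantom$activity[region] <- tissue_value(cfg, "soft", "activity_mean")
  phantom$organs[[organ]] <- region & FALSE
  other <- phantom$organs[[paste0(setdiff(c("left", "right"), side), "_lung")]]
  if (!is.na(residual_lung_hu) && any(other)) {
    n2 <- sum(other)
    mr_mean2 <- tissue_value(cfg, "lung", "mr_mean") +
      (residual_lung_hu - default_tissue_table()$ct_hu_mean[2]) * HU_TO_MR_SLOPE
    vals2 <- with_seed(derive_seed(phantom$seed, "residual_lung"), list(
      ct = rnorm(n2, 0, tissue_value(cfg, "lung", "ct_hu_sd")),
      mr = rnorm(n2, 0, tissue_value(cfg, "lung", "mr_sd"))
    ))
    phantom$ct_hu[other] <- residual_lung_hu + vals2$ct
    phantom$mr[other] <- pmax(mr_mean2 * phantom$bias_field[other] + vals2$mr, 0)
    phantom$hu_means["lung"] <- residual_lung_hu
  }
  affected <- dilate_mask(region, affected_dilate_vox) & phantom_body_mask(phantom)
  record_outlier(phantom, "single_lung", list(side = side), affected,
                 support = dilate_mask(region, affected_dilate_vox) | other)
}

#' Add a small soft-tissue nodule inside a lung
#'
#' The nodule takes soft-tissue-like CT and MR values (the lesion row of the
#' tissue table) and activity equal to \code{uptake_ratio} times the
#' soft-tissue activity. The default radius gives a 1.0 mL sphere, inside
#' the 0.5--1.9 mL range typical of small malignant lesions.
#'
#' @param phantom \code{torso_phantom}
#' @param center physical point (mm, length 2 or 3); the whole sphere must
#'   lie inside a lung
#' @param radius_mm nodule radius (mm); default 6.2 mm, i.e. 1.0 mL
#' @param uptake_ratio lesion-to-soft-tissue activity ratio
#' @return corrupted phantom with a \code{lesion_k} organ mask added
#' @export
add_lung_nodule <- function(phantom, center = NULL, radius_mm = 6.2,
                            uptake_ratio = 4) {
  dims <- dim(phantom$mr)
  lungs <- phantom$organs$right_lung | phantom$organs$left_lung
  if (is.null(center)) {
    # default: centre of the right lung (or the remaining lung)
    which_l <- if (any(phantom$organs$right_lung)) "right_lung" else "left_lung"
    idx <- which(phantom$organs[[which_l]], arr.ind = TRUE)
    cvox <- round(colMeans(idx))
    center <- c((cvox[1] - (dims[1] + 1) / 2) * phantom$spacing[1],
                (cvox[2] - (dims[2] + 1) / 2) * phantom$spacing[2],
                (cvox[3] - (dims[3] + 1) / 2) * phantom$spacing[3])
  }
  vox <- sphere_mask(dims, phantom$spacing, center, radius_mm)
  if (!any(vox)) stop_sctpet("nodule sphere contains no voxels on this grid")
  if (any(vox & !lungs))
    stop_sctpet("nodule sphere must lie entirely inside a lung")
  cfg <- phantom$config
  n <- sum(vox)
  lesion_mean <- unname(phantom$hu_means["soft"]) +
    tissue_value(cfg, "lesion", "ct_hu_mean") - tissue_value(cfg, "soft", "ct_hu_mean")
  vals <- with_seed(derive_seed(phantom$seed, "nodule", round(center[1]), round(center[2])), list(
    ct = lesion_mean + rnorm(n, 0, tissue_value(cfg, "lesion", "ct_hu_sd")),
    mr = tissue_value(cfg, "lesion", "mr_mean") * phantom$bias_field[vox] +
      rnorm(n, 0, tissue_value(cfg, "lesion", "mr_sd"))
  ))
  phantom$labels[vox] <- label_code("lesion")
  phantom$ct_hu[vox] <- vals$ct
  phantom$mr[vox] <- pmax(vals$mr, 0)
  phantom$activity[vox] <- uptake_ratio * tissue_value(cfg, "soft", "activity_mean")
  lesion_name <- sprintf("lesion_%d", 1 +
    sum(grepl("^lesion_", names(phantom$organs))))
  phantom$organs[[lesion_name]] <- vox
  record_outlier(phantom, "nodule",
                 list(center = center, radius_mm = radius_mm,
                      uptake_ratio = uptake_ratio, organ = lesion_name), vox)
}

#' Simulate inter-session misalignment of the MR volume
#'
#' Warps the MR through a smooth random B-spline deformation with the stated
#' peak displacement magnitude, returning both the moved MR and the true
#' field (for registration-recovery tests).
#'
#' @param phantom \code{torso_phantom}
#' @param magnitude_mm peak displacement magnitude (mm)
#' @param seed integer seed for the random field
#' @param grid_spacing_mm control-point spacing of the random field
#' @return list(mr_moved, truth_field) where \code{truth_field} is a
#'   \code{deformation_field}
#' @export
simulate_session_misalignment <- function(phantom, magnitude_mm = 6, seed = 1L,
                                          grid_spacing_mm = 48) {
  field <- random_deformation(dim(phantom$mr), phantom$spacing, magnitude_mm,
                              seed, grid_spacing_mm)
  mr_moved <- resample_volume(phantom$mr, field, interpolation = "linear",
                              fill = air_mr_level(phantom))
  list(mr_moved = mr_moved, truth_field = field)
}
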