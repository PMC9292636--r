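# Quantitative comparison of candidate-AC PET reconstructions against the
# CT-based reference: voxel-wise relative SUV bias with a 0.05 SUV validity
# floor, region statistics, RMSE, HU-threshold tissue masks, lesion VOI
# tables and paired t-tests.

#' Voxel-wise relative SUV bias
#'
#' bias(v) = 100 * (PET_sCT(v) - PET_CT(v)) / PET_CT(v), computed only where
#' the reference exceeds the validity floor (0.05 SUV by default) to avoid
#' artificially inflated bias in near-zero voxels.
#'
#' @param pet_sct candidate-AC SUV volume
#' @param pet_ct reference (CT-based AC) SUV volume
#' @param floor reference SUV below which voxels are excluded
#' @return list(bias, valid): bias volume in percent (NA outside validity)
#'   and the logical validity mask
#' @export
voxel_bias_map <- function(pet_sct, pet_ct, floor = 0.05) {
  pet_sct <- as_vol3d(pet_sct); pet_ct <- as_vol3d(pet_ct)
  if (!identical(dim(pet_sct), dim(pet_ct)))
    stop_sctpet("PET volumes must share a grid")
  valid <- pet_ct >= floor
  bias <- array(NA_real_, dim = dim(pet_ct))
  bias[valid] <- 100 * (pet_sct[valid] - pet_ct[valid]) / pet_ct[valid]
  list(bias = bias, valid = valid)
}

#' Bias statistics over a region
#'
#' Mean, SD, absolute mean and absolute SD of the bias over valid voxels of
#' the mask. An empty intersection is reported explicitly (n_voxels = 0,
#' empty = TRUE), never as a silent zero.
#' @param bias bias volume (percent) from \code{\link{voxel_bias_map}}
#' @param valid validity mask
#' @param mask region mask
#' @return list(mean, sd, abs_mean, abs_sd, n_voxels, empty)
#' @export
region_stats <- function(bias, valid, mask) {
  sel <- as_vol3d(valid) & as_vol3d(mask)
  n <- sum(sel)
  if (n == 0) {
    return(list(mean = NA_real_, sd = NA_real_, abs_mean = NA_real_,
                abs_sd = NA_real_, n_voxels = 0L, empty = TRUE))
  }
  b <- as_vol3d(bias)[sel]
  list(mean = mean(b), sd = if (n > 1) sd(b) else 0,
       abs_mean = mean(abs(b)), abs_sd = if (n > 1) sd(abs(b)) else 0,
       n_voxels = n, empty = FALSE)
}

#' Root mean square error between two volumes over a mask
#' @param pet_sct,pet_ct volumes on the same grid
#' @param mask logical mask (defaults to everywhere)
#' @return scalar RMSE
#' @export
rmse_volumes <- function(pet_sct, pet_ct, mask = NULL) {
  pet_sct <- as_vol3d(pet_sct); pet_ct <- as_vol3d(pet_ct)
  if (!identical(dim(pet_sct), dim(pet_ct)))
    stop_sctpet("volumes must share a grid")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(pet_ct))
  d <- (pet_ct[as_vol3d(mask)] - pet_sct[as_vol3d(mask)])^2
  sqrt(mean(d))
}

#' Tissue masks from the reference CT
#'
#' Soft tissue: reference CT in the closed interval [-400, 160] HU inside
#' the body; bone: CT > 160 HU inside the body; lungs are taken from truth
#' labels (standing in for manual delineation).
#' @param reference_ct reference CT volume (HU)
#' @param truth_lungs logical lung mask
#' @param body logical body mask
#' @return list(soft, bone, lung, body) of logical masks
#' @export
tissue_masks_from_ct <- function(reference_ct, truth_lungs, body) {
  reference_ct <- as_vol3d(reference_ct)
  body <- as_vol3d(body); truth_lungs <- as_vol3d(truth_lungs)
  soft <- reference_ct >= -400 & reference_ct <= 160 & body & !truth_lungs
  bone <- reference_ct > 160 & body
  list(soft = soft, bone = bone, lung = truth_lungs & body, body = body)
}

#' Lesion VOI bias table
#'
#' Per-lesion mean bias, volume and maximum SUV. Lesion volumes outside the
#' configured plausibility band are flagged.
#' @param bias bias volume (percent)
#' @param valid validity mask
#' @param lesions named list of logical lesion masks
#' @param spacing voxel spacing (mm)
#' @param suv optional SUV volume for SUV_max
#' @param volume_band_ml plausibility band (mL) for lesion volumes
#' @return data.frame with one row per lesion
#' @export
voi_bias <- function(bias, valid, lesions, spacing = c(2, 2, 2), suv = NULL,
                     volume_band_ml = c(0.5, 1.9)) {
  vox_ml <- prod(spacing) / 1000
  rows <- lapply(names(lesions), function(nm) {
    st <- region_stats(bias, valid, lesions[[nm]])
    vol <- sum(lesions[[nm]]) * vox_ml
    data.frame(lesion = nm, volume_ml = vol,
               in_band = vol >= volume_band_ml[1] & vol <= volume_band_ml[2],
               mean_bias = st$mean, n_voxels = st$n_voxels,
               suv_max = if (!is.null(suv)) max(as_vol3d(suv)[lesions[[nm]]]) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Paired two-sided t-test with degenerate-case conventions
#'
#' Identical vectors give p = 1 by convention; a constant non-zero shift
#' (zero-variance differences) gives t = +/-Inf and p = 0, with a warning.
#' @param a,b paired per-subject metric vectors
#' @return list(t, p, significant, degenerate)
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop_sctpet("paired vectors must have equal length")
  d <- a - b
  if (all(abs(d) < .Machine$double.eps * 100)) {
    return(list(t = 0, p = 1, significant = FALSE, degenerate = "identical"))
  }
  if (sd(d) < .Machine$double.eps * 100 * max(1, abs(mean(d)))) {
    warning("zero-variance paired differences: p reported as 0 by convention")
    return(list(t = sign(mean(d)) * Inf, p = 0, significant = TRUE,
                degenerate = "constant_shift"))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < 0.05, degenerate = "none")
}

#' Assemble a bias report
#'
#' One row per tissue/region/lesion group and arm, plus per-arm RMSE and
#' between-arm paired tests on a per-subject summary metric.
#'
#' @param region_table data.frame with columns subject, region, arm, and the
#'   \code{\link{region_stats}} fields
#' @param rmse_table data.frame with columns subject, arm, rmse
#' @param voi_table optional data.frame from \code{\link{voi_bias}}
#' @param test_metric region whose per-subject mean bias feeds the paired
#'   tests between arms
#' @return object of class \code{bias_report}: list(summary, regions, rmse,
#'   vois, tests)
#' @export
build_report <- function(region_table, rmse_table, voi_table = NULL,
                         test_metric = "body") {
  arms <- unique(region_table$arm)
  regions <- unique(region_table$region)
  summary <- do.call(rbind, lapply(regions, function(rg) {
    do.call(rbind, lapply(arms, function(ar) {
      sub <- region_table[region_table$region == rg & region_table$arm == ar, ]
      data.frame(region = rg, arm = ar,
                 mean_bias = mean(sub$mean, na.rm = TRUE),
                 sd_bias = sd(sub$mean[!is.na(sub$mean)]),
                 abs_mean_bias = mean(sub$abs_mean, na.rm = TRUE),
                 abs_sd_bias = sd(sub$abs_mean[!is.na(sub$abs_mean)]),
                 n_subjects = sum(!is.na(sub$mean)))
    }))
  }))
  tests <- NULL
  tsub <- region_table[region_table$region == test_metric, ]
  if (nrow(tsub) > 0 && length(arms) > 1) {
    combs <- utils::combn(arms, 2, simplify = FALSE)
    tests <- do.call(rbind, lapply(combs, function(pr) {
      a <- tsub$mean[tsub$arm == pr[1]][order(tsub$subject[tsub$arm == pr[1]])]
      b <- tsub$mean[tsub$arm == pr[2]][order(tsub$subject[tsub$arm == pr[2]])]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 2) return(NULL)
      tt <- paired_ttest(a[ok], b[ok])
      data.frame(arm_a = pr[1], arm_b = pr[2], t = tt$t, p = tt$p,
                 significant = tt$significant, region = test_metric)
    }))
  }
  structure(list(summary = summary, regions = region_table,
                 rmse = rmse_table, vois = voi_table, tests = tests),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat("<bias_report>\n")
  s <- x$summary
  for (rg in unique(s$region)) {
    cat(sprintf("  %-14s", rg))
    for (i in which(s$region == rg)) {
      cat(sprintf(" %s % .1f +/- %.1f (|%.1f| +/- %.1f)", s$arm[i],
                  s$mean_bias[i], s$sd_bias[i] %||% NA,
                  s$abs_mean_bias[i], s$abs_sd_bias[i] %||% NA))
    }
    cat("\n")
  }
  invisible(x)
}

#' Write a bias report as CSV and Markdown
#' @param report \code{bias_report}
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in c("summary", "regions", "rmse", "vois", "tests")) {
    df <- report[[nm]]
    if (is.null(df)) next
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  md <- file.path(dir, "report.md")
  s <- report$summary
  lines <- c("# SUV bias report", "",
             "| Region | Arm | Mean +/- SD (%) | Abs mean +/- SD (%) | n |",
             "|---|---|---|---|---|")
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf("| %s | %s | %.1f +/- %.1f | %.1f +/- %.1f | %d |",
                              s$region[i], s$arm[i], s$mean_bias[i],
                              ifelse(is.na(s$sd_bias[i]), 0, s$sd_bias[i]),
                              s$abs_mean_bias[i],
                              ifelse(is.na(s$abs_sd_bias[i]), 0, s$abs_sd_bias[i]),
                              s$n_subjects[i]))
  }
  if (!is.null(report$tests)) {
    lines <- c(lines, "", "## Paired tests", "",
               "| Arm A | Arm B | t | p | significant |", "|---|---|---|---|---|")
    for (i in seq_len(nrow(report$tests))) {
      tt <- report$tests[i, ]
      lines <- c(lines, sprintf("| %s | %s | %.3f | %.4g | %s |", tt$arm_a,
                                tt$arm_b, tt$t, tt$p, tt$significant))
    }
  }
  writeLines(lines, md)
  invisible(c(paths, md))
}
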