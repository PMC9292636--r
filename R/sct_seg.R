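# Three-class segmentation attenuation map: body contour on the normalized
# MR, lung segmentation inside the body, then fixed class values
# soft tissue -> (0 HU, 0.096 cm^-1), background air -> (-1000 HU, 0 cm^-1),
# lung -> (-770 HU, 0.022 cm^-1). No bone class exists by construction,
# which is the documented cause of this method's bone bias.

SEG_CLASS_VALUES <- data.frame(
  class = c("background_air", "lung", "soft_tissue"),
  code = c(0L, 1L, 2L),
  hu = c(-1000, -770, 0),
  mu = c(0, 0.022, 0.096)
)

#' Delineate the body contour on a normalized MR volume
#'
#' Otsu threshold on the whole volume, morphological closing, largest
#' connected component per slice, holes filled. Regions with absent MR
#' signal (truncated arms, susceptibility voids at the body edge) are
#' excluded by construction -- thresholding cannot see absent signal.
#'
#' @param mr_norm MR volume normalized to [0, 1]
#' @param closing_radius morphology closing radius (voxels)
#' @return logical body mask
#' @export
delineate_body <- function(mr_norm, closing_radius = 2) {
  mr_norm <- as_vol3d(mr_norm)
  if (diff(range(mr_norm)) <= 0)
    stop_sctpet("cannot delineate a body on a constant image")
  thr <- otsu_threshold(as.vector(mr_norm))
  raw <- mr_norm > thr
  if (!any(raw)) stop_sctpet("body delineation produced an empty mask")
  out <- raw
  for (k in seq_len(dim(raw)[3])) {
    m <- close_and_fill(raw[, , k], closing_radius)
    out[, , k] <- close_and_fill(largest_component(m), 0)
  }
  if (!any(out)) stop_sctpet("body delineation produced an empty mask")
  out
}

#' Segment the lungs inside the body
#'
#' Low-intensity components interior to the body, kept if larger than a
#' per-slice area prior (so bone cross-sections stay excluded) and centred
#' in the thoracic band of the slice (a positional prior mimicking vendor
#' anatomical constraints). Kept components are hole-filled, so bright
#' structures enclosed by lung (small nodules) are absorbed into the lung
#' class -- the documented small-lesion failure mode of this method. A
#' metal-induced void larger than the area prior is, by the same rule,
#' mis-labelled as lung; callers can detect this via the returned
#' \code{attr(, "n_components")}.
#'
#' @param mr_norm normalized MR volume
#' @param body logical body mask
#' @param min_area_cm2 per-slice area prior (cm^2)
#' @param band_y fraction of the body's posterior half-extent excluded from
#'   the lung search (the retro-spinal band)
#' @param spacing voxel spacing (mm)
#' @return logical lung mask with attribute \code{n_components} (per slice)
#' @export
segment_lungs <- function(mr_norm, body, min_area_cm2 = 8, band_y = 0.5,
                          spacing = c(2, 2, 2)) {
  mr_norm <- as_vol3d(mr_norm); body <- as_vol3d(body)
  dims <- dim(mr_norm)
  vox_area_cm2 <- prod(spacing[1:2]) / 100
  out <- array(FALSE, dim = dims)
  ncomp <- integer(dims[3])
  for (k in seq_len(dims[3])) {
    bk <- body[, , k]
    if (!any(bk)) next
    # candidate components are found at vendor-like coarseness: light
    # smoothing erases structures of a few voxels, so small bright lesions
    # inside the lung do not split or punch through the candidate region
    # (the method's documented small-lesion failure mode); the final mask
    # boundary is then taken from the unsmoothed image
    sm <- box_mean(mr_norm[, , k], 1)
    inside <- sm[bk]
    if (diff(range(inside)) <= 0) next
    thr <- otsu_threshold(inside)
    dark <- bk & sm < thr
    thr_u <- otsu_threshold(mr_norm[, , k][bk])
    dark_u <- bk & mr_norm[, , k] < thr_u
    # positional prior: exclude the deep posterior band where the spine sits
    ys <- grid_coords_mm(dims[2], spacing[2])
    yb <- range(ys[apply(bk, 2, any)])
    band_lo <- yb[1] + band_y * (0 - yb[1]) # from posterior edge halfway to centre
    ymat <- matrix(ys, dims[1], dims[2], byrow = TRUE)
    lab <- EBImage::bwlabel(dark * 1)
    nmax <- max(lab)
    kept <- matrix(FALSE, dims[1], dims[2])
    nc <- 0L
    if (nmax > 0) {
      areas <- tabulate(lab[lab > 0], nbins = nmax) * vox_area_cm2
      for (ci in seq_len(nmax)) {
        comp <- lab == ci
        if (areas[ci] >= min_area_cm2 && mean(ymat[comp]) > band_lo) {
          # sharp boundary from the unsmoothed image; interior holes
          # (enclosed bright lesions) are filled into the lung class
          halo <- as.matrix(EBImage::dilate(EBImage::Image(comp * 1),
                                            EBImage::makeBrush(3, "box"))) > 0.5
          refined <- close_and_fill(dark_u & halo, 0)
          if (!any(refined)) refined <- close_and_fill(comp, 0)
          kept <- kept | refined
          nc <- nc + 1L
        }
      }
    }
    out[, , k] <- kept & bk
    ncomp[k] <- nc
  }
  attr(out, "n_components") <- ncomp
  out
}

#' Build the three-class segmentation sCT and attenuation map
#'
#' @param mr_norm normalized MR volume
#' @param spacing voxel spacing (mm)
#' @param min_area_cm2 lung area prior passed to \code{\link{segment_lungs}}
#' @return list with \code{class_map} (integer codes per
#'   \code{SEG_CLASS_VALUES}), \code{sct_hu}, \code{mu_map}
#'   (an \code{attenuation_map} with source "seg"), \code{body},
#'   \code{lungs}
#' @export
build_seg_sct <- function(mr_norm, spacing = c(2, 2, 2), min_area_cm2 = 8) {
  mr_norm <- as_vol3d(mr_norm)
  all_air <- diff(range(mr_norm)) <= 0
  if (all_air) {
    cls <- array(0L, dim = dim(mr_norm))
    body <- array(FALSE, dim = dim(mr_norm))
    lungs <- body
  } else {
    body <- delineate_body(mr_norm)
    lungs <- segment_lungs(mr_norm, body, min_area_cm2 = min_area_cm2,
                           spacing = spacing)
    cls <- array(0L, dim = dim(mr_norm))
    cls[body] <- 2L
    cls[lungs] <- 1L
  }
  sct_hu <- array(SEG_CLASS_VALUES$hu[cls + 1L], dim = dim(cls))
  mu <- array(SEG_CLASS_VALUES$mu[cls + 1L], dim = dim(cls))
  list(class_map = cls, sct_hu = sct_hu,
       mu_map = attenuation_map(mu, source = "seg", spacing = spacing),
       body = body, lungs = lungs)
}
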