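# Desk-scale 2D PET physics. Parallel-beam geometry over 180 degrees; the
# system matrix is a sparse pixel-driven splat projector (each voxel
# deposits its value, times the voxel size, into the two radial bins
# straddling its projection), so line integrals of mu give attenuation
# factors exp(-integral mu dl) and OSEM sees a matched forward/backward
# pair (the backprojector is the exact adjoint).

#' Parallel-beam projection geometry
#' @param n_angles number of projection angles over [0, 180) degrees
#' @param n_bins number of radial bins
#' @param bin_spacing radial bin spacing (mm)
#' @return object of class \code{projection_geometry}
#' @export
projection_geometry <- function(n_angles = 180L, n_bins = 128L,
                                bin_spacing = 2) {
  structure(list(n_angles = as.integer(n_angles), n_bins = as.integer(n_bins),
                 bin_spacing = bin_spacing,
                 angles = (seq_len(n_angles) - 1) * pi / n_angles),
            class = "projection_geometry")
}

#' Default geometry for an image grid
#' @param dims image dims
#' @param spacing voxel spacing (mm)
#' @param n_angles number of angles
#' @return \code{projection_geometry} whose radial extent covers the grid
#'   diagonal
#' @export
geometry_for_grid <- function(dims, spacing, n_angles = 180L) {
  diag_mm <- sqrt(sum((dims[1:2] * spacing[1:2])^2))
  n_bins <- 2L * as.integer(ceiling(diag_mm / spacing[1] / 2)) + 1L
  projection_geometry(n_angles, n_bins, spacing[1])
}

# sparse system matrix A: rows = (bin, angle), cols = pixels; entries are
# bilinear radial splat weights times the pixel footprint (mm), so
# A %*% image approximates the line integrals (in value * mm)
system_matrix <- function(geom, dims, spacing) {
  key <- sprintf("sysmat_%d_%d_%g_%d_%d_%g_%g", geom$n_angles, geom$n_bins,
                 geom$bin_spacing, dims[1], dims[2], spacing[1], spacing[2])
  A <- .sctpet_cache[[key]]
  if (!is.null(A)) return(A)
  nx <- dims[1]; ny <- dims[2]
  co <- slice_coords(nx, ny, spacing)
  x <- as.vector(co$x); y <- as.vector(co$y)
  npix <- nx * ny
  ctr <- (geom$n_bins + 1) / 2
  # pixel footprint: area / bin spacing = length contribution (mm)
  wpix <- prod(spacing[1:2]) / geom$bin_spacing
  rows_l <- vector("list", geom$n_angles)
  cols_l <- vector("list", geom$n_angles)
  vals_l <- vector("list", geom$n_angles)
  for (a in seq_len(geom$n_angles)) {
    th <- geom$angles[a]
    s <- x * cos(th) + y * sin(th)
    b <- s / geom$bin_spacing + ctr
    b0 <- floor(b)
    fb <- b - b0
    ok0 <- b0 >= 1 & b0 <= geom$n_bins
    ok1 <- (b0 + 1) >= 1 & (b0 + 1) <= geom$n_bins
    roff <- (a - 1L) * geom$n_bins
    rows_l[[a]] <- c(roff + b0[ok0], roff + b0[ok1] + 1L)
    cols_l[[a]] <- c(which(ok0), which(ok1))
    vals_l[[a]] <- c((1 - fb[ok0]) * wpix, fb[ok1] * wpix)
  }
  A <- Matrix::sparseMatrix(
    i = unlist(rows_l), j = unlist(cols_l), x = unlist(vals_l),
    dims = c(geom$n_angles * geom$n_bins, npix)
  )
  .sctpet_cache[[key]] <- A
  A
}

#' Convert CT numbers to 511 keV linear attenuation coefficients
#'
#' Piecewise-linear (bilinear) conversion anchored at the class values of
#' the three-class map: mu = 0.096 (HU + 1000) / 1000 for HU <= 0 (so air at
#' -1000 HU maps to 0 and water-equivalent soft tissue at 0 HU to
#' 0.096 cm^-1), and a shallower bone slope above 0 HU chosen so cortical
#' bone at 1000 HU maps to 0.172 cm^-1. Negative results clamp to zero.
#'
#' @param ct_hu CT volume (HU)
#' @param source provenance tag: "reference_ct", "seg", "atlas" or "dl"
#' @param spacing voxel spacing (mm)
#' @return \code{attenuation_map}
#' @export
hu_to_mu <- function(ct_hu, source = "reference_ct", spacing = c(2, 2, 2)) {
  ct_hu <- as_vol3d(ct_hu)
  k_bone <- (0.172 - 0.096) / 1000
  mu <- ifelse(ct_hu <= 0, 0.096 * (ct_hu + 1000) / 1000,
               0.096 + k_bone * ct_hu)
  mu <- pmax(mu, 0)
  attenuation_map(mu, source = source, spacing = spacing)
}

#' Attenuation map container
#' @param mu volume of linear attenuation coefficients (cm^-1 at 511 keV)
#' @param source provenance tag
#' @param spacing voxel spacing (mm)
#' @return object of class \code{attenuation_map}
#' @export
attenuation_map <- function(mu, source = "reference_ct", spacing = c(2, 2, 2)) {
  mu <- as_vol3d(mu)
  if (any(mu < 0)) stop_sctpet("attenuation coefficients must be >= 0")
  structure(list(mu = mu, source = source, spacing = spacing),
            class = "attenuation_map")
}

#' @export
print.attenuation_map <- function(x, ...) {
  cat(sprintf("<attenuation_map> source=%s, mu in [%.3f, %.3f] cm^-1\n",
              x$source, min(x$mu), max(x$mu)))
  invisible(x)
}

#' Attenuation factor sinogram
#'
#' a(LOR) = exp(-line integral of mu along the LOR, in cm); values in (0, 1].
#' @param mu_map \code{attenuation_map}
#' @param geom \code{projection_geometry}
#' @return array (n_bins, n_angles, nz) of attenuation factors
#' @export
attenuation_factors <- function(mu_map, geom) {
  dims <- dim(mu_map$mu)
  A <- system_matrix(geom, dims, mu_map$spacing)
  out <- array(1, dim = c(geom$n_bins, geom$n_angles, dims[3]))
  for (k in seq_len(dims[3])) {
    li <- as.numeric(A %*% as.vector(mu_map$mu[, , k])) / 10 # mm * cm^-1 -> unitless
    out[, , k] <- exp(-matrix(li, geom$n_bins, geom$n_angles))
  }
  out
}

#' Attenuated forward projection of an activity map
#'
#' y = a_true * R(activity), optionally scaled to a total count budget per
#' slice and Poisson-sampled.
#'
#' @param activity activity volume (arbitrary units, >= 0)
#' @param mu_true true \code{attenuation_map}
#' @param geom \code{projection_geometry}
#' @param total_counts expected counts per slice, or "noiseless"
#' @param seed integer seed for the Poisson draw
#' @return object of class \code{sinogram}: list(counts, geom, noise, seed,
#'   scale)
#' @export
forward_project <- function(activity, mu_true, geom,
                            total_counts = "noiseless", seed = 1L) {
  activity <- as_vol3d(activity)
  dims <- dim(activity)
  A <- system_matrix(geom, dims, mu_true$spacing)
  af <- attenuation_factors(mu_true, geom)
  counts <- array(0, dim = c(geom$n_bins, geom$n_angles, dims[3]))
  for (k in seq_len(dims[3])) {
    p <- matrix(as.numeric(A %*% as.vector(activity[, , k])),
                geom$n_bins, geom$n_angles) * af[, , k]
    counts[, , k] <- p
  }
  scale <- 1
  noise <- "noiseless"
  if (!identical(total_counts, "noiseless")) {
    tot <- sum(counts)
    if (tot > 0) {
      scale <- total_counts * dims[3] / tot
      counts <- counts * scale
    }
    counts <- with_seed(derive_seed(seed, "poisson"),
                        array(rpois(length(counts), counts), dim = dim(counts)))
    noise <- "poisson"
  }
  structure(list(counts = counts, geom = geom, noise = noise,
                 seed = seed, scale = scale),
            class = "sinogram")
}

#' OSEM reconstruction with a candidate attenuation map
#'
#' Ordered-subset EM with the candidate attenuation factors inside the
#' system model (attenuated Poisson data, no scatter/randoms). Subsets are
#' angle-interleaved; the multiplicative update preserves non-negativity.
#'
#' @param sino \code{sinogram}
#' @param mu_candidate \code{attenuation_map} on the image grid
#' @param dims image dims c(nx, ny, nz)
#' @param iterations full iterations (default 4)
#' @param subsets number of angle subsets (default 8); must divide the
#'   angle count
#' @return reconstructed activity volume (same grid as \code{mu_candidate})
#' @export
osem_reconstruct <- function(sino, mu_candidate, dims = dim(mu_candidate$mu),
                             iterations = 4L, subsets = 8L) {
  geom <- sino$geom
  if (geom$n_angles %% subsets != 0)
    stop_sctpet("subset count (%d) must divide the number of angles (%d)",
                subsets, geom$n_angles)
  if (!identical(dim(mu_candidate$mu)[1:2], as.integer(dims[1:2])))
    stop_sctpet("mu_candidate grid does not match the image grid")
  spacing <- mu_candidate$spacing
  A <- system_matrix(geom, dims, spacing)
  af <- attenuation_factors(mu_candidate, geom)
  npix <- dims[1] * dims[2]
  recon <- array(0, dim = dims)
  # angle-interleaved subsets; precompute row indices once
  sub_rows <- lapply(seq_len(subsets), function(s) {
    angles <- seq(s, geom$n_angles, by = subsets)
    as.vector(outer(seq_len(geom$n_bins), (angles - 1L) * geom$n_bins, `+`))
  })
  sub_A <- lapply(sub_rows, function(r) A[r, , drop = FALSE])
  for (k in seq_len(dims[3])) {
    afk <- as.vector(af[, , k])
    yk <- as.vector(sino$counts[, , k])
    sens <- lapply(seq_len(subsets), function(s) {
      as.numeric(Matrix::crossprod(sub_A[[s]], afk[sub_rows[[s]]]))
    })
    f <- rep(1, npix)
    eps <- 1e-12
    for (it in seq_len(iterations)) {
      for (s in seq_len(subsets)) {
        r <- sub_rows[[s]]
        q <- afk[r] * as.numeric(sub_A[[s]] %*% f)
        ratio <- ifelse(q > eps, yk[r] / q, 0)
        bp <- as.numeric(Matrix::crossprod(sub_A[[s]], afk[r] * ratio))
        upd <- ifelse(sens[[s]] > eps, bp / sens[[s]], 0)
        f <- f * upd
      }
    }
    recon[, , k] <- matrix(f, dims[1], dims[2])
  }
  recon
}

#' Convert a reconstruction to SUV-like units
#'
#' Phantoms have no injected dose or body weight, so the SUV surrogate
#' normalizes by the body mean of the REFERENCE (CT-based AC)
#' reconstruction; the same factor must be applied to every arm of a
#' subject, which leaves relative bias unchanged.
#'
#' @param recon reconstructed activity volume
#' @param body logical body mask (non-empty)
#' @param reference reference-arm reconstruction supplying the scale
#'   (defaults to \code{recon} itself)
#' @return SUV volume (reference body mean = 1 by construction)
#' @export
to_suv <- function(recon, body, reference = recon) {
  body <- as_vol3d(body)
  if (!any(body)) stop_sctpet("body mask is empty; SUV scale undefined")
  m <- mean(as_vol3d(reference)[body])
  if (!is.finite(m) || m <= 0)
    stop_sctpet("reference body mean must be positive")
  as_vol3d(recon) / m
}
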