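# Exact Euclidean distance transform (Felzenszwalb-Huttenlocher lower
# envelope of parabolas), per transaxial slice, with anisotropic in-plane
# spacing. The signed distance is measured to the mask's boundary voxels
# (mask voxels with a 4-neighbour outside), negative strictly inside,
# positive outside, zero on the boundary itself.

# 1D squared distance transform of sampled function f at positions pos;
# only finite parabolas enter the lower envelope
edt_1d <- function(f, pos) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0) return(rep(Inf, n))
  v <- integer(length(fin))
  z <- numeric(length(fin) + 1)
  k <- 1L
  v[1] <- fin[1]
  z[1] <- -Inf; z[2] <- Inf
  for (q in fin[-1]) {
    p <- v[k]
    s <- ((f[q] + pos[q]^2) - (f[p] + pos[p]^2)) / (2 * (pos[q] - pos[p]))
    while (s <= z[k]) {
      k <- k - 1L
      p <- v[k]
      s <- ((f[q] + pos[q]^2) - (f[p] + pos[p]^2)) / (2 * (pos[q] - pos[p]))
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1] <- Inf
  }
  d <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1] < pos[q]) k <- k + 1L
    d[q] <- (pos[q] - pos[v[k]])^2 + f[v[k]]
  }
  d
}

# squared EDT to the TRUE voxels of a logical slice, anisotropic spacing (mm)
edt2_slice <- function(seed_slice, spacing) {
  nx <- nrow(seed_slice); ny <- ncol(seed_slice)
  if (!any(seed_slice)) return(matrix(Inf, nx, ny))
  g <- matrix(Inf, nx, ny)
  g[seed_slice] <- 0
  posx <- seq_len(nx) * spacing[1]
  for (j in seq_len(ny)) {
    col <- g[, j]
    if (all(!is.finite(col))) next
    g[, j] <- edt_1d(col, posx)
  }
  posy <- seq_len(ny) * spacing[2]
  for (i in seq_len(nx)) {
    g[i, ] <- edt_1d(g[i, ], posy)
  }
  g
}

boundary_voxels <- function(mask_slice) {
  nx <- nrow(mask_slice); ny <- ncol(mask_slice)
  pad <- matrix(FALSE, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- mask_slice
  nb_out <- !pad[1:nx, 2:(ny + 1)] | !pad[3:(nx + 2), 2:(ny + 1)] |
    !pad[2:(nx + 1), 1:ny] | !pad[2:(nx + 1), 3:(ny + 2)]
  mask_slice & nb_out
}

#' Signed Euclidean distance map of a binary mask
#'
#' Distance in mm to the mask's boundary voxels, computed slice-wise with
#' the exact lower-envelope transform: negative strictly inside the mask,
#' positive outside, and exactly zero on boundary voxels.
#'
#' @param mask logical volume (or matrix)
#' @param spacing voxel spacing (mm); in-plane components are used
#' @return numeric volume of signed distances (mm)
#' @export
signed_distance_map <- function(mask, spacing = c(1, 1, 1)) {
  mask <- as_vol3d(mask)
  if (!any(mask)) stop_sctpet("signed distance of an empty mask is undefined")
  dims <- dim(mask)
  out <- array(0, dim = dims)
  for (k in seq_len(dims[3])) {
    msk <- mask[, , k]
    if (!any(msk)) { out[, , k] <- Inf; next }
    bnd <- boundary_voxels(msk)
    d <- sqrt(edt2_slice(bnd, spacing[1:2]))
    d[msk & !bnd] <- -d[msk & !bnd]
    out[, , k] <- d
  }
  out
}
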