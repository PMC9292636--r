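# Internal helpers shared across modules: seeded RNG scoping, coordinate
# grids, interpolation, small image ops. Volumes are plain 3D arrays
# [nx, ny, nz] with physical voxel spacing (mm) passed alongside; slice
# stacks are treated as independent transaxial planes.

.sctpet_cache <- new.env(parent = emptyenv())

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers never
#' perturb the global random stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible child seed from a master seed
#'
#' Hierarchical seeding: every stage of an experiment (subject, noise,
#' training, Poisson sampling) draws its own seed from the master seed and a
#' label, so any stage can be replayed in isolation. The result is always a
#' valid 32-bit R integer.
#'
#' @param master integer master seed
#' @param ... labels (strings or integers) identifying the stage
#' @return integer seed in [1, 2^31 - 2]
#' @export
derive_seed <- function(master, ...) {
  parts <- c(as.character(master), vapply(list(...), as.character, ""))
  h <- 0
  for (s in parts) {
    for (ch in utf8ToInt(s)) {
      h <- (h * 31 + ch) %% 2147483629
    }
    h <- (h * 131 + 7) %% 2147483629
  }
  as.integer(h + 1)
}

# millimetre coordinates of voxel centres, centred on the grid
grid_coords_mm <- function(n, spacing) {
  (seq_len(n) - (n + 1) / 2) * spacing
}

# meshgrid of in-plane physical coordinates for an [nx, ny] slice
slice_coords <- function(nx, ny, spacing) {
  list(
    x = matrix(grid_coords_mm(nx, spacing[1]), nx, ny),
    y = matrix(grid_coords_mm(ny, spacing[2]), nx, ny, byrow = TRUE)
  )
}

as_vol3d <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

n_slices <- function(vol) dim(as_vol3d(vol))[3]

# Bilinear sampling of a 2D slice at fractional voxel coordinates (1-based).
# Out-of-domain points take `fill`.
bilinear_sample <- function(img, xi, yi, fill = 0) {
  nx <- nrow(img); ny <- ncol(img)
  ok <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
  # clamp the lower cell corner so points on the final row/column
  # interpolate exactly; out-of-domain points are masked afterwards
  x0 <- pmin(pmax(floor(xi), 1), nx - 1)
  y0 <- pmin(pmax(floor(yi), 1), ny - 1)
  fx <- xi - x0; fy <- yi - y0
  i00 <- x0 + (y0 - 1) * nx
  v <- (1 - fx) * (1 - fy) * img[i00] +
    fx * (1 - fy) * img[i00 + 1] +
    (1 - fx) * fy * img[i00 + nx] +
    fx * fy * img[i00 + nx + 1]
  v[!ok] <- fill
  v
}

# Nearest-neighbour sampling (for label volumes)
nearest_sample <- function(img, xi, yi, fill = 0) {
  nx <- nrow(img); ny <- ncol(img)
  xr <- round(xi); yr <- round(yi)
  ok <- xr >= 1 & xr <= nx & yr >= 1 & yr <= ny
  xrc <- pmin(pmax(xr, 1), nx)
  yrc <- pmin(pmax(yr, 1), ny)
  v <- img[xrc + (yrc - 1) * nx]
  v[!ok] <- fill
  v
}

# 2x mean-pool downsampling of a slice (used by multi-resolution registration)
downsample2 <- function(img) {
  nx <- nrow(img); ny <- ncol(img)
  nx2 <- nx %/% 2; ny2 <- ny %/% 2
  img <- img[seq_len(2 * nx2), seq_len(2 * ny2), drop = FALSE]
  0.25 * (img[seq(1, 2 * nx2, 2), seq(1, 2 * ny2, 2)] +
    img[seq(2, 2 * nx2, 2), seq(1, 2 * ny2, 2)] +
    img[seq(1, 2 * nx2, 2), seq(2, 2 * ny2, 2)] +
    img[seq(2, 2 * nx2, 2), seq(2, 2 * ny2, 2)])
}

# Box-mean filter over a (2r+1)^2 window via integral images, edge-normalised
box_mean <- function(img, r) {
  if (r <= 0) return(img)
  nx <- nrow(img); ny <- ncol(img)
  pad <- matrix(0, nx + 1, ny + 1)
  pad[-1, -1] <- img
  ii <- apply(apply(pad, 2, cumsum), 1, cumsum) # t(integral image)
  ii <- t(ii)
  x1 <- pmax(seq_len(nx) - r, 1); x2 <- pmin(seq_len(nx) + r, nx)
  y1 <- pmax(seq_len(ny) - r, 1); y2 <- pmin(seq_len(ny) + r, ny)
  s <- ii[x2 + 1, y2 + 1, drop = FALSE] - ii[x1, y2 + 1, drop = FALSE] -
    ii[x2 + 1, y1, drop = FALSE] + ii[x1, y1, drop = FALSE]
  cnt <- outer(x2 - x1 + 1, y2 - y1 + 1)
  s / cnt
}

# Otsu threshold on a numeric vector (256-bin histogram)
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  h <- tabulate(pmin(pmax(floor((x - r[1]) / diff(r) * n_bins) + 1, 1), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  r[1] + (k / n_bins) * diff(r)
}

# Largest connected component of a logical slice (8-connectivity)
largest_component <- function(mask_slice) {
  lab <- EBImage::bwlabel(mask_slice)
  if (max(lab) == 0) return(mask_slice & FALSE)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

# Morphological closing + hole filling of a logical slice
close_and_fill <- function(mask_slice, radius = 2) {
  if (radius > 0) {
    brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
    m <- EBImage::closing(EBImage::Image(mask_slice * 1), brush)
  } else {
    m <- EBImage::Image(mask_slice * 1)
  }
  as.matrix(EBImage::fillHull(m)) > 0.5
}

# Binary dilation of a logical volume, slice-wise, disc radius in voxels
dilate_mask <- function(mask, radius) {
  mask <- as_vol3d(mask)
  if (radius <= 0) return(mask)
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  out <- mask
  for (k in seq_len(dim(mask)[3])) {
    out[, , k] <- as.matrix(EBImage::dilate(EBImage::Image(mask[, , k] * 1), brush)) > 0.5
  }
  out
}

stop_sctpet <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
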