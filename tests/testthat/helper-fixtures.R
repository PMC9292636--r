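# Shared fixtures. Phantoms are cached per test run so several test files
# can reuse the same generated subjects.

.fx <- new.env()

desk_config <- function(nz = 1L) {
  phantom_config(grid_shape = c(64L, 64L, nz), voxel_spacing = c(4, 4, 4))
}

# smaller anatomy on a 48x48 grid: fast enough for training loops
small_config <- function(nz = 1L) {
  phantom_config(grid_shape = c(48L, 48L, nz), voxel_spacing = c(4, 4, 4),
                 anatomy_scale = 0.62)
}

fixture_phantom <- function(seed = 7L, nz = 1L) {
  key <- sprintf("ph_%d_%d", seed, nz)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- generate_phantom(desk_config(nz), seed)
  }
  .fx[[key]]
}

fixture_mr_norm <- function(seed = 7L) {
  key <- sprintf("mrn_%d", seed)
  if (is.null(.fx[[key]])) {
    ph <- fixture_phantom(seed)
    .fx[[key]] <- normalize_unit_range(correct_bias_field(
      ph$mr, ph$mr > otsu_vec(ph$mr)))
  }
  .fx[[key]]
}

otsu_vec <- function(x) sctpet:::otsu_threshold(as.vector(x))

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# independent rotation-based parallel projector (oracle for the sparse
# splat projector): rotate the image so the projection direction aligns
# with a grid axis, then sum columns
rotate_project_oracle <- function(img, spacing, angles) {
  nx <- nrow(img); ny <- ncol(img)
  co <- sctpet:::slice_coords(nx, ny, spacing)
  sapply(angles, function(th) {
    # sample the source at R(theta) x, so the radial coordinate aligns with
    # the first matrix axis and the line integral is a row sum
    xs <- co$x * cos(th) - co$y * sin(th)
    ys <- co$x * sin(th) + co$y * cos(th)
    xi <- xs / spacing[1] + (nx + 1) / 2
    yi <- ys / spacing[2] + (ny + 1) / 2
    rot <- matrix(sctpet:::bilinear_sample(img, xi, yi, 0), nx, ny)
    rowSums(rot) * spacing[2]
  })
}
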