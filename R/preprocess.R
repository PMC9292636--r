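# MR conditioning and registration. Deformation fields are dense per-voxel
# displacement vectors (mm) on the fixed-image grid; affine and B-spline
# stages compose into one field. The similarity metric is (normalized)
# mutual information; the affine stage uses Nelder-Mead, the B-spline stage
# a simultaneous-perturbation stochastic gradient descent in the adaptive
# stochastic gradient family. Slices of a stack are registered independently.

#' Create an identity deformation field
#' @param dims volume dims c(nx, ny, nz)
#' @param spacing voxel spacing (mm)
#' @return \code{deformation_field}: list(dx, dy, spacing, log)
#' @export
identity_field <- function(dims, spacing) {
  z <- array(0, dim = dims)
  structure(list(dx = z, dy = z, spacing = spacing, log = list()),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  m <- sqrt(x$dx^2 + x$dy^2)
  cat(sprintf("<deformation_field> %s, |d| mean %.2f mm, max %.2f mm\n",
              paste(dim(x$dx), collapse = " x "), mean(m), max(m)))
  invisible(x)
}

# cubic B-spline basis matrix mapping control coefficients to dense values
bspline_basis <- function(n, spacing, grid_spacing_mm) {
  pos <- grid_coords_mm(n, spacing)
  extent <- c(pos[1] - 2 * grid_spacing_mm, pos[n] + 2 * grid_spacing_mm)
  knots <- seq(extent[1], extent[2], by = grid_spacing_mm)
  b3 <- function(t) {
    at <- abs(t)
    ifelse(at < 1, (4 - 6 * at^2 + 3 * at^3) / 6,
           ifelse(at < 2, (2 - at)^3 / 6, 0))
  }
  B <- outer(pos, knots, function(p, k) b3((p - k) / grid_spacing_mm))
  B
}

# dense field from control coefficient matrices (one per component)
field_from_coeffs <- function(cx, cy, Bx, By) {
  list(dx = Bx %*% cx %*% t(By), dy = Bx %*% cy %*% t(By))
}

#' Smooth random B-spline deformation with a stated peak magnitude
#' @param dims volume dims
#' @param spacing voxel spacing (mm)
#' @param magnitude_mm peak displacement magnitude
#' @param seed integer seed
#' @param grid_spacing_mm control-point spacing
#' @return \code{deformation_field}
#' @export
random_deformation <- function(dims, spacing, magnitude_mm, seed = 1L,
                               grid_spacing_mm = 48) {
  Bx <- bspline_basis(dims[1], spacing[1], grid_spacing_mm)
  By <- bspline_basis(dims[2], spacing[2], grid_spacing_mm)
  fld <- identity_field(dims, spacing)
  with_seed(seed, {
    for (k in seq_len(dims[3])) {
      cx <- matrix(rnorm(ncol(Bx) * ncol(By)), ncol(Bx))
      cy <- matrix(rnorm(ncol(Bx) * ncol(By)), ncol(Bx))
      d <- field_from_coeffs(cx, cy, Bx, By)
      peak <- max(sqrt(d$dx^2 + d$dy^2))
      if (peak > 0) {
        fld$dx[, , k] <- d$dx / peak * magnitude_mm
        fld$dy[, , k] <- d$dy / peak * magnitude_mm
      }
    }
  })
  fld
}

#' Compose two deformation fields
#'
#' Returns the field equivalent to warping with \code{inner} after
#' \code{outer}: d(x) = d_inner(x + d_outer(x)) + d_outer(x). Used to chain
#' the affine and B-spline stages.
#' @param inner,outer \code{deformation_field}s on the same grid
#' @return composed \code{deformation_field}
#' @export
compose_fields <- function(inner, outer) {
  dims <- dim(outer$dx)
  sp <- outer$spacing
  out <- outer
  for (k in seq_len(dims[3])) {
    xs <- matrix(seq_len(dims[1]), dims[1], dims[2])
    ys <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
    xi <- xs + outer$dx[, , k] / sp[1]
    yi <- ys + outer$dy[, , k] / sp[2]
    out$dx[, , k] <- outer$dx[, , k] +
      matrix(bilinear_sample(inner$dx[, , k], xi, yi, 0), dims[1], dims[2])
    out$dy[, , k] <- outer$dy[, , k] +
      matrix(bilinear_sample(inner$dy[, , k], xi, yi, 0), dims[1], dims[2])
  }
  out$log <- c(inner$log, outer$log)
  out
}

#' Resample a volume through a deformation field
#'
#' output(x) = input(x + d(x)); linear interpolation for intensity images,
#' nearest-neighbour for label volumes. Out-of-domain voxels take
#' \code{fill}.
#' @param img volume (3D array or matrix)
#' @param field \code{deformation_field} on the output grid
#' @param interpolation "linear" or "nearest"
#' @param fill background fill value
#' @return warped volume
#' @export
resample_volume <- function(img, field, interpolation = c("linear", "nearest"),
                            fill = 0) {
  interpolation <- match.arg(interpolation)
  img <- as_vol3d(img)
  dims <- dim(field$dx)
  sp <- field$spacing
  out <- array(fill, dim = dims)
  xs <- matrix(seq_len(dims[1]), dims[1], dims[2])
  ys <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  for (k in seq_len(dims[3])) {
    xi <- xs + field$dx[, , k] / sp[1]
    yi <- ys + field$dy[, , k] / sp[2]
    v <- if (interpolation == "linear") {
      bilinear_sample(img[, , min(k, dim(img)[3])], xi, yi, fill)
    } else {
      nearest_sample(img[, , min(k, dim(img)[3])], xi, yi, fill)
    }
    out[, , k] <- matrix(v, dims[1], dims[2])
  }
  out
}

#' Correct a smooth multiplicative bias field
#'
#' N4-style correction: a low-order polynomial surface is fitted in the log
#' domain to the voxels of the dominant tissue class -- selected as the
#' neighbourhood of the main mode of the masked log-intensity histogram --
#' and divided out; selection and fit are iterated with a shrinking window
#' so the residual bias, not anatomy, drives the surface. A bias-free input
#' is left (near) unchanged because the modal class is then constant and
#' its fitted surface flat.
#'
#' @param mr MR volume (arbitrary units, positive inside the body)
#' @param mask logical body mask (same dims); must be non-empty
#' @param order polynomial order of the fitted surface per slice
#' @param windows shrinking half-widths (log units) of the modal selection
#' @return corrected MR volume; the estimated field is attached as
#'   attribute \code{"bias_field"}
#' @export
correct_bias_field <- function(mr, mask, order = 3,
                               windows = c(0.3, 0.2, 0.15)) {
  mr <- as_vol3d(mr); mask <- as_vol3d(mask)
  if (!any(mask)) stop_sctpet("body mask is empty; nothing to correct")
  dims <- dim(mr)
  out <- mr
  field_all <- array(1, dim = dims)
  co <- slice_coords(dims[1], dims[2], c(1, 1))
  xh <- co$x / max(abs(co$x)); yh <- co$y / max(abs(co$y))
  # polynomial design up to total order `order`
  terms <- list()
  for (i in 0:order) for (j in 0:(order - i)) terms[[length(terms) + 1]] <- c(i, j)
  X <- vapply(terms, function(t) as.vector(xh^t[1] * yh^t[2]),
              numeric(length(xh)))
  eps <- 1e-6
  for (k in seq_len(dims[3])) {
    m <- as.vector(mask[, , k]) & as.vector(mr[, , k]) > eps
    if (sum(m) < 3 * ncol(X)) next
    lv0 <- log(as.vector(mr[, , k])[m])
    Xm <- X[m, , drop = FALSE]
    lv <- lv0
    total <- numeric(ncol(X))
    for (w in windows) {
      if (diff(range(lv)) < 1e-8) break
      den <- stats::density(lv, n = 256)
      mode <- den$x[which.max(den$y)]
      sel <- abs(lv - mode) < w
      if (sum(sel) < 3 * ncol(X)) break
      fit <- stats::lm.fit(Xm[sel, , drop = FALSE], lv[sel])
      cf <- fit$coefficients
      cf[!is.finite(cf)] <- 0
      lv <- lv - as.vector(Xm %*% cf)
      total <- total + cf
    }
    logf <- X %*% total
    logf <- logf - mean(logf[m])
    field <- matrix(exp(logf), dims[1], dims[2])
    sl <- mr[, , k]
    corr <- sl / field
    sl[mask[, , k]] <- corr[mask[, , k]]
    out[, , k] <- sl
    field_all[, , k] <- field
  }
  attr(out, "bias_field") <- field_all
  out
}

#' Match the intensity histogram of one volume to a reference
#'
#' Monotone quantile mapping: the empirical quantile function of the input
#' is mapped onto the reference's. Degenerate (constant) inputs map to the
#' reference median.
#' @param mr input volume
#' @param reference_mr reference volume
#' @param n_quantiles number of quantile knots
#' @return volume with the reference's intensity distribution
#' @export
match_histogram <- function(mr, reference_mr, n_quantiles = 256) {
  q <- seq(0, 1, length.out = n_quantiles + 1)
  xq <- quantile(mr, q, names = FALSE, type = 7)
  yq <- quantile(reference_mr, q, names = FALSE, type = 7)
  if (diff(range(xq)) <= 0) {
    out <- mr
    out[] <- stats::median(reference_mr)
    return(out)
  }
  # collapse duplicated input knots (flat histogram regions)
  grp <- cumsum(c(TRUE, diff(xq) > 0))
  xk <- tapply(xq, grp, utils::tail, 1)
  yk <- tapply(yq, grp, mean)
  out <- mr
  out[] <- approx(as.numeric(xk), as.numeric(yk), xout = as.vector(mr),
                  rule = 2)$y
  out
}

#' Normalize intensities to the unit range
#'
#' Linear map of [p_low, p_high] percentiles to [0, 1], clipping outside.
#' Percentiles are order statistics (inverse-ECDF quantiles), which makes
#' the operation exactly idempotent. A zero-range image maps to all zeros.
#' @param img volume
#' @param clip_percentiles c(low, high) percentiles (0-100)
#' @return volume in [0, 1]
#' @export
normalize_unit_range <- function(img, clip_percentiles = c(0, 99.5)) {
  lo <- quantile(img, clip_percentiles[1] / 100, names = FALSE, type = 1)
  hi <- quantile(img, clip_percentiles[2] / 100, names = FALSE, type = 1)
  if (hi <= lo) {
    img[] <- 0
    return(img)
  }
  pmin(pmax((img - lo) / (hi - lo), 0), 1)
}

# --- mutual information ------------------------------------------------------

# Normalized mutual information (Studholme) of two equal-length vectors
nmi_vectors <- function(a, b, bins = 48) {
  ra <- range(a); rb <- range(b)
  if (diff(ra) <= 0 || diff(rb) <= 0) return(1)
  ia <- pmin(pmax(floor((a - ra[1]) / diff(ra) * bins) + 1L, 1L), bins)
  ib <- pmin(pmax(floor((b - rb[1]) / diff(rb) * bins) + 1L, 1L), bins)
  jo <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins)
  p <- jo / sum(jo)
  px <- rowSums(matrix(p, bins)); py <- colSums(matrix(p, bins))
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hj <- ent(p)
  if (hj <= 0) return(2)
  (ent(px) + ent(py)) / hj
}

# warp one slice by affine parameters p = (tx, ty, theta, log sx, log sy, shear)
affine_warp_slice <- function(img, p, spacing, fill) {
  nx <- nrow(img); ny <- ncol(img)
  co <- slice_coords(nx, ny, spacing)
  ct <- cos(p[3]); st <- sin(p[3])
  sx <- exp(p[4]); sy <- exp(p[5]); sh <- p[6]
  # source point = S %*% R %*% x + t (sampling the moving image)
  xr <- ct * co$x - st * co$y
  yr <- st * co$x + ct * co$y
  xs <- sx * xr + sh * yr + p[1]
  ys <- sy * yr + p[2]
  xi <- xs / spacing[1] + (nx + 1) / 2
  yi <- ys / spacing[2] + (ny + 1) / 2
  matrix(bilinear_sample(img, xi, yi, fill), nx, ny)
}

affine_field_slice <- function(p, nx, ny, spacing) {
  co <- slice_coords(nx, ny, spacing)
  ct <- cos(p[3]); st <- sin(p[3])
  sx <- exp(p[4]); sy <- exp(p[5]); sh <- p[6]
  xr <- ct * co$x - st * co$y
  yr <- st * co$x + ct * co$y
  list(dx = sx * xr + sh * yr + p[1] - co$x,
       dy = sy * yr + p[2] - co$y)
}

register_affine_slice <- function(mov, fix, spacing, bins, fill,
                                  maxit = c(150, 120), search_mm = 16) {
  obj_for <- function(m, f, sp) {
    function(p) -nmi_vectors(as.vector(affine_warp_slice(m, p, sp, fill)),
                             as.vector(f), bins)
  }
  p0 <- rep(0, 6)
  scale_par <- c(4, 4, 0.04, 0.04, 0.04, 0.04)
  if (min(dim(fix)) >= 32) {
    m2 <- downsample2(mov); f2 <- downsample2(fix)
    obj2 <- obj_for(m2, f2, spacing * 2)
    # coarse exhaustive translation search: the MI landscape has sub-voxel
    # interpolation ripple, so a gradient-free simplex needs a basin start
    step <- max(spacing) * 2
    cand <- expand.grid(tx = seq(-search_mm, search_mm, by = step),
                        ty = seq(-search_mm, search_mm, by = step))
    vals <- vapply(seq_len(nrow(cand)), function(i)
      obj2(c(cand$tx[i], cand$ty[i], 0, 0, 0, 0)), 0)
    best <- which.min(vals)
    p0 <- c(cand$tx[best], cand$ty[best], 0, 0, 0, 0)
    r <- optim(p0, obj2, method = "Nelder-Mead",
               control = list(maxit = maxit[1], parscale = scale_par))
    p0 <- r$par
  }
  r <- optim(p0, obj_for(mov, fix, spacing), method = "Nelder-Mead",
             control = list(maxit = maxit[2], parscale = scale_par))
  r$par
}

# SPSA optimization of B-spline control coefficients on NMI
register_bspline_slice <- function(mov, fix, spacing, bins, fill,
                                   grid_spacing_mm = 40, iterations = 300,
                                   max_disp_mm = 12, seed = 42L,
                                   theta0 = NULL, smooth = TRUE) {
  if (smooth) {
    # the metric is evaluated on lightly smoothed images: sub-voxel
    # interpolation ripple in the joint histogram otherwise drowns the
    # stochastic gradient signal
    mov <- box_mean(mov, 1)
    fix <- box_mean(fix, 1)
  }
  nx <- nrow(mov); ny <- ncol(mov)
  Bx <- bspline_basis(nx, spacing[1], grid_spacing_mm)
  By <- bspline_basis(ny, spacing[2], grid_spacing_mm)
  ncx <- ncol(Bx); ncy <- ncol(By)
  npar <- 2 * ncx * ncy
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  fv <- as.vector(fix)
  objective <- function(theta) {
    cx <- matrix(theta[1:(ncx * ncy)], ncx)
    cy <- matrix(theta[(ncx * ncy + 1):npar], ncx)
    d <- field_from_coeffs(cx, cy, Bx, By)
    xi <- xs + d$dx / spacing[1]
    yi <- ys + d$dy / spacing[2]
    -nmi_vectors(bilinear_sample(mov, xi, yi, fill), fv, bins)
  }
  theta <- if (!is.null(theta0) && length(theta0) == npar) theta0 else rep(0, npar)
  best <- list(theta = theta, f = objective(theta))
  A <- 15; c0 <- 0.8; step0 <- 1.2 # target initial control-point step (mm)
  trace <- numeric(0)
  with_seed(seed, {
    # auto-scale the gain: with Bernoulli perturbations every gradient
    # component has magnitude |f+ - f-| / (2c); probe it at the start
    probe <- replicate(5, {
      delta <- sample(c(-1, 1), npar, replace = TRUE)
      abs(objective(theta + c0 * delta) - objective(theta - c0 * delta)) / (2 * c0)
    })
    gmag <- max(mean(probe), 1e-8)
    a0 <- step0 * (1 + A)^0.602 / gmag
    for (it in seq_len(iterations)) {
      ak <- a0 / (it + A)^0.602
      ck <- c0 / it^0.101
      delta <- sample(c(-1, 1), npar, replace = TRUE)
      fp <- objective(theta + ck * delta)
      fm <- objective(theta - ck * delta)
      ghat <- (fp - fm) / (2 * ck) * delta
      theta <- theta - ak * ghat
      theta <- pmin(pmax(theta, -max_disp_mm), max_disp_mm)
      if (it %% 10 == 0 || it == iterations) {
        f <- objective(theta)
        trace <- c(trace, -f)
        if (f < best$f) best <- list(theta = theta, f = f)
      }
    }
  })
  theta <- best$theta
  cx <- matrix(theta[1:(ncx * ncy)], ncx)
  cy <- matrix(theta[(ncx * ncy + 1):npar], ncx)
  d <- field_from_coeffs(cx, cy, Bx, By)
  list(dx = d$dx, dy = d$dy, trace = trace, nmi = -best$f, theta = theta)
}

#' Register a moving volume onto a fixed volume
#'
#' One registration stage driven by (normalized) mutual information.
#' The affine stage optimises translation, rotation, anisotropic scale and
#' shear with Nelder-Mead at two resolutions; the B-spline stage optimises a
#' free-form control grid with simultaneous-perturbation stochastic gradient
#' descent. The returned field maps the moving image onto the fixed grid;
#' the best-seen metric value is kept, so the reported mutual information
#' never decreases relative to the initial value.
#'
#' @param moving,fixed volumes on grids with overlapping physical extents
#' @param stage "affine" or "bspline"
#' @param metric only "mutual_information" (normalized) is available
#' @param spacing voxel spacing (mm)
#' @param init_field optional initial \code{deformation_field} (e.g. the
#'   affine result before a B-spline refinement); composed into the output
#' @param bins joint-histogram bins
#' @param fill background fill for out-of-domain samples
#' @param origin_moving,origin_fixed physical centre offsets (mm); used only
#'   to verify that the two grids overlap
#' @param control control parameters for the B-spline stage
#'   (grid_spacing_mm, iterations, max_disp_mm, seed)
#' @return \code{deformation_field} with a \code{log} entry per slice
#'   recording initial and final metric values
#' @export
register_images <- function(moving, fixed, stage = c("affine", "bspline"),
                            metric = "mutual_information",
                            spacing = c(2, 2, 2), init_field = NULL,
                            bins = 48, fill = NULL,
                            origin_moving = c(0, 0), origin_fixed = c(0, 0),
                            control = list()) {
  stage <- match.arg(stage)
  if (!identical(metric, "mutual_information"))
    stop_sctpet("unsupported metric '%s'", metric)
  moving <- as_vol3d(moving); fixed <- as_vol3d(fixed)
  dm <- dim(moving); df <- dim(fixed)
  # physical extents (centred at the stated origins) must overlap
  half_m <- dm[1:2] * spacing[1:2] / 2
  half_f <- df[1:2] * spacing[1:2] / 2
  if (any(abs(origin_moving - origin_fixed) >= half_m + half_f))
    stop_sctpet("moving and fixed grids do not overlap in physical space")
  if (is.null(fill)) fill <- as.numeric(quantile(moving, 0.01, names = FALSE))
  work_mov <- if (!is.null(init_field)) {
    resample_volume(moving, init_field, "linear", fill)
  } else moving
  field <- identity_field(df, spacing)
  for (k in seq_len(df[3])) {
    mk <- work_mov[, , min(k, dim(work_mov)[3])]
    fk <- fixed[, , k]
    nmi0 <- nmi_vectors(as.vector(mk), as.vector(fk), bins)
    if (stage == "affine") {
      p <- register_affine_slice(mk, fk, spacing[1:2], bins, fill)
      d <- affine_field_slice(p, df[1], df[2], spacing[1:2])
      nmi1 <- nmi_vectors(as.vector(affine_warp_slice(mk, p, spacing[1:2], fill)),
                          as.vector(fk), bins)
      if (nmi1 < nmi0) { # keep identity rather than a worse fit
        d <- list(dx = matrix(0, df[1], df[2]), dy = matrix(0, df[1], df[2]))
        nmi1 <- nmi0
      }
      field$dx[, , k] <- d$dx; field$dy[, , k] <- d$dy
      field$log[[k]] <- list(stage = "affine", nmi_initial = nmi0, nmi_final = nmi1)
    } else {
      ctl <- utils::modifyList(list(grid_spacing_mm = 40, iterations = 300,
                                    max_disp_mm = 12, seed = 42L), control)
      r <- register_bspline_slice(mk, fk, spacing[1:2], bins, fill,
                                  ctl$grid_spacing_mm, ctl$iterations,
                                  ctl$max_disp_mm, ctl$seed)
      nmi1 <- max(r$nmi, nmi0)
      if (r$nmi < nmi0) {
        r$dx[] <- 0; r$dy[] <- 0
      }
      field$dx[, , k] <- r$dx; field$dy[, , k] <- r$dy
      field$log[[k]] <- list(stage = "bspline", nmi_initial = nmi0,
                             nmi_final = nmi1, trace = r$trace)
    }
  }
  if (!is.null(init_field)) field <- compose_fields(init_field, field)
  field
}

#' Affine followed by B-spline registration
#'
#' Convenience wrapper running the two stages of the standard pipeline and
#' composing their fields. If the B-spline stage fails to improve the metric
#' on a slice, one retry with a perturbed control-point spacing is attempted.
#' @inheritParams register_images
#' @param bspline_control control list for the B-spline stage
#' @return composed \code{deformation_field}
#' @export
register_pair <- function(moving, fixed, spacing = c(2, 2, 2), bins = 48,
                          fill = NULL, bspline_control = list()) {
  af <- register_images(moving, fixed, "affine", spacing = spacing,
                        bins = bins, fill = fill)
  bf <- register_images(moving, fixed, "bspline", spacing = spacing,
                        init_field = af, bins = bins, fill = fill,
                        control = bspline_control)
  improved <- vapply(bf$log, function(l) {
    is.null(l$nmi_final) || l$nmi_final >= (l$nmi_initial %||% 0)
  }, TRUE)
  if (!all(improved)) {
    ctl <- utils::modifyList(bspline_control,
                             list(grid_spacing_mm =
                                    (bspline_control$grid_spacing_mm %||% 40) * 1.5))
    bf <- register_images(moving, fixed, "bspline", spacing = spacing,
                          init_field = af, bins = bins, fill = fill,
                          control = ctl)
  }
  bf
}
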