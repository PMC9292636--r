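# NIfTI-1 and YAML interchange. Volumes carry their spacing in the NIfTI
# pixdim; organ masks are written as uint8 label volumes.

#' Write a volume as NIfTI-1
#' @param vol 3D array (logical volumes are written as 0/1)
#' @param path output path (.nii or .nii.gz)
#' @param spacing voxel spacing (mm)
#' @return the path, invisibly
#' @export
write_volume <- function(vol, path, spacing = c(2, 2, 2)) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  vol <- as_vol3d(vol)
  if (is.logical(vol)) vol <- array(as.integer(vol), dim = dim(vol))
  img <- RNifti::asNifti(vol, list(pixdim = c(-1, spacing, rep(1, 4))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#' @param path NIfTI file
#' @return list(data = 3D array, spacing = voxel spacing in mm)
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  # a trailing singleton dimension may be squeezed on read; pad to 3D
  list(data = as_vol3d(array(as.numeric(img), dim = dim(img))),
       spacing = c(pd, rep(1, 3))[1:3])
}

#' Write a phantom bundle (volumes + organ masks + config) to a directory
#' @param phantom \code{torso_phantom}
#' @param dir output directory
#' @return the directory, invisibly
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- phantom$spacing
  write_volume(phantom$labels, file.path(dir, "labels.nii.gz"), sp)
  write_volume(phantom$ct_hu, file.path(dir, "ct_hu.nii.gz"), sp)
  write_volume(phantom$mr, file.path(dir, "mr.nii.gz"), sp)
  write_volume(phantom$activity, file.path(dir, "activity.nii.gz"), sp)
  organs <- array(0L, dim = dim(phantom$labels))
  for (i in seq_along(phantom$organs)) {
    organs[phantom$organs[[i]]] <- i
  }
  write_volume(organs, file.path(dir, "organs.nii.gz"), sp)
  write_phantom_config(phantom$config, file.path(dir, "config.yaml"),
                       extra = list(subject_seed = phantom$seed,
                                    organ_names = names(phantom$organs),
                                    outliers = lapply(phantom$outliers_applied,
                                                      function(o) c(type = o$type, o$params))))
  invisible(dir)
}

#' Write a phantom configuration as YAML
#' @param config \code{phantom_config}
#' @param path output path
#' @param extra named list appended to the file
#' @return the path, invisibly
#' @export
write_phantom_config <- function(config, path, extra = list()) {
  obj <- unclass(config)
  obj$tissue_table <- as.list(config$tissue_table)
  obj$rib_spec <- as.list(config$rib_spec)
  obj$lung_centers <- as.vector(t(config$lung_centers))
  yaml::write_yaml(c(obj, extra), path)
  invisible(path)
}

#' Read a phantom configuration from YAML
#' @param path YAML file written by \code{\link{write_phantom_config}}
#' @return \code{phantom_config}
#' @export
read_phantom_config <- function(path) {
  obj <- yaml::read_yaml(path)
  phantom_config(
    grid_shape = unlist(obj$grid_shape),
    voxel_spacing = unlist(obj$voxel_spacing),
    body_axes = unlist(obj$body_axes),
    arm_radius = obj$arm_radius, arm_offset = obj$arm_offset,
    lung_axes = unlist(obj$lung_axes),
    lung_centers = matrix(unlist(obj$lung_centers), 2, 2, byrow = TRUE,
                          dimnames = list(c("right", "left"), NULL)),
    spine_radius = obj$spine_radius, spine_center = unlist(obj$spine_center),
    marrow_radius = obj$marrow_radius,
    rib_spec = as.data.frame(obj$rib_spec),
    fat_thickness = obj$fat_thickness,
    tissue_table = as.data.frame(obj$tissue_table),
    mr_bias_field_amplitude = obj$mr_bias_field_amplitude,
    jitter_sd = obj$jitter_sd, noise_seed = obj$noise_seed
  )
}

#' Write a deformation field as a NIfTI displacement volume
#' @param field \code{deformation_field}
#' @param path output path; components stack along a 4th dimension
#' @return the path, invisibly
#' @export
write_field <- function(field, path) {
  arr <- array(c(field$dx, field$dy), dim = c(dim(field$dx), 2))
  img <- RNifti::asNifti(arr, list(pixdim = c(-1, field$spacing, 1, rep(1, 3))))
  RNifti::writeNifti(img, path)
  invisible(path)
}
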