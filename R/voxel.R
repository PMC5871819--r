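#' Voxel volumes
#'
#' A `voxel_volume` is a 3D grid with physical spacing (mm per voxel, default
#' 0.7 isotropic as in thin-slice chest CT) and origin, carrying either a
#' binary label (`surface_labels`, `lung_mask`, `lumen_mask`) or integer
#' Hounsfield attenuation (`hu_attenuation`).
#'
#' @param grid 3D array; binary kinds must contain only 0/1.
#' @param spacing positive numeric 3-vector, mm per voxel.
#' @param origin numeric 3-vector, mm position of voxel (1,1,1).
#' @param kind one of `"surface_labels"`, `"hu_attenuation"`, `"lung_mask"`,
#'   `"lumen_mask"`.
#' @return a `voxel_volume`.
#' @export
voxel_volume <- function(grid,
                         spacing = c(0.7, 0.7, 0.7),
                         origin = c(0, 0, 0),
                         kind = c("surface_labels", "hu_attenuation",
                                  "lung_mask", "lumen_mask")) {
  kind <- match.arg(kind)
  if (length(dim(grid)) != 3) stop("grid must be a 3D array")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (kind != "hu_attenuation" && !all(grid %in% c(0, 1)))
    stop("binary volume kinds must contain only 0 and 1")
  structure(list(grid = grid, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), kind = kind),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("voxel_volume [%s]: %s voxels, spacing %s mm\n", x$kind,
              paste(dim(x$grid), collapse = "x"),
              paste(format(x$spacing), collapse = "/")))
  invisible(x)
}

#' Write a voxel volume as NIfTI
#'
#' @param vol a `voxel_volume`.
#' @param path output path; use a `.nii` suffix (uncompressed).
#' @export
write_volume <- function(vol, path) {
  im <- RNifti::asNifti(vol$grid)
  RNifti::pixdim(im) <- vol$spacing
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a voxel volume from NIfTI
#'
#' Voxel spacing is taken from the NIfTI pixdim; the origin is set to 0
#' (phantom volumes generated by this package are origin-0).
#'
#' @param path NIfTI file.
#' @param kind the volume kind (see [voxel_volume()]).
#' @return a `voxel_volume`.
#' @export
read_volume <- function(path, kind = "surface_labels") {
  im <- RNifti::readNifti(path)
  voxel_volume(as.array(im), spacing = RNifti::pixdim(im)[1:3], kind = kind)
}

#' Point cloud of the 1-voxels
#'
#' Converts a binary volume to a point cloud in mm: one point per voxel with
#' value 1, at origin + (index - 1) * spacing. This is the input of the
#' degree-2 void descriptor.
#'
#' @param vol a binary `voxel_volume`.
#' @return an m x 3 matrix of coordinates (mm).
#' @export
voxel_to_pointcloud <- function(vol) {
  if (vol$kind == "hu_attenuation")
    stop("contract violation: point clouds come from binary volumes")
  idx <- which(vol$grid == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("degenerate input: volume has no 1-voxels")
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}
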