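# File formats: NIfTI volumes (RNifti), FSL-dialect bval/bvec gradient
# tables, TSV tables and YAML configuration echo.

#' Write a gradient scheme as FSL bval/bvec files
#'
#' FSL dialect: one row of b-values; three rows of direction components
#' (3 x N), in image coordinates.
#'
#' @param scheme A `gradient_scheme`.
#' @param bval_path,bvec_path Output paths.
#' @export
write_bvals_bvecs <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             bval_path)
  bv <- t(scheme$bvecs)
  writeLines(apply(bv, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec_path)
  invisible(NULL)
}

#' Read FSL bval/bvec files
#'
#' Accepts both bvec dialects (3 x N rows or N x 3 columns), disambiguated by
#' shape; directions are re-normalised. Entries with |b| < `b0_threshold` are
#' classified as b0.
#'
#' @param bval_path,bvec_path Input paths.
#' @param b0_threshold b-value below which a volume counts as non-weighted.
#' @return A `gradient_scheme`.
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path, b0_threshold = 50) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- lapply(readLines(bvec_path), function(l)
    scan(text = l, quiet = TRUE))
  rows <- rows[vapply(rows, length, integer(1)) > 0]
  m <- do.call(rbind, rows)
  if (nrow(m) == 3 && ncol(m) != 3) {
    bvecs <- t(m)
  } else if (ncol(m) == 3 && nrow(m) != 3) {
    bvecs <- m
  } else if (nrow(m) == 3 && ncol(m) == 3) {
    bvecs <- m # ambiguous 3 x 3; either reading is a valid direction set
  } else {
    stop(sprintf("format error: %s is neither 3 x N nor N x 3", bvec_path))
  }
  if (nrow(bvecs) != length(bvals))
    stop(sprintf("format error: %s has %d entries but %s has %d directions",
                 bval_path, length(bvals), bvec_path, nrow(bvecs)))
  dw <- abs(bvals) >= b0_threshold
  bvecs[dw, ] <- normalize_rows(bvecs[dw, , drop = FALSE])
  bvecs[!dw, ] <- 0
  b <- if (any(dw)) stats::median(bvals[dw]) else 0
  structure(list(bvals = bvals, bvecs = bvecs, b_value = b),
            class = "gradient_scheme")
}

#' Write a 3D or 4D volume as NIfTI
#'
#' RAS+ scaled affine with the given voxel size; integer data are written as
#' int16, floating point as float32.
#'
#' @param data Numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Isotropic voxel size in mm.
#' @export
write_volume <- function(data, path, voxel_size) {
  datatype <- if (is.integer(data) || all(data == round(data)))
    "int16" else "float"
  img <- RNifti::asNifti(data * 1)
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path Input path.
#' @return List: `data` (array), `voxel_size` (first three pixdims),
#'   `affine`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       voxel_size = RNifti::pixdim(img)[1:3],
       affine = RNifti::xform(img))
}

#' Read a diffusion-weighted dataset
#'
#' Reads the 4D NIfTI plus its gradient table, checking that the volume
#' count matches the gradient entries.
#'
#' @param dwi_path,bval_path,bvec_path Input paths.
#' @return A `dwi_volume` (data, scheme, voxel_size, affine).
#' @export
read_dwi <- function(dwi_path, bval_path, bvec_path) {
  vol <- read_volume(dwi_path)
  scheme <- read_bvals_bvecs(bval_path, bvec_path)
  nvol <- if (length(dim(vol$data)) == 4) dim(vol$data)[4] else 1L
  if (nvol != length(scheme$bvals))
    stop(sprintf("format error: %s has %d volumes but %s lists %d b-values",
                 dwi_path, nvol, bval_path, length(scheme$bvals)))
  structure(list(data = vol$data, scheme = scheme,
                 voxel_size = vol$voxel_size[1], affine = vol$affine),
            class = "dwi_volume")
}

#' Write a phantom dataset to a directory
#'
#' Emits the noisy 4D volume, bval/bvec, ground-truth label and mask volumes
#' and a YAML echo of the configuration.
#'
#' @param phantom A [generate_phantom()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- phantom$config$voxel_size
  write_volume(phantom$dwi$data, file.path(dir, "dwi.nii.gz"), vs)
  write_bvals_bvecs(phantom$scheme, file.path(dir, "dwi.bval"),
                    file.path(dir, "dwi.bvec"))
  tr <- phantom$truth
  write_volume(tr$layer_labels, file.path(dir, "layer_labels.nii.gz"), vs)
  write_volume(tr$area_labels, file.path(dir, "area_labels.nii.gz"), vs)
  write_volume(tr$wm_mask * 1L, file.path(dir, "wm_mask.nii.gz"), vs)
  write_volume(tr$gm_mask * 1L, file.path(dir, "gm_mask.nii.gz"), vs)
  write_volume(tr$pial_mask * 1L, file.path(dir, "pial_mask.nii.gz"), vs)
  write_volume(tr$background_mask * 1L,
               file.path(dir, "background_mask.nii.gz"), vs)
  cfg <- phantom$config
  cfg$layer_spec <- as.list(cfg$layer_spec)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @keywords internal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
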