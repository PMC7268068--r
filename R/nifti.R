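# NIfTI import/export for trial beta images and masks, so the decoding
# stages accept real per-trial beta volumes alongside simulated matrices.

#' Write a trial beta matrix as a 4-D NIfTI stack
#'
#' Voxels are placed at their grid coordinates inside a volume covering the
#' coordinate bounding box; one 3-D volume per trial.
#'
#' @param B Trials x voxels matrix.
#' @param coords Integer voxel coordinates (voxels x 3, 1-based).
#' @param path Output `.nii` / `.nii.gz` path.
#' @param spacing_mm Isotropic voxel spacing recorded in the header.
#' @param dims Volume dimensions; default the coordinate bounding box.
#' @return `path`, invisibly.
#' @export
write_betas_nifti <- function(B, coords, path, spacing_mm = 1.5, dims = NULL) {
  coords <- as.matrix(coords)
  check_param(nrow(coords) == ncol(B), "`coords` must have one row per voxel")
  if (is.null(dims)) dims <- apply(coords, 2, max)
  arr <- array(0, dim = c(dims, nrow(B)))
  for (tr in seq_len(nrow(B)))
    arr[cbind(coords, tr)] <- B[tr, ]
  img <- RNifti::asNifti(arr, pixdim = c(rep(spacing_mm, 3), 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a voxel mask as a 3-D NIfTI volume
#'
#' @param coords Integer in-mask voxel coordinates (voxels x 3, 1-based).
#' @param path Output path.
#' @param spacing_mm Voxel spacing.
#' @param dims Volume dimensions; default the coordinate bounding box.
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(coords, path, spacing_mm = 1.5, dims = NULL) {
  coords <- as.matrix(coords)
  if (is.null(dims)) dims <- apply(coords, 2, max)
  arr <- array(0L, dim = dims)
  arr[coords] <- 1L
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = rep(spacing_mm, 3)), path)
  invisible(path)
}

#' Read a 4-D beta stack and mask into a trial beta matrix
#'
#' Extracts the in-mask voxels of every trial volume, returning the
#' trials x voxels matrix plus the mask coordinates — the format all
#' decoding stages consume. An events table (see [read_events_tsv()])
#' supplies the trial metadata.
#'
#' @param beta_path 4-D NIfTI of per-trial betas.
#' @param mask_path 3-D NIfTI mask (nonzero = in mask); `NULL` keeps all
#'   nonzero-variance voxels.
#' @param events Optional `"fc_design"` from [read_events_tsv()]; its trial
#'   table is attached to the result.
#' @return Trials x voxels matrix with attributes `coords` (voxels x 3)
#'   and, if given, `trials`.
#' @export
read_betas_nifti <- function(beta_path, mask_path = NULL, events = NULL) {
  arr <- as.array(RNifti::readNifti(beta_path))
  check_param(length(dim(arr)) == 4, "beta image must be 4-D (x, y, z, trial)")
  d <- dim(arr)
  if (!is.null(mask_path)) {
    mask <- as.array(RNifti::readNifti(mask_path)) != 0
    check_param(all(dim(mask) == d[1:3]), "mask and beta volumes differ in shape")
  } else {
    mask <- array(TRUE, dim = d[1:3])
  }
  coords <- which(mask, arr.ind = TRUE)
  flat <- matrix(arr, prod(d[1:3]), d[4])
  B <- t(flat[which(mask), , drop = FALSE])
  colnames(B) <- paste0("v", seq_len(ncol(B)))
  attr(B, "coords") <- unname(coords)
  if (!is.null(events)) attr(B, "trials") <- events$trials
  B
}
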