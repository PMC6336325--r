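#' NIfTI input/output for image containers
#'
#' Volumes are stored as NIfTI-1 (.nii or .nii.gz). Dynamic images carry a
#' JSON timing sidecar next to the volume (same basename, .json extension)
#' unless another path is given. Atlases pair a label volume with a TSV label
#' table (columns label, name, tissue_class, is_reference).
#'
#' @param img image container to write.
#' @param path NIfTI file path.
#' @param sidecar_path path of the JSON timing sidecar; default replaces the
#'   NIfTI extension with `.json`.
#' @return Writers return `path` invisibly; readers return the container.
#' @name nifti_io
NULL

sidecar_default <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

# Plain numeric array from a niftiImage, with RNifti attributes dropped.
nifti_array <- function(nii) {
  vox <- as.array(nii)
  array(as.numeric(vox), dim(vox))
}

write_nifti_array <- function(voxels, voxel_size_mm, path) {
  nd <- length(dim(voxels))
  img <- RNifti::asNifti(voxels)
  pd <- RNifti::pixdim(img)
  pd[seq_len(min(3L, nd))] <- voxel_size_mm
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
write_dynamic_image <- function(img, path, sidecar_path = sidecar_default(path)) {
  stopifnot(inherits(img, "dynamic_image"))
  write_nifti_array(img$voxels, img$voxel_size_mm, path)
  write_frame_sidecar(img$schedule, sidecar_path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_dynamic_image <- function(path, sidecar_path = sidecar_default(path)) {
  nii <- RNifti::readNifti(path)
  vox <- nifti_array(nii)
  if (length(dim(vox)) != 4L) stop("expected a 4D NIfTI volume")
  schedule <- read_frame_sidecar(sidecar_path)
  dynamic_image(vox, RNifti::pixdim(nii)[1L], schedule)
}

#' @rdname nifti_io
#' @export
write_static_image <- function(img, path) {
  stopifnot(inherits(img, "static_image"))
  write_nifti_array(img$voxels, img$voxel_size_mm, path)
}

#' @rdname nifti_io
#' @export
read_static_image <- function(path) {
  nii <- RNifti::readNifti(path)
  vox <- nifti_array(nii)
  if (length(dim(vox)) != 3L) stop("expected a 3D NIfTI volume")
  static_image(vox, RNifti::pixdim(nii)[1L])
}

#' @rdname nifti_io
#' @param atlas a `pet_atlas`.
#' @param table_path path of the TSV label table.
#' @export
write_atlas <- function(atlas, path, table_path) {
  stopifnot(inherits(atlas, "pet_atlas"))
  write_nifti_array(atlas$labels, atlas$voxel_size_mm, path)
  utils::write.table(atlas$table, table_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_atlas <- function(path, table_path) {
  nii <- RNifti::readNifti(path)
  labels <- nifti_array(nii)
  storage.mode(labels) <- "integer"
  tab <- utils::read.table(table_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  tab$is_reference <- as.logical(tab$is_reference)
  pet_atlas(labels, tab, RNifti::pixdim(nii)[1L])
}
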