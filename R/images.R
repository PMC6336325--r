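#' Image containers
#'
#' `dynamic_image` binds a 4D activity array (x, y, z, frame; kBq/mL) to a
#' [frame_schedule()] and an isotropic voxel size. `static_image` holds a 3D
#' volume on the same grid contract (kBq/mL before normalization, unitless
#' after).
#'
#' @param voxels 4D (dynamic) or 3D (static) numeric array.
#' @param voxel_size_mm isotropic voxel spacing in millimetres.
#' @param schedule a `frame_schedule`; its length must equal the frame axis.
#' @return An object of class `dynamic_image` or `static_image`.
#' @export
dynamic_image <- function(voxels, voxel_size_mm, schedule) {
  if (length(dim(voxels)) != 4L)
    stop("voxels must be a 4D array (x, y, z, frame)")
  stopifnot(inherits(schedule, "frame_schedule"))
  if (dim(voxels)[4L] != n_frames(schedule))
    stop("frame axis length must equal the schedule length")
  if (!all(is.finite(voxels)))
    stop("activity values must be finite")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      !is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("voxel_size_mm must be a single positive number")
  structure(list(voxels = voxels, voxel_size_mm = voxel_size_mm,
                 schedule = schedule),
            class = "dynamic_image")
}

#' @rdname dynamic_image
#' @export
static_image <- function(voxels, voxel_size_mm) {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (!all(is.finite(voxels)))
    stop("voxel values must be finite")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      !is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("voxel_size_mm must be a single positive number")
  structure(list(voxels = voxels, voxel_size_mm = voxel_size_mm),
            class = "static_image")
}

spatial_dim <- function(img) {
  d <- dim(img$voxels)
  d[seq_len(3L)]
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<dynamic_image> %dx%dx%d voxels x %d frames, %.1f mm\n",
              d[1], d[2], d[3], d[4], x$voxel_size_mm))
  invisible(x)
}

#' @export
print.static_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<static_image> %dx%dx%d voxels, %.1f mm\n",
              d[1], d[2], d[3], x$voxel_size_mm))
  invisible(x)
}

#' Time-activity curve
#'
#' Mean activity per frame for a voxel or region, with frame mid-times and
#' durations carried along so kinetic fits can rebuild the acquisition grid.
#'
#' @param mid_s frame mid-times (s), strictly increasing.
#' @param value mean activity per frame (kBq/mL).
#' @param duration_s frame durations (s).
#' @return An object of class `tac`.
#' @export
tac <- function(mid_s, value, duration_s) {
  mid_s <- as.numeric(mid_s); value <- as.numeric(value)
  duration_s <- as.numeric(duration_s)
  if (length(mid_s) != length(value) || length(mid_s) != length(duration_s))
    stop("mid_s, value and duration_s must have equal length")
  if (is.unsorted(mid_s, strictly = TRUE))
    stop("mid_s must be strictly increasing")
  if (any(duration_s <= 0)) stop("durations must be positive")
  structure(list(mid_s = mid_s, value = value, duration_s = duration_s),
            class = "tac")
}

tac_from_schedule <- function(schedule, value) {
  tac(frame_mid_s(schedule), value, frame_duration_s(schedule))
}

# Rebuild the frame schedule implied by a TAC (mid -/+ half duration).
schedule_of_tac <- function(x) {
  frame_schedule(x$mid_s - x$duration_s / 2, x$mid_s + x$duration_s / 2)
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %d frames, peak %.3g at %.0f s\n",
              length(x$value), max(x$value), x$mid_s[which.max(x$value)]))
  invisible(x)
}

#' Labelled volume-of-interest atlas
#'
#' An integer label volume (0 = background) plus a label table naming each
#' region and marking the reference region (cerebellar grey matter in the
#' shipped phantom), which must be present and non-empty.
#'
#' @param labels 3D integer array of region labels; 0 is background.
#' @param table data.frame with columns `label`, `name`, `tissue_class`,
#'   `is_reference` (exactly one `TRUE` row).
#' @param voxel_size_mm isotropic voxel spacing in millimetres.
#' @return An object of class `pet_atlas`.
#' @export
pet_atlas <- function(labels, table, voxel_size_mm) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be nonnegative integers")
  need <- c("label", "name", "tissue_class", "is_reference")
  if (!all(need %in% names(table)))
    stop("table must have columns label, name, tissue_class, is_reference")
  if (sum(table$is_reference) != 1L)
    stop("exactly one region must be marked as reference")
  if (anyDuplicated(table$label) || anyDuplicated(table$name))
    stop("labels and names must be unique")
  present <- sort(unique(as.vector(labels)))
  present <- present[present != 0]
  if (!all(table$label %in% present))
    stop("every table label must be non-empty in the label volume")
  ref <- table$label[table$is_reference]
  structure(list(labels = labels, table = table,
                 reference_label = ref, voxel_size_mm = voxel_size_mm),
            class = "pet_atlas")
}

#' @rdname pet_atlas
#' @param atlas a `pet_atlas`.
#' @param region a region label (numeric) or region name (character).
#' @return `region_mask` returns a logical 3D array.
#' @export
region_mask <- function(atlas, region) {
  stopifnot(inherits(atlas, "pet_atlas"))
  if (is.character(region)) {
    i <- match(region, atlas$table$name)
    if (is.na(i)) stop(sprintf("unknown region '%s'", region))
    region <- atlas$table$label[i]
  }
  atlas$labels == region
}

#' @rdname pet_atlas
#' @export
reference_mask <- function(atlas) region_mask(atlas, atlas$reference_label)

#' @rdname pet_atlas
#' @export
brain_mask <- function(atlas) atlas$labels > 0

#' @export
print.pet_atlas <- function(x, ...) {
  cat(sprintf("<pet_atlas> %d regions, reference '%s'\n",
              nrow(x$table), x$table$name[x$table$is_reference]))
  invisible(x)
}
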