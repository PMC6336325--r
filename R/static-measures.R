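#' Early-frame time intervals
#'
#' The five canonical ePIB intervals (seconds post injection) shipped as
#' named constants: 20--40 s, 20--60 s, 20--100 s, 20--130 s and 1--8 min.
#'
#' @return A named list of `interval` objects.
#' @export
epib_intervals <- function() {
  list("20-40s" = interval(20, 40),
       "20-60s" = interval(20, 60),
       "20-100s" = interval(20, 100),
       "20-130s" = interval(20, 130),
       "1-8min" = interval(60, 480))
}

#' @rdname epib_intervals
#' @param t_start_s,t_end_s interval bounds in seconds, `0 <= start < end`.
#' @export
interval <- function(t_start_s, t_end_s) {
  if (!is.numeric(t_start_s) || !is.numeric(t_end_s) ||
      t_start_s < 0 || t_end_s <= t_start_s)
    stop("interval requires 0 <= t_start_s < t_end_s")
  structure(list(t_start_s = as.numeric(t_start_s),
                 t_end_s = as.numeric(t_end_s)), class = "interval")
}

# Pro-rata overlap (seconds) of each frame with an interval.
frame_overlap_s <- function(schedule, iv) {
  pmax(0, pmin(schedule$end_s, iv$t_end_s) - pmax(schedule$start_s, iv$t_start_s))
}

#' Time-weighted average of dynamic frames over an interval
#'
#' Voxelwise weighted mean of the frames, each frame weighted by the duration
#' of its overlap with the interval; frames partially inside contribute
#' pro-rata.
#'
#' @param dyn a `dynamic_image`.
#' @param iv an [interval()] (or `c(start, end)` in seconds).
#' @return A `static_image` (kBq/mL).
#' @export
weighted_frame_average <- function(dyn, iv) {
  stopifnot(inherits(dyn, "dynamic_image"))
  if (!inherits(iv, "interval")) iv <- interval(iv[1L], iv[2L])
  w <- frame_overlap_s(dyn$schedule, iv)
  if (sum(w) <= 0) stop("interval does not overlap the frame schedule")
  d <- dim(dyn$voxels)
  m <- matrix(dyn$voxels, prod(d[1:3]), d[4L])
  static_image(array(as.vector(m %*% w) / sum(w), d[1:3]), dyn$voxel_size_mm)
}

ref_region_mean <- function(img, atlas) {
  if (!identical(as.integer(dim(atlas$labels)), as.integer(dim(img$voxels))))
    stop("atlas grid must match the image")
  mean(img$voxels[reference_mask(atlas)])
}

#' Early-frame (ePIB) image
#'
#' Time-weighted average of the frames in the interval, normalized to the
#' reference-region mean of the same averaged volume (unitless).
#'
#' @inheritParams weighted_frame_average
#' @param atlas a `pet_atlas` providing the reference region.
#' @return A unitless `static_image`.
#' @export
epib_map <- function(dyn, iv, atlas) {
  avg <- weighted_frame_average(dyn, iv)
  ref <- ref_region_mean(avg, atlas)
  if (!is.finite(ref) || ref <= 0)
    stop("reference-region mean must be positive")
  static_image(avg$voxels / ref, avg$voxel_size_mm)
}

#' Standardized uptake value ratio map
#'
#' Divides a static uptake image by its reference-region mean (cerebellar
#' grey matter in the shipped phantom). Any global dose/body-weight scaling
#' cancels in the ratio.
#'
#' @param static a `static_image`.
#' @param atlas a `pet_atlas` providing the reference region.
#' @return A unitless `static_image`.
#' @export
suvr_map <- function(static, atlas) {
  stopifnot(inherits(static, "static_image"))
  ref <- ref_region_mean(static, atlas)
  if (!is.finite(ref) || ref <= 0)
    stop("reference-region mean must be positive")
  static_image(static$voxels / ref, static$voxel_size_mm)
}

#' Group mean difference image
#'
#' Voxelwise mean over subjects of (measure map - SUVR map), the per-group
#' difference image contrasting a flow surrogate with FDG uptake.
#'
#' @param measure_maps list of `static_image` (one per subject).
#' @param suvr_maps matched list of `static_image` on the same grid.
#' @return A `static_image` with the mean difference.
#' @export
mean_difference_image <- function(measure_maps, suvr_maps) {
  n <- length(measure_maps)
  if (n < 1L || length(suvr_maps) != n)
    stop("measure_maps and suvr_maps must be matched non-empty lists")
  d0 <- dim(measure_maps[[1L]]$voxels)
  acc <- array(0, d0)
  for (i in seq_len(n)) {
    m <- measure_maps[[i]]; s <- suvr_maps[[i]]
    if (!identical(dim(m$voxels), d0) || !identical(dim(s$voxels), d0))
      stop("all maps must share one grid")
    acc <- acc + (m$voxels - s$voxels)
  }
  structure(list(voxels = acc / n,
                 voxel_size_mm = measure_maps[[1L]]$voxel_size_mm),
            class = "static_image")
}
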