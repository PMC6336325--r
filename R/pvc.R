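#' Geometric transfer matrix partial-volume correction
#'
#' The geometric transfer matrix (GTM) quantifies cross-contamination between
#' regions under a Gaussian point-spread function: entry `W[i, j]` is the mean
#' over region i of the PSF-smoothed indicator of region j. Observed regional
#' means then satisfy `observed = W %*% true`, and the correction solves this
#' linear system for the true means.
#'
#' @param atlas a `pet_atlas`; all table regions must be non-empty.
#' @param fwhm_mm PSF full width at half maximum in millimetres (>= 0; 0
#'   yields the identity matrix).
#' @return `build_gtm` returns a `gtm` object with the matrix `W`, the region
#'   names, `fwhm_mm` and the matrix condition number.
#' @export
build_gtm <- function(atlas, fwhm_mm) {
  stopifnot(inherits(atlas, "pet_atlas"))
  if (fwhm_mm < 0) stop("fwhm_mm must be nonnegative")
  regions <- atlas$table$label
  masks <- lapply(regions, function(l) region_mask(atlas, l))
  if (any(!vapply(masks, any, logical(1)))) stop("empty region in atlas")
  n <- length(regions)
  W <- matrix(0, n, n, dimnames = list(atlas$table$name, atlas$table$name))
  for (j in seq_len(n)) {
    ind <- static_image(array(as.numeric(masks[[j]]), dim(atlas$labels)),
                        atlas$voxel_size_mm)
    sm <- smooth_gaussian(ind, fwhm_mm)$voxels
    for (i in seq_len(n)) W[i, j] <- mean(sm[masks[[i]]])
  }
  gtm(W, atlas$table$name, fwhm_mm)
}

#' @rdname build_gtm
#' @param W region-by-region transfer matrix with entries in `[0, 1]`.
#' @param regions ordered region names.
#' @export
gtm <- function(W, regions, fwhm_mm) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W) || nrow(W) != length(regions))
    stop("W must be square with one row per region")
  cond <- tryCatch(kappa(W, exact = TRUE), error = function(e) Inf)
  structure(list(W = W, regions = regions, fwhm_mm = fwhm_mm,
                 condition = cond), class = "gtm")
}

#' @export
print.gtm <- function(x, ...) {
  cat(sprintf("<gtm> %d regions, fwhm %.1f mm, condition %.3g\n",
              length(x$regions), x$fwhm_mm, x$condition))
  invisible(x)
}

#' @rdname build_gtm
#' @param observed_means numeric vector of observed regional means, in the
#'   GTM's region order.
#' @param gtm a `gtm` object.
#' @return `gtm_correct` returns a list with the `corrected` named vector and
#'   the `condition` number used as a diagnostic.
#' @export
gtm_correct <- function(observed_means, gtm) {
  stopifnot(inherits(gtm, "gtm"))
  if (length(observed_means) != nrow(gtm$W))
    stop("observed_means length must match the GTM")
  if (!is.finite(gtm$condition) || gtm$condition > 1e8)
    stop("ill-conditioned GTM")
  corrected <- as.numeric(solve(gtm$W, observed_means))
  names(corrected) <- gtm$regions
  list(corrected = corrected, condition = gtm$condition)
}

#' GTM-corrected regional means of a static map
#'
#' Convenience wrapper: observed regional means of `img` over the atlas
#' regions, corrected with a GTM built at the given PSF width.
#'
#' @param img a `static_image`.
#' @param atlas a `pet_atlas`.
#' @param fwhm_mm PSF width in millimetres.
#' @return Named numeric vector of corrected regional means.
#' @export
pvc_regional_means <- function(img, atlas, fwhm_mm) {
  observed <- regional_means(img, atlas)
  g <- build_gtm(atlas, fwhm_mm)
  gtm_correct(observed[g$regions], g)$corrected
}
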