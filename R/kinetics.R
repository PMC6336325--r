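#' SRTM and SRTM2 basis-function kinetic modelling
#'
#' The simplified reference tissue model writes a target-tissue TAC as
#' \deqn{C_T(t) = R_1 C_R(t) + (k_2 - R_1 k_{2a}) [C_R \otimes e^{-k_{2a} t}](t)}
#' with apparent efflux \eqn{k_{2a} = k_2 / (1 + BP_{ND})}. Fitting scans a
#' grid of \eqn{k_{2a}} candidates (theta), solving a linear least-squares
#' problem per candidate (basis-function method). The two-step variant
#' (SRTM2) fixes the reference efflux \eqn{k_2'} globally, leaving a single
#' linear coefficient \eqn{R_1} per candidate.
#'
#' Rate constants are expressed in 1/min; frame timing in seconds is
#' converted at the fit boundary.
#'
#' @name srtm
NULL

# ---- numerical backbone ----------------------------------------------------

# Uniform fine time grid (minutes) covering a schedule, step <= dt_s seconds.
fine_grid_min <- function(schedule, dt_s = 1) {
  t_end <- max(schedule$end_s)
  n <- ceiling(t_end / dt_s)
  seq(0, t_end, length.out = n + 1L) / 60
}

# Linear interpolation of a reference TAC onto the fine grid, anchored at
# C_R(0) = 0 (tracer injection) and held constant beyond the last mid-time.
interp_ref_fine <- function(ref_tac, t_min) {
  xs <- ref_tac$mid_s / 60
  ys <- ref_tac$value
  if (xs[1L] > 0) { xs <- c(0, xs); ys <- c(0, ys) }
  stats::approx(xs, ys, xout = t_min, rule = 2)$y
}

# Causal convolution [f (x) exp(-theta t)](t_i) on a uniform grid via the
# O(N) recursion y_i = phi y_{i-1} + dt/2 (f_i + phi f_{i-1}), phi = e^{-theta dt}.
exp_conv <- function(f, t_min, theta) {
  dt <- t_min[2L] - t_min[1L]
  phi <- exp(-theta * dt)
  n <- length(f)
  x <- c(0, dt / 2 * (f[-1L] + phi * f[-n]))
  as.numeric(stats::filter(x, phi, method = "recursive"))
}

# Trapezoid average of a fine-grid curve over each frame interval.
frame_average <- function(values, t_min, schedule) {
  dt <- t_min[2L] - t_min[1L]
  i0 <- pmin(pmax(round(schedule$start_s / 60 / dt), 0) + 1L, length(values))
  i1 <- pmin(pmax(round(schedule$end_s / 60 / dt), 0) + 1L, length(values))
  vapply(seq_along(i0), function(f) {
    idx <- i0[f]:i1[f]
    v <- values[idx]
    if (length(v) < 2L) return(v[1L])
    (sum(v) - (v[1L] + v[length(v)]) / 2) / (length(v) - 1L)
  }, numeric(1))
}

# Reference values on the schedule: the measured frame values themselves when
# the schedules coincide, otherwise the frame average of the interpolated
# curve. Keeps the R1 regressor free of interpolation error.
ref_on_schedule <- function(ref_tac, schedule, cr_fine, t_min) {
  if (length(ref_tac$value) == n_frames(schedule) &&
      max(abs(ref_tac$mid_s - frame_mid_s(schedule))) <= 1e-6)
    ref_tac$value
  else
    frame_average(cr_fine, t_min, schedule)
}

# Frame-level reference regressor and exponential-convolution basis matrix
# (n_frames x n_theta) shared by forward model and fits.
srtm_basis <- function(ref_tac, schedule, theta_grid, dt_s = 1) {
  t_min <- fine_grid_min(schedule, dt_s)
  cr <- interp_ref_fine(ref_tac, t_min)
  B <- vapply(theta_grid,
              function(th) frame_average(exp_conv(cr, t_min, th), t_min, schedule),
              numeric(n_frames(schedule)))
  list(t_min = t_min, cr_fine = cr,
       r = ref_on_schedule(ref_tac, schedule, cr, t_min),
       B = matrix(B, n_frames(schedule), length(theta_grid)))
}

check_ref_covers <- function(ref_tac, schedule) {
  if (max(ref_tac$mid_s) < max(frame_mid_s(schedule)) - 1e-6 ||
      min(ref_tac$mid_s) > min(frame_mid_s(schedule)) + 1e-6)
    stop("schedule mismatch: reference TAC does not cover the schedule")
}

#' Default apparent-efflux candidate grid
#'
#' 100 log-spaced k2a values spanning 0.006--0.6 1/min, covering plausible
#' PIB kinetics in tissue and background.
#'
#' @param n number of candidates.
#' @param min,max grid range in 1/min.
#' @return Sorted positive numeric vector.
#' @export
default_theta_grid <- function(n = 100, min = 0.006, max = 0.6) {
  exp(seq(log(min), log(max), length.out = n))
}

#' SRTM2 configuration
#'
#' @param k2_prime fixed reference efflux constant in 1/min, or `NULL` to
#'   estimate it from the first-pass SRTM fits.
#' @param theta_grid k2a candidate grid (1/min), sorted and positive.
#' @param bp_threshold BPnd cutoff above which voxels enter the k2' pooling
#'   (default 0.05).
#' @return An object of class `srtm2_config`.
#' @export
srtm2_config <- function(k2_prime = NULL, theta_grid = default_theta_grid(),
                         bp_threshold = 0.05) {
  theta_grid <- as.numeric(theta_grid)
  if (length(theta_grid) < 1L || any(theta_grid <= 0) ||
      is.unsorted(theta_grid, strictly = TRUE))
    stop("theta_grid must be strictly positive and sorted increasing")
  if (!is.null(k2_prime) && k2_prime <= 0) stop("k2_prime must be positive")
  structure(list(k2_prime = k2_prime, theta_grid = theta_grid,
                 bp_threshold = bp_threshold), class = "srtm2_config")
}

# ---- forward model ---------------------------------------------------------

#' Simulate a target TAC under the simplified reference tissue model
#'
#' Evaluates the SRTM operational equation on the acquisition schedule. The
#' convolution term is computed on a fine uniform grid (<= 1 s step, linear
#' interpolation of the reference curve from its frame mid-times) and
#' averaged over each frame interval; the `R1 * C_R` term uses the measured
#' reference frame values directly, so `R1 = 1, BPnd = 0` reproduces the
#' reference TAC exactly.
#'
#' @param ref_tac reference-region [tac()].
#' @param R1 delivery ratio (unitless).
#' @param k2 target efflux constant (1/min), positive.
#' @param BPnd non-displaceable binding potential, > -1.
#' @param schedule output [frame_schedule()]; defaults to the reference TAC's.
#' @param dt_s fine-grid step in seconds (<= 1 recommended).
#' @return A [tac()] with the model target curve.
#' @export
srtm_forward <- function(ref_tac, R1, k2, BPnd,
                         schedule = schedule_of_tac(ref_tac), dt_s = 1) {
  stopifnot(inherits(ref_tac, "tac"), inherits(schedule, "frame_schedule"))
  if (k2 <= 0) stop("k2 must be positive")
  if (BPnd <= -1) stop("BPnd must be greater than -1")
  check_ref_covers(ref_tac, schedule)
  k2a <- k2 / (1 + BPnd)
  t_min <- fine_grid_min(schedule, dt_s)
  cr <- interp_ref_fine(ref_tac, t_min)
  ct <- ref_on_schedule(ref_tac, schedule, cr, t_min) * R1 +
    (k2 - R1 * k2a) * frame_average(exp_conv(cr, t_min, k2a), t_min, schedule)
  tac_from_schedule(schedule, ct)
}

# ---- scalar fits -----------------------------------------------------------

new_srtm_fit <- function(R1, k2, BPnd, k2a, rss, method, clipped = FALSE) {
  structure(list(R1 = R1, k2 = k2, BPnd = BPnd, k2a = k2a, rss = rss,
                 method = method, clipped = clipped), class = "srtm_fit")
}

#' @export
print.srtm_fit <- function(x, ...) {
  cat(sprintf("<srtm_fit:%s> R1=%.4f k2=%.4f BPnd=%.4f k2a=%.4f rss=%.3g\n",
              x$method, x$R1, x$k2, x$BPnd, x$k2a, x$rss))
  invisible(x)
}

# Two-coefficient LSQ y ~ a r + b B(theta); returns coefficients and RSS,
# clipping a (= R1) at zero.
srtm_solve_2 <- function(y, r, b) {
  rr <- sum(r * r); rb <- sum(r * b); bb <- sum(b * b); yy <- sum(y * y)
  ry <- sum(r * y); by <- sum(b * y)
  det <- rr * bb - rb * rb
  if (det <= 0) return(list(a = 0, b = 0, rss = yy, clipped = FALSE))
  a <- (bb * ry - rb * by) / det
  bc <- (rr * by - rb * ry) / det
  clipped <- FALSE
  if (a < 0) {
    a <- 0; bc <- by / bb; clipped <- TRUE
  }
  rss <- yy - 2 * (a * ry + bc * by) +
    a * a * rr + 2 * a * bc * rb + bc * bc * bb
  list(a = a, b = bc, rss = max(rss, 0), clipped = clipped)
}

# One-coefficient LSQ y ~ R1 m for SRTM2, R1 clipped at zero.
srtm2_solve_1 <- function(y, m) {
  mm <- sum(m * m); my <- sum(m * y); yy <- sum(y * y)
  if (mm <= 0) return(list(R1 = 0, rss = yy, clipped = FALSE))
  R1 <- my / mm
  clipped <- R1 < 0
  if (clipped) R1 <- 0
  list(R1 = R1, rss = max(yy - 2 * R1 * my + R1 * R1 * mm, 0),
       clipped = clipped)
}

check_fit_inputs <- function(target_tac, ref_tac) {
  stopifnot(inherits(target_tac, "tac"), inherits(ref_tac, "tac"))
  if (length(target_tac$value) != length(ref_tac$value) ||
      max(abs(target_tac$mid_s - ref_tac$mid_s)) > 1e-6)
    stop("schedule mismatch: target and reference TACs differ")
  if (all(ref_tac$value == 0)) stop("degenerate design: reference TAC is zero")
}

# Golden-section refinement of RSS(theta) on a log-scaled bracket.
refine_theta <- function(rss_fun, lo, hi) {
  f <- function(lt) rss_fun(exp(lt))
  opt <- stats::optimize(f, c(log(lo), log(hi)), tol = 1e-10)
  exp(opt$minimum)
}

#' Fit the simplified reference tissue model to one TAC
#'
#' Basis-function estimation: for each candidate theta (= k2a) the model is
#' linear in `(R1, k2 - R1 k2a)`; the candidate with minimal residual sum of
#' squares wins (ties toward the smallest theta), optionally followed by a
#' local golden-section refinement of theta between its grid neighbours.
#' R1 is constrained nonnegative by clipping.
#'
#' @param target_tac,ref_tac target and reference [tac()] on one schedule.
#' @param theta_grid k2a candidates (1/min).
#' @param refine logical; refine theta continuously around the grid argmin.
#' @param dt_s fine-grid step in seconds.
#' @return An `srtm_fit` with elements `R1`, `k2`, `BPnd`, `k2a`, `rss`.
#' @export
fit_srtm <- function(target_tac, ref_tac, theta_grid = default_theta_grid(),
                     refine = TRUE, dt_s = 1) {
  check_fit_inputs(target_tac, ref_tac)
  if (length(theta_grid) < 1L) stop("theta_grid must be non-empty")
  schedule <- schedule_of_tac(target_tac)
  bas <- srtm_basis(ref_tac, schedule, theta_grid, dt_s)
  y <- target_tac$value
  sols <- lapply(seq_along(theta_grid),
                 function(k) srtm_solve_2(y, bas$r, bas$B[, k]))
  rss <- vapply(sols, `[[`, numeric(1), "rss")
  k <- which.min(rss)
  theta <- theta_grid[k]
  sol <- sols[[k]]
  if (refine && length(theta_grid) > 1L) {
    lo <- theta_grid[max(k - 1L, 1L)]
    hi <- theta_grid[min(k + 1L, length(theta_grid))]
    rss_fun <- function(th) {
      b <- frame_average(exp_conv(bas$cr_fine, bas$t_min, th),
                         bas$t_min, schedule)
      srtm_solve_2(y, bas$r, b)$rss
    }
    theta <- refine_theta(rss_fun, lo, hi)
    b <- frame_average(exp_conv(bas$cr_fine, bas$t_min, theta),
                       bas$t_min, schedule)
    cand <- srtm_solve_2(y, bas$r, b)
    if (cand$rss <= sol$rss) sol <- cand else theta <- theta_grid[k]
  }
  k2 <- sol$a * theta + sol$b
  new_srtm_fit(R1 = sol$a, k2 = k2, BPnd = k2 / theta - 1, k2a = theta,
               rss = sol$rss, method = "srtm", clipped = sol$clipped)
}

#' Fit SRTM2 (fixed reference efflux) to one TAC
#'
#' With `k2' = k2 / R1` fixed, the SRTM operational equation collapses to
#' `C_T = R1 [C_R + (k2' - theta) (C_R (x) e^{-theta t})]`, a single linear
#' coefficient per theta candidate. `BPnd = R1 k2' / theta - 1` by identity.
#'
#' @inheritParams fit_srtm
#' @param k2_prime fixed reference efflux constant (1/min), positive.
#' @return An `srtm_fit`.
#' @export
fit_srtm2 <- function(target_tac, ref_tac, k2_prime,
                      theta_grid = default_theta_grid(), refine = TRUE,
                      dt_s = 1) {
  check_fit_inputs(target_tac, ref_tac)
  if (!is.numeric(k2_prime) || length(k2_prime) != 1L || k2_prime <= 0)
    stop("k2_prime must be a single positive number")
  schedule <- schedule_of_tac(target_tac)
  bas <- srtm_basis(ref_tac, schedule, theta_grid, dt_s)
  y <- target_tac$value
  sols <- lapply(seq_along(theta_grid), function(k) {
    m <- bas$r + (k2_prime - theta_grid[k]) * bas$B[, k]
    srtm2_solve_1(y, m)
  })
  rss <- vapply(sols, `[[`, numeric(1), "rss")
  k <- which.min(rss)
  theta <- theta_grid[k]
  sol <- sols[[k]]
  if (refine && length(theta_grid) > 1L) {
    lo <- theta_grid[max(k - 1L, 1L)]
    hi <- theta_grid[min(k + 1L, length(theta_grid))]
    rss_fun <- function(th) {
      b <- frame_average(exp_conv(bas$cr_fine, bas$t_min, th),
                         bas$t_min, schedule)
      srtm2_solve_1(y, bas$r + (k2_prime - th) * b)$rss
    }
    theta <- refine_theta(rss_fun, lo, hi)
    b <- frame_average(exp_conv(bas$cr_fine, bas$t_min, theta),
                       bas$t_min, schedule)
    cand <- srtm2_solve_1(y, bas$r + (k2_prime - theta) * b)
    if (cand$rss <= sol$rss) sol <- cand else theta <- theta_grid[k]
  }
  new_srtm_fit(R1 = sol$R1, k2 = sol$R1 * k2_prime,
               BPnd = sol$R1 * k2_prime / theta - 1, k2a = theta,
               rss = sol$rss, method = "srtm2", clipped = sol$clipped)
}

# ---- k2' pooling -----------------------------------------------------------

#' Pooled reference efflux constant from first-pass SRTM fits
#'
#' Each voxel proposes `k2' = k2 / R1` (the SRTM identifiability relation);
#' the global estimate is the median over voxels whose BPnd exceeds the
#' threshold, where k2' is identifiable.
#'
#' @param first_pass a list of `srtm_fit` objects, or a list/data.frame with
#'   numeric elements `R1`, `k2`, `BPnd` (voxelwise vectors).
#' @param bp_threshold BPnd cutoff (default 0.05).
#' @return The pooled k2' scalar (1/min).
#' @export
estimate_k2prime <- function(first_pass, bp_threshold = 0.05) {
  if (is.list(first_pass) && length(first_pass) > 0 &&
      inherits(first_pass[[1L]], "srtm_fit")) {
    R1 <- vapply(first_pass, `[[`, numeric(1), "R1")
    k2 <- vapply(first_pass, `[[`, numeric(1), "k2")
    BPnd <- vapply(first_pass, `[[`, numeric(1), "BPnd")
  } else {
    R1 <- as.numeric(first_pass$R1)
    k2 <- as.numeric(first_pass$k2)
    BPnd <- as.numeric(first_pass$BPnd)
  }
  ok <- is.finite(R1) & is.finite(k2) & is.finite(BPnd) &
    R1 > 0 & BPnd > bp_threshold
  if (!any(ok)) stop("k2prime pool empty")
  stats::median(k2[ok] / R1[ok])
}

# ---- voxelwise parametric mapping ------------------------------------------

# Vectorized first-pass SRTM over a frames x voxels matrix. Pure grid search
# (no per-voxel refinement); R1 clipped at zero.
fit_srtm_matrix <- function(Y, r, B, theta_grid) {
  rr <- sum(r * r)
  rty <- drop(crossprod(r, Y))                    # 1 x V
  bty <- crossprod(B, Y)                          # K x V
  yty <- colSums(Y * Y)
  V <- ncol(Y)
  best <- list(rss = rep(Inf, V), a = numeric(V), b = numeric(V),
               theta = numeric(V), clipped = logical(V))
  for (k in seq_along(theta_grid)) {
    b <- B[, k]
    rb <- sum(r * b); bb <- sum(b * b)
    det <- rr * bb - rb * rb
    if (det <= 0) next
    byk <- bty[k, ]
    a <- (bb * rty - rb * byk) / det
    bc <- (rr * byk - rb * rty) / det
    neg <- a < 0
    if (any(neg)) {
      a[neg] <- 0
      bc[neg] <- byk[neg] / bb
    }
    rss <- yty - 2 * (a * rty + bc * byk) +
      a * a * rr + 2 * a * bc * rb + bc * bc * bb
    upd <- rss < best$rss
    if (any(upd)) {
      best$rss[upd] <- rss[upd]; best$a[upd] <- a[upd]
      best$b[upd] <- bc[upd]; best$theta[upd] <- theta_grid[k]
      best$clipped[upd] <- neg[upd]
    }
  }
  k2 <- best$a * best$theta + best$b
  list(R1 = best$a, k2 = k2, k2a = best$theta,
       BPnd = k2 / best$theta - 1, rss = pmax(best$rss, 0),
       clipped = best$clipped)
}

# Vectorized SRTM2 with fixed k2'.
fit_srtm2_matrix <- function(Y, r, B, theta_grid, k2_prime) {
  rr <- sum(r * r)
  rty <- drop(crossprod(r, Y))
  bty <- crossprod(B, Y)
  yty <- colSums(Y * Y)
  V <- ncol(Y)
  best <- list(rss = rep(Inf, V), R1 = numeric(V), theta = numeric(V),
               clipped = logical(V))
  for (k in seq_along(theta_grid)) {
    w <- k2_prime - theta_grid[k]
    b <- B[, k]
    mm <- rr + 2 * w * sum(r * b) + w * w * sum(b * b)
    if (mm <= 0) next
    my <- rty + w * bty[k, ]
    R1 <- my / mm
    neg <- R1 < 0
    if (any(neg)) R1[neg] <- 0
    rss <- yty - 2 * R1 * my + R1 * R1 * mm
    upd <- rss < best$rss
    if (any(upd)) {
      best$rss[upd] <- rss[upd]; best$R1[upd] <- R1[upd]
      best$theta[upd] <- theta_grid[k]; best$clipped[upd] <- neg[upd]
    }
  }
  list(R1 = best$R1, k2 = best$R1 * k2_prime, k2a = best$theta,
       BPnd = best$R1 * k2_prime / best$theta - 1,
       rss = pmax(best$rss, 0), clipped = best$clipped)
}

#' Voxelwise R1 parametric mapping (two-pass SRTM / SRTM2)
#'
#' Runs the full two-pass procedure: (1) voxelwise basis-function SRTM with
#' the reference TAC taken from the atlas reference region; (2) pooling of
#' the reference efflux constant k2' as the median of `k2 / R1` over voxels
#' with BPnd above the configured threshold; (3) voxelwise SRTM2 with k2'
#' fixed, yielding the final R1, BPnd and k2a maps. Voxels whose TAC is
#' identically zero are skipped (maps set to `NaN`, excluded from the fit
#' mask).
#'
#' @param dyn a brain-masked `dynamic_image`.
#' @param atlas a `pet_atlas` whose reference region is non-empty.
#' @param cfg an [srtm2_config()]; if `cfg$k2_prime` is `NULL` it is
#'   estimated from the first pass.
#' @param dt_s fine-grid step in seconds for the convolution basis.
#' @return An object of class `kinetic_maps` with `static_image` elements
#'   `R1_map`, `BPnd_map`, `k2a_map`, the scalar `k2_prime`, the logical
#'   `fit_mask`, and diagnostics (`n_clipped`, first-pass summaries).
#' @export
parametric_r1 <- function(dyn, atlas, cfg = srtm2_config(), dt_s = 1) {
  stopifnot(inherits(dyn, "dynamic_image"), inherits(atlas, "pet_atlas"),
            inherits(cfg, "srtm2_config"))
  if (!identical(as.integer(dim(atlas$labels)), as.integer(spatial_dim(dyn))))
    stop("atlas grid must match the dynamic image")
  ref <- reference_mask(atlas)
  if (!any(ref)) stop("empty region")
  ref_tac <- extract_tac(dyn, ref)
  d <- dim(dyn$voxels)
  M <- matrix(dyn$voxels, prod(d[1:3]), d[4L])
  fit_vox <- rowSums(abs(M)) > 0
  if (!is.null(dyn$brain_mask)) fit_vox <- fit_vox & as.vector(dyn$brain_mask)
  if (!any(fit_vox)) stop("no voxels to fit")
  Y <- t(M[fit_vox, , drop = FALSE])
  bas <- srtm_basis(ref_tac, dyn$schedule, cfg$theta_grid, dt_s)

  pass1 <- fit_srtm_matrix(Y, bas$r, bas$B, cfg$theta_grid)
  k2p <- cfg$k2_prime
  if (is.null(k2p)) k2p <- estimate_k2prime(pass1, cfg$bp_threshold)
  pass2 <- fit_srtm2_matrix(Y, bas$r, bas$B, cfg$theta_grid, k2p)

  # static_image() requires all-finite values; parameter maps are NaN outside
  # the fit mask, so build them directly.
  mk <- function(v) {
    m <- array(NaN, d[1:3])
    m[fit_vox] <- v
    structure(list(voxels = m, voxel_size_mm = dyn$voxel_size_mm),
              class = "static_image")
  }
  structure(list(
    R1_map = mk(pass2$R1), BPnd_map = mk(pass2$BPnd), k2a_map = mk(pass2$k2a),
    k2_prime = k2p,
    fit_mask = array(fit_vox, d[1:3]),
    n_clipped = sum(pass2$clipped),
    pass1 = list(R1 = pass1$R1, k2 = pass1$k2, BPnd = pass1$BPnd),
    config = cfg), class = "kinetic_maps")
}

#' @export
print.kinetic_maps <- function(x, ...) {
  cat(sprintf("<kinetic_maps> %d fitted voxels, k2' = %.4f /min, %d clipped\n",
              sum(x$fit_mask), x$k2_prime, x$n_clipped))
  invisible(x)
}

#' Write kinetic maps to disk
#'
#' Writes R1, BPnd and k2a volumes as NIfTI plus a JSON file holding the
#' pooled k2', the configuration and fit diagnostics.
#'
#' @param maps a `kinetic_maps` object.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_kinetic_maps <- function(maps, dir, prefix = "subject") {
  stopifnot(inherits(maps, "kinetic_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(dir, paste0(prefix, "_", c("R1", "BPnd", "k2a"), ".nii.gz"))
  write_nifti_array(maps$R1_map$voxels, maps$R1_map$voxel_size_mm, files[1L])
  write_nifti_array(maps$BPnd_map$voxels, maps$BPnd_map$voxel_size_mm, files[2L])
  write_nifti_array(maps$k2a_map$voxels, maps$k2a_map$voxel_size_mm, files[3L])
  meta <- file.path(dir, paste0(prefix, "_kinetics.json"))
  jsonlite::write_json(list(
    k2_prime = maps$k2_prime, n_fitted = sum(maps$fit_mask),
    n_clipped = maps$n_clipped,
    theta_grid_range = range(maps$config$theta_grid),
    bp_threshold = maps$config$bp_threshold),
    meta, auto_unbox = TRUE, digits = NA)
  invisible(c(files, meta))
}
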