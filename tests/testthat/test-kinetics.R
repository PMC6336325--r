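test_that("srtm_forward reduces to the reference when R1 = 1, BPnd = 0", {
  out <- srtm_forward(ref23, R1 = 1, k2 = 0.2, BPnd = 0, sched23)
  expect_lt(max(abs(out$value - ref23$value)), 1e-8)
})

test_that("srtm_forward reaches the (1 + BPnd) steady state for constant input", {
  cr <- tac_from_schedule(sched23, rep(8, n_frames(sched23)))
  R1 <- 0.7; k2 <- 0.3; BPnd <- 0.5
  k2a <- k2 / (1 + BPnd)                      # 0.2 /min
  out <- srtm_forward(cr, R1, k2, BPnd, sched23)
  late <- frame_mid_s(sched23) / 60 > 5 / k2a
  expect_true(any(late))
  ratio <- out$value[late] / 8
  expect_lt(max(abs(ratio / (1 + BPnd) - 1)), 0.01)
})

test_that("srtm_forward matches an FFT convolution oracle on a gamma input", {
  mid <- frame_mid_s(sched23) / 60
  gamma_cr <- tac_from_schedule(sched23, 30 * mid * exp(-mid / 4))
  R1 <- 0.85; k2 <- 0.15; BPnd <- 0.5
  k2a <- k2 / (1 + BPnd)
  got <- srtm_forward(gamma_cr, R1, k2, BPnd, sched23)$value

  # independent oracle: rectangle-rule FFT convolution on a 0.1 s grid
  dt <- 0.1 / 60
  tt <- seq(0, max(sched23$end_s) / 60, by = dt)
  cr_fine <- approx(c(0, mid), c(0, gamma_cr$value), xout = tt, rule = 2)$y
  conv <- stats::convolve(cr_fine, rev(exp(-k2a * tt)), type = "open")
  conv <- conv[seq_along(tt)] * dt
  favg <- function(v) vapply(seq_len(n_frames(sched23)), function(f) {
    sel <- tt * 60 >= sched23$start_s[f] & tt * 60 <= sched23$end_s[f]
    mean(v[sel])
  }, numeric(1))
  oracle <- R1 * gamma_cr$value + (k2 - R1 * k2a) * favg(conv)
  expect_lt(max(abs(got - oracle) / max(abs(oracle))), 0.005)
})

test_that("srtm_forward validates inputs", {
  expect_error(srtm_forward(ref23, 1, -0.1, 0, sched23), "k2")
  expect_error(srtm_forward(ref23, 1, 0.1, -1.5, sched23), "BPnd")
  short <- frame_schedule(0, 10)
  short_tac <- tac_from_schedule(short, 1)
  expect_error(srtm_forward(short_tac, 1, 0.1, 0, sched23), "mismatch")
})

test_that("fit_srtm recovers itself and noiseless forward parameters", {
  f0 <- fit_srtm(ref23, ref23)
  expect_equal(f0$R1, 1, tolerance = 1e-6)
  expect_equal(f0$BPnd, 0, tolerance = 1e-6)
  expect_lt(f0$rss, 1e-10 * sum(ref23$value^2))

  truth <- list(R1 = 0.85, k2 = 0.15, BPnd = 0.5)
  y <- srtm_forward(ref23, truth$R1, truth$k2, truth$BPnd, sched23)
  f <- fit_srtm(y, ref23)
  expect_lt(abs(f$R1 - truth$R1) / truth$R1, 0.01)
  expect_lt(abs(f$k2 - truth$k2) / truth$k2, 0.01)
  expect_lt(abs(f$BPnd - truth$BPnd) / truth$BPnd, 0.01)
  expect_equal(f$BPnd, f$k2 / f$k2a - 1, tolerance = 1e-12)
})

test_that("fit_srtm median R1 is accurate under 2% peak noise", {
  truth <- list(R1 = 0.9, k2 = 0.117, BPnd = 0.8)
  y0 <- srtm_forward(ref23, truth$R1, truth$k2, truth$BPnd, sched23)$value
  sigma <- 0.02 * max(y0)
  set.seed(42)
  Y <- matrix(y0, length(y0), 200) + matrix(rnorm(200 * length(y0), 0, sigma),
                                            length(y0), 200)
  grid <- default_theta_grid()
  bas <- petflow:::srtm_basis(ref23, sched23, grid)
  fits <- petflow:::fit_srtm_matrix(Y, bas$r, bas$B, grid)
  expect_lt(abs(median(fits$R1) - truth$R1) / truth$R1, 0.02)
})

test_that("fit_srtm errors on degenerate input", {
  zero <- tac_from_schedule(sched23, rep(0, n_frames(sched23)))
  y <- srtm_forward(ref23, 1, 0.1, 0, sched23)
  expect_error(fit_srtm(y, zero), "degenerate")
  short <- tac_from_schedule(frame_schedule(0, 10), 1)
  expect_error(fit_srtm(short, ref23), "mismatch")
})

test_that("estimated R1 is invariant to common rescaling of both TACs", {
  y <- srtm_forward(ref23, 0.8, 0.12, 1.2, sched23)
  f1 <- fit_srtm(y, ref23)
  y2 <- tac_from_schedule(sched23, y$value * 37.5)
  r2 <- tac_from_schedule(sched23, ref23$value * 37.5)
  f2 <- fit_srtm(y2, r2)
  expect_equal(f2$R1, f1$R1, tolerance = 1e-6)
  expect_equal(f2$BPnd, f1$BPnd, tolerance = 1e-6)
})

test_that("grid refinement never worsens the SRTM2 residual", {
  y <- srtm_forward(ref23, 0.95, 0.14, 0.7, sched23)
  coarse <- default_theta_grid(25)
  fine <- sort(c(coarse, default_theta_grid(60, 0.01, 0.5)))
  f_coarse <- fit_srtm2(y, ref23, 0.13, coarse, refine = FALSE)
  f_fine <- fit_srtm2(y, ref23, 0.13, fine, refine = FALSE)
  expect_lte(f_fine$rss, f_coarse$rss + 1e-12)
})

test_that("fit_srtm2 recovers parameters and satisfies the BPnd identity", {
  f0 <- fit_srtm2(ref23, ref23, k2_prime = 0.13)
  expect_equal(f0$R1, 1, tolerance = 1e-6)
  expect_equal(f0$BPnd, 0, tolerance = 1e-6)

  y <- srtm_forward(ref23, 0.9, 0.9 * 0.13, 1.2, sched23)
  f <- fit_srtm2(y, ref23, k2_prime = 0.13)
  expect_lt(abs(f$R1 - 0.9) / 0.9, 0.01)
  expect_lt(abs(f$BPnd - 1.2) / 1.2, 0.01)
  expect_equal(f$BPnd, f$R1 * 0.13 / f$k2a - 1, tolerance = 1e-12)
  expect_error(fit_srtm2(y, ref23, k2_prime = -1), "positive")
})

test_that("estimate_k2prime pools k2/R1 medians above the BPnd threshold", {
  mk <- function(R1, k2, BPnd)
    structure(list(R1 = R1, k2 = k2, BPnd = BPnd, k2a = k2 / (1 + BPnd),
                   rss = 0, method = "srtm", clipped = FALSE),
              class = "srtm_fit")
  fits <- replicate(5, mk(1, 0.12, 1), simplify = FALSE)
  expect_equal(estimate_k2prime(fits), 0.12)

  # sub-threshold voxels carry absurd candidates but are excluded
  fits2 <- c(fits, list(mk(0.01, 9, 0.04), mk(0.02, 7, 0.05)))
  expect_equal(estimate_k2prime(fits2), 0.12)

  set.seed(8)
  R1 <- runif(50, 0.5, 1.2); k2 <- runif(50, 0.05, 0.3)
  BPnd <- runif(50, -0.2, 2)
  pool <- list(R1 = R1, k2 = k2, BPnd = BPnd)
  keep <- BPnd > 0.05
  cand <- sort((k2 / R1)[keep])
  m <- length(cand)
  oracle <- if (m %% 2 == 1) cand[(m + 1) / 2] else
    mean(cand[m / 2 + 0:1])
  expect_identical(estimate_k2prime(pool), oracle)

  expect_error(estimate_k2prime(list(R1 = 1, k2 = 0.1, BPnd = 0.01)),
               "pool empty")
})

test_that("parametric_r1 is self-consistent and deterministic", {
  fix <- noiseless_subject()
  dyn <- apply_brain_mask(fix$subject$dynamic_pib, brain_mask(fix$atlas))
  km <- parametric_r1(dyn, fix$atlas)
  truth <- fix$subject$truth$R1_map$voxels
  fm <- km$fit_mask
  expect_lt(max(abs(km$R1_map$voxels[fm] - truth[fm]) / truth[fm]), 0.02)
  expect_lt(abs(km$k2_prime - fix$spec$k2_prime_true) /
              fix$spec$k2_prime_true, 0.05)

  refv <- reference_mask(fix$atlas)
  expect_lt(max(abs(km$R1_map$voxels[refv] - 1)), 0.02)

  km2 <- parametric_r1(dyn, fix$atlas)
  expect_identical(km$R1_map$voxels, km2$R1_map$voxels)
  expect_identical(km$k2_prime, km2$k2_prime)

  expect_true(all(is.nan(km$R1_map$voxels[!fm])))
})
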