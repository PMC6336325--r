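test_that("phantom atlas partitions the brain with all named regions", {
  atl <- make_phantom_atlas(c(24, 24, 24), 4, 4)
  counts <- table(atl$labels[atl$labels > 0])
  expect_equal(sort(as.integer(names(counts))), atl$table$label)
  expect_true(all(counts > 0))
  expect_true("cerebellum_gm" %in% atl$table$name)
  expect_gte(sum(atl$table$tissue_class == "cortical"), 2)
  expect_gte(sum(atl$table$tissue_class == "subcortical"), 1)
  expect_equal(atl$table$name[atl$table$is_reference], "cerebellum_gm")

  atl2 <- make_phantom_atlas(c(24, 24, 24), 4, 4)
  expect_identical(atl$labels, atl2$labels)

  atl16 <- make_phantom_atlas(c(16, 16, 16), 3, 4)
  expect_true(all(table(atl16$labels[atl16$labels > 0]) > 0))

  expect_error(make_phantom_atlas(c(12, 16, 16)), "too small")
  expect_error(make_phantom_atlas(c(16, 16, 16), 2), "at least 3")
})

test_that("reference TAC has injection-like shape and is deterministic", {
  fine <- attr(ref23, "fine")
  expect_lt(ref23$value[1], 0.1 * max(ref23$value))
  v <- fine$value
  n_max <- sum(diff(sign(diff(v))) == -2)
  expect_equal(n_max, 1L)
  expect_true(all(v >= 0) && v[1] == 0)

  again <- simulate_reference_tac(sched23, seed = 999)
  expect_identical(again$value, ref23$value)
})

test_that("reference TAC matches a one-tissue ODE oracle", {
  isp <- feng_input_spec()
  fine <- attr(simulate_reference_tac(sched23, isp), "fine")
  cp <- function(t) isp$scale *
    ((isp$A1 * t - isp$A2 - isp$A3) * exp(-isp$lambda1 * t) +
       isp$A2 * exp(-isp$lambda2 * t) + isp$A3 * exp(-isp$lambda3 * t))
  ode <- deSolve::ode(c(C = 0), fine$t_min,
                      function(t, y, p) list(isp$K1_ref * cp(t) -
                                               isp$k2_ref * y[1]),
                      NULL, rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(ode[, 2] - fine$value)) / max(fine$value), 0.005)
})

test_that("noiseless subjects reproduce the forward model exactly", {
  fix <- noiseless_subject()
  atl <- fix$atlas; sub <- fix$subject
  ref_tac <- simulate_reference_tac(sched23, fix$spec$input_spec)
  reg <- fix$spec$regions
  i <- which(reg$name == "putamen")
  expected <- srtm_forward(ref_tac, reg$R1[i],
                           reg$R1[i] * fix$spec$k2_prime_true,
                           reg$BPnd[i], sched23)$value
  vox <- which(atl$labels == atl$table$label[atl$table$name == "putamen"],
               arr.ind = TRUE)[1, ]
  got <- sub$dynamic_pib$voxels[vox[1], vox[2], vox[3], ]
  expect_equal(got, expected, tolerance = 1e-12)

  # regional means of the true R1 volume equal the configured truths
  rm <- regional_means(sub$truth$R1_map, atl)
  expect_equal(unname(rm[reg$name]), reg$R1, tolerance = 1e-12)
})

test_that("subjects are reproducible from their seed", {
  atl <- make_phantom_atlas(c(16, 16, 16), 3, 4)
  spec <- default_kinetic_spec(atl, "PIB+")
  s1 <- simulate_subject(atl, spec, seed = 31)
  s2 <- simulate_subject(atl, spec, seed = 31)
  s3 <- simulate_subject(atl, spec, seed = 32)
  expect_identical(s1$dynamic_pib$voxels, s2$dynamic_pib$voxels)
  expect_identical(s1$static_fdg$voxels, s2$static_fdg$voxels)
  expect_false(identical(s1$dynamic_pib$voxels, s3$dynamic_pib$voxels))
})

test_that("kinetic specs enforce the reference-region convention", {
  regs <- data.frame(name = c("cerebellum_gm", "ctx"),
                     R1 = c(1, 0.9), BPnd = c(0, 1))
  expect_s3_class(region_kinetic_spec(regs), "region_kinetic_spec")
  bad <- regs; bad$R1[1] <- 0.9
  expect_error(region_kinetic_spec(bad), "reference region must have R1 = 1")
  neg <- regs; neg$BPnd[2] <- -0.2
  expect_error(region_kinetic_spec(neg), "nonnegative")
})

test_that("cohorts have requested sizes, ordered BPnd, and reproduce", {
  atl <- make_phantom_atlas(c(16, 16, 16), 3, 4)
  for (seed in c(1, 2, 3)) {
    co <- simulate_cohort(4, 3, seed = seed, atlas = atl, noise_scale = 0.02)
    g <- vapply(co$subjects, `[[`, character(1), "group")
    expect_equal(sum(g == "PIB+"), 4)
    expect_equal(sum(g == "PIB-"), 3)
    cort <- atl$table$name[atl$table$tissue_class == "cortical"]
    mean_bp <- function(s)
      mean(s$truth$regions$BPnd[s$truth$regions$name %in% cort])
    bp_pos <- mean(vapply(co$subjects[g == "PIB+"], mean_bp, numeric(1)))
    bp_neg <- mean(vapply(co$subjects[g == "PIB-"], mean_bp, numeric(1)))
    expect_gt(bp_pos, bp_neg)
  }
  c1 <- simulate_cohort(2, 2, seed = 5, atlas = atl)
  c2 <- simulate_cohort(2, 2, seed = 5, atlas = atl)
  expect_identical(c1$subjects[[3]]$dynamic_pib$voxels,
                   c2$subjects[[3]]$dynamic_pib$voxels)
  expect_error(simulate_cohort(0, 3, atlas = atl), "at least 1")
})

test_that("cohort directories round-trip through disk", {
  dir <- withr::local_tempdir()
  atl <- make_phantom_atlas(c(16, 16, 16), 3, 4)
  co <- simulate_cohort(2, 2, seed = 8, atlas = atl)
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(length(back$subjects), 4)
  expect_equal(vapply(back$subjects, `[[`, character(1), "group"),
               vapply(co$subjects, `[[`, character(1), "group"))
  expect_equal(back$subjects[[1]]$dynamic_pib$voxels,
               co$subjects[[1]]$dynamic_pib$voxels, tolerance = 0)
  expect_equal(back$subjects[[2]]$truth$regions$R1,
               co$subjects[[2]]$truth$regions$R1, tolerance = 1e-6)
})
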