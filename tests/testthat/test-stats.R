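test_that("build_regional_table averages maps over atlas regions", {
  atl <- slab_atlas(c(4, 4, 4), split = 2)
  mk <- function(v) static_image(v, 2)
  const <- mk(array(1, c(4, 4, 4)))
  tab <- build_regional_table(
    list(list(subject = "s1", group = "G", measure = "M", map = const)), atl)
  expect_equal(tab$value, c(1, 1))

  set.seed(9)
  r <- array(runif(64), c(4, 4, 4))
  norm <- suvr_map(mk(r), atl)
  tab2 <- build_regional_table(
    list(list(subject = "s1", group = "G", measure = "SUVR", map = norm)), atl)
  expect_equal(tab2$value[tab2$region == "A"], 1, tolerance = 1e-12)
  expect_equal(tab2$value[tab2$region == "B"],
               mean(norm$voxels[3:4, , ]), tolerance = 1e-12)

  expect_error(build_regional_table(
    list(list(subject = "s1", group = "G", measure = "M", map = NULL)), atl),
    "missing map")
})

test_that("fit_regression matches the closed-form normal equations", {
  x <- c(1, 2, 3, 4)
  f <- fit_regression(x, 2 * x + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)

  fc <- fit_regression(x, rep(5, 4))
  expect_equal(fc$slope, 0)
  expect_equal(fc$r_squared, 0)

  set.seed(10)
  x <- rnorm(20); y <- 0.4 * x + rnorm(20, 0, 0.3)
  f2 <- fit_regression(x, y)
  sxx <- sum((x - mean(x))^2)
  slope_o <- sum((x - mean(x)) * (y - mean(y))) / sxx
  int_o <- mean(y) - slope_o * mean(x)
  r_o <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sxx * sum((y - mean(y))^2))
  expect_equal(f2$slope, slope_o, tolerance = 1e-10)
  expect_equal(f2$intercept, int_o, tolerance = 1e-10)
  expect_equal(f2$pearson_r, r_o, tolerance = 1e-10)
  expect_equal(f2$r_squared, r_o^2, tolerance = 1e-10)

  expect_error(fit_regression(rep(1, 5), rnorm(5)), "constant x")
  expect_error(fit_regression(1:2, 1:2), "at least 3")
})

test_that("fit_regression is equivariant under scaling of y", {
  set.seed(12)
  x <- rnorm(15); y <- 1.5 * x + rnorm(15, 0, 0.2)
  f1 <- fit_regression(x, y)
  f2 <- fit_regression(x, 7 * y)
  expect_equal(f2$slope, 7 * f1$slope, tolerance = 1e-10)
  expect_equal(f2$intercept, 7 * f1$intercept, tolerance = 1e-10)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-12)
})

test_that("bland_altman computes bias, limits and trend", {
  refv <- c(1, 2, 3)
  b0 <- bland_altman(refv, refv)
  expect_equal(b0$bias, 0)
  expect_equal(c(b0$loa_low, b0$loa_high), c(0, 0))

  # hand-computed: differences (-1, 1, -1, 1)
  refv <- c(1, 1, 1, 1)
  tst <- c(0, 2, 0, 2)
  b <- bland_altman(refv, tst)
  expect_equal(b$bias, 0)
  expect_equal(b$sd_diff, sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(b$loa_high, 1.96 * sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(b$loa_low, -1.96 * sqrt(4 / 3), tolerance = 1e-12)

  # bias identically equals the difference of means
  set.seed(13)
  a <- rnorm(30); c2 <- rnorm(30)
  bb <- bland_altman(a, c2)
  expect_equal(bb$bias, mean(c2) - mean(a), tolerance = 1e-14)
  # trend regresses differences on the reference
  tr <- fit_regression(a, c2 - a)
  expect_equal(bb$trend$slope, tr$slope, tolerance = 1e-12)

  expect_error(bland_altman(1:4, 1:5), "length mismatch")
})

test_that("group t-tests with FDR behave across regions", {
  mk_tab <- function(vals_a, vals_b, regions = c("r1", "r2", "r3")) {
    do.call(rbind, lapply(seq_along(regions), function(i) {
      rbind(data.frame(subject = paste0("a", 1:4), group = "G1",
                       region = regions[i], measure = "M",
                       value = vals_a[[i]]),
            data.frame(subject = paste0("b", 1:4), group = "G2",
                       region = regions[i], measure = "M",
                       value = vals_b[[i]]))
    }))
  }
  set.seed(14)
  base <- lapply(1:3, function(i) rnorm(4))
  same <- group_ttests_fdr(mk_tab(base, base), "M")
  expect_equal(same$t, rep(0, 3))
  expect_equal(same$p, rep(1, 3))
  expect_equal(same$p_fdr, rep(1, 3))

  shifted <- base
  shifted[[2]] <- base[[2]] + 10 * sd(base[[2]])
  res <- group_ttests_fdr(mk_tab(shifted, base), "M",
                          groups = c("G1", "G2"))
  expect_lt(res$p_fdr[res$region == "r2"], 0.05)
  expect_gt(res$t[res$region == "r2"], 0)

  # adjusted p-values match a brute-force Benjamini-Hochberg step-up
  bh_oracle <- function(p) {
    n <- length(p); o <- order(p); adj <- numeric(n)
    prev <- 1
    for (i in n:1) {
      prev <- min(prev, p[o[i]] * n / i)
      adj[o[i]] <- prev
    }
    adj
  }
  expect_equal(res$p_fdr, bh_oracle(res$p), tolerance = 1e-15)
  expect_equal(bh_oracle(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.5), tolerance = 1e-15)
  expect_true(all(diff(sort(res$p_fdr)) >= 0) && all(res$p_fdr <= 1))

  one_group <- mk_tab(base, base)
  one_group$group <- "G1"
  expect_error(group_ttests_fdr(one_group, "M"), "two groups")
  tiny <- mk_tab(base, base)
  tiny <- tiny[!(tiny$group == "G2" & tiny$subject != "b1"), ]
  expect_error(group_ttests_fdr(tiny, "M"), "at least 2")
})
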