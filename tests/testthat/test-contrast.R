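test_that("contrast formula behaves as the normalized difference", {
  expect_equal(compute_contrast(100, 100), 0)
  expect_equal(compute_contrast(100, 80), 20 / 90, tolerance = 1e-12)
  expect_equal(compute_contrast(80, 100), -compute_contrast(100, 80))
  expect_equal(compute_contrast(200, 160), compute_contrast(100, 80))
  c_ex <- compute_contrast(c(10, 1e6), c(1e-6, 1))
  expect_true(all(c_ex > -2 & c_ex < 2))
  expect_error(compute_contrast(-1, 5), "positive")
})

test_that("boundary sampling uses 1 mm WM depth and 35% cortical depth", {
  # custom column phantom: thickness 10 slab, intensity = z index so the
  # sampled voxel is read off directly
  g <- phantom_geometry(shape = c(24, 24, 40), margin_vox = 4,
                        slab_thickness_vox = 10, nucleus_radius_vox = 2)
  lab <- phantom_labels(g)
  img <- array(rep(seq_len(40), each = 24 * 24), c(24, 24, 40))
  tab <- sample_boundary(img, lab, g)
  bz <- g$border_wm_z
  # WM: first voxel below the border (its center is the nearest to 1 mm)
  expect_true(all(tab$wm_int == bz))
  # GM: round-half-up(0.35 * 10) = 4th voxel above the border
  expect_true(all(tab$gm_int == bz + 4))
  expect_equal(nrow(tab), (g$xr[2] - g$xr[1] + 1) * (g$yr[2] - g$yr[1] + 1))
  expect_equal(attr(tab, "qc")$n_skipped, 0L)
})

test_that("homogeneous tissues give one identical closed-form contrast", {
  ph <- build_phantom(small_geometry())
  img <- synthesize(ph$maps, mprage_protocol(), "r1")
  tab <- sample_boundary(img, ph$labels, ph$geometry)
  # two tissue regimes only (cortical and sensorimotor-like slab halves)
  expect_lte(length(unique(round(tab$contrast, 12))), 2)
  wm_f <- signal_terms(1.05, mprage_protocol())$f_r1
  gm_f <- signal_terms(0.72, mprage_protocol())$f_r1
  expect_true(any(abs(tab$contrast - compute_contrast(wm_f, gm_f)) < 1e-12))
})

test_that("sites without the required WM depth are skipped and counted", {
  g <- phantom_geometry(shape = c(24, 24, 40), margin_vox = 4,
                        slab_thickness_vox = 6, nucleus_radius_vox = 2)
  lab <- phantom_labels(g)
  # carve the WM away under part of the border: those sites lack 1 mm WM
  lab[5:8, , g$border_wm_z] <- 5L
  img <- array(1, c(24, 24, 40))
  tab <- sample_boundary(img, lab, g)
  expect_equal(attr(tab, "qc")$n_skipped, 4L * (g$yr[2] - g$yr[1] + 1))
})

test_that("both closed forms of the contrast change agree where required", {
  expect_equal(predict_contrast_change(1, 0.7, "printed"), 0)
  expect_equal(predict_contrast_change(1, 0.7, "derived"), 0)
  expect_equal(predict_contrast_change(1.2, 0.7, "printed"), 0.149733, tolerance = 1e-5)
  expect_equal(predict_contrast_change(1.2, 0.7, "derived"), 0.179028, tolerance = 1e-5)
  grid <- expand.grid(r_pd = c(0.8, 0.95, 1, 1.1, 1.3),
                      r_t1 = c(0.4, 0.7, 0.95))
  p1 <- predict_contrast_change(grid$r_pd, grid$r_t1, "printed")
  p2 <- predict_contrast_change(grid$r_pd, grid$r_t1, "derived")
  expect_equal(sign(p1), sign(p2))
  expect_equal(sign(p2), sign(grid$r_pd - 1))
})

test_that("the derived form reproduces the pipeline contrast difference exactly", {
  ph <- build_phantom(small_geometry())
  imgs <- synthesize_set(ph$maps, mprage_protocol())
  a <- sample_boundary(imgs$r1, ph$labels, ph$geometry)
  b <- sample_boundary(imgs$r1pd, ph$labels, ph$geometry)
  r_t1 <- a$gm_int / a$wm_int
  r_pd <- (b$gm_int / b$wm_int) / r_t1
  delta_pipe <- a$contrast - b$contrast
  delta_pred <- predict_contrast_change(r_pd, r_t1, "derived")
  expect_lt(max(abs(delta_pred - delta_pipe) / pmax(abs(delta_pipe), 1e-12)),
            1e-12)
  # the mechanism's sign rule at every site
  expect_equal(sign(delta_pipe), sign(r_pd - 1))
})

test_that("no-intercept regression matches the normal equations and flags exact fits", {
  x <- c(-2, -1, 0.5, 1, 3)
  y <- 2 * x
  r <- regress_delta(y, x)
  expect_equal(r$beta, 2)
  expect_equal(max(abs(r$residuals)), 0)
  expect_true(r$exact_fit)
  expect_true(is.infinite(r$t_value))

  # orthogonal response: beta exactly zero
  x2 <- c(1, 1, -1, -1)
  y2 <- c(1, -1, 1, -1)
  expect_equal(regress_delta(y2, x2)$beta, 0)

  # general case equals sum(xy)/sum(x^2)
  set.seed(5)
  x3 <- rnorm(50); y3 <- rnorm(50)
  expect_equal(regress_delta(y3, x3)$beta, sum(x3 * y3) / sum(x3^2),
               tolerance = 1e-14)

  expect_error(regress_delta(c(1, 2), c(0, 0)), "all-zero")
})

test_that("noisy slope recovery stays within three analytic standard errors", {
  set.seed(202)
  n <- 500
  x <- rnorm(n, 0, 0.1)
  sigma <- 0.05
  y <- 2 * x + rnorm(n, 0, sigma)
  r <- regress_delta(y, x)
  se_analytic <- sigma / sqrt(sum(x^2))
  expect_lt(abs(r$beta - 2), 3 * se_analytic)
  expect_equal(r$se, se_analytic, tolerance = 0.15)
})

test_that("pre-smoothing is applied symmetrically to both inputs", {
  set.seed(7)
  x <- rnorm(100)
  y <- 3 * x
  # exact proportionality survives identical linear smoothing
  r <- regress_delta(y, x, smooth_fwhm = 10)
  expect_equal(r$beta, 3, tolerance = 1e-12)
  expect_true(r$exact_fit)
})
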