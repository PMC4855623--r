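test_that("EM recovers well-separated components and matches moments at K = 1", {
  set.seed(31)
  mu_true <- c(0, 10)  # 10 sigma apart
  x <- c(rnorm(5000, mu_true[1], 1), rnorm(5000, mu_true[2], 1))
  fit <- fit_gmm_em(x, K = 2, seed = 1)
  expect_true(fit$converged)
  got <- sort(fit$mean)
  expect_lt(max(abs(got - mu_true)), 0.1)

  f1 <- fit_gmm_em(x, K = 1)
  expect_equal(f1$mean, mean(x))
  expect_equal(f1$sd, sqrt(mean((x - mean(x))^2)))

  expect_error(fit_gmm_em(rnorm(25), K = 3), "10 K")
})

test_that("the EM log-likelihood trace never decreases", {
  set.seed(32)
  x <- c(rnorm(2000, 0, 1), rnorm(2000, 3, 0.5), rnorm(2000, 7, 2))
  fit <- fit_gmm_em(x, K = 3, seed = 2)
  expect_gt(length(fit$loglik), 2)
  expect_true(all(diff(fit$loglik) > -1e-7))
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust resolves helpers on the search path
  set.seed(33)
  x <- c(rnorm(3000, 0, 1), rnorm(3000, 6, 1.5))
  fit <- fit_gmm_em(x, K = 2, seed = 1)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$mean), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
})

test_that("noiseless piecewise-constant images are classified exactly", {
  g <- small_geometry()
  ph <- build_phantom(g)
  img <- synthesize(ph$maps, mprage_protocol(), "r1pdr2s")
  mask <- phantom_brain_mask(g)
  rep <- classify_and_measure(img, mask, smooth_fwhm_mm = 0, noise_sigma = 0,
                              geometry = g)
  truth <- ph$labels
  # ground-truth class -> proxy codes: CSF 1, GM 2, WM 3; nuclei are GM
  map3 <- c(3L, 2L, 2L, 2L, 1L)[truth]
  expect_true(all(rep$labels[mask] == map3[mask]))
  gm_true <- sum(truth %in% c(2L, 3L, 4L) & mask)
  expect_equal(unname(rep$volumes_mm3["gm"]), gm_true, tolerance = 0.01)
  # exact thickness on classification-derived labels
  expect_equal(unname(mean(rep$thickness_mm)), g$slab_thickness_vox)
})

test_that("tissue volumes always sum to the masked volume", {
  g <- small_geometry()
  ph <- build_phantom(g)
  mask <- phantom_brain_mask(g)
  for (tag in c("r1", "r1pd")) {
    img <- synthesize(ph$maps, mprage_protocol(), tag)
    rep <- classify_and_measure(img, mask, noise_sigma = 0.02, seed = 4)
    expect_equal(unname(sum(rep$volumes_mm3)), sum(mask) * 1)
  }
})

test_that("morphometry reports are identical across reruns at a fixed seed", {
  g <- small_geometry()
  ph <- build_phantom(g)
  img <- synthesize(ph$maps, mprage_protocol(), "r1")
  mask <- phantom_brain_mask(g)
  a <- classify_and_measure(img, mask, noise_sigma = 0.01, seed = 11,
                            geometry = g)
  b <- classify_and_measure(img, mask, noise_sigma = 0.01, seed = 11,
                            geometry = g)
  expect_identical(a$volumes_mm3, b$volumes_mm3)
  expect_identical(a$labels, b$labels)
  expect_identical(as.numeric(a$thickness_mm), as.numeric(b$thickness_mm))
})

test_that("slab thickness is read off ground-truth labels exactly", {
  g <- phantom_geometry(shape = c(32, 32, 32), margin_vox = 4,
                        slab_thickness_vox = 8, nucleus_radius_vox = 3)
  lab <- phantom_labels(g)
  th <- measure_slab_thickness(lab, g)
  expect_true(all(th == 8))
  # destroy the GM column at one site: NaN plus QC count
  lab[g$xr[1], g$yr[1], (g$border_wm_z + 1):(g$border_wm_z + 8)] <- 5L
  th2 <- measure_slab_thickness(lab, g)
  expect_equal(sum(is.nan(th2)), 1)
  expect_equal(attr(th2, "qc")$n_nan, 1L)
})

test_that("raising cortical PD never raises the PD-image GM volume relative to R1-only", {
  # noiseless, smoothed: the monotone mechanism behind the apparent
  # volume differences
  g <- small_geometry()
  mask <- phantom_brain_mask(g)
  rel_gm <- vapply(c(0.75, 0.83, 0.95), function(pd_gm) {
    tt <- tissue_table()
    tt$pd[tt$name %in% c("cortical_gm", "sensorimotor_gm")] <- pd_gm
    ph <- build_phantom(g, tt)
    ia <- synthesize(ph$maps, mprage_protocol(), "r1")
    ib <- synthesize(ph$maps, mprage_protocol(), "r1pd")
    va <- classify_and_measure(ia, mask, noise_sigma = 0, seed = 1)$volumes_mm3["gm"]
    vb <- classify_and_measure(ib, mask, noise_sigma = 0, seed = 1)$volumes_mm3["gm"]
    unname(vb - va)
  }, numeric(1))
  expect_true(all(diff(rel_gm) <= 0))
})
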