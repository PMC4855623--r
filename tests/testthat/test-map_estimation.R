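te8 <- seq(2.34, 18.72, length.out = 8)

make_stack <- function(s_fun, dm = c(3, 3, 3)) {
  arr <- array(NA_real_, c(dm, length(te8)))
  for (e in seq_along(te8)) arr[, , , e] <- s_fun(te8[e])
  arr
}

test_that("R2* log-linear fit is exact on noise-free exponentials", {
  mask <- array(TRUE, c(3, 3, 3))
  stack <- make_stack(function(te) 1000 * exp(-te * 0.040))
  fit <- fit_r2star(stack, te8, mask)
  expect_equal(unname(fit$r2s[2, 2, 2]), 40, tolerance = 1e-10)
  expect_equal(unname(fit$s0[1, 1, 1]), 1000, tolerance = 1e-8)
  expect_equal(fit$qc$n_clipped, 0L)

  # constant signal: R2* = 0
  fit0 <- fit_r2star(make_stack(function(te) 500), te8, mask)
  expect_equal(max(abs(fit0$r2s)), 0, tolerance = 1e-10)

  # global scaling leaves R2* unchanged, scales S0
  fitk <- fit_r2star(3 * stack, te8, mask)
  expect_equal(fitk$r2s, fit$r2s, tolerance = 1e-12)
  expect_equal(fitk$s0, 3 * fit$s0, tolerance = 1e-8)
})

test_that("R2* fit flags degenerate voxels and rejects short echo trains", {
  mask <- array(TRUE, c(2, 2, 2))
  stack <- make_stack(function(te) 1000 * exp(-te * 0.02), c(2, 2, 2))
  stack[1, 1, 1, 4] <- -5  # non-positive signal
  fit <- fit_r2star(stack, te8, mask)
  expect_true(is.nan(fit$r2s[1, 1, 1]))
  expect_equal(fit$qc$n_nonpositive, 1L)
  expect_false(any(is.nan(fit$r2s[-1])))

  # negative true slope (signal increasing): clipped to zero, counted
  inc <- make_stack(function(te) 100 * exp(+te * 0.01), c(2, 2, 2))
  fiti <- fit_r2star(inc, te8, mask)
  expect_equal(unname(fiti$r2s[1, 1, 1]), 0)
  expect_equal(fiti$qc$n_clipped, 8L)

  expect_error(fit_r2star(stack[, , , 1, drop = FALSE], te8[1], mask),
               "two echoes")
})

test_that("noisy R2* fit stays within the Monte-Carlo calibrated bound", {
  # sigma = 1% of S0; bound 0.025 frozen from a 100,000-voxel
  # Monte-Carlo of the same generative model (median rel. err. 0.0183)
  set.seed(101)
  dm <- c(25, 20, 20)  # 10,000 voxels
  stack <- make_stack(function(te) 1000 * exp(-te * 0.040), dm)
  stack <- stack + array(rnorm(length(stack), 0, 10), dim(stack))
  mask <- array(TRUE, dm)
  fit <- fit_r2star(stack, te8, mask)
  med <- median(abs(fit$r2s[mask] - 40) / 40, na.rm = TRUE)
  expect_lt(med, 0.025)
  # rerun with the same draw is identical
  set.seed(101)
  stack2 <- make_stack(function(te) 1000 * exp(-te * 0.040), dm)
  stack2 <- stack2 + array(rnorm(length(stack2), 0, 10), dim(stack2))
  expect_identical(fit_r2star(stack2, te8, mask)$r2s, fit$r2s)
})

ernst <- function(t1_ms, pd, tr, a_deg, b1 = 1) {
  a <- a_deg * pi / 180 * b1
  e1 <- exp(-tr / t1_ms)
  pd * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

test_that("two-point R1/PD inversion recovers the generating values exactly", {
  dm <- c(2, 2, 2)
  t1 <- 950; pd <- 0.69; tr <- 24.5
  p1 <- flash_protocol(tr, 6, 2.34)
  p2 <- flash_protocol(tr, 21, 2.34)
  mask <- array(TRUE, dm)
  for (b1f in c(1, 0.9)) {
    s1 <- array(ernst(t1, pd, tr, 6, b1f), dm)
    s2 <- array(ernst(t1, pd, tr, 21, b1f), dm)
    b1 <- if (b1f == 1) NULL else b1_map(array(b1f, dm))
    fit <- fit_r1_pd(s1, s2, p1, p2, b1 = b1, mask = mask)
    expect_equal(unname(fit$r1[1, 1, 1]), 1000 / 950, tolerance = 1e-12)
    expect_equal(unname(fit$pd[1, 1, 1]), 0.69, tolerance = 1e-12)
  }
  # PD scales with the signal; R1 does not
  s1 <- array(ernst(t1, pd, tr, 6), dm)
  s2 <- array(ernst(t1, pd, tr, 21), dm)
  fit1 <- fit_r1_pd(s1, s2, p1, p2, mask = mask)
  fit5 <- fit_r1_pd(5 * s1, 5 * s2, p1, p2, mask = mask)
  expect_equal(fit5$r1, fit1$r1, tolerance = 1e-12)
  expect_equal(fit5$pd, 5 * fit1$pd, tolerance = 1e-12)
})

test_that("ignoring a true B1 bias shifts R1 as the Ernst root-finder predicts", {
  t1 <- 950; pd <- 0.69; tr <- 24.5; b1f <- 0.9
  dm <- c(1, 1, 1)
  s1 <- array(ernst(t1, pd, tr, 6, b1f), dm)
  s2 <- array(ernst(t1, pd, tr, 21, b1f), dm)
  p1 <- flash_protocol(tr, 6, 2.34)
  p2 <- flash_protocol(tr, 21, 2.34)
  fit <- fit_r1_pd(s1, s2, p1, p2, mask = array(TRUE, dm))  # B1 ignored
  r1_biased <- fit$r1[1, 1, 1]

  # independent oracle: solve S1/S2 = E(a1, T1)/E(a2, T1) for T1 at
  # *nominal* angles by bisection on the Ernst equation
  ratio <- s1[1] / s2[1]
  f <- function(t1x) ernst(t1x, 1, tr, 6) / ernst(t1x, 1, tr, 21) - ratio
  t1_oracle <- uniroot(f, c(50, 20000), tol = 1e-10)$root
  expect_equal(r1_biased, 1000 / t1_oracle, tolerance = 1e-6)
  # direction: under-flipping (B1 < 1) ignored biases R1 upward here
  expect_equal(sign(r1_biased - 1000 / 950), sign(1000 / t1_oracle - 1000 / 950))
})

test_that("non-physical slopes and identical angles are rejected", {
  dm <- c(2, 1, 1)
  p1 <- flash_protocol(24.5, 6, 2.34)
  p2 <- flash_protocol(24.5, 21, 2.34)
  # voxel 1: inconsistent pair whose linearized slope is negative
  # (no E1 in (0,1) explains it); voxel 2: a physical Ernst pair
  s1 <- array(c(1, ernst(950, 0.7, 24.5, 6)), dm)
  s2 <- array(c(3.5, ernst(950, 0.7, 24.5, 21)), dm)
  fit <- fit_r1_pd(s1, s2, p1, p2, mask = array(TRUE, dm))
  expect_true(is.nan(fit$r1[1, 1, 1]))
  expect_false(is.nan(fit$r1[2, 1, 1]))
  expect_equal(fit$qc$n_nonphysical, 1L)
  expect_equal(fit$qc$n_fitted, 1L)
  expect_error(fit_r1_pd(s1, s2, p1, p1, mask = array(TRUE, dm)),
               "different flip angles")
})

test_that("estimate_maps round-trips the phantom and reports reproducible QC", {
  ph <- build_phantom(small_geometry())
  fset <- simulate_flash_set(ph, noise_sigma = 0)
  est <- estimate_maps(fset)
  i <- est$mask & ph$maps$mask
  expect_gt(sum(i), 1000)
  expect_lt(max(abs(est$r1[i] - ph$maps$r1[i]) / ph$maps$r1[i]), 1e-8)
  expect_lt(max(abs(est$pd[i] - ph$maps$pd[i]) / ph$maps$pd[i]), 1e-8)
  expect_lt(max(abs(est$r2s[i] - ph$maps$r2s[i]) /
                  pmax(ph$maps$r2s[i], 1e-6)), 1e-8)
  expect_equal(est$qc$n_nan, 0L)

  # B1-biased acquisition, corrected fit: same exact recovery
  b1 <- make_b1_field(ph$geometry, 0.15, seed = 3)
  fsetb <- simulate_flash_set(ph, b1 = b1)
  estb <- estimate_maps(fsetb, b1 = b1)
  ib <- estb$mask & ph$maps$mask
  expect_lt(max(abs(estb$r1[ib] - ph$maps$r1[ib]) / ph$maps$r1[ib]), 1e-8)

  # noisy QC counts identical across reruns of the same seed
  fsn <- simulate_flash_set(ph, noise_sigma = 0.05, seed = 9)
  q1 <- estimate_maps(fsn)$qc
  fsn2 <- simulate_flash_set(ph, noise_sigma = 0.05, seed = 9)
  q2 <- estimate_maps(fsn2)$qc
  expect_identical(q1, q2)

  # empty mask warns and yields empty maps
  fset$mask[] <- FALSE
  expect_warning(est0 <- estimate_maps(fset), "empty mask")
  expect_equal(sum(est0$mask), 0)
})

test_that("noise-free fitted R2* is monotone in the generating R2*", {
  mask <- array(TRUE, c(1, 1, 1))
  r2_true <- c(0, 5, 10, 20, 40, 60) / 1000
  fitted <- vapply(r2_true, function(r2) {
    st <- make_stack(function(te) 800 * exp(-te * r2), c(1, 1, 1))
    fit_r2star(st, te8, mask)$r2s[1, 1, 1]
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
  expect_equal(fitted, r2_true * 1000, tolerance = 1e-8)
})
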