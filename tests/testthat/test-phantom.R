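test_that("phantom maps are piecewise constant and deterministic", {
  g <- small_geometry()
  ph <- build_phantom(g)
  tt <- tissue_table()
  for (j in seq_len(nrow(tt))) {
    sel <- ph$labels == tt$label[j]
    expect_true(all(ph$maps$r1[sel] == tt$r1[j]))
    expect_true(all(ph$maps$pd[sel] == tt$pd[j]))
    expect_true(all(ph$maps$r2s[sel] == tt$r2s[j]))
  }
  # same seed twice: bit-identical (with heterogeneity on)
  a <- build_phantom(g, heterogeneity_sd = 0.05, seed = 42)
  b <- build_phantom(g, heterogeneity_sd = 0.05, seed = 42)
  expect_identical(a$maps$r1, b$maps$r1)
  expect_identical(a$maps$pd, b$maps$pd)

  # heterogeneity: per-tissue mean within 3 SE of the table value
  wm <- a$maps$r1[a$labels == 1]
  se <- 0.05 * tissue_table()$r1[1] / sqrt(length(wm))
  expect_lt(abs(mean(wm) - tissue_table()$r1[1]), 3 * se)
})

test_that("phantom regions are disjoint and CSF anchors the PD maximum", {
  g <- small_geometry()
  lab <- phantom_labels(g)
  expect_setequal(unique(as.vector(lab)), 1:5)
  tt <- tissue_table()
  expect_true(all(tt$pd[tt$name != "csf"] < tt$pd[tt$name == "csf"]))
  # a nucleus placed outside the WM block is rejected
  g2 <- small_geometry()
  g2$nucleus_centers[1, ] <- c(2, 2, 2)
  expect_error(phantom_labels(g2), "overlaps")
})

test_that("FLASH simulation peaks at the Ernst angle and is deterministic", {
  dm <- c(1, 1, 1)
  r1 <- 1.0  # 1/s; TR 24.5 ms
  maps1 <- function() quantitative_maps(array(r1, dm), array(0.8, dm),
                                        array(0, dm), array(TRUE, dm))
  tr <- 24.5
  ernst_deg <- acos(exp(-tr * r1 / 1000)) * 180 / pi
  grid <- seq(0.5, 30, by = 0.25)
  sig <- vapply(grid, function(a) {
    p <- flash_protocol(tr, a, 0.001)
    simulate_flash(maps1(), p, noise_sigma = 0)[1, 1, 1, 1]
  }, numeric(1))
  expect_equal(grid[which.max(sig)], ernst_deg, tolerance = 0.3)

  # R2* = 0: all echoes identical
  g <- small_geometry()
  ph <- build_phantom(g)
  m0 <- quantitative_maps(ph$maps$r1, ph$maps$pd,
                          array(0, g$shape), ph$maps$mask)
  st <- simulate_flash(m0, flash_protocol_defaults("pdw"))
  expect_equal(st[, , , 1], st[, , , 8], tolerance = 1e-14)

  # fixed seed reproducibility of the noise
  s1 <- simulate_flash(ph$maps, flash_protocol_defaults("pdw"),
                       noise_sigma = 0.02, seed = 7)
  s2 <- simulate_flash(ph$maps, flash_protocol_defaults("pdw"),
                       noise_sigma = 0.02, seed = 7)
  expect_identical(s1, s2)
})

test_that("B1 field spans the requested amplitude and varies smoothly", {
  g <- small_geometry()
  expect_equal(make_b1_field(g, 0)$relative_flip_factor,
               array(1, g$shape))
  b1 <- make_b1_field(g, 0.2, seed = 4)
  f <- b1$relative_flip_factor
  expect_gte(min(f), 0.8)
  expect_lte(max(f), 1.2)
  # finite-difference gradient bounded by the cosine construction:
  # max |df/dx| <= amplitude * pi / (shape/3) per axis
  for (d in 1:3) {
    m <- matrix(aperm(f, c(d, setdiff(1:3, d))), nrow = g$shape[d])
    df <- abs(diff(m))
    bound <- 0.2 * pi / (g$shape[d] / 1.05) # small slack over amplitude*pi/n
    expect_lt(max(df), bound)
  }
})

test_that("cohort construction follows the specified age model exactly", {
  g <- small_geometry()
  # zero slopes and zero noise: identical subjects
  sp0 <- cohort_spec(n_subjects = 5, slopes = list(),
                     between_subject_sd = 0, seed = 2)
  co0 <- generate_cohort(sp0, g)
  for (i in 2:5)
    expect_identical(co0$tissue_tables[[i]], co0$tissue_tables[[1]])

  # linear GM R1 decline, zero noise: exactly on the line
  sl <- -0.002
  sp1 <- cohort_spec(n_subjects = 8, slopes = list(r1_cortical_gm = sl),
                     between_subject_sd = 0, seed = 2)
  co1 <- generate_cohort(sp1, g)
  base <- tissue_table()$r1[tissue_table()$name == "cortical_gm"]
  got <- vapply(co1$tissue_tables, function(t)
    t$r1[t$name == "cortical_gm"], numeric(1))
  expect_equal(got, base * (1 + sl * co1$subjects$age_c), tolerance = 1e-12)

  # with subject noise: OLS recovers the slope within 3 SE
  sp2 <- cohort_spec(n_subjects = 40, slopes = list(r1_cortical_gm = sl),
                     between_subject_sd = 0.02, seed = 3)
  co2 <- generate_cohort(sp2, g)
  y <- vapply(co2$tissue_tables, function(t)
    t$r1[t$name == "cortical_gm"], numeric(1))
  x <- co2$subjects$age_c
  fit <- lm(y ~ x)
  se <- summary(fit)$coefficients["x", "Std. Error"]
  expect_lt(abs(coef(fit)["x"] - base * sl), 3 * se)
})

test_that("the full loop phantom -> acquisition -> maps -> synthesis closes", {
  ph <- build_phantom(small_geometry())
  fset <- simulate_flash_set(ph, noise_sigma = 0)
  est <- estimate_maps(fset)
  prot <- mprage_protocol()
  from_truth <- synthesize_set(ph$maps, prot)
  from_est <- synthesize_set(est, prot)
  i <- est$mask & ph$maps$mask
  for (tag in names(from_truth)) {
    a <- from_truth[[tag]]$intensity[i]
    b <- from_est[[tag]]$intensity[i]
    expect_lt(max(abs(a - b) / abs(a)), 1e-8)
  }
})
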