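#' Gray-white matter contrast
#'
#' `C = (WM - GM) / ((WM + GM) / 2)`: the normalized intensity
#' difference between white and gray matter at a boundary site. C lies
#' in (-2, 2), is positive iff WM is brighter than GM (the T1-weighted
#' polarity), changes sign when the intensities are swapped, and is
#' invariant under global intensity scaling.
#'
#' @param wm_intensity,gm_intensity Positive signal intensities
#'   (vectorized).
#' @return Dimensionless contrast values.
#' @examples
#' compute_contrast(100, 80)  # 20 / 90
#' @export
compute_contrast <- function(wm_intensity, gm_intensity) {
  assert_that(all(is.finite(wm_intensity)) && all(wm_intensity > 0) &&
                all(is.finite(gm_intensity)) && all(gm_intensity > 0),
              "intensities must be positive and finite")
  (wm_intensity - gm_intensity) / ((wm_intensity + gm_intensity) / 2)
}

#' Sample WM and GM intensities along the slab boundary
#'
#' For every boundary site (an (x, y) column of the phantom's planar
#' GM-WM border), samples the WM intensity 1 mm subjacent to the border
#' along the boundary normal (the slab axis) and the GM intensity at
#' 35% of the local cortical thickness from the border. Depths are
#' mapped to voxel indices by round-half-up with a minimum of one voxel
#' from the border; sampling is nearest-voxel, without interpolation.
#' Sites whose GM run is thinner than one voxel, or without the required
#' WM depth inside the volume, are skipped and counted.
#'
#' @param image A `synthetic_image` (or a bare 3D array).
#' @param labels Integer label volume ([phantom_labels()] coding: GM
#'   labels 2 and 3, WM label 1).
#' @param geometry The [phantom_geometry()] that defines the border.
#' @return data.frame of class `boundary_samples` with columns
#'   `site_id`, `x`, `y`, `wm_int`, `gm_int`, `contrast`, `modality`,
#'   plus attribute `qc` (number of skipped sites).
#' @export
sample_boundary <- function(image, labels, geometry) {
  intensity <- if (inherits(image, "synthetic_image")) image$intensity else image
  tag <- if (inherits(image, "synthetic_image")) image$tag else NA_character_
  assert_that(same_dim(intensity, labels), "labels must align with the image")
  g <- geometry
  vox <- g$voxel_mm
  wm_depth <- max(1L, round_half_up(1 / vox))      # 1 mm into WM
  xs <- g$xr[1]:g$xr[2]; ys <- g$yr[1]:g$yr[2]
  bz <- g$border_wm_z
  n_skip <- 0L
  rows <- vector("list", length(xs) * length(ys))
  k <- 0L
  for (x in xs) for (y in ys) {
    col <- labels[x, y, ]
    gm_run <- 0L
    z <- bz + 1L
    while (z <= length(col) && col[z] %in% c(2L, 3L)) {
      gm_run <- gm_run + 1L
      z <- z + 1L
    }
    wm_z <- bz - wm_depth + 1L
    if (gm_run < 1L || wm_z < 1L || col[wm_z] != 1L) {
      n_skip <- n_skip + 1L
      next
    }
    depth <- max(1L, round_half_up(0.35 * gm_run))
    gm_z <- bz + depth
    k <- k + 1L
    rows[[k]] <- c(x, y, intensity[x, y, wm_z], intensity[x, y, gm_z])
  }
  m <- do.call(rbind, rows[seq_len(k)])
  out <- data.frame(site_id = seq_len(k), x = m[, 1], y = m[, 2],
                    wm_int = m[, 3], gm_int = m[, 4])
  out$contrast <- compute_contrast(out$wm_int, out$gm_int)
  out$modality <- tag
  attr(out, "qc") <- list(n_skipped = n_skip)
  class(out) <- c("boundary_samples", class(out))
  out
}

#' Predicted contrast change from PD inclusion
#'
#' Closed-form prediction of the contrast change
#' `C({R1}) - C({R1,PD})` from the gray/white intensity ratios
#' `R_PD = PD_GM / PD_WM` and `R_T1w(R1) = I_GM / I_WM` of the
#' R1-only image. Two algebraic forms are provided:
#'
#' * `"printed"`: `4 (R_PD - 1) R / ((1 + R_PD) (1 + R))`,
#' * `"derived"`: `4 R (R_PD - 1) / ((1 + R) (1 + R_PD R))`,
#'
#' writing `R` for `R_T1w(R1)`. The `"derived"` form is the exact
#' algebraic consequence of the contrast definition applied to the two
#' image types (and matches the brute-force pipeline difference to
#' machine precision); the `"printed"` form is an alternative published
#' variant retained for comparison. The two agree in sign everywhere
#' and coincide at `R_PD = 1` (both zero). The default is `"derived"`.
#'
#' @param r_pd GM/WM ratio of PD (positive, vectorized).
#' @param r_t1w_r1 GM/WM intensity ratio of the `{R1}` image (positive).
#' @param form `"derived"` (default) or `"printed"`.
#' @return Predicted contrast change (dimensionless).
#' @examples
#' predict_contrast_change(1.2, 0.7, "printed")  # ~0.1497
#' predict_contrast_change(1.2, 0.7, "derived")  # ~0.1790
#' @export
predict_contrast_change <- function(r_pd, r_t1w_r1,
                                    form = c("derived", "printed")) {
  form <- match.arg(form)
  assert_that(all(r_pd > 0) && all(r_t1w_r1 > 0), "ratios must be positive")
  if (form == "printed") {
    4 * (r_pd - 1) * r_t1w_r1 / ((1 + r_pd) * (1 + r_t1w_r1))
  } else {
    4 * r_t1w_r1 * (r_pd - 1) / ((1 + r_t1w_r1) * (1 + r_pd * r_t1w_r1))
  }
}

#' No-intercept regression of thickness change on contrast change
#'
#' Fits `delta_thickness = beta * delta_contrast + residual` by least
#' squares through the origin across boundary sites, the site-wise
#' analogue of a vertex-wise linear model. Optionally both inputs are
#' smoothed beforehand with a 1D Gaussian along the site ordering
#' (`smooth_fwhm` in site units; off by default). The t statistic is
#' `beta / SE(beta)` with `SE^2 = RSS / (n - 1) / sum(x^2)`; an exact
#' fit (zero residual variance) is reported as `t = Inf` with
#' `exact_fit = TRUE`.
#'
#' @param delta_thickness,delta_contrast Equal-length numeric vectors
#'   over sites (n >= 2).
#' @param smooth_fwhm FWHM of the optional 1D pre-smoothing, in site
#'   index units; 0 disables.
#' @return Object of class `contrast_regression`: `beta`, `se`,
#'   `t_value`, `p_value` (two-sided), `residuals`, `n`, `exact_fit`.
#' @export
regress_delta <- function(delta_thickness, delta_contrast, smooth_fwhm = 0) {
  assert_that(length(delta_thickness) == length(delta_contrast),
              "inputs must have equal length")
  n <- length(delta_contrast)
  assert_that(n >= 2, "at least two sites are required")
  if (smooth_fwhm > 0) {
    delta_thickness <- .smooth1d(delta_thickness, fwhm_to_sigma(smooth_fwhm))
    delta_contrast <- .smooth1d(delta_contrast, fwhm_to_sigma(smooth_fwhm))
  }
  sxx <- sum(delta_contrast^2)
  assert_that(sxx > 0, "all-zero delta_contrast: beta undefined")
  beta <- sum(delta_thickness * delta_contrast) / sxx
  res <- delta_thickness - beta * delta_contrast
  rss <- sum(res^2)
  sigma2 <- rss / (n - 1)
  exact <- sigma2 < .Machine$double.eps * max(1, sum(delta_thickness^2))
  se <- sqrt(sigma2 / sxx)
  t <- if (exact) Inf * sign(beta) else beta / se
  p <- if (exact) 0 else 2 * stats::pt(-abs(t), df = n - 1)
  structure(list(beta = beta, se = se, t_value = t, p_value = p,
                 residuals = res, n = n, exact_fit = exact),
            class = "contrast_regression")
}

#' @export
print.contrast_regression <- function(x, ...) {
  cat(sprintf("No-intercept regression over %d sites: beta = %.4g, t = %.3g%s\n",
              x$n, x$beta, x$t_value,
              if (x$exact_fit) " (exact fit)" else ""))
  invisible(x)
}

.smooth1d <- function(v, sigma) {
  r <- ceiling(3 * sigma)
  if (r < 1) return(v)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- length(v)
  acc <- numeric(n)
  for (j in -r:r) {
    idx <- pmin(pmax(seq_len(n) + j, 1L), n)
    acc <- acc + k[j + r + 1] * v[idx]
  }
  acc
}
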