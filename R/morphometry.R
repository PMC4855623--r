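#' One-dimensional Gaussian mixture fitted by EM
#'
#' Expectation-maximization for a K-component univariate Gaussian
#' mixture over masked voxel intensities, the intensity-only stand-in
#' for probabilistic tissue classification. Initialization is
#' deterministic: component means at the (k - 1/2)/K intensity
#' quantiles, equal weights, common initial standard deviation. The
#' log-likelihood is recorded every iteration and is non-decreasing; a
#' near-empty component whose standard deviation collapses below the
#' floor (`1e-6 sd(x)`) is re-seeded at a random data point (seeded,
#' and the event logged), while a heavy component on identical values
#' (a point mass, as in noiseless piecewise-constant images) is clamped
#' at the floor and kept. Non-convergence within `max_iter` returns the
#' current fit with a warning flag.
#'
#' @param x Numeric vector of intensities (`n >= 10 K`).
#' @param K Number of components (>= 1).
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence threshold on the per-observation
#'   log-likelihood change (`|ll - ll_prev| / n < tol`).
#' @param seed Integer seed (used only if a component must be
#'   re-seeded).
#' @return Object of class `gmm1d`: `mean`, `sd`, `weight` (length K),
#'   `loglik` (trace, one entry per iteration), `converged`,
#'   `n_reseeded`, `responsibilities` (n x K), `K`, `n`.
#' @export
fit_gmm_em <- function(x, K = 3, max_iter = 300, tol = 1e-9, seed = 1) {
  assert_that(K >= 1, "K must be at least 1")
  n <- length(x)
  assert_that(n >= 10 * K, "need at least 10 K observations")
  if (K == 1) {
    mu <- mean(x)
    sg <- sqrt(mean((x - mu)^2))
    return(structure(list(mean = mu, sd = sg, weight = 1,
                          loglik = sum(stats::dnorm(x, mu, sg, log = TRUE)),
                          converged = TRUE, n_reseeded = 0L,
                          responsibilities = matrix(1, n, 1), K = 1L, n = n),
                     class = "gmm1d"))
  }
  sdx <- stats::sd(x)
  assert_that(sdx > 0, "intensities are constant; no mixture to fit")
  mu <- stats::quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE)
  sg <- rep(sdx / K, K)
  w <- rep(1 / K, K)
  sd_floor <- 1e-6 * sdx
  set.seed(as.integer(seed))
  ll_trace <- numeric(0)
  converged <- FALSE
  n_reseeded <- 0L
  r <- NULL
  for (it in seq_len(max_iter)) {
    d <- vapply(seq_len(K),
                function(k) w[k] * stats::dnorm(x, mu[k], sg[k]),
                numeric(n))
    s <- rowSums(d) + .Machine$double.xmin
    ll <- sum(log(s))
    ll_trace <- c(ll_trace, ll)
    r <- d / s
    nk <- colSums(r)
    w <- nk / n
    mu <- colSums(r * x) / nk
    for (k in seq_len(K)) {
      sg[k] <- sqrt(sum(r[, k] * (x - mu[k])^2) / nk[k])
      if (!is.finite(sg[k]) || sg[k] < sd_floor) {
        if (is.finite(sg[k]) && nk[k] / n >= 0.02) {
          # a heavy component on (near-)identical values: a point mass,
          # not a collapse; clamp at the floor and keep it
          sg[k] <- sd_floor
        } else {
          mu[k] <- x[sample.int(n, 1)]
          sg[k] <- sdx / K
          w <- rep(1 / K, K)
          n_reseeded <- n_reseeded + 1L
        }
      }
    }
    if (it > 1 && abs(ll - ll_trace[it - 1]) / n < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("fit_gmm_em: EM did not converge within max_iter")
  structure(list(mean = as.numeric(mu), sd = as.numeric(sg),
                 weight = as.numeric(w), loglik = ll_trace,
                 converged = converged, n_reseeded = n_reseeded,
                 responsibilities = r, K = as.integer(K), n = n),
            class = "gmm1d")
}

#' @export
print.gmm1d <- function(x, ...) {
  cat(sprintf("Gaussian mixture, K = %d, n = %d, %s after %d iterations\n",
              x$K, x$n, if (x$converged) "converged" else "NOT converged",
              length(x$loglik)))
  ord <- order(x$mean)
  cat(sprintf("  mean %s | sd %s | weight %s\n",
              paste(signif(x$mean[ord], 4), collapse = " "),
              paste(signif(x$sd[ord], 3), collapse = " "),
              paste(signif(x$weight[ord], 3), collapse = " ")))
  invisible(x)
}

#' Segment an image into CSF/GM/WM and measure apparent volumes
#'
#' Intensity-driven morphometry proxy: optionally smooths the image
#' with a small Gaussian (acquisition point-spread scale), fits a
#' K-component Gaussian mixture to the masked intensities, labels every
#' masked voxel by maximum posterior, and assigns components to tissues
#' by mean intensity order using the T1-weighted polarity (brightest =
#' WM, darkest = CSF). Volumes are label counts times the voxel volume;
#' classification is exhaustive over the mask, so the three volumes sum
#' to the masked volume.
#'
#' @param image A `synthetic_image` or bare 3D array.
#' @param mask Logical 3D array of voxels to classify.
#' @param K Number of mixture components (default 3: CSF, GM, WM).
#' @param voxel_mm Voxel edge length in mm (taken from the image if
#'   available).
#' @param smooth_fwhm_mm Pre-classification intensity smoothing FWHM in
#'   mm (default 2, the point-spread scale of a 1 mm acquisition; 0
#'   disables).
#' @param noise_sigma Optional additive Gaussian noise (relative to the
#'   maximum masked intensity) applied before smoothing, emulating
#'   acquisition noise on a noise-free synthetic image.
#' @param seed Integer seed (noise draw and EM re-seeding).
#' @param fit_subsample Maximum number of voxels used to *fit* the
#'   mixture (a deterministic stride through the masked voxels); all
#'   masked voxels are classified with the fitted model. `Inf` fits on
#'   everything.
#' @param geometry Optional [phantom_geometry()]; when given, slab
#'   thickness per boundary site is measured on the classified labels.
#' @return Object of class `morphometry_report`: `volumes_mm3` (named
#'   gm/wm/csf), `labels` (3D array: 0 outside mask, 1 CSF, 2 GM,
#'   3 WM), `fit` (the `gmm1d`), `thickness_mm` (per site, if geometry
#'   given), `qc`.
#' @export
classify_and_measure <- function(image, mask, K = 3, voxel_mm = NULL,
                                 smooth_fwhm_mm = 2, noise_sigma = 0,
                                 seed = 1, fit_subsample = 40000,
                                 geometry = NULL) {
  intensity <- if (inherits(image, "synthetic_image")) image$intensity else image
  if (is.null(voxel_mm))
    voxel_mm <- if (inherits(image, "synthetic_image")) image$voxel_mm else 1
  assert_that(same_dim(intensity, mask), "mask must match the image grid")
  mask <- array(as.logical(mask), dim(mask))
  assert_that(any(mask), "mask is empty")
  # non-finite voxels (outside the estimated-map support) behave as air
  n_nonfinite <- sum(!is.finite(intensity[mask]))
  intensity[!is.finite(intensity)] <- 0
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    s <- noise_sigma * max(intensity[mask], na.rm = TRUE)
    intensity <- intensity + array(stats::rnorm(length(intensity), 0, s),
                                   dim(intensity))
  }
  if (smooth_fwhm_mm > 0)
    intensity <- smooth_gaussian3d(intensity, smooth_fwhm_mm, voxel_mm)
  x <- intensity[mask]
  xfit <- if (length(x) > fit_subsample)
    x[round(seq(1, length(x), length.out = fit_subsample))] else x
  fit <- fit_gmm_em(xfit, K = K, seed = derive_seed(seed, 3))
  ord <- order(fit$mean)  # ascending: CSF ... WM
  resp <- .gmm_posterior(x, fit)
  cls <- max.col(resp, ties.method = "first")
  rank_of <- match(cls, ord)  # 1 = darkest (CSF), K = brightest (WM)
  # map to tissue codes 1 CSF, 2 GM, 3 WM for K = 3; for general K the
  # darkest is CSF, brightest WM, everything between GM
  tissue <- ifelse(rank_of == 1, 1L, ifelse(rank_of == K, 3L, 2L))
  labels <- array(0L, dim(intensity))
  labels[mask] <- tissue
  vv <- voxel_mm^3
  volumes <- c(gm = sum(tissue == 2L) * vv,
               wm = sum(tissue == 3L) * vv,
               csf = sum(tissue == 1L) * vv)
  distinct_modes <- length(unique(round((fit$mean - min(fit$mean)) /
                                          max(stats::sd(x), 1e-300), 3)))
  flagged <- distinct_modes < K
  if (flagged)
    warning("classify_and_measure: fewer distinct intensity modes than K")
  thickness <- if (!is.null(geometry))
    measure_slab_thickness(labels, geometry, gm_codes = 2L) else NULL
  structure(list(volumes_mm3 = volumes, labels = labels, fit = fit,
                 thickness_mm = thickness, voxel_mm = voxel_mm,
                 qc = list(n_mask = sum(mask), flagged = flagged,
                           n_nonfinite = n_nonfinite,
                           n_reseeded = fit$n_reseeded,
                           converged = fit$converged)),
            class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  v <- x$volumes_mm3
  cat(sprintf("Morphometry report: GM %.0f mm3, WM %.0f mm3, CSF %.0f mm3\n",
              v["gm"], v["wm"], v["csf"]))
  if (!is.null(x$thickness_mm))
    cat(sprintf("  slab thickness: mean %.2f mm over %d sites (%d NaN)\n",
                mean(x$thickness_mm, na.rm = TRUE), length(x$thickness_mm),
                sum(is.nan(x$thickness_mm))))
  invisible(x)
}

#' Slab cortical thickness from a label volume
#'
#' For every boundary site (column of the planar GM-WM border), the
#' length of the first contiguous GM run along the slab normal, times
#' the voxel size: the slab analogue of the shortest GM/WM-to-GM/CSF
#' boundary distance. Classification places the apparent GM/WM
#' boundary where the intensities put it, not on the nominal border
#' plane: the measured run is the contiguous GM run containing the
#' first GM voxel at or above the border, extended downward across the
#' border if the apparent boundary moved into WM (thicker cortex) and
#' starting higher if boundary voxels were absorbed into WM (thinner
#' cortex). The upward search is bounded by twice the nominal slab
#' thickness; sites with no GM voxel in the window give `NaN` and are
#' counted.
#'
#' @param labels Integer 3D array.
#' @param geometry A [phantom_geometry()].
#' @param gm_codes Integer codes counting as GM. The default
#'   `c(2L, 3L)` fits ground-truth phantom labels (cortical and
#'   sensorimotor GM); classified label volumes from
#'   [classify_and_measure()] code GM as 2 only (3 is WM there), so
#'   they are measured with `gm_codes = 2L`.
#' @return Numeric vector of thicknesses in mm (one per site, `NaN`
#'   where no GM run was found) with attribute `qc`.
#' @export
measure_slab_thickness <- function(labels, geometry, gm_codes = c(2L, 3L)) {
  g <- geometry
  assert_that(identical(dim(labels), g$shape),
              "labels grid must match the geometry")
  xs <- g$xr[1]:g$xr[2]; ys <- g$yr[1]:g$yr[2]
  bz <- g$border_wm_z
  nz <- g$shape[3]
  z_top <- min(nz, bz + 2L * g$slab_thickness_vox)
  z_bot <- max(1L, bz - g$slab_thickness_vox)
  out <- numeric(length(xs) * length(ys))
  k <- 0L
  n_nan <- 0L
  is_gm <- function(v) v %in% gm_codes
  for (x in xs) for (y in ys) {
    k <- k + 1L
    col <- labels[x, y, ]
    z <- bz + 1L
    while (z <= z_top && !is_gm(col[z])) z <- z + 1L
    run <- 0L
    if (z <= z_top) {
      # extend downward across the border if the apparent boundary
      # moved into WM
      zlo <- z
      while (zlo - 1L >= z_bot && is_gm(col[zlo - 1L])) zlo <- zlo - 1L
      while (z <= nz && is_gm(col[z])) z <- z + 1L
      run <- z - zlo
    }
    if (run == 0L) {
      out[k] <- NaN
      n_nan <- n_nan + 1L
    } else {
      out[k] <- run * g$voxel_mm
    }
  }
  attr(out, "qc") <- list(n_nan = n_nan)
  out
}

# E-step responsibilities for arbitrary data under a fitted gmm1d
.gmm_posterior <- function(x, fit) {
  d <- vapply(seq_len(fit$K),
              function(k) fit$weight[k] * stats::dnorm(x, fit$mean[k], fit$sd[k]),
              numeric(length(x)))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  d / (rowSums(d) + .Machine$double.xmin)
}
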