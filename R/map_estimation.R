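#' Voxelwise R2* estimation from a multi-echo stack
#'
#' Ordinary least-squares regression of the log signal on echo time,
#' `ln S(TE) = ln S0 - TE * R2*`, fitted independently per voxel. The
#' fit is carried out in 1/ms and converted to 1/s for output. Negative
#' fitted R2* values (noise or air) are clipped to 0 and counted;
#' masked voxels with a non-positive signal at any echo cannot enter the
#' log fit and are set to `NaN` and counted.
#'
#' @param volumes_4d 4D signal array (x, y, z, echo).
#' @param te_ms Echo times in ms, one per 4th-dimension slice, at least
#'   two.
#' @param mask 3D logical array.
#' @return List with `r2s` (3D array, 1/s; `NaN` outside mask), `s0`
#'   (extrapolated TE = 0 signal) and `qc` (counts `n_clipped`,
#'   `n_nonpositive`, `n_fitted`).
#' @examples
#' te <- seq(2.34, 18.72, length.out = 8)
#' sig <- array(rep(1000 * exp(-te * 0.040), each = 8), c(2, 2, 2, 8))
#' fit <- fit_r2star(sig, te, array(TRUE, c(2, 2, 2)))
#' fit$r2s[1, 1, 1]  # 40 1/s
#' @export
fit_r2star <- function(volumes_4d, te_ms, mask) {
  assert_that(length(dim(volumes_4d)) == 4, "volumes_4d must be 4D")
  assert_that(length(te_ms) >= 2, "at least two echoes are required")
  assert_that(dim(volumes_4d)[4] == length(te_ms),
              "echo dimension must match te_ms")
  dm <- dim(volumes_4d)[1:3]
  assert_that(identical(dm, dim(mask)), "mask grid must match volumes")
  mask <- array(as.logical(mask), dm)

  nvox <- prod(dm)
  S <- matrix(volumes_4d, nrow = nvox)          # voxels x echoes
  inside <- which(as.vector(mask))
  r2s <- array(NaN, dm)
  s0 <- array(NaN, dm)
  n_clipped <- 0L
  n_nonpos <- 0L
  if (length(inside)) {
    Si <- S[inside, , drop = FALSE]
    bad <- rowSums(Si <= 0 | !is.finite(Si)) > 0
    n_nonpos <- sum(bad)
    good <- inside[!bad]
    if (length(good)) {
      X <- cbind(1, -te_ms)
      # closed-form OLS, one solve shared by all voxels
      beta <- solve(crossprod(X), t(X) %*% t(log(S[good, , drop = FALSE])))
      r2_ms <- beta[2, ]
      clip <- r2_ms < 0
      n_clipped <- sum(clip)
      r2_ms[clip] <- 0
      r2s[good] <- r2_ms * .MS_PER_S
      s0[good] <- exp(beta[1, ])
    }
  }
  list(r2s = r2s, s0 = s0,
       qc = list(n_clipped = as.integer(n_clipped),
                 n_nonpositive = as.integer(n_nonpos),
                 n_fitted = length(inside) - as.integer(n_nonpos)))
}

#' Two-point R1 and PD estimation from dual-flip-angle FLASH
#'
#' Exact inversion of the spoiled gradient-echo (Ernst) steady-state
#' signal from two acquisitions that differ only in flip angle. Each
#' voxel's two signals are linearized as `y = E1 * x + PD * (1 - E1)`
#' with `y = S / sin(a_eff)` and `x = S / tan(a_eff)`; the slope through
#' the two points gives `E1 = exp(-TR * R1)`, hence `R1 = -ln(E1) / TR`,
#' and the intercept gives `PD = (y - E1 x) / (1 - E1)`. When a B1 map
#' is supplied the effective local flip angle is
#' `nominal * relative_flip_factor`, which removes transmit-field bias
#' exactly for a consistent forward model.
#'
#' Voxels whose slope falls outside (0, 1) have no physical E1 and are
#' set to `NaN` and counted in the QC report.
#'
#' @param pdw_te0,t1w_te0 3D signal arrays at (extrapolated) TE = 0.
#' @param pdw_protocol,t1w_protocol [flash_protocol()] objects; the TRs
#'   must agree and the flip angles must differ.
#' @param b1 Optional [b1_map()].
#' @param mask 3D logical array.
#' @return List with `r1` (1/s), `pd` (input signal units), and `qc`
#'   (count `n_nonphysical`).
#' @export
fit_r1_pd <- function(pdw_te0, t1w_te0, pdw_protocol, t1w_protocol,
                      b1 = NULL, mask = NULL) {
  assert_that(length(dim(pdw_te0)) == 3 && same_dim(pdw_te0, t1w_te0),
              "pdw_te0 and t1w_te0 must be aligned 3D arrays")
  assert_that(pdw_protocol$flip_deg != t1w_protocol$flip_deg,
              "the two acquisitions must have different flip angles")
  assert_that(isTRUE(all.equal(pdw_protocol$tr_ms, t1w_protocol$tr_ms)),
              "two-point estimation assumes a common TR")
  dm <- dim(pdw_te0)
  if (is.null(mask)) mask <- array(TRUE, dm)
  assert_that(identical(dim(mask), dm), "mask grid must match volumes")
  mask <- array(as.logical(mask), dm)
  tr <- pdw_protocol$tr_ms

  b1f <- if (is.null(b1)) 1 else {
    assert_that(identical(dim(b1$relative_flip_factor), dm),
                "B1 map grid must match volumes")
    as.vector(b1$relative_flip_factor)[as.vector(mask)]
  }
  a1 <- pdw_protocol$flip_deg * pi / 180 * b1f
  a2 <- t1w_protocol$flip_deg * pi / 180 * b1f
  assert_that(all(abs(a1 - a2) > .Machine$double.eps),
              "effective flip angles are identical; E1 slope undefined")

  s1 <- pdw_te0[mask]
  s2 <- t1w_te0[mask]
  y1 <- s1 / sin(a1); x1 <- s1 / tan(a1)
  y2 <- s2 / sin(a2); x2 <- s2 / tan(a2)
  e1 <- (y2 - y1) / (x2 - x1)
  ok <- is.finite(e1) & e1 > 0 & e1 < 1
  r1v <- pdv <- rep(NaN, length(e1))
  r1v[ok] <- -log(e1[ok]) / tr * .MS_PER_S
  pdv[ok] <- (y1[ok] - e1[ok] * x1[ok]) / (1 - e1[ok])

  r1 <- array(NaN, dm); pd <- array(NaN, dm)
  r1[mask] <- r1v; pd[mask] <- pdv
  list(r1 = r1, pd = pd,
       qc = list(n_nonphysical = as.integer(sum(!ok)),
                 n_fitted = as.integer(sum(ok))))
}

#' Estimate R1, PD and R2* maps from a dual-flip-angle FLASH dataset
#'
#' Composition of the map-calculation pipeline: R2* by log-linear
#' regression over the PD-weighted echoes only ([fit_r2star()]); R1 and
#' PD by two-point inversion from the minimal-TE PD-weighted and
#' T1-weighted images ([fit_r1_pd()]), optionally B1-corrected. With
#' `correct_r2star_decay = TRUE` (default) the two first-echo images are
#' divided by `exp(-TE1 * R2*)` using the fitted R2* map before the
#' two-point fit, removing the residual R2* weighting of the minimal-TE
#' images so that noise-free data are recovered exactly.
#'
#' @param data A [multi_echo_flash_set()].
#' @param b1 Optional [b1_map()].
#' @param correct_r2star_decay Logical; extrapolate the first-echo
#'   images to TE = 0 with the fitted R2* map.
#' @param voxel_mm Voxel size recorded in the output maps.
#' @return A [quantitative_maps()] object with an additional `qc`
#'   element (per-stage counts; a `warnings` character vector for
#'   degenerate input).
#' @export
estimate_maps <- function(data, b1 = NULL, correct_r2star_decay = TRUE,
                          voxel_mm = 1) {
  assert_that(inherits(data, "multi_echo_flash_set"),
              "data must be a multi_echo_flash_set")
  mask <- data$mask
  warnings <- character()
  if (!any(mask)) {
    warning("estimate_maps: empty mask; returning empty maps")
    warnings <- c(warnings, "empty mask")
  }
  fr2 <- fit_r2star(data$pdw_volumes, data$pdw_protocol$te_ms, mask)

  te1_pdw <- data$pdw_protocol$te_ms[1]
  te1_t1w <- data$t1w_protocol$te_ms[1]
  pdw1 <- data$pdw_volumes[, , , 1, drop = TRUE]
  t1w1 <- data$t1w_volumes[, , , 1, drop = TRUE]
  if (correct_r2star_decay) {
    dec <- fr2$r2s / .MS_PER_S  # 1/ms
    pdw1 <- pdw1 / exp(-te1_pdw * dec)
    t1w1 <- t1w1 / exp(-te1_t1w * dec)
  }
  f1 <- fit_r1_pd(pdw1, t1w1, data$pdw_protocol, data$t1w_protocol,
                  b1 = b1, mask = mask)

  # joint validity: all three parameters defined
  ok <- is.finite(f1$r1) & is.finite(f1$pd) & is.finite(fr2$r2s) & mask
  r1 <- array(NaN, dim(mask)); pd <- array(NaN, dim(mask))
  r2s <- array(NaN, dim(mask))
  r1[ok] <- f1$r1[ok]; pd[ok] <- f1$pd[ok]; r2s[ok] <- fr2$r2s[ok]
  maps <- quantitative_maps(r1, pd, r2s, ok, voxel_mm = voxel_mm)
  maps$qc <- list(r2star = fr2$qc, r1_pd = f1$qc,
                  n_mask = as.integer(sum(mask)),
                  n_valid = as.integer(sum(ok)),
                  n_nan = as.integer(sum(mask) - sum(ok)),
                  warnings = warnings)
  maps
}
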