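#' @keywords internal
"_PACKAGE"

# ms <-> s conversion for relaxation rates; asserted in tests
.MS_PER_S <- 1000

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("morphosynth_invalid_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop_invalid(msg)
  invisible(TRUE)
}

# FWHM (mm) -> gaussian sigma (mm)
fwhm_to_sigma <- function(fwhm) fwhm / sqrt(8 * log(2))

# deterministic child seeds so pipeline stages do not share a stream;
# kept below 2^31 - 1
derive_seed <- function(seed, stage) {
  (as.numeric(seed) * 1003 + stage * 7919) %% 2147483647
}

#' Separable 3D Gaussian smoothing
#'
#' Convolves a 3D volume with an isotropic Gaussian kernel, applied
#' separably along each axis with replicated (nearest) edge padding.
#'
#' @param x 3D numeric array.
#' @param fwhm_mm Full width at half maximum of the kernel in mm; `0`
#'   returns `x` unchanged.
#' @param voxel_mm Voxel edge length in mm (isotropic grid).
#' @return Smoothed array of the same dimensions.
#' @export
smooth_gaussian3d <- function(x, fwhm_mm, voxel_mm = 1) {
  assert_that(length(dim(x)) == 3, "x must be a 3D array")
  assert_that(fwhm_mm >= 0, "fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(x)
  sigma <- fwhm_to_sigma(fwhm_mm) / voxel_mm  # voxel units
  r <- ceiling(3 * sigma)
  if (r < 1) return(x)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  for (d in 1:3) x <- .smooth_axis(x, k, r, d)
  x
}

.smooth_axis <- function(x, k, r, d) {
  dm <- dim(x)
  perm <- c(d, setdiff(1:3, d))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = dm[d])
  nr <- nrow(m)
  acc <- matrix(0, nr, ncol(m))
  for (j in -r:r) {
    idx <- pmin(pmax(seq_len(nr) + j, 1L), nr)
    acc <- acc + k[j + r + 1] * m[idx, , drop = FALSE]
  }
  aperm(array(acc, dim(xp)), order(perm))
}

# round-half-up; base round() is round-half-even, which would sample the
# 35% cortical depth inconsistently across thicknesses
round_half_up <- function(x) floor(x + 0.5)

same_dim <- function(a, b) identical(dim(a), dim(b))
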