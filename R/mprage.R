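#' MPRAGE signal terms for a given R1
#'
#' Evaluates the intermediate quantities of the MPRAGE steady-state
#' signal for the longitudinal relaxation rate `r1` and a protocol:
#' the apparent relaxation time during the pulse train
#' `T1* = 1 / (R1 - ln(cos alpha) / ES)`, the exponentials
#' `E1 = exp(-TI_pre * R1)`, `E2 = exp(-TD * R1)`,
#' `E3 = exp(-tau / T1*)`, `E4 = exp(-tau / (2 T1*))`, and the R1-driven
#' signal factor sampled at the center of the readout train
#'
#' \deqn{f_{R1} = E_4 \frac{1 - 2E_1 + E_1 E_2}{1 + E_1 E_2 E_3}
#'   + T_1^* R_1 \frac{1 + E_1 E_2 E_3 - E_4 - E_4 E_1 E_2}
#'                    {1 + E_1 E_2 E_3}}
#'
#' where `T1* R1` is the train-driven steady-state magnetization
#' `M0*/M0`. The expression follows from the inversion - recovery -
#' pulse-train - delay cycle in steady state with continuous apparent
#' relaxation during the train.
#'
#' @param r1 R1 values in 1/s (scalar, vector or array); must be
#'   positive (non-positive values yield `NaN` and a QC count).
#' @param protocol An [mprage_protocol()].
#' @return List of class `mprage_signal_terms` with elements `t1_star_ms`,
#'   `e1`, `e2`, `e3`, `e4`, `f_r1` (same shape as `r1`) and `qc`.
#' @examples
#' st <- signal_terms(1.0, mprage_protocol())
#' st$t1_star_ms  # about 444.2
#' @export
signal_terms <- function(r1, protocol) {
  assert_that(inherits(protocol, "mprage_protocol"),
              "protocol must be an mprage_protocol")
  a <- protocol$flip_deg * pi / 180
  assert_that(cos(a) > 0, "cos(alpha) must be positive")
  r1_ms <- r1 / .MS_PER_S
  bad <- !is.finite(r1_ms) | r1_ms <= 0
  r1w <- r1_ms
  r1w[bad] <- NA_real_

  t1s <- 1 / (r1w - log(cos(a)) / protocol$es_ms)
  e1 <- exp(-protocol$ti_pre_ms * r1w)
  e2 <- exp(-protocol$td_ms * r1w)
  e3 <- exp(-protocol$tau_ms / t1s)
  e4 <- exp(-protocol$tau_ms / (2 * t1s))
  den <- 1 + e1 * e2 * e3
  f <- e4 * (1 - 2 * e1 + e1 * e2) / den +
    t1s * r1w * (1 + e1 * e2 * e3 - e4 - e4 * e1 * e2) / den
  f[bad] <- NaN
  out <- list(t1_star_ms = t1s, e1 = e1, e2 = e2, e3 = e3, e4 = e4,
              f_r1 = f,
              qc = list(n_nonpositive_r1 = as.integer(sum(bad))))
  class(out) <- "mprage_signal_terms"
  out
}

.MODALITY_SETS <- list(
  r1       = c("R1"),
  r1pd     = c("R1", "PD"),
  r1r2s    = c("R1", "R2s"),
  r1pdr2s  = c("R1", "PD", "R2s")
)

modality_tag <- function(modality) {
  for (tag in names(.MODALITY_SETS))
    if (setequal(modality, .MODALITY_SETS[[tag]])) return(tag)
  stop_invalid("unknown modality subset: ", paste(modality, collapse = ","))
}

#' Synthesize an MPRAGE T1-weighted image from quantitative maps
#'
#' Computes `intensity = sin(alpha) * f_R1 * f_PD * f_R2s` voxelwise,
#' where `f_PD = PD` and `f_R2s = exp(-TE * R2*)`, with every factor
#' *not* selected by `modality` replaced by exactly 1. `modality` must
#' contain `"R1"`: the image types are `{R1}`, `{R1,PD}`, `{R1,R2s}`
#' and `{R1,PD,R2s}`. Non-finite map values propagate `NaN`.
#'
#' @param maps A [quantitative_maps()] object.
#' @param protocol An [mprage_protocol()].
#' @param modality Character subset of `c("R1", "PD", "R2s")`, or one of
#'   the tags `"r1"`, `"r1pd"`, `"r1r2s"`, `"r1pdr2s"`.
#' @return Object of class `synthetic_image` with fields `intensity`
#'   (3D array, arbitrary units), `modality`, `tag`, `protocol`,
#'   `voxel_mm`.
#' @export
synthesize <- function(maps, protocol, modality = c("R1", "PD", "R2s")) {
  assert_that(inherits(maps, "quantitative_maps"),
              "maps must be a quantitative_maps object")
  if (length(modality) == 1 && modality %in% names(.MODALITY_SETS))
    modality <- .MODALITY_SETS[[modality]]
  assert_that(all(modality %in% c("R1", "PD", "R2s")),
              "modality must be a subset of R1, PD, R2s")
  assert_that("R1" %in% modality,
              "every synthetic image type includes R1")
  st <- signal_terms(maps$r1, protocol)
  intensity <- sin(protocol$flip_deg * pi / 180) * st$f_r1
  if ("PD" %in% modality) intensity <- intensity * maps$pd
  if ("R2s" %in% modality)
    intensity <- intensity * exp(-protocol$te_ms * maps$r2s / .MS_PER_S)
  structure(list(intensity = intensity, modality = sort(modality),
                 tag = modality_tag(modality), protocol = protocol,
                 voxel_mm = maps$voxel_mm),
            class = "synthetic_image")
}

#' @export
print.synthetic_image <- function(x, ...) {
  dm <- dim(x$intensity)
  cat(sprintf("Synthetic MPRAGE T1w image {%s}: %d x %d x %d voxels\n",
              paste(x$modality, collapse = ","), dm[1], dm[2], dm[3]))
  invisible(x)
}

#' Synthesize the full set of four image types
#'
#' Fan-out of [synthesize()] over the four parameter subsets
#' `{R1}`, `{R1,PD}`, `{R1,R2s}`, `{R1,PD,R2s}`.
#'
#' @inheritParams synthesize
#' @return Named list (`r1`, `r1pd`, `r1r2s`, `r1pdr2s`) of
#'   `synthetic_image` objects sharing grid and protocol.
#' @export
synthesize_set <- function(maps, protocol) {
  lapply(.MODALITY_SETS, function(m) synthesize(maps, protocol, m))
}

#' Discrete Bloch-train reference simulation of the MPRAGE signal
#'
#' Independent validation oracle for [signal_terms()]: simulates the
#' MPRAGE cycle pulse by pulse (perfect inversion, free recovery, then
#' `n_lines` instantaneous `cos(alpha)` rotations separated by `es_ms`
#' of T1 recovery, then the TD delay), solves the affine one-cycle map
#' for its fixed point, and reads out `sin(alpha) * Mz` just before the
#' pulse at the center of the train. It shares no code with the
#' closed-form expression; differences reflect the continuous-relaxation
#' approximation of the analytic form.
#'
#' @param r1 R1 in 1/s (vectorized).
#' @param protocol An [mprage_protocol()].
#' @return Simulated signal (same scale as `sin(alpha) * f_r1`).
#' @export
mprage_bloch_reference <- function(r1, protocol) {
  assert_that(inherits(protocol, "mprage_protocol"),
              "protocol must be an mprage_protocol")
  a <- protocol$flip_deg * pi / 180
  vapply(r1, function(r1s) {
    r1_ms <- r1s / .MS_PER_S
    ca <- cos(a)
    e_es <- exp(-protocol$es_ms * r1_ms)
    e_ti <- exp(-protocol$ti_pre_ms * r1_ms)
    e_td <- exp(-protocol$td_ms * r1_ms)
    # track Mz as affine function of the cycle-start value: Mz = A*m0 + B
    A <- -1; B <- 0                       # inversion
    A <- A * e_ti; B <- B * e_ti + (1 - e_ti)
    k_center <- floor(protocol$n_lines / 2) + 1  # first pulse at/after tau/2
    A_c <- NA_real_; B_c <- NA_real_
    for (k in seq_len(protocol$n_lines)) {
      if (k == k_center) { A_c <- A; B_c <- B }
      A <- A * ca; B <- B * ca
      A <- A * e_es; B <- B * e_es + (1 - e_es)
    }
    A <- A * e_td; B <- B * e_td + (1 - e_td)
    m_ss <- B / (1 - A)                   # steady state at cycle start
    sin(a) * (A_c * m_ss + B_c)
  }, numeric(1))
}
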