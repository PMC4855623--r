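#' Quantitative parameter maps
#'
#' Container for co-registered voxel maps of the longitudinal relaxation
#' rate R1 (1/s), proton density PD (arbitrary units, free water of the
#' phantom normalized to 1) and the effective transverse relaxation rate
#' R2* (1/s), plus a brain mask. Inside the mask R1 and PD must be
#' positive and R2* non-negative; `NaN` is allowed only outside the mask.
#'
#' @param r1 3D array, R1 in 1/s.
#' @param pd 3D array, PD in arbitrary units.
#' @param r2s 3D array, R2* in 1/s.
#' @param mask 3D logical array.
#' @param voxel_mm Isotropic voxel size in mm.
#' @return Object of class `quantitative_maps`.
#' @export
quantitative_maps <- function(r1, pd, r2s, mask, voxel_mm = 1) {
  assert_that(length(dim(r1)) == 3, "maps must be 3D arrays")
  assert_that(same_dim(r1, pd) && same_dim(r1, r2s) && same_dim(r1, mask),
              "r1, pd, r2s and mask must share one voxel grid")
  mask <- array(as.logical(mask), dim(mask))
  inside <- mask & !is.na(mask)
  if (any(inside)) {
    assert_that(all(is.finite(r1[inside])) && all(r1[inside] > 0),
                "r1 must be positive and finite inside the mask")
    assert_that(all(is.finite(pd[inside])) && all(pd[inside] > 0),
                "pd must be positive and finite inside the mask")
    assert_that(all(is.finite(r2s[inside])) && all(r2s[inside] >= 0),
                "r2s must be non-negative and finite inside the mask")
  }
  structure(list(r1 = r1, pd = pd, r2s = r2s, mask = mask,
                 voxel_mm = voxel_mm),
            class = "quantitative_maps")
}

#' @export
print.quantitative_maps <- function(x, ...) {
  dm <- dim(x$r1)
  n <- sum(x$mask)
  cat(sprintf("Quantitative maps (R1, PD, R2*): %d x %d x %d voxels at %g mm, %d in mask\n",
              dm[1], dm[2], dm[3], x$voxel_mm, n))
  if (n > 0)
    cat(sprintf("  R1 [%0.3g, %0.3g] 1/s; PD [%0.3g, %0.3g]; R2* [%0.3g, %0.3g] 1/s\n",
                min(x$r1[x$mask]), max(x$r1[x$mask]),
                min(x$pd[x$mask]), max(x$pd[x$mask]),
                min(x$r2s[x$mask]), max(x$r2s[x$mask])))
  invisible(x)
}

#' B1 transmit field map
#'
#' Relative flip-angle factor (achieved / nominal), 1.0 at nominal.
#'
#' @param relative_flip_factor 3D array with values in (0, 2].
#' @return Object of class `b1_map`.
#' @export
b1_map <- function(relative_flip_factor) {
  assert_that(length(dim(relative_flip_factor)) == 3, "B1 map must be 3D")
  assert_that(all(relative_flip_factor > 0 & relative_flip_factor <= 2),
              "B1 relative flip factors must lie in (0, 2]")
  structure(list(relative_flip_factor = relative_flip_factor), class = "b1_map")
}

#' Dual-flip-angle multi-echo FLASH dataset
#'
#' Bundles the PD-weighted and T1-weighted multi-echo stacks (4D arrays,
#' x-y-z-echo) with their protocols and a mask, validating that the echo
#' dimension matches the protocol and that all volumes share a grid.
#'
#' @param pdw_volumes,t1w_volumes 4D signal arrays.
#' @param pdw_protocol,t1w_protocol [flash_protocol()] objects.
#' @param mask 3D logical array.
#' @return Object of class `multi_echo_flash_set`.
#' @export
multi_echo_flash_set <- function(pdw_volumes, t1w_volumes,
                                 pdw_protocol, t1w_protocol, mask) {
  assert_that(inherits(pdw_protocol, "flash_protocol") &&
                inherits(t1w_protocol, "flash_protocol"),
              "protocols must be flash_protocol objects")
  assert_that(length(dim(pdw_volumes)) == 4 && length(dim(t1w_volumes)) == 4,
              "echo stacks must be 4D (x, y, z, echo)")
  assert_that(dim(pdw_volumes)[4] == length(pdw_protocol$te_ms),
              "PDw echo dimension must match pdw_protocol$te_ms")
  assert_that(dim(t1w_volumes)[4] == length(t1w_protocol$te_ms),
              "T1w echo dimension must match t1w_protocol$te_ms")
  assert_that(identical(dim(pdw_volumes)[1:3], dim(t1w_volumes)[1:3]) &&
                identical(dim(pdw_volumes)[1:3], dim(mask)),
              "spatial grids of volumes and mask must be identical")
  structure(list(pdw_volumes = pdw_volumes, t1w_volumes = t1w_volumes,
                 pdw_protocol = pdw_protocol, t1w_protocol = t1w_protocol,
                 mask = array(as.logical(mask), dim(mask))),
            class = "multi_echo_flash_set")
}

#' Normalize PD to the CSF anchor
#'
#' Rescales the PD map so that the median PD inside a CSF reference
#' region equals 1 (free water). PD otherwise stays in arbitrary
#' units proportional to the acquired signal scale.
#'
#' @param maps A [quantitative_maps()].
#' @param csf_mask Logical 3D array marking reference CSF voxels.
#' @return The maps with rescaled `pd`.
#' @export
normalize_pd_csf <- function(maps, csf_mask) {
  assert_that(inherits(maps, "quantitative_maps"), "maps required")
  assert_that(same_dim(maps$pd, csf_mask), "csf_mask grid must match maps")
  ref <- maps$pd[csf_mask & maps$mask]
  ref <- ref[is.finite(ref)]
  assert_that(length(ref) > 0, "no finite PD values in the CSF reference")
  maps$pd <- maps$pd / stats::median(ref)
  maps
}
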