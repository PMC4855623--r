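#' Default tissue parameter table
#'
#' Per-class R1 (1/s), PD (free water = 1) and R2* (1/s) used by the
#' digital phantom. The values are order-of-magnitude 3 T literature
#' values chosen to produce the contrast regimes of interest: white
#' matter (high R1, low PD), cortical gray matter, a "sensorimotor-like"
#' heavily myelinated gray-matter region (high R1, PD ratio to WM closer
#' to 1), iron-rich deep-nucleus gray matter (high R2*), and CSF (PD
#' anchor at 1, maximal by construction).
#'
#' @return A data.frame with columns `name`, `label`, `r1`, `pd`, `r2s`.
#' @export
tissue_table <- function() {
  data.frame(
    name  = c("wm", "cortical_gm", "sensorimotor_gm", "deep_nucleus", "csf"),
    label = 1:5,
    r1    = c(1.05, 0.72, 0.85, 0.95, 0.24),
    pd    = c(0.69, 0.83, 0.78, 0.75, 1.00),
    r2s   = c(21,   16,   21,   45,   1),
    stringsAsFactors = FALSE
  )
}

validate_tissue_table <- function(tissues) {
  need <- c("name", "label", "r1", "pd", "r2s")
  assert_that(all(need %in% names(tissues)),
              "tissue table needs columns name, label, r1, pd, r2s")
  assert_that(all(tissues$r1 > 0) && all(tissues$pd > 0) && all(tissues$r2s > 0),
              "tissue parameters must be positive")
  icsf <- which(tissues$name == "csf")
  assert_that(length(icsf) == 1 && all(tissues$pd[-icsf] < tissues$pd[icsf]),
              "CSF must have the maximal PD (normalization anchor)")
  invisible(tissues)
}

#' Phantom geometry
#'
#' A brain-like slab phantom on an isotropic grid: a rectangular white
#' matter core, a cortical gray-matter slab of configurable thickness on
#' its upper (+z) face with a planar GM-WM border whose normal is the z
#' axis, a "sensorimotor-like" sub-slab occupying the lower-x half of
#' the slab, two spherical iron-rich nuclei embedded in the WM core, and
#' CSF filling the remainder. A brain mask (tissue plus a thin CSF rim)
#' is provided for analysis.
#'
#' @param shape Integer vector of 3 voxel counts (default 64^3).
#' @param voxel_mm Isotropic voxel size in mm.
#' @param slab_thickness_vox Thickness of the GM slab in voxels
#'   (default 8).
#' @param margin_vox In-plane margin of the tissue block from the volume
#'   edge (default 8).
#' @param nucleus_radius_vox Radius of each deep nucleus (default 5).
#' @return Object of class `phantom_geometry` describing all regions in
#'   1-based voxel indices, including `border_wm_z` (last WM plane of
#'   the slab boundary) and the boundary-site footprint.
#' @export
phantom_geometry <- function(shape = c(64, 64, 64), voxel_mm = 1,
                             slab_thickness_vox = 8, margin_vox = 8,
                             nucleus_radius_vox = 5) {
  shape <- as.integer(shape)
  assert_that(length(shape) == 3 && all(shape >= 24),
              "shape must be 3 voxel counts, each >= 24")
  assert_that(slab_thickness_vox >= 2, "slab must be at least 2 voxels thick")
  m <- as.integer(margin_vox)
  xr <- c(m + 1L, shape[1] - m)
  yr <- c(m + 1L, shape[2] - m)
  zmax_wm <- as.integer(round(shape[3] * 0.625))
  zr_wm <- c(m + 1L, zmax_wm)
  zr_gm <- c(zmax_wm + 1L, zmax_wm + as.integer(slab_thickness_vox))
  assert_that(zr_gm[2] < shape[3] - 2,
              "slab does not fit: reduce slab_thickness_vox or margin_vox")
  zmid <- as.integer(round(mean(zr_wm)))
  x3 <- round(xr[1] + diff(xr) / 3)
  x23 <- round(xr[1] + 2 * diff(xr) / 3)
  structure(list(
    shape = shape, voxel_mm = voxel_mm,
    xr = xr, yr = yr, zr_wm = zr_wm, zr_gm = zr_gm,
    border_wm_z = zr_wm[2],
    slab_thickness_vox = as.integer(slab_thickness_vox),
    sm_x = c(xr[1], as.integer(round(mean(xr)))),  # sensorimotor-like half
    nucleus_centers = rbind(c(x3, round(mean(yr)), zmid),
                            c(x23, round(mean(yr)), zmid)),
    nucleus_radius_vox = nucleus_radius_vox
  ), class = "phantom_geometry")
}

.sphere_idx <- function(shape, center, radius) {
  co <- arrayInd(seq_len(prod(shape)), shape)
  which((co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 +
          (co[, 3] - center[3])^2 <= radius^2)
}

#' Label volume of a phantom geometry
#'
#' @param geometry A [phantom_geometry()].
#' @return Integer 3D array with labels matching [tissue_table()]:
#'   1 WM, 2 cortical GM, 3 sensorimotor-like GM, 4 deep nucleus, 5 CSF.
#' @export
phantom_labels <- function(geometry) {
  g <- geometry
  lab <- array(5L, g$shape)
  lab[g$xr[1]:g$xr[2], g$yr[1]:g$yr[2], g$zr_wm[1]:g$zr_wm[2]] <- 1L
  lab[g$xr[1]:g$xr[2], g$yr[1]:g$yr[2], g$zr_gm[1]:g$zr_gm[2]] <- 2L
  lab[g$sm_x[1]:g$sm_x[2], g$yr[1]:g$yr[2], g$zr_gm[1]:g$zr_gm[2]] <- 3L
  for (i in seq_len(nrow(g$nucleus_centers))) {
    idx <- .sphere_idx(g$shape, g$nucleus_centers[i, ], g$nucleus_radius_vox)
    assert_that(all(lab[idx] == 1L),
                "nucleus overlaps a non-WM region; adjust geometry")
    lab[idx] <- 4L
  }
  lab
}

#' Brain mask for a phantom geometry
#'
#' Tissue block plus a rim of CSF of `rim_vox` voxels, the analysis
#' analogue of a skull-stripped brain mask.
#'
#' @param geometry A [phantom_geometry()].
#' @param rim_vox Rim width in voxels.
#' @return Logical 3D array.
#' @export
phantom_brain_mask <- function(geometry, rim_vox = 2) {
  g <- geometry
  m <- array(FALSE, g$shape)
  r <- as.integer(rim_vox)
  m[max(1, g$xr[1] - r):min(g$shape[1], g$xr[2] + r),
    max(1, g$yr[1] - r):min(g$shape[2], g$yr[2] + r),
    max(1, g$zr_wm[1] - r):min(g$shape[3], g$zr_gm[2] + 2L * r)] <- TRUE
  m
}

#' Build ground-truth quantitative maps for a phantom
#'
#' Fills the labeled geometry with the per-tissue parameter values,
#' optionally adding within-tissue Gaussian heterogeneity
#' (multiplicative, truncated to stay positive). Deterministic given
#' `seed`.
#'
#' @param geometry A [phantom_geometry()].
#' @param tissues Tissue parameter table, see [tissue_table()].
#' @param heterogeneity_sd Within-tissue relative standard deviation
#'   (0 = piecewise constant).
#' @param seed Integer seed for the heterogeneity draw.
#' @return List of class `phantom` with `maps` ([quantitative_maps()],
#'   mask = brain mask), `labels`, `geometry`, `tissues`.
#' @export
build_phantom <- function(geometry = phantom_geometry(),
                          tissues = tissue_table(),
                          heterogeneity_sd = 0, seed = 1) {
  validate_tissue_table(tissues)
  lab <- phantom_labels(geometry)
  look <- function(col) {
    v <- tissues[[col]][match(as.vector(lab), tissues$label)]
    array(v, geometry$shape)
  }
  r1 <- look("r1"); pd <- look("pd"); r2s <- look("r2s")
  if (heterogeneity_sd > 0) {
    set.seed(as.integer(seed))
    n <- prod(geometry$shape)
    jitter <- function(x) {
      f <- 1 + stats::rnorm(n, 0, heterogeneity_sd)
      x * array(pmax(f, 0.05), geometry$shape)
    }
    r1 <- jitter(r1); pd <- jitter(pd); r2s <- jitter(r2s)
  }
  mask <- phantom_brain_mask(geometry)
  structure(list(maps = quantitative_maps(r1, pd, r2s, mask,
                                          voxel_mm = geometry$voxel_mm),
                 labels = lab, geometry = geometry, tissues = tissues,
                 heterogeneity_sd = heterogeneity_sd, seed = seed),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Digital brain phantom: %s voxels, slab thickness %d vox, %d tissue classes\n",
              paste(x$geometry$shape, collapse = " x "),
              x$geometry$slab_thickness_vox, nrow(x$tissues)))
  invisible(x)
}

#' Spoiled gradient-echo steady-state signal (Ernst equation)
#'
#' `S = PD sin(a_eff) (1 - E1) / (1 - cos(a_eff) E1) exp(-TE R2*)` with
#' `E1 = exp(-TR R1)`; the forward model of the FLASH acquisitions.
#'
#' @param r1 R1 in 1/s; `pd` proton density; `r2s` R2* in 1/s
#'   (vectorized, common shapes).
#' @param pd,r2s See `r1`.
#' @param tr_ms,te_ms,flip_deg Acquisition parameters.
#' @param b1_factor Relative flip-angle factor (1 = nominal).
#' @return Signal in the units of `pd`.
#' @export
flash_signal <- function(r1, pd, r2s, tr_ms, te_ms, flip_deg, b1_factor = 1) {
  a <- flip_deg * pi / 180 * b1_factor
  e1 <- exp(-tr_ms * r1 / .MS_PER_S)
  pd * sin(a) * (1 - e1) / (1 - cos(a) * e1) * exp(-te_ms * r2s / .MS_PER_S)
}

#' Simulate a multi-echo FLASH acquisition from quantitative maps
#'
#' Forward model for the mapping acquisitions: the Ernst steady-state
#' signal at each echo time with optional B1 modulation of the flip
#' angle and additive Gaussian noise, independent across voxels and
#' echoes. `noise_sigma` is expressed as a fraction of the maximum
#' noise-free signal in the stack. Deterministic given `seed`.
#'
#' @param maps A [quantitative_maps()].
#' @param protocol A [flash_protocol()].
#' @param b1 Optional [b1_map()].
#' @param noise_sigma Relative noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return 4D array (x, y, z, echo).
#' @export
simulate_flash <- function(maps, protocol, b1 = NULL, noise_sigma = 0,
                           seed = 1) {
  assert_that(inherits(maps, "quantitative_maps"), "maps required")
  assert_that(inherits(protocol, "flash_protocol"), "flash protocol required")
  assert_that(noise_sigma >= 0, "noise_sigma must be non-negative")
  assert_that(all(protocol$te_ms < 1000), "echo times outside physical range")
  dm <- dim(maps$r1)
  b1f <- if (is.null(b1)) 1 else b1$relative_flip_factor
  ne <- length(protocol$te_ms)
  out <- array(NA_real_, c(dm, ne))
  for (e in seq_len(ne)) {
    out[, , , e] <- flash_signal(maps$r1, maps$pd, maps$r2s,
                                 protocol$tr_ms, protocol$te_ms[e],
                                 protocol$flip_deg, b1f)
  }
  # outside-mask voxels carry NaN maps; give them zero signal (air)
  out[!is.finite(out)] <- 0
  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    s <- noise_sigma * max(out)
    out <- out + array(stats::rnorm(length(out), 0, s), dim(out))
  }
  out
}

#' Smooth multiplicative B1 transmit field
#'
#' Low-order cosine bias field spanning `[1 - amplitude, 1 + amplitude]`
#' across the volume, with smoothly varying orientation drawn from the
#' seed. Amplitude 0 gives a uniform field of 1.
#'
#' @param geometry A [phantom_geometry()].
#' @param amplitude Relative amplitude in `[0, 1)`.
#' @param seed Integer seed for the field orientation phase.
#' @return A [b1_map()].
#' @export
make_b1_field <- function(geometry, amplitude = 0.1, seed = 1) {
  assert_that(amplitude >= 0 && amplitude < 1, "amplitude must be in [0, 1)")
  shape <- geometry$shape
  if (amplitude == 0) return(b1_map(array(1, shape)))
  set.seed(as.integer(seed))
  ph <- stats::runif(3, 0, 2 * pi)
  ax <- seq(0, pi, length.out = shape[1])
  ay <- seq(0, pi, length.out = shape[2])
  az <- seq(0, pi, length.out = shape[3])
  fx <- cos(ax + ph[1]); fy <- cos(ay + ph[2]); fz <- cos(az + ph[3])
  f <- outer(outer(fx, fy, `+`), fz, `+`) / 3  # in [-1, 1]
  b1_map(1 + amplitude * f)
}

#' Cohort specification
#'
#' Describes a simulated multi-subject cohort with age- and
#' sex-structured tissue parameters: for subject i and tissue class c,
#' `param = base * (1 + slope * (age - mean age) + quad * (age - mean
#' age)^2 + subject effect)`, with the subject effect drawn once per
#' subject and parameter as Gaussian with `between_subject_sd`. Slopes
#' are relative (per year and per year^2). Defaults emulate a healthy
#' ageing cohort of 120 adults aged 18-78 with a mild linear R1 decline
#' in gray matter; PD and R2* trends are off unless requested.
#'
#' @param n_subjects Number of subjects (>= 2; default 120).
#' @param age_range Two ages in years (default c(18, 78)); ages are
#'   drawn uniformly.
#' @param slopes Named list of per-year relative slopes, entries named
#'   `<param>_<tissue>` (e.g. `r1_cortical_gm = -0.002`); tissues not
#'   named keep their base value.
#' @param quad_slopes Same structure, per-year-squared (mean-centred age
#'   squared).
#' @param between_subject_sd Relative between-subject SD (default 0.02).
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 120, age_range = c(18, 78),
                        slopes = list(r1_cortical_gm = -0.002,
                                      r1_sensorimotor_gm = -0.002),
                        quad_slopes = list(),
                        between_subject_sd = 0.02, seed = 1) {
  assert_that(n_subjects >= 2, "a cohort needs at least 2 subjects")
  assert_that(length(age_range) == 2 && age_range[1] < age_range[2],
              "age_range must be increasing")
  structure(list(n_subjects = as.integer(n_subjects),
                 age_range = as.numeric(age_range),
                 slopes = slopes, quad_slopes = quad_slopes,
                 between_subject_sd = between_subject_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a simulated ageing cohort
#'
#' Draws ages and sexes, applies the age model of [cohort_spec()] to the
#' tissue parameter table of each subject, and returns per-subject
#' parameter tables plus the ground-truth effect sizes for recovery
#' tests. Maps for a subject are built lazily via
#' [subject_phantom()] to keep memory bounded.
#'
#' @param spec A [cohort_spec()].
#' @param geometry A [phantom_geometry()].
#' @param tissues Base tissue table.
#' @return Object of class `cohort`: data.frame `subjects` (subject,
#'   age, age_c, sex), list `tissue_tables`, the centred-age mean, and
#'   the truth (`spec`).
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            geometry = phantom_geometry(),
                            tissues = tissue_table()) {
  validate_tissue_table(tissues)
  set.seed(spec$seed)
  n <- spec$n_subjects
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  sex <- rep(c("m", "f"), length.out = n)[sample.int(n)]
  age_c <- age - mean(age)
  key <- function(param, tis) paste0(param, "_", tis)
  tabs <- vector("list", n)
  for (i in seq_len(n)) {
    ti <- tissues
    for (param in c("r1", "pd", "r2s")) {
      for (j in seq_len(nrow(ti))) {
        k <- key(param, ti$name[j])
        sl <- spec$slopes[[k]] %||% 0
        qd <- spec$quad_slopes[[k]] %||% 0
        noise <- if (spec$between_subject_sd > 0)
          stats::rnorm(1, 0, spec$between_subject_sd) else 0
        ti[[param]][j] <- ti[[param]][j] *
          (1 + sl * age_c[i] + qd * age_c[i]^2 + noise)
      }
    }
    tabs[[i]] <- ti
  }
  structure(list(subjects = data.frame(subject = seq_len(n), age = age,
                                       age_c = age_c, sex = sex,
                                       stringsAsFactors = FALSE),
                 tissue_tables = tabs, mean_age = mean(age),
                 geometry = geometry, base_tissues = tissues, spec = spec),
            class = "cohort")
}

#' Ground-truth phantom for one cohort subject
#'
#' @param cohort A [generate_cohort()] result.
#' @param i Subject index.
#' @param heterogeneity_sd Within-tissue heterogeneity, as in
#'   [build_phantom()].
#' @return A `phantom` for subject `i` (seeded per subject).
#' @export
subject_phantom <- function(cohort, i, heterogeneity_sd = 0) {
  assert_that(inherits(cohort, "cohort"), "cohort required")
  build_phantom(cohort$geometry, cohort$tissue_tables[[i]],
                heterogeneity_sd = heterogeneity_sd,
                seed = derive_seed(cohort$spec$seed, 100 + i))
}
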