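#' Pipeline run configuration
#'
#' One serializable object holding everything a full run needs: the
#' seed, the phantom geometry and tissue table, the FLASH and MPRAGE
#' protocols, acquisition noise, the modality list, morphometry
#' settings, and an optional cohort block. The resolved configuration
#' is written beside the outputs of every run.
#'
#' @param seed Master seed; all stage seeds are derived from it.
#' @param geometry [phantom_geometry()] arguments as a list, or a
#'   ready-made object.
#' @param tissues Tissue table (defaults to [tissue_table()]).
#' @param flash_noise_sigma Relative noise of the simulated FLASH
#'   acquisitions.
#' @param b1_amplitude Amplitude of the simulated transmit field; the
#'   generated B1 map is also passed to the map fitter.
#' @param mprage MPRAGE protocol ([mprage_protocol()] or argument
#'   list).
#' @param modalities Modality tags to synthesize.
#' @param morph_noise_sigma,morph_smooth_fwhm_mm Morphometry proxy
#'   settings (see [classify_and_measure()]).
#' @param cohort Optional [cohort_spec()] (or argument list) enabling
#'   the cohort + GLM stage; `NULL` skips it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       geometry = list(),
                       tissues = tissue_table(),
                       flash_noise_sigma = 0.01,
                       b1_amplitude = 0,
                       mprage = list(),
                       modalities = c("r1", "r1pd", "r1r2s", "r1pdr2s"),
                       morph_noise_sigma = 0.01,
                       morph_smooth_fwhm_mm = 2,
                       cohort = NULL) {
  geom <- if (inherits(geometry, "phantom_geometry")) geometry
          else do.call(phantom_geometry, geometry)
  mpr <- if (inherits(mprage, "mprage_protocol")) mprage
         else do.call(mprage_protocol, mprage)
  coh <- if (is.null(cohort) || inherits(cohort, "cohort_spec")) cohort
         else do.call(cohort_spec, cohort)
  assert_that(all(modalities %in% c("r1", "r1pd", "r1r2s", "r1pdr2s")),
              "unknown modality tag")
  structure(list(seed = as.integer(seed), geometry = geom, tissues = tissues,
                 flash_noise_sigma = flash_noise_sigma,
                 b1_amplitude = b1_amplitude, mprage = mpr,
                 modalities = modalities,
                 morph_noise_sigma = morph_noise_sigma,
                 morph_smooth_fwhm_mm = morph_smooth_fwhm_mm,
                 cohort = coh),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments (`seed`,
#' `geometry`, `flash_noise_sigma`, `b1_amplitude`, `mprage`,
#' `modalities`, `morph_noise_sigma`, `morph_smooth_fwhm_mm`,
#' `cohort`); unknown keys raise an error naming the offender.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "tissues")
  bad <- setdiff(names(y), known)
  assert_that(length(bad) == 0,
              paste0("unknown configuration key(s): ", paste(bad, collapse = ", ")))
  do.call(run_config, y)
}

#' Run the full phantom-to-GLM pipeline
#'
#' Executes, in order: phantom construction, simulated dual-flip-angle
#' multi-echo FLASH acquisition (with optional B1 field), map
#' estimation, synthesis of the requested image types, boundary
#' contrast analysis with the closed-form contrast-change prediction,
#' morphometry of every image type, and (when a cohort is configured)
#' the cohort simulation with the modality x age interaction GLM.
#' All outputs are written under `out_dir` together with the resolved
#' configuration and a manifest listing every artifact with its MD5
#' checksum; a rerun with the same configuration is bit-identical.
#' Any stage failure aborts with a stage-named error after writing the
#' partial manifest.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return The manifest (named list of files and checksums), invisibly;
#'   the in-memory stage results are attached as attribute `results`.
#' @export
run_all <- function(config, out_dir) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  results <- list()
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      write_json_report(list(failed_stage = name, files = manifest),
                        file.path(out_dir, "manifest.json"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  add <- function(path) {
    manifest[[basename(path)]] <<- unname(tools::md5sum(path))
    path
  }
  cfg_path <- file.path(out_dir, "config.json")
  write_json_report(.serialize_config(config), cfg_path)
  add(cfg_path)

  phants <- stage("phantom", function() {
    ph <- build_phantom(config$geometry, config$tissues,
                        seed = derive_seed(config$seed, 1))
    write_volume_nifti(ph$labels, file.path(out_dir, "labels.nii"),
                       config$geometry$voxel_mm)
    add(file.path(out_dir, "labels.nii"))
    ph
  })
  results$phantom <- phants

  flash <- stage("fit-maps", function() {
    b1 <- if (config$b1_amplitude > 0)
      make_b1_field(config$geometry, config$b1_amplitude,
                    derive_seed(config$seed, 2)) else NULL
    pdw <- simulate_flash(phants$maps, flash_protocol_defaults("pdw"), b1,
                          config$flash_noise_sigma, derive_seed(config$seed, 3))
    t1w <- simulate_flash(phants$maps, flash_protocol_defaults("t1w"), b1,
                          config$flash_noise_sigma, derive_seed(config$seed, 4))
    fset <- multi_echo_flash_set(pdw, t1w, flash_protocol_defaults("pdw"),
                                 flash_protocol_defaults("t1w"), phants$maps$mask)
    maps <- estimate_maps(fset, b1 = b1, voxel_mm = config$geometry$voxel_mm)
    write_maps(maps, file.path(out_dir, "maps"))
    for (f in list.files(file.path(out_dir, "maps"), full.names = TRUE)) add(f)
    maps
  })
  results$maps <- flash

  images <- stage("synthesize", function() {
    imgs <- lapply(config$modalities, function(tag)
      synthesize(flash, config$mprage, tag))
    names(imgs) <- config$modalities
    for (tag in config$modalities) {
      p <- file.path(out_dir, paste0("t1w_", tag, ".nii"))
      write_volume_nifti(imgs[[tag]]$intensity, p, config$geometry$voxel_mm)
      add(p)
    }
    imgs
  })
  results$images <- images

  contrast <- stage("contrast", function() {
    tabs <- lapply(images, function(im)
      sample_boundary(im, phants$labels, config$geometry))
    tab <- do.call(rbind, tabs)
    p <- file.path(out_dir, "boundary_contrast.csv")
    utils::write.csv(tab, p, row.names = FALSE)
    add(p)
    pred <- NULL
    if (all(c("r1", "r1pd") %in% names(tabs))) {
      a <- tabs$r1; b <- tabs$r1pd
      r_t1 <- a$gm_int / a$wm_int
      r_pd <- (b$gm_int / b$wm_int) / r_t1
      pred <- data.frame(site_id = a$site_id,
                         delta_measured = a$contrast - b$contrast,
                         delta_derived = predict_contrast_change(r_pd, r_t1, "derived"),
                         delta_printed = predict_contrast_change(r_pd, r_t1, "printed"))
      p2 <- file.path(out_dir, "contrast_change.csv")
      utils::write.csv(pred, p2, row.names = FALSE)
      add(p2)
    }
    list(samples = tabs, prediction = pred)
  })
  results$contrast <- contrast

  morph <- stage("morphometry", function() {
    mask <- phantom_brain_mask(config$geometry)
    reps <- lapply(seq_along(images), function(i)
      classify_and_measure(images[[i]], mask,
                           smooth_fwhm_mm = config$morph_smooth_fwhm_mm,
                           noise_sigma = config$morph_noise_sigma,
                           seed = derive_seed(config$seed, 10 + i),
                           geometry = config$geometry))
    names(reps) <- names(images)
    summary <- lapply(reps, function(r)
      c(as.list(r$volumes_mm3),
        list(mean_thickness_mm = mean(r$thickness_mm, na.rm = TRUE))))
    p <- file.path(out_dir, "morphometry.json")
    write_json_report(summary, p)
    add(p)
    reps
  })
  results$morphometry <- morph

  if (!is.null(config$cohort)) {
    results$glm <- stage("glm", function() {
      res <- cohort_interaction_analysis(config$cohort, config$geometry,
                                         config$tissues,
                                         noise_sigma = config$morph_noise_sigma,
                                         smooth_fwhm_mm = config$morph_smooth_fwhm_mm)
      p <- file.path(out_dir, "glm_interaction.json")
      write_json_report(res[c("interaction_estimate", "interaction_t",
                              "interaction_p", "n_subjects")], p)
      add(p)
      p2 <- file.path(out_dir, "cohort_volumes.csv")
      utils::write.csv(res$data, p2, row.names = FALSE)
      add(p2)
      res
    })
  }

  mpath <- file.path(out_dir, "manifest.json")
  write_json_report(list(files = manifest), mpath)
  structure(invisible(manifest), results = results)
}

.serialize_config <- function(config) {
  list(seed = config$seed,
       geometry = unclass(config$geometry),
       tissues = config$tissues,
       flash_noise_sigma = config$flash_noise_sigma,
       b1_amplitude = config$b1_amplitude,
       mprage = unclass(config$mprage),
       modalities = config$modalities,
       morph_noise_sigma = config$morph_noise_sigma,
       morph_smooth_fwhm_mm = config$morph_smooth_fwhm_mm,
       cohort = if (is.null(config$cohort)) NULL else unclass(config$cohort))
}

#' Cohort modality x age interaction analysis
#'
#' Simulates the configured cohort, computes the apparent GM volume of
#' the `{R1}` and `{R1,PD}` image types for every subject with the
#' morphometry proxy, and fits the paired GLM with subject-mean
#' removal, modality indicators and the modality x centred-age
#' interaction. The one-tailed interaction test asks whether the
#' age-related apparent GM volume difference between the two image
#' types changes with age (the direction is determined by the injected
#' PD trend; the test statistic is returned signed, with a two-and
#' one-tailed p).
#'
#' @param spec A [cohort_spec()].
#' @param geometry,tissues Phantom settings.
#' @param modalities Two modality tags to compare (default
#'   `c("r1", "r1pd")`).
#' @param protocol MPRAGE protocol.
#' @param noise_sigma,smooth_fwhm_mm Morphometry proxy settings.
#' @param direction Hypothesized sign of the age x second-modality
#'   coefficient; `"negative"` (default) tests for a stronger
#'   age-related apparent GM volume loss in the second image type.
#' @return List: `data` (per subject x modality GM volumes),
#'   `interaction_estimate` and `interaction_t` (raw signs of the age x
#'   second-modality coefficient), `interaction_p` (one-tailed in the
#'   hypothesized direction), `interaction_p_two`, `n_subjects`, `fit`.
#' @export
cohort_interaction_analysis <- function(spec, geometry = phantom_geometry(),
                                        tissues = tissue_table(),
                                        modalities = c("r1", "r1pd"),
                                        protocol = mprage_protocol(),
                                        noise_sigma = 0.01,
                                        smooth_fwhm_mm = 2,
                                        direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  cohort <- generate_cohort(spec, geometry, tissues)
  mask <- phantom_brain_mask(geometry)
  n <- spec$n_subjects
  rows <- vector("list", n * length(modalities))
  k <- 0L
  for (i in seq_len(n)) {
    ph <- subject_phantom(cohort, i)
    for (m in modalities) {
      img <- synthesize(ph$maps, protocol, m)
      rep <- classify_and_measure(img, mask,
                                  smooth_fwhm_mm = smooth_fwhm_mm,
                                  noise_sigma = noise_sigma,
                                  seed = derive_seed(spec$seed, 1000 + i))
      k <- k + 1L
      rows[[k]] <- data.frame(subject = i, modality = m,
                              age = cohort$subjects$age[i],
                              sex = cohort$subjects$sex[i],
                              gm_volume_mm3 = unname(rep$volumes_mm3["gm"]))
    }
  }
  dat <- do.call(rbind, rows)
  X <- build_design(dat, terms = c("subject", "modality", "modality_age"))
  fit <- fit_glm(X, dat$gm_volume_mm3)
  cn <- paste0("age_x_", modalities[2])
  sgn <- if (direction == "negative") -1 else 1
  cv <- sgn * as.numeric(rownames(fit$beta) == cn)
  ct <- glm_contrast(fit, cv)
  est <- sgn * ct$estimate
  t_signed <- sgn * ct$t
  p_two <- 2 * stats::pt(-abs(t_signed), df = fit$df)
  list(data = dat, interaction_estimate = est, interaction_t = t_signed,
       interaction_p = ct$p, interaction_p_two = p_two,
       n_subjects = n, fit = fit)
}
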