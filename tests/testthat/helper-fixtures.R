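# Small phantom settings shared across tests: large enough for a clean
# slab boundary and nuclei, small enough for fast EM and smoothing.
small_geometry <- function(shape = c(32, 32, 32)) {
  phantom_geometry(shape = shape, margin_vox = 4,
                   slab_thickness_vox = 6, nucleus_radius_vox = 3)
}

# noise-free dual-flip-angle acquisition of a phantom
simulate_flash_set <- function(ph, noise_sigma = 0, b1 = NULL, seed = 1) {
  pdw_p <- flash_protocol_defaults("pdw")
  t1w_p <- flash_protocol_defaults("t1w")
  pdw <- simulate_flash(ph$maps, pdw_p, b1, noise_sigma, seed = seed)
  t1w <- simulate_flash(ph$maps, t1w_p, b1, noise_sigma, seed = seed + 1)
  multi_echo_flash_set(pdw, t1w, pdw_p, t1w_p, ph$maps$mask)
}

# dilated nucleus neighbourhood mask
nucleus_neighbourhood <- function(geometry, grow = 2) {
  m <- array(FALSE, geometry$shape)
  for (i in seq_len(nrow(geometry$nucleus_centers))) {
    idx <- morphosynth:::.sphere_idx(geometry$shape,
                                     geometry$nucleus_centers[i, ],
                                     geometry$nucleus_radius_vox + grow)
    m[idx] <- TRUE
  }
  m
}
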