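# shared scene/acquisition factories for the tests; unit tests use the
# package defaults unless a smaller or noiseless variant is needed

noiseless_acq <- function(seed = 1L, ...) {
  acquisition_spec(psf_sigma_um = c(0, 0), photon_gain = Inf,
                   read_noise_sd = 0, seed = seed, ...)
}

quiet_acq <- function(seed = 1L, ...) {
  acquisition_spec(photon_gain = 1000, read_noise_sd = 2, seed = seed, ...)
}

# random logical volume for fuzzing morphology / labeling
random_mask <- function(dim3, p = 0.4, seed = 1L) {
  withr::with_seed(seed, array(stats::runif(prod(dim3)) < p, dim3))
}

# ids of non-cytosol objects present in a channel
channel_truth_ids <- function(scene, channel) {
  ob <- scene$objects
  flag <- if (channel == "red") ob$in_red else ob$in_green
  ob$id[flag & ob$kind != "cytosol"]
}

channel_truth_mask <- function(scene, channel) {
  ids <- channel_truth_ids(scene, channel)
  array(scene$label %in% ids, dim(scene$label))
}

# scene whose structures share one intensity level per channel, so the red
# channel is exactly three-level (background / cytosol / bright structures)
# and the clean-limit masks coincide with the ground-truth supports
uniform_spec <- function(seed = 1L, ...) {
  scene_spec(er_intensity = 2, ring_intensity = 2, vesicle_intensity = 2,
             seed = seed, ...)
}
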