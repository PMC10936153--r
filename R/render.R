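# forward optics + detector model for synthetic scenes

# separable Gaussian blur; sigma given per axis in voxels. Each axis is a
# banded-matrix multiply; rows are renormalized at the boundary so flat
# regions stay flat near the edges of the stack.
gaussian_blur3d <- function(a, sigma_vox) {
  blur_axis <- function(mat_n, sigma) {
    n <- mat_n
    K <- stats::dnorm(outer(seq_len(n), seq_len(n), `-`), sd = sigma)
    K[abs(outer(seq_len(n), seq_len(n), `-`)) > ceiling(4 * sigma)] <- 0
    K / rowSums(K)
  }
  d <- dim(a)
  if (sigma_vox[1] > 1e-8) {
    K <- blur_axis(d[1], sigma_vox[1])
    a <- array(K %*% matrix(a, d[1]), d)
  }
  if (sigma_vox[2] > 1e-8) {
    K <- blur_axis(d[2], sigma_vox[2])
    a <- aperm(array(K %*% matrix(aperm(a, c(2, 1, 3)), d[2]),
                     d[c(2, 1, 3)]), c(2, 1, 3))
  }
  if (sigma_vox[3] > 1e-8) {
    K <- blur_axis(d[3], sigma_vox[3])
    a <- aperm(array(K %*% matrix(aperm(a, c(3, 1, 2)), d[3]),
                     d[c(3, 1, 2)]), c(2, 3, 1))
  }
  a
}

# Poisson shot noise + Gaussian read noise, clamped to non-negative counts.
# photon_gain = Inf bypasses the shot-noise stage (noiseless limit).
detect_channel <- function(clean, photon_gain, read_noise_sd) {
  d <- dim(clean)
  out <- if (is.infinite(photon_gain)) {
    clean
  } else {
    array(stats::rpois(length(clean), photon_gain * clean), d)
  }
  if (read_noise_sd > 0)
    out <- out + array(stats::rnorm(length(clean), 0, read_noise_sd), d)
  array(pmax(out, 0), d)
}

#' Render a scene through the acquisition model
#'
#' Produces the two-channel intensity volume a confocal microscope would
#' record for a (static) scene: clean painted intensities, green-to-red
#' bleed-through, Gaussian PSF blur, photobleaching `exp(-k t)` per channel,
#' Poisson shot noise at `photon_gain` photons per unit intensity, and
#' additive Gaussian read noise. With `t_steps > 1` the same scene is imaged
#' repeatedly (bleaching accumulating, fresh noise per frame), giving a 4D
#' (t,z,y,x) volume. Deterministic for fixed scene and acquisition seeds.
#'
#' @param scene a [make_scene()] result.
#' @param acq an [acquisition_spec()].
#' @param t_steps number of frames (>= 1).
#' @param t_offset frame index of the first rendered frame, used when
#'   assembling a time-lapse frame by frame so bleaching continues across
#'   calls; the bleach factor of frame `i` is `exp(-k (t_offset + i - 1))`.
#' @return A [channel_pair_volume()]; intensities are photon counts (or the
#'   clean relative intensities when `photon_gain = Inf`).
#' @export
render_scene <- function(scene, acq, t_steps = 1L, t_offset = 0L) {
  stopifnot(inherits(scene, "ground_truth_scene"),
            inherits(acq, "acquisition_spec"))
  if (!is_count(t_steps) || t_steps < 1L) stopf("t_steps must be >= 1")
  clean <- paint_channels(scene)
  red <- clean$red
  green <- clean$green
  if (acq$bleed_alpha > 0) {
    red <- red + acq$bleed_alpha * clean$green
    if (acq$bleed_symmetric) green <- green + acq$bleed_alpha * clean$red
  }
  vs <- scene$spec$voxel_size_um
  sig <- c(acq$psf_sigma_um[1] / vs[1], acq$psf_sigma_um[2] / vs[2],
           acq$psf_sigma_um[2] / vs[3])
  red <- gaussian_blur3d(red, sig)
  green <- gaussian_blur3d(green, sig)

  frames <- withr::with_seed(acq$seed, {
    lapply(seq_len(t_steps), function(t) {
      tt <- t_offset + t - 1
      list(
        red = detect_channel(red * exp(-acq$bleach_rate[["red"]] * tt),
                             acq$photon_gain, acq$read_noise_sd),
        green = detect_channel(green * exp(-acq$bleach_rate[["green"]] * tt),
                               acq$photon_gain, acq$read_noise_sd)
      )
    })
  })
  if (t_steps == 1L) {
    channel_pair_volume(frames[[1]]$red, frames[[1]]$green, vs)
  } else {
    d <- dim(red)
    r4 <- array(0, c(t_steps, d))
    g4 <- array(0, c(t_steps, d))
    for (t in seq_len(t_steps)) {
      r4[t, , , ] <- frames[[t]]$red
      g4[t, , , ] <- frames[[t]]$green
    }
    channel_pair_volume(r4, g4, vs)
  }
}

#' Simulate a live-cell time-lapse with vesicle motion
#'
#' Convenience wrapper for 4D experiments: the scene evolves by seeded
#' Gaussian vesicle motion between frames ([advance_time()]) while the
#' acquisition model (including cumulative photobleaching and fresh noise
#' per frame) renders each frame. Ground-truth scenes for every frame are
#' returned so tracking and per-frame masks can be scored against truth.
#'
#' @inheritParams render_scene
#' @param motion_sd_um per-axis vesicle step sd in um between frames.
#' @return A list with `pair` (4D [channel_pair_volume()]) and `scenes`
#'   (list of per-frame ground-truth scenes).
#' @export
simulate_timeseries <- function(scene, acq, t_steps, motion_sd_um = 0) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  if (!is_count(t_steps) || t_steps < 2L) stopf("t_steps must be >= 2")
  scenes <- vector("list", t_steps)
  scenes[[1]] <- scene
  for (t in 2:t_steps) {
    scenes[[t]] <- advance_time(scenes[[t - 1]], motion_sd_um,
                                seed = scene$spec$seed + 7919L * t)
  }
  frames <- lapply(seq_len(t_steps), function(t) {
    acq_t <- acq
    acq_t$seed <- acq$seed + 104729L + t
    render_scene(scenes[[t]], acq_t, t_steps = 1L, t_offset = t - 1L)
  })
  d <- dim(frames[[1]]$red)
  r4 <- array(0, c(t_steps, d))
  g4 <- array(0, c(t_steps, d))
  for (t in seq_len(t_steps)) {
    r4[t, , , ] <- frames[[t]]$red
    g4[t, , , ] <- frames[[t]]$green
  }
  list(pair = channel_pair_volume(r4, g4, scene$spec$voxel_size_um),
       scenes = scenes)
}
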