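#' Specify a synthetic two-channel hyphal scene
#'
#' A scene emulates a short stretch of a fungal hypha imaged by confocal
#' microscopy: a cylindrical cell filled with dim cytosolic signal, an axial
#' endoplasmic-reticulum (ER) tube, optional perinuclear rings (the nuclear
#' envelope is continuous with the ER), and sub-micron ER-derived vesicles
#' placed in the cytosol around the tube. Each vesicle carries both
#' fluorophores with probability `coloc_fraction`, otherwise exactly one,
#' so the generator has a known ground-truth degree of colocalization.
#'
#' Geometry is defined in physical micrometres and discretized onto an
#' anisotropic voxel grid (`voxel_size_um`, typically dz > dxy as in a
#' confocal z-stack). The hyphal axis runs along x.
#'
#' @param shape_zyx integer vector (nz, ny, nx), voxels per axis.
#' @param voxel_size_um numeric (dz, dy, dx) voxel spacing in micrometres.
#' @param hypha_radius_um radius of the hyphal cylinder (um).
#' @param er_tube_radius_um radius of the axial ER tube (um).
#' @param n_rings number of perinuclear rings, evenly spaced along the axis.
#' @param ring_radius_um,ring_thickness_um mid-shell radius and full shell
#'   thickness of each perinuclear ring (um).
#' @param n_vesicles number of vesicles to place.
#' @param vesicle_radius_um_range (min, max) vesicle radius in um; vesicles
#'   are sub-micron compartments, so `max` should stay well below 0.5.
#' @param coloc_fraction probability `f` in \[0, 1\] that a vesicle carries
#'   both fluorophores; the realized fraction is recorded in the scene.
#' @param cytosol_level named numeric `c(red = , green = )`, relative
#'   intensity of the diffuse cytosolic signal in each channel (structures
#'   have intensity `er_intensity` / `vesicle_intensity`).
#' @param er_intensity,ring_intensity,vesicle_intensity relative clean
#'   intensities of the labelled structures (unit = vesicle brightness).
#' @param min_gap_um minimal clearance between a vesicle surface and any
#'   other structure. The default (0.3 um) exceeds the largest
#'   centre-to-centre distance of 26-adjacent voxels at the default voxel
#'   size, so distinct ground-truth objects can never touch after
#'   discretization.
#' @param seed integer RNG seed; identical spec + seed gives a bit-identical
#'   scene.
#'
#' @return An object of class `scene_spec` (a validated list).
#' @seealso [make_scene()], [render_scene()]
#' @export
scene_spec <- function(shape_zyx = c(16L, 96L, 96L),
                       voxel_size_um = c(0.25, 0.1, 0.1),
                       hypha_radius_um = 1.6,
                       er_tube_radius_um = 0.5,
                       n_rings = 1L,
                       ring_radius_um = 0.7,
                       ring_thickness_um = 0.2,
                       n_vesicles = 12L,
                       vesicle_radius_um_range = c(0.2, 0.35),
                       coloc_fraction = 0.5,
                       cytosol_level = c(red = 0.12, green = 0.08),
                       er_intensity = 0.65,
                       ring_intensity = 0.65,
                       vesicle_intensity = 2.0,
                       min_gap_um = 0.3,
                       seed = 1L) {
  shape_zyx <- as.integer(shape_zyx)
  if (length(shape_zyx) != 3L || any(shape_zyx < 1L))
    stopf("shape_zyx must be 3 positive voxel counts")
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stopf("voxel_size_um must be 3 positive spacings (dz, dy, dx)")
  if (coloc_fraction < 0 || coloc_fraction > 1)
    stopf("coloc_fraction must lie in [0, 1], got %g", coloc_fraction)
  if (length(vesicle_radius_um_range) != 2L ||
      any(vesicle_radius_um_range <= 0) ||
      diff(vesicle_radius_um_range) < 0)
    stopf("vesicle_radius_um_range must be an increasing positive pair")
  if (vesicle_radius_um_range[2] > hypha_radius_um)
    stopf("vesicle radius (max %g um) must not exceed the hyphal radius (%g um)",
          vesicle_radius_um_range[2], hypha_radius_um)
  if (hypha_radius_um <= 0 || er_tube_radius_um <= 0)
    stopf("radii must be positive")
  if (!is_count(n_vesicles) || !is_count(n_rings))
    stopf("n_vesicles and n_rings must be non-negative counts")
  lv <- c(red = NA_real_, green = NA_real_)
  lv[names(cytosol_level) %||% c("red", "green")] <- cytosol_level
  if (anyNA(lv)) stopf("cytosol_level needs red and green entries")
  structure(list(
    shape_zyx = shape_zyx, voxel_size_um = as.numeric(voxel_size_um),
    hypha_radius_um = hypha_radius_um, er_tube_radius_um = er_tube_radius_um,
    n_rings = as.integer(n_rings), ring_radius_um = ring_radius_um,
    ring_thickness_um = ring_thickness_um,
    n_vesicles = as.integer(n_vesicles),
    vesicle_radius_um_range = as.numeric(vesicle_radius_um_range),
    coloc_fraction = coloc_fraction, cytosol_level = lv,
    er_intensity = er_intensity, ring_intensity = ring_intensity,
    vesicle_intensity = vesicle_intensity,
    min_gap_um = min_gap_um, seed = as.integer(seed)
  ), class = "scene_spec")
}

#' Specify the image-formation (acquisition) model
#'
#' The forward model applied to a clean painted scene, in order: green-to-red
#' bleed-through, Gaussian point-spread blur, per-channel photobleaching
#' `exp(-k t)`, Poisson shot noise at `photon_gain` expected photons per unit
#' intensity, and additive Gaussian read noise (in photon units). The read
#' noise is a fixed floor: it does not bleach, which is what makes the
#' Pearson coefficient of a bleaching channel decay even though the
#' coefficient itself is scale-invariant.
#'
#' @param psf_sigma_um numeric (sigma_z, sigma_xy) Gaussian blur in um;
#'   0 disables blur.
#' @param photon_gain expected photons at unit clean intensity; `Inf` gives
#'   the noiseless limit (intensities passed through unchanged).
#' @param read_noise_sd standard deviation of additive Gaussian detector
#'   noise, in photons.
#' @param bleed_alpha fraction `alpha` in \[0, 1) of the clean green signal
#'   added to the red channel before blur (spectral bleed-through of a
#'   bright green fluorophore into the red detector).
#' @param bleed_symmetric also add `alpha` times red into green.
#' @param bleach_rate named numeric `c(red = , green = )`, photobleaching
#'   rate per time step for each channel.
#' @param seed integer seed for the noise draws.
#'
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(psf_sigma_um = c(0.2, 0.08),
                             photon_gain = 25,
                             read_noise_sd = 3,
                             bleed_alpha = 0,
                             bleed_symmetric = FALSE,
                             bleach_rate = c(red = 0, green = 0),
                             seed = 1L) {
  if (length(psf_sigma_um) != 2L || any(psf_sigma_um < 0))
    stopf("psf_sigma_um must be two non-negative values (sigma_z, sigma_xy)")
  if (!(photon_gain > 0)) stopf("photon_gain must be > 0")
  if (read_noise_sd < 0) stopf("read_noise_sd must be >= 0")
  if (bleed_alpha < 0 || bleed_alpha >= 1)
    stopf("bleed_alpha must lie in [0, 1), got %g", bleed_alpha)
  k <- c(red = 0, green = 0)
  k[names(bleach_rate) %||% c("red", "green")] <- bleach_rate
  if (any(k < 0)) stopf("bleach_rate must be >= 0")
  structure(list(
    psf_sigma_um = as.numeric(psf_sigma_um), photon_gain = photon_gain,
    read_noise_sd = read_noise_sd, bleed_alpha = bleed_alpha,
    bleed_symmetric = isTRUE(bleed_symmetric), bleach_rate = k,
    seed = as.integer(seed)
  ), class = "acquisition_spec")
}

# ---- geometry ---------------------------------------------------------------

# label volume ids: 0 outside, 1 cytosol, 2 ER tube, 2+1..2+n_rings rings,
# then vesicles. Painted in that order, so later (smaller, brighter)
# structures override earlier ones and every voxel has exactly one id.
build_label_volume <- function(objects, spec) {
  d <- spec$shape_zyx
  vs <- spec$voxel_size_um
  z <- axis_coords_um(d[1], vs[1])
  y <- axis_coords_um(d[2], vs[2])
  x <- axis_coords_um(d[3], vs[3])
  zc <- d[1] * vs[1] / 2
  yc <- d[2] * vs[2] / 2

  # radial distance from the hyphal axis: (nz, ny) sheet, constant along x
  r_ax2 <- outer((z - zc)^2, (y - yc)^2, `+`)
  lab <- array(0L, d)
  cyt <- array(rep(r_ax2 <= spec$hypha_radius_um^2, d[3]), d)
  lab[cyt] <- 1L
  er <- array(rep(r_ax2 <= spec$er_tube_radius_um^2, d[3]), d)
  lab[er] <- 2L

  spheres <- objects[objects$kind %in% c("perinuclear_ring", "vesicle"), ,
                     drop = FALSE]
  for (i in seq_len(nrow(spheres))) {
    ob <- spheres[i, ]
    r_out <- if (ob$kind == "perinuclear_ring")
      ob$radius_um + spec$ring_thickness_um / 2 else ob$radius_um
    # bounding box in voxel indices keeps the distance evaluation local
    iz <- which(abs(z - ob$z_um) <= r_out)
    iy <- which(abs(y - ob$y_um) <= r_out)
    ix <- which(abs(x - ob$x_um) <= r_out)
    if (!length(iz) || !length(iy) || !length(ix)) next
    d2 <- outer(outer((z[iz] - ob$z_um)^2, (y[iy] - ob$y_um)^2, `+`),
                (x[ix] - ob$x_um)^2, `+`)
    inside <- if (ob$kind == "perinuclear_ring") {
      r_in <- max(ob$radius_um - spec$ring_thickness_um / 2, 0)
      d2 <= r_out^2 & d2 >= r_in^2
    } else {
      d2 <= r_out^2
    }
    sub <- lab[iz, iy, ix, drop = FALSE]
    sub[inside] <- as.integer(ob$id)
    lab[iz, iy, ix] <- sub
  }
  lab
}

#' Generate a ground-truthed hyphal scene
#'
#' Places the static structures (cytosol cylinder, axial ER tube, perinuclear
#' rings) deterministically, then draws vesicle positions by seeded rejection
#' sampling inside the cytosolic annulus around the ER tube, keeping every
#' vesicle clear of the tube, the rings, the cell boundary and all other
#' vesicles by at least `min_gap_um`. Channel membership of each vesicle is
#' Bernoulli(`coloc_fraction`) for dual labelling, otherwise a fair coin
#' picks the single channel.
#'
#' @param spec a [scene_spec()].
#' @param max_tries rejection-sampling retries allowed per vesicle before
#'   the placement is declared infeasible.
#'
#' @return An object of class `ground_truth_scene`: a list with `objects`
#'   (data frame: id, kind, center in um, radius_um, in_red, in_green),
#'   `label` (integer voxel array of object ids, 0 = outside the cell),
#'   `true_f` (realized dual-labelled vesicle fraction; `NaN` when the scene
#'   has no vesicles), and the `spec`.
#' @export
make_scene <- function(spec, max_tries = 1000L) {
  stopifnot(inherits(spec, "scene_spec"))
  d <- spec$shape_zyx
  vs <- spec$voxel_size_um
  ext <- d * vs
  zc <- ext[1] / 2
  yc <- ext[2] / 2

  objects <- data.frame(
    id = c(1L, 2L), kind = c("cytosol", "ER_tube"),
    z_um = c(NA, zc), y_um = c(NA, yc), x_um = c(NA, ext[3] / 2),
    radius_um = c(spec$hypha_radius_um, spec$er_tube_radius_um),
    intensity = c(NA, spec$er_intensity),
    in_red = TRUE, in_green = TRUE, stringsAsFactors = FALSE
  )
  if (spec$n_rings > 0L) {
    rx <- ext[3] * seq_len(spec$n_rings) / (spec$n_rings + 1)
    objects <- rbind(objects, data.frame(
      id = 2L + seq_len(spec$n_rings), kind = "perinuclear_ring",
      z_um = zc, y_um = yc, x_um = rx, radius_um = spec$ring_radius_um,
      intensity = spec$ring_intensity, in_red = TRUE, in_green = TRUE,
      stringsAsFactors = FALSE
    ))
  }

  nv <- spec$n_vesicles
  if (nv > 0L) {
    ring_centers <- objects[objects$kind == "perinuclear_ring",
                            c("z_um", "y_um", "x_um"), drop = FALSE]
    ring_excl <- spec$ring_radius_um + spec$ring_thickness_um / 2
    ves <- withr::with_seed(spec$seed, {
      centers <- matrix(NA_real_, nv, 3)
      radii <- stats::runif(nv, spec$vesicle_radius_um_range[1],
                            spec$vesicle_radius_um_range[2])
      dual <- stats::runif(nv) < spec$coloc_fraction
      red_only <- stats::runif(nv) < 0.5
      for (i in seq_len(nv)) {
        r <- radii[i]
        lo <- spec$er_tube_radius_um + r + spec$min_gap_um
        hi <- spec$hypha_radius_um - r
        if (hi <= lo)
          stopf(paste0("no room for a vesicle of radius %.3g um between the ",
                       "ER tube (%.3g um) and the cell wall (%.3g um)"),
                r, spec$er_tube_radius_um, spec$hypha_radius_um)
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          rad <- sqrt(stats::runif(1, lo^2, hi^2))  # uniform over the annulus
          th <- stats::runif(1, 0, 2 * pi)
          cand <- c(zc + rad * cos(th), yc + rad * sin(th),
                    stats::runif(1, r + spec$min_gap_um,
                                 ext[3] - r - spec$min_gap_um))
          if (cand[1] < r || cand[1] > ext[1] - r ||
              cand[2] < r || cand[2] > ext[2] - r) next
          ok <- TRUE
          if (nrow(ring_centers) > 0) {
            dr <- sqrt(dist2_um(matrix(cand, 1), as.matrix(ring_centers)))
            ok <- all(dr > ring_excl + r + spec$min_gap_um)
          }
          if (ok && i > 1L) {
            prev <- centers[seq_len(i - 1L), , drop = FALSE]
            dp <- sqrt(dist2_um(matrix(cand, 1), prev))
            ok <- all(dp > radii[seq_len(i - 1L)] + r + spec$min_gap_um)
          }
          if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
        }
        if (!placed)
          stopf(paste0("could not place vesicle %d of %d after %d tries; the ",
                       "scene (shape %s, hypha radius %.3g um) is too crowded"),
                i, nv, max_tries, paste(d, collapse = "x"),
                spec$hypha_radius_um)
      }
      list(centers = centers, radii = radii, dual = dual,
           red_only = red_only)
    })
    objects <- rbind(objects, data.frame(
      id = max(objects$id) + seq_len(nv), kind = "vesicle",
      z_um = ves$centers[, 1], y_um = ves$centers[, 2],
      x_um = ves$centers[, 3], radius_um = ves$radii,
      intensity = spec$vesicle_intensity,
      in_red = ves$dual | ves$red_only,
      in_green = ves$dual | !ves$red_only, stringsAsFactors = FALSE
    ))
    true_f <- mean(ves$dual)
  } else {
    true_f <- NaN
  }

  structure(list(
    objects = objects,
    label = build_label_volume(objects, spec),
    true_f = true_f, spec = spec
  ), class = "ground_truth_scene")
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  nv <- sum(x$objects$kind == "vesicle")
  cat(sprintf(
    "<ground_truth_scene> %s voxels, %d vesicle(s), realized coloc fraction %s\n",
    paste(x$spec$shape_zyx, collapse = "x"), nv, format(x$true_f)))
  invisible(x)
}

# clean per-channel intensity volumes (no optics, no noise)
paint_channels <- function(scene) {
  spec <- scene$spec
  lab <- scene$label
  red <- array(0, dim(lab))
  green <- array(0, dim(lab))
  # a structure absent from a channel is filled at cytosol level: unlabelled
  # compartments are spectrally indistinguishable from the surrounding cytosol
  for (i in seq_len(nrow(scene$objects))) {
    ob <- scene$objects[i, ]
    vox <- lab == ob$id
    if (ob$kind == "cytosol") {
      red[vox] <- spec$cytosol_level[["red"]]
      green[vox] <- spec$cytosol_level[["green"]]
    } else {
      red[vox] <- if (ob$in_red) ob$intensity else spec$cytosol_level[["red"]]
      green[vox] <- if (ob$in_green) ob$intensity else spec$cytosol_level[["green"]]
    }
  }
  list(red = red, green = green)
}

#' Advance a scene by one motion step
#'
#' Perturbs every vesicle centre by an isotropic Gaussian step (sd
#' `motion_sd_um` per axis), clips the centre so the vesicle stays inside
#' the volume, and rebuilds the label volume. The ER tube and rings are
#' static; object ids are preserved, so tracks can be scored against truth.
#'
#' @param scene a `ground_truth_scene`.
#' @param motion_sd_um per-axis step standard deviation in um (0 = static).
#' @param seed integer seed for the step.
#' @return The moved `ground_truth_scene`.
#' @export
advance_time <- function(scene, motion_sd_um, seed = scene$spec$seed + 1L) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  if (motion_sd_um < 0) stopf("motion_sd_um must be >= 0")
  if (motion_sd_um == 0) return(scene)
  iv <- which(scene$objects$kind == "vesicle")
  if (!length(iv)) return(scene)
  ext <- scene$spec$shape_zyx * scene$spec$voxel_size_um
  ob <- scene$objects
  step <- withr::with_seed(seed,
    matrix(stats::rnorm(3 * length(iv), 0, motion_sd_um), ncol = 3))
  for (j in seq_along(iv)) {
    i <- iv[j]
    r <- ob$radius_um[i]
    ob$z_um[i] <- min(max(ob$z_um[i] + step[j, 1], r), ext[1] - r)
    ob$y_um[i] <- min(max(ob$y_um[i] + step[j, 2], r), ext[2] - r)
    ob$x_um[i] <- min(max(ob$x_um[i] + step[j, 3], r), ext[3] - r)
  }
  scene$objects <- ob
  scene$label <- build_label_volume(ob, scene$spec)
  scene
}
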