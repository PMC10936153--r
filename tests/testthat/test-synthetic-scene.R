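test_that("scene specs validate their invariants", {
  expect_error(scene_spec(shape_zyx = c(0, 10, 10)), "positive")
  expect_error(scene_spec(coloc_fraction = 1.2), "\\[0, 1\\]")
  expect_error(scene_spec(vesicle_radius_um_range = c(2, 3),
                          hypha_radius_um = 1.5), "hyphal radius")
  expect_error(acquisition_spec(bleed_alpha = 1), "bleed_alpha")
  expect_error(acquisition_spec(photon_gain = 0), "photon_gain")
})

test_that("a vesicle-free scene has only ER structures and undefined true_f", {
  sc <- make_scene(scene_spec(n_vesicles = 0, seed = 4))
  expect_true(all(sc$objects$kind %in% c("cytosol", "ER_tube", "perinuclear_ring")))
  expect_true(is.nan(sc$true_f))
})

test_that("coloc_fraction = 1 dual-labels every vesicle; f = 0 none", {
  sc1 <- make_scene(scene_spec(n_vesicles = 10, coloc_fraction = 1, seed = 2))
  ves <- sc1$objects[sc1$objects$kind == "vesicle", ]
  expect_true(all(ves$in_red & ves$in_green))
  expect_identical(sc1$true_f, 1)
  sc0 <- make_scene(scene_spec(n_vesicles = 10, coloc_fraction = 0, seed = 2))
  ves0 <- sc0$objects[sc0$objects$kind == "vesicle", ]
  expect_true(!any(ves0$in_red & ves0$in_green))
  expect_true(all(xor(ves0$in_red, ves0$in_green)))
  expect_identical(sc0$true_f, 0)
})

test_that("realized coloc fraction stays within binomial bounds at f = 0.5", {
  # larger scene so 200 vesicles fit; truth is the exact dual-label count
  sc <- make_scene(scene_spec(shape_zyx = c(16, 96, 480), n_vesicles = 200,
                              coloc_fraction = 0.5, seed = 7))
  ves <- sc$objects[sc$objects$kind == "vesicle", ]
  expect_equal(sc$true_f, mean(ves$in_red & ves$in_green))
  expect_gte(sc$true_f, 0.4)
  expect_lte(sc$true_f, 0.6)
})

test_that("scene generation is deterministic and vesicles respect geometry", {
  sc1 <- make_scene(scene_spec(seed = 9))
  sc2 <- make_scene(scene_spec(seed = 9))
  expect_identical(sc1$objects, sc2$objects)
  expect_identical(sc1$label, sc2$label)
  spec <- sc1$spec
  ves <- sc1$objects[sc1$objects$kind == "vesicle", ]
  ext <- spec$shape_zyx * spec$voxel_size_um
  ax <- sqrt((ves$z_um - ext[1] / 2)^2 + (ves$y_um - ext[2] / 2)^2)
  expect_true(all(ax + ves$radius_um <= spec$hypha_radius_um + 1e-9))
  expect_true(all(ax - ves$radius_um >= spec$er_tube_radius_um - 1e-9))
  # pairwise separation: no two vesicles overlap
  n <- nrow(ves)
  cen <- as.matrix(ves[, c("z_um", "y_um", "x_um")])
  dd <- as.matrix(dist(cen))
  sep <- outer(ves$radius_um, ves$radius_um, `+`)
  expect_true(all(dd[upper.tri(dd)] > sep[upper.tri(sep)]))
})

test_that("overcrowded placement fails with an informative error", {
  expect_error(
    make_scene(scene_spec(shape_zyx = c(12, 48, 48), n_vesicles = 400),
               max_tries = 50),
    "too crowded|no room")
})

test_that("every labelled voxel maps to exactly one object id", {
  sc <- make_scene(scene_spec(seed = 5))
  ids <- sort(unique(as.vector(sc$label)))
  expect_true(all(ids %in% c(0L, sc$objects$id)))
  # conservation: painted intensity equals per-object volume x intensity
  painted <- hyphacoloc:::paint_channels(sc)
  for (ch in c("red", "green")) {
    expected <- sum(vapply(seq_len(nrow(sc$objects)), function(i) {
      ob <- sc$objects[i, ]
      vol <- sum(sc$label == ob$id)
      flag <- if (ch == "red") ob$in_red else ob$in_green
      lvl <- if (ob$kind == "cytosol" || !flag)
        sc$spec$cytosol_level[[ch]] else ob$intensity
      vol * lvl
    }, numeric(1)))
    expect_equal(sum(painted[[ch]]), expected, tolerance = 1e-12)
  }
})

test_that("noiseless rendering reproduces painted intensities exactly", {
  sc <- make_scene(scene_spec(seed = 3))
  pair <- render_scene(sc, noiseless_acq())
  painted <- hyphacoloc:::paint_channels(sc)
  expect_identical(pair$red, painted$red)
  expect_identical(pair$green, painted$green)
})

test_that("rendering is deterministic under a fixed seed and non-negative", {
  sc <- make_scene(scene_spec(seed = 6))
  acq <- acquisition_spec(seed = 42)
  p1 <- render_scene(sc, acq)
  p2 <- render_scene(sc, acq)
  expect_identical(p1$red, p2$red)
  expect_identical(p1$green, p2$green)
  expect_gte(min(p1$red), 0)
  expect_gte(min(p1$green), 0)
})

test_that("bleed-through puts red signal into green-only vesicles", {
  sc <- make_scene(scene_spec(coloc_fraction = 0, seed = 8))
  ob <- sc$objects
  gv <- ob$id[ob$kind == "vesicle" & ob$in_green & !ob$in_red]
  expect_gt(length(gv), 0)
  p0 <- render_scene(sc, noiseless_acq())
  p3 <- render_scene(sc, noiseless_acq(bleed_alpha = 0.5))
  vox <- sc$label == gv[1]
  expect_equal(mean(p0$red[vox]), sc$spec$cytosol_level[["red"]])
  expect_equal(mean(p3$red[vox]),
               sc$spec$cytosol_level[["red"]] + 0.5 * sc$spec$vesicle_intensity,
               tolerance = 1e-12)
})

test_that("bleaching against a fixed noise floor lowers signal-to-background", {
  # mean over seeds of (foreground mean / background mean) per frame must
  # decay: the signal bleaches while read noise does not
  ratios <- sapply(1:20, function(s) {
    sc <- make_scene(scene_spec(seed = s))
    acq <- acquisition_spec(bleach_rate = c(red = 0.3, green = 0),
                            seed = s + 50)
    pair <- render_scene(sc, acq, t_steps = 6)
    fg <- channel_truth_mask(sc, "red")
    bg <- sc$label == 0L
    sapply(1:6, function(t) {
      fr <- get_frame(pair, t)
      mean(fr$red[fg]) / mean(fr$red[bg])
    })
  })
  expect_true(all(diff(rowMeans(ratios)) < 0))
})

test_that("zero motion leaves the scene unchanged; large steps are clipped", {
  sc <- make_scene(scene_spec(seed = 2))
  expect_identical(advance_time(sc, 0), sc)
  moved <- advance_time(sc, 50, seed = 99)
  ves <- moved$objects[moved$objects$kind == "vesicle", ]
  ext <- sc$spec$shape_zyx * sc$spec$voxel_size_um
  expect_true(all(ves$z_um >= ves$radius_um & ves$z_um <= ext[1] - ves$radius_um))
  expect_true(all(ves$y_um >= ves$radius_um & ves$y_um <= ext[2] - ves$radius_um))
  expect_true(all(ves$x_um >= ves$radius_um & ves$x_um <= ext[3] - ves$radius_um))
  expect_identical(moved$objects$id, sc$objects$id)
})

test_that("mean squared displacement grows linearly with step count", {
  sc <- make_scene(scene_spec(n_vesicles = 15, seed = 12))
  sd_step <- 0.05
  pos <- function(s) as.matrix(
    s$objects[s$objects$kind == "vesicle", c("z_um", "y_um", "x_um")])
  p0 <- pos(sc)
  cur <- sc
  msd <- numeric(100)
  for (t in 1:100) {
    cur <- advance_time(cur, sd_step, seed = 1000L + t)
    msd[t] <- mean(rowSums((pos(cur) - p0)^2))
  }
  fit <- stats::lm(msd ~ seq_along(msd))
  slope <- unname(coef(fit)[2])
  expect_gt(stats::cor(msd, seq_along(msd)), 0.95)
  # 3D diffusion: msd ~ 3 sd^2 t (clipping at boundaries only dampens it)
  expect_gt(slope, 3 * sd_step^2 * 0.6)
  expect_lt(slope, 3 * sd_step^2 * 1.5)
})
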